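# Within-mode and across-K performance scores. For equal-K pairs the
# pairwise similarity under the optimal alignment is G' = 1 - sqrt(D),
# with D the optimal alignment dissimilarity, so per-mode scores can be
# read directly off the replicate graph.

#' Mean pairwise similarity within a mode
#'
#' H' of a mode is the mean of G' over all unordered member pairs, each
#' evaluated under the pair's optimal alignment; singleton modes score 1
#' by convention.
#'
#' @param graph a [build_replicate_graph()] result.
#' @param mode character vector of member replicate ids.
#' @export
mode_h_prime <- function(graph, mode) {
  if (!length(mode)) stop("mode is empty")
  if (length(mode) == 1L) return(1)
  idx <- match(mode, graph$node_ids)
  if (anyNA(idx)) stop("mode members missing from the replicate graph")
  D <- graph$dissimilarities[idx, idx]
  mean(1 - sqrt(D[upper.tri(D)]))
}

#' Weighted within-mode similarity scores at one K
#'
#' Combines per-mode H' values into the replicate-weighted score
#' \deqn{\bar H_K = \frac{1}{R_K} \sum_\ell |M_\ell| H'_\ell}
#' and its singleton-excluded variant
#' \deqn{\tilde H_K = \frac{1}{R_K - s_K} \sum_{|M_\ell| > 1} |M_\ell|
#'   H'_\ell,}
#' which strips the automatic score of 1 that singleton modes contribute.
#' When every mode is a singleton, the excluded score is undefined and
#' reported as `NA`.
#'
#' @param mode_set a [detect_modes()] result.
#' @param per_mode_H numeric vector of H' values, one per mode in order.
#' @return a `similarity_scores` list: `per_mode_H`, `weighted_H`,
#'   `singleton_excluded_H`, `singleton_count`.
#' @export
weighted_scores <- function(mode_set, per_mode_H) {
  sizes <- lengths(mode_set$modes)
  if (length(per_mode_H) != length(sizes)) {
    stop("need one H' value per mode")
  }
  R <- sum(sizes)
  s <- sum(sizes == 1L)
  h_bar <- sum(sizes * per_mode_H) / R
  keep <- sizes > 1L
  h_tilde <- if (any(keep)) sum(sizes[keep] * per_mode_H[keep]) / (R - s) else NA_real_
  structure(
    list(per_mode_H = per_mode_H, weighted_H = h_bar,
         singleton_excluded_H = h_tilde, singleton_count = s),
    class = "similarity_scores"
  )
}

#' Within-mode scores straight from a replicate graph
#'
#' Convenience wrapper computing [mode_h_prime()] for every mode and
#' feeding the results to [weighted_scores()].
#'
#' @inheritParams mode_h_prime
#' @param mode_set a [detect_modes()] result over the same graph.
#' @export
compute_scores <- function(graph, mode_set) {
  h <- vapply(mode_set$modes, function(m) mode_h_prime(graph, m), 0)
  weighted_scores(mode_set, h)
}

#' @export
print.similarity_scores <- function(x, ...) {
  cat("within-mode similarity: H-bar = ", format(x$weighted_H, digits = 4),
      ", singleton-excluded = ",
      if (is.na(x$singleton_excluded_H)) "NA"
      else format(x$singleton_excluded_H, digits = 4),
      " (", x$singleton_count, " singleton(s))\n", sep = "")
  invisible(x)
}

#' Merged-column G' between modes at K and K + 1
#'
#' Under the optimal many-to-one alignment of a (K+1)-cluster mode onto a
#' K-cluster mode, exactly two of the larger mode's clusters collide on
#' one target. Summing those two columns produces an N x K matrix whose
#' G' similarity with the smaller mode's consensus is the across-K score.
#'
#' @param mode_K mode consensus with K clusters.
#' @param mode_K1 mode consensus with K + 1 clusters.
#' @param alignment many-to-one alignment of `mode_K1`'s clusters onto
#'   `mode_K`'s (e.g. from [align_modes_merge()] or [align_modes_direct()]);
#'   must collide exactly one cluster pair.
#' @inheritParams align_modes_direct
#' @export
across_k_gprime <- function(mode_K, mode_K1, alignment,
                            method = c("mean", "representative")) {
  method <- match.arg(method)
  Q <- as_matrix(consensus_matrix(mode_K, method))
  P <- as_matrix(consensus_matrix(mode_K1, method))
  map <- alignment_mapping(alignment)
  K <- ncol(Q)
  if (ncol(P) != K + 1L || length(map) != K + 1L) {
    stop("expected cluster counts K and K + 1 with a length K + 1 alignment")
  }
  hits <- tabulate(map, nbins = K)
  if (!(sum(hits == 2L) == 1L && sum(hits == 1L) == K - 1L)) {
    stop("alignment must collide exactly one cluster pair")
  }
  merged <- vapply(seq_len(K), function(k) {
    rowSums(P[, map == k, drop = FALSE])
  }, numeric(nrow(P)))
  g_prime(Q, merged)
}
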