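# Across-K alignment: consensus memberships of modes at adjacent entries
# of the decreasing sorted list of distinct K values are aligned pairwise,
# either directly (many-to-one ILP between the consensus matrices, any K
# gap) or by the merge strategy (enumerate all ways of summing one pair of
# columns of the larger-K mode, then equal-K alignment; consecutive K
# only). Edges carry weight mu = 1 - D; the maximum-weight edge of each
# layer pair is its anchor.

#' Directly align two mode consensuses
#'
#' Many-to-one alignment of the consensus matrices, with the larger-K mode
#' as source. The edge weight is \eqn{\mu = 1 - D}; for unequal K the
#' dissimilarity can exceed 1, in which case the negative weight is kept
#' (with a warning), not clamped.
#'
#' @param A mode consensus with the larger (or equal) cluster count.
#' @param B mode consensus with the smaller (or equal) cluster count.
#' @param method which consensus matrix to align, `"mean"` (default) or
#'   `"representative"`.
#' @return list with `alignment` (source = larger K), `cost`, `weight`.
#' @export
align_modes_direct <- function(A, B, method = c("mean", "representative")) {
  method <- match.arg(method)
  Am <- as_matrix(consensus_matrix(A, method))
  Bm <- as_matrix(consensus_matrix(B, method))
  if (nrow(Am) != nrow(Bm)) stop("modes cover different numbers of individuals")
  al <- align_pair(Am, Bm)
  mu <- 1 - al$cost
  if (mu < 0) {
    warning("across-K mode pair aligned with negative weight ",
            format(mu, digits = 4))
  }
  list(alignment = al, cost = al$cost, weight = mu)
}

# expand a merge candidate's equal-K permutation into the many-to-one
# mapping from the (K+1)-cluster mode's columns onto the K-cluster mode
expand_merge_mapping <- function(pair, K1, perm) {
  kept <- setdiff(seq_len(K1), pair[2L])   # column pair[2] folded into pair[1]
  pos <- match(seq_len(K1), kept)
  pos[pair[2L]] <- match(pair[1L], kept)
  perm[pos]
}

#' Align two modes by merging clusters of the larger-K mode
#'
#' Enumerates all `choose(K+1, 2)` ways of summing one pair of columns of
#' the (K+1)-cluster mode `B` into a single column, aligns each merged
#' K-column matrix to the K-cluster mode `A` by equal-K alignment, and
#' keeps the candidate with the smallest dissimilarity (ties: the
#' lexicographically smallest merged pair).
#'
#' @param A mode consensus with K clusters.
#' @param B mode consensus with K + 1 clusters.
#' @inheritParams align_modes_direct
#' @return list with the winning `merged_pair`, `merged_matrix`,
#'   `permutation` (merged columns onto `A`), the expanded many-to-one
#'   `alignment` from `B`'s K + 1 clusters onto `A`'s K, `cost`, `weight`,
#'   and `candidates` (a data frame of every merged pair and its cost).
#' @export
align_modes_merge <- function(A, B, method = c("mean", "representative")) {
  method <- match.arg(method)
  Am <- as_matrix(consensus_matrix(A, method))
  Bm <- as_matrix(consensus_matrix(B, method))
  if (ncol(Bm) != ncol(Am) + 1L) {
    stop("merge alignment needs cluster counts K and K + 1; got ",
         ncol(Am), " and ", ncol(Bm))
  }
  if (nrow(Am) != nrow(Bm)) stop("modes cover different numbers of individuals")
  K1 <- ncol(Bm)

  pairs <- utils::combn(K1, 2L)
  cand <- vector("list", ncol(pairs))
  for (c_idx in seq_len(ncol(pairs))) {
    a <- pairs[1L, c_idx]; b <- pairs[2L, c_idx]
    merged <- Bm[, -b, drop = FALSE]
    merged[, match(a, setdiff(seq_len(K1), b))] <- Bm[, a] + Bm[, b]
    al <- align_pair(merged, Am)   # equal K: source = merged
    cand[[c_idx]] <- list(pair = c(a, b), merged = merged, al = al,
                          cost = al$cost)
  }
  costs <- vapply(cand, `[[`, 0, "cost")
  win <- which(costs <= min(costs) + 1e-12)[1L]  # combn order is lexicographic
  w <- cand[[win]]
  mapping <- expand_merge_mapping(w$pair, K1, w$al$mapping)
  expanded <- new_alignment(mapping, ncol(Am),
                            replicate_dissimilarity(Bm, Am, mapping))
  list(merged_pair = w$pair,
       merged_matrix = membership_matrix(w$merged),
       permutation = w$al,
       alignment = expanded,
       cost = w$cost,
       weight = 1 - w$cost,
       candidates = data.frame(a = pairs[1L, ], b = pairs[2L, ], cost = costs))
}

#' Assemble the multipartite graph of modes across K
#'
#' Layers are the distinct K values sorted in decreasing order; every mode
#' pair between adjacent layers receives an edge (alignment, dissimilarity
#' D, weight 1 - D). The anchor of a layer pair is its maximum-weight
#' edge, ties broken by larger combined mode size and then by smallest
#' mode indices.
#'
#' @param layers named list (names = K values) of lists of
#'   [build_consensus()] results, each inner list in mode order.
#' @param method `"direct"` (any K gaps) or `"merge"` (requires adjacent
#'   sorted K values to be consecutive integers).
#' @param consensus_method consensus matrix used for alignment.
#' @return an `across_k_graph`: `k_values` (decreasing), `layers`, `edges`
#'   (one data-frame-like list per adjacent layer pair), `anchors`.
#' @export
build_across_k_graph <- function(layers, method = c("direct", "merge"),
                                 consensus_method = c("mean", "representative")) {
  method <- match.arg(method)
  consensus_method <- match.arg(consensus_method)
  if (!length(layers)) stop("no mode layers supplied")
  ks <- as.integer(names(layers))
  if (anyNA(ks)) stop("layers must be named by their K values")
  ord <- order(ks, decreasing = TRUE)
  ks <- ks[ord]
  layers <- layers[ord]

  edges <- list()
  anchors <- list()
  if (length(ks) > 1L) {
    for (p in seq_len(length(ks) - 1L)) {
      k_hi <- ks[p]; k_lo <- ks[p + 1L]
      if (method == "merge" && k_hi != k_lo + 1L) {
        stop("merge alignment requires consecutive K values; got ",
             k_hi, " and ", k_lo)
      }
      hi <- layers[[p]]; lo <- layers[[p + 1L]]
      recs <- list()
      for (i in seq_along(hi)) {
        for (j in seq_along(lo)) {
          e <- if (method == "direct" || k_hi == k_lo) {
            align_modes_direct(hi[[i]], lo[[j]], method = consensus_method)
          } else {
            align_modes_merge(lo[[j]], hi[[i]], method = consensus_method)
          }
          recs[[length(recs) + 1L]] <- list(
            hi_mode = i, lo_mode = j,
            alignment = e$alignment, cost = e$cost, weight = e$weight,
            merged_pair = e$merged_pair,
            size = length(hi[[i]]$member_ids) + length(lo[[j]]$member_ids)
          )
        }
      }
      mus <- vapply(recs, `[[`, 0, "weight")
      sizes <- vapply(recs, `[[`, 0, "size")
      his <- vapply(recs, `[[`, 0, "hi_mode")
      los <- vapply(recs, `[[`, 0, "lo_mode")
      best <- order(-mus, -sizes, his, los)[1L]
      key <- paste(k_hi, k_lo, sep = "-")
      edges[[key]] <- recs
      anchors[[key]] <- recs[[best]]
    }
  }
  structure(
    list(k_values = ks, layers = layers, edges = edges, anchors = anchors,
         method = method, consensus_method = consensus_method),
    class = "across_k_graph"
  )
}

#' @export
print.across_k_graph <- function(x, ...) {
  cat("across-K mode graph (", x$method, "): layers K = ",
      paste(x$k_values, collapse = ", "), "\n", sep = "")
  for (key in names(x$edges)) {
    a <- x$anchors[[key]]
    cat("  ", key, ": ", length(x$edges[[key]]), " edge(s), anchor (M",
        a$hi_mode, ", M", a$lo_mode, ") weight ",
        format(a$weight, digits = 4), "\n", sep = "")
  }
  invisible(x)
}
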