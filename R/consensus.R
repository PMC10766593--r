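# Mode consensus: every member is permuted into a common cluster frame —
# the frame of the mode's most central member (largest within-mode weight
# sum) — reusing the pairwise optimal alignments already stored in the
# replicate graph. The mean of the aligned members is the default
# consensus; the central member itself is the representative consensus.

#' Most central member of a mode
#'
#' Returns the replicate with the largest sum of edge weights to the other
#' members of its mode; singleton modes return their only member, and ties
#' go to the smallest replicate id.
#'
#' @param graph a [build_replicate_graph()] result.
#' @param mode character vector of member replicate ids.
#' @export
select_representative <- function(graph, mode) {
  if (!length(mode)) stop("mode is empty")
  mode <- sort(mode)
  if (length(mode) == 1L) return(mode)
  idx <- match(mode, graph$node_ids)
  if (anyNA(idx)) stop("mode members missing from the replicate graph")
  W <- graph$weights[idx, idx]
  diag(W) <- 0
  sums <- rowSums(W)
  mode[which.max(sums)]  # ties: first of the sorted ids
}

#' Consensus membership of a mode
#'
#' Aligns each member into the representative's cluster frame via the
#' stored pairwise optimal alignments (no new optimization) and averages
#' the aligned matrices entrywise. Rows of the mean remain unit-sum
#' because averaging preserves row-stochasticity.
#'
#' @param graph a [build_replicate_graph()] result covering the mode.
#' @param mode character vector of member replicate ids.
#' @param replicates the list of [q_replicate()]s the graph was built from.
#' @return a `mode_consensus`: `K`, `member_ids`, `mean_matrix`,
#'   `representative_id`, `representative_matrix`, and per-member
#'   `member_permutations` into the common frame.
#' @export
build_consensus <- function(graph, mode, replicates) {
  mode <- sort(mode)
  rep_id <- select_representative(graph, mode)
  by_id <- stats::setNames(replicates, vapply(replicates, `[[`, "", "id"))
  if (!all(mode %in% names(by_id))) stop("mode members missing from replicate list")
  K <- by_id[[rep_id]]$K

  perms <- list()
  aligned <- list()
  for (id in mode) {
    if (id == rep_id) {
      perms[[id]] <- seq_len(K)
      aligned[[id]] <- as_matrix(by_id[[id]])
    } else {
      al <- graph$alignments[[pair_key(id, rep_id)]]
      if (is.null(al)) stop("no stored alignment from ", id, " to ", rep_id)
      perms[[id]] <- al$mapping
      aligned[[id]] <- apply_alignment(by_id[[id]], al)
    }
  }
  mean_m <- Reduce(`+`, aligned) / length(aligned)
  structure(
    list(K = K, member_ids = mode, mean_matrix = membership_matrix(mean_m),
         representative_id = rep_id,
         representative_matrix = by_id[[rep_id]]$matrix,
         member_permutations = perms),
    class = "mode_consensus"
  )
}

#' Extract a mode's consensus matrix
#'
#' @param consensus a [build_consensus()] result.
#' @param method `"mean"` (default) or `"representative"`.
#' @export
consensus_matrix <- function(consensus, method = c("mean", "representative")) {
  method <- match.arg(method)
  if (method == "mean") consensus$mean_matrix else consensus$representative_matrix
}

#' @export
print.mode_consensus <- function(x, ...) {
  cat("mode consensus: K = ", x$K, ", ", length(x$member_ids),
      " member(s), representative ", x$representative_id, "\n", sep = "")
  invisible(x)
}
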