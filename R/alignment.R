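# Optimal many-to-one cluster alignment.
#
# An alignment maps each of K1 source clusters to one of K2 <= K1 target
# clusters so that every target is hit at least once (a surjection; a
# permutation when K1 = K2), minimizing the summed cluster costs. This is a
# binary integer program over the K1 x K2 indicator matrix W:
#   min sum_ij W_ij C_ij   s.t.  row sums = 1, column sums >= 1, W binary.
# Cluster counts in practice are small (tens at most), so the program is
# solved exactly by depth-first branch-and-bound over the rows of W with an
# admissible surjectivity-aware lower bound; no LP relaxation is involved.

new_alignment <- function(mapping, K2, cost) {
  mapping <- as.integer(mapping)
  W <- matrix(0L, length(mapping), K2)
  W[cbind(seq_along(mapping), mapping)] <- 1L
  structure(list(mapping = mapping, indicator = W, cost = cost),
            class = "cluster_alignment")
}

#' @export
print.cluster_alignment <- function(x, ...) {
  cat("cluster alignment: (", paste(x$mapping, collapse = ", "),
      "), cost ", format(x$cost, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Cost matrix between the clusters of two replicates
#'
#' Entry (i, j) is the [cluster_cost()] between source cluster i and target
#' cluster j. The caller orients the pair so the source has at least as
#' many clusters as the target; [align_pair()] does this automatically.
#'
#' @param Q source membership matrix (K1 clusters, K1 >= K2).
#' @param P target membership matrix (K2 clusters).
#' @return K1 x K2 numeric cost matrix.
#' @export
build_cost_matrix <- function(Q, P) {
  Q <- as_matrix(Q); P <- as_matrix(P)
  if (nrow(Q) != nrow(P)) stop("replicates have different numbers of individuals")
  if (ncol(Q) < ncol(P)) {
    stop("source must have at least as many clusters as target; swap the arguments")
  }
  N <- nrow(Q)
  # (q_i - p_j)^2 summed over individuals, for all column pairs at once;
  # clamp the tiny negatives the expansion can produce for identical columns
  crossprod_term <- crossprod(Q, P)
  pmax((outer(colSums(Q^2), colSums(P^2), `+`) - 2 * crossprod_term), 0) / (2 * N)
}

# minimum completion cost of the surjection program given rows 1..(i-1)
# already mapped (covered = logical over targets, cost so far excluded).
# Returns Inf when infeasible.
surjection_completion <- function(C, start_row, covered) {
  K1 <- nrow(C); K2 <- ncol(C)
  row_min <- apply(C, 1L, min)
  # suffix sums of per-row minima for the cheap part of the bound
  suffix <- rev(cumsum(rev(row_min)))
  suffix <- c(suffix, 0)
  best <- Inf

  rec <- function(i, covered, cost) {
    uncovered <- which(!covered)
    remaining <- K1 - i + 1L
    if (length(uncovered) > remaining) return(invisible())
    if (i > K1) {
      if (cost < best) best <<- cost
      return(invisible())
    }
    lb <- cost + suffix[i]
    if (length(uncovered)) {
      rows <- i:K1
      for (j in uncovered) {
        lb <- lb + min(C[rows, j] - row_min[rows])
      }
    }
    if (lb >= best - 1e-12) return(invisible())
    for (j in seq_len(K2)) {
      cov2 <- covered
      cov2[j] <- TRUE
      rec(i + 1L, cov2, cost + C[i, j])
    }
  }
  rec(start_row, covered, 0)
  best
}

#' Solve the cluster-alignment integer program exactly
#'
#' Finds the minimum-cost many-to-one mapping for a cost matrix with
#' K1 >= K2 by exact branch-and-bound over the binary indicator variables.
#' Among co-optimal mappings the lexicographically smallest (reading
#' alpha(1), alpha(2), ... as a word) is returned: after the optimal cost
#' is known, each alpha(i) in turn is fixed to the smallest target whose
#' completion can still attain the optimum (within 1e-9). The returned
#' indicator matrix is verified against the constraint system.
#'
#' @param C K1 x K2 cost matrix, K1 >= K2, finite entries.
#' @return a `cluster_alignment`: `mapping` (length K1), binary `indicator`
#'   matrix, and the optimal `cost`.
#' @export
solve_alignment_ilp <- function(C) {
  C <- as.matrix(C)
  K1 <- nrow(C); K2 <- ncol(C)
  if (K2 < 1L || K1 < K2) stop("cost matrix needs K1 >= K2 >= 1")
  if (any(!is.finite(C))) stop("cost matrix entries must be finite")

  opt <- surjection_completion(C, 1L, rep(FALSE, K2))
  if (!is.finite(opt)) stop("internal error: surjection program infeasible")

  tol <- 1e-9
  mapping <- integer(K1)
  covered <- rep(FALSE, K2)
  cost_so_far <- 0
  for (i in seq_len(K1)) {
    fixed <- FALSE
    for (j in seq_len(K2)) {
      cov2 <- covered
      cov2[j] <- TRUE
      rest <- if (i < K1) {
        surjection_completion(C, i + 1L, cov2)
      } else if (all(cov2)) 0 else Inf
      if (cost_so_far + C[i, j] + rest <= opt + tol) {
        mapping[i] <- j
        covered <- cov2
        cost_so_far <- cost_so_far + C[i, j]
        fixed <- TRUE
        break
      }
    }
    if (!fixed) stop("internal error: no optimality-preserving target for row ", i)
  }

  al <- new_alignment(mapping, K2, cost_so_far)
  verify_alignment(al, C)
  al
}

# defense against arithmetic drift: the indicator must satisfy the
# constraint system and reproduce the reported objective
verify_alignment <- function(al, C) {
  W <- al$indicator
  stopifnot(all(rowSums(W) == 1L), all(colSums(W) >= 1L),
            all(W %in% c(0L, 1L)))
  if (abs(sum(W * C) - al$cost) > 1e-9) {
    stop("internal error: alignment cost inconsistent with its indicator")
  }
  invisible(al)
}

# number of surjections [K1] -> [K2], by inclusion-exclusion
count_surjections <- function(K1, K2) {
  j <- 0:K2
  sum((-1)^j * choose(K2, j) * (K2 - j)^K1)
}

#' Exhaustive-enumeration alignment oracle
#'
#' Enumerates every surjective mapping in lexicographic order and returns
#' the minimum-cost one, breaking ties identically to
#' [solve_alignment_ilp()] (lexicographically smallest mapping within 1e-9
#' of the optimum). Intended as an independent check of the
#' branch-and-bound solver on small instances.
#'
#' @param C K1 x K2 cost matrix with K1 >= K2.
#' @param max_enumeration guard on the number of surjections (default 1e6).
#' @return a `cluster_alignment`.
#' @export
brute_force_alignment <- function(C, max_enumeration = 1e6) {
  C <- as.matrix(C)
  K1 <- nrow(C); K2 <- ncol(C)
  if (K2 < 1L || K1 < K2) stop("cost matrix needs K1 >= K2 >= 1")
  if (count_surjections(K1, K2) > max_enumeration) {
    stop("too many surjections to enumerate (> ", format(max_enumeration), ")")
  }

  best_cost <- Inf
  best_map <- NULL
  chosen <- integer(K1)
  # pass 1: exact minimum; pass 2: first (lexicographic) mapping within tol
  enumerate <- function(i, covered, cost, accept, stop_at_first) {
    if (sum(!covered) > K1 - i + 1L) return(FALSE)
    if (i > K1) {
      if (accept(cost)) {
        best_cost <<- min(best_cost, cost)
        best_map <<- chosen
        return(TRUE)
      }
      return(FALSE)
    }
    for (j in seq_len(K2)) {
      chosen[i] <<- j
      cov2 <- covered
      cov2[j] <- TRUE
      if (enumerate(i + 1L, cov2, cost + C[i, j], accept, stop_at_first) &&
          stop_at_first) {
        return(TRUE)
      }
    }
    FALSE
  }
  enumerate(1L, rep(FALSE, K2), 0,
            function(cost) cost < best_cost, stop_at_first = FALSE)
  opt <- best_cost
  best_cost <- Inf
  enumerate(1L, rep(FALSE, K2), 0,
            function(cost) cost <= opt + 1e-9, stop_at_first = TRUE)

  al <- new_alignment(best_map, K2, sum(C[cbind(seq_len(K1), best_map)]))
  verify_alignment(al, C)
  al
}

#' Optimally align one replicate to another
#'
#' Orients the pair so the replicate with more clusters is the source
#' (ties: the first argument), builds the cluster cost matrix, and solves
#' for the optimal many-to-one alignment. The result's `swapped` field
#' records whether `P` (rather than `Q`) acted as the source, so callers
#' can apply the permutation to whichever replicate they hold.
#'
#' @param Q,P replicates ([q_replicate()]) or membership matrices on the
#'   same individuals.
#' @param method `"ilp"` for the branch-and-bound solver or `"brute"` for
#'   the exhaustive oracle.
#' @return a `cluster_alignment` with extra fields `swapped`, `source_K`,
#'   `target_K`; `mapping` sends source clusters to target clusters and
#'   `cost` equals the replicate dissimilarity under that mapping.
#' @export
align_pair <- function(Q, P, method = c("ilp", "brute")) {
  method <- match.arg(method)
  Qm <- as_matrix(Q); Pm <- as_matrix(P)
  if (nrow(Qm) != nrow(Pm)) stop("replicates have different numbers of individuals")
  swapped <- ncol(Pm) > ncol(Qm)
  src <- if (swapped) Pm else Qm
  tgt <- if (swapped) Qm else Pm
  C <- build_cost_matrix(src, tgt)
  al <- if (method == "ilp") solve_alignment_ilp(C) else brute_force_alignment(C)
  al$swapped <- swapped
  al$source_K <- ncol(src)
  al$target_K <- ncol(tgt)
  al
}

# inverse of a permutation alignment (equal K only)
invert_alignment <- function(al) {
  K <- length(al$mapping)
  if (ncol(al$indicator) != K) stop("only permutation alignments can be inverted")
  inv <- integer(K)
  inv[al$mapping] <- seq_len(K)
  out <- new_alignment(inv, K, al$cost)
  out$swapped <- !isTRUE(al$swapped)
  out$source_K <- al$target_K
  out$target_K <- al$source_K
  out
}

#' Rearrange a matrix's columns into its alignment target's frame
#'
#' For a permutation alignment mapping source cluster i to target cluster
#' alpha(i), returns the source matrix with column i moved to position
#' alpha(i), i.e. the matrix expressed in the target's cluster order.
#'
#' @param m source membership matrix.
#' @param alignment permutation alignment (or integer mapping).
#' @export
apply_alignment <- function(m, alignment) {
  m <- as_matrix(m)
  map <- alignment_mapping(alignment)
  if (length(map) != ncol(m)) stop("alignment does not match the matrix's clusters")
  if (length(unique(map)) != ncol(m)) {
    stop("only permutation alignments can be applied to reorder columns")
  }
  inv <- integer(length(map))
  inv[map] <- seq_along(map)
  m[, inv, drop = FALSE]
}
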