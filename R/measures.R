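#' Dissimilarity between two clusters
#'
#' The cost between cluster column q of one replicate and cluster column p
#' of another is the mean squared coefficient difference scaled into the
#' unit interval:
#' \deqn{C(q, p) = \frac{1}{2N}\sum_{\ell=1}^{N} (q_\ell - p_\ell)^2.}
#' Because both columns lie in \[0, 1\], C is always in \[0, 1\].
#'
#' @param q_col,p_col length-N numeric membership columns.
#' @param N number of individuals (defaults to `length(q_col)`).
#' @return a single cost in \[0, 1\].
#' @export
cluster_cost <- function(q_col, p_col, N = length(q_col)) {
  q_col <- as.numeric(q_col)
  p_col <- as.numeric(p_col)
  if (length(q_col) != length(p_col) || length(q_col) != N) {
    stop("cluster columns must both have length N = ", N)
  }
  sum((q_col - p_col)^2) / (2 * N)
}

# coerce an alignment argument to a plain integer mapping
alignment_mapping <- function(alignment) {
  if (inherits(alignment, "cluster_alignment")) return(alignment$mapping)
  as.integer(alignment)
}

#' Dissimilarity between two replicates under an alignment
#'
#' Sums the cluster costs along a many-to-one mapping \eqn{\alpha} from the
#' clusters of `Q` (K1 of them) onto the clusters of `P` (K2, with
#' K1 >= K2):
#' \deqn{D(Q, \alpha(P)) = \sum_{k=1}^{K_1} C(q_{\cdot k}, p_{\cdot\alpha(k)}).}
#' For equal cluster counts D never exceeds 1; for K1 > K2 it can, because
#' several source clusters charge against the same target column.
#'
#' @param Q,P membership matrices (or replicates) on the same individuals.
#' @param alignment a [solve_alignment_ilp()] result or an integer vector
#'   mapping each column of `Q` to a column of `P`.
#' @return the dissimilarity D >= 0.
#' @export
replicate_dissimilarity <- function(Q, P, alignment) {
  Q <- as_matrix(Q); P <- as_matrix(P)
  if (nrow(Q) != nrow(P)) stop("replicates have different numbers of individuals")
  map <- alignment_mapping(alignment)
  if (length(map) != ncol(Q)) {
    stop("alignment maps ", length(map), " clusters but Q has ", ncol(Q))
  }
  if (any(map < 1L) || any(map > ncol(P))) stop("alignment targets outside P's clusters")
  sum((Q - P[, map, drop = FALSE])^2) / (2 * nrow(Q))
}

#' G' similarity between equal-size membership matrices
#'
#' The Frobenius-norm similarity
#' \deqn{G'(Q, P) = 1 - \frac{\|Q - P\|_F}{\sqrt{2N}},}
#' which is 1 for identical matrices and 0 for hard assignments that
#' disagree on every individual. It is tied to the replicate dissimilarity
#' by the identity \eqn{D(Q, P) = (1 - G')^2}.
#'
#' @param Q,P membership matrices of identical dimensions.
#' @return G' in \[0, 1\].
#' @export
g_prime <- function(Q, P) {
  Q <- as_matrix(Q); P <- as_matrix(P)
  if (!identical(dim(Q), dim(P))) stop("G' requires matrices of identical size")
  1 - sqrt(sum((Q - P)^2) / (2 * nrow(Q)))
}

#' Jaccard-derived similarity between two clusters
#'
#' Restricts the squared-difference comparison to the support
#' \eqn{N^* = \{\ell : q_\ell + p_\ell > 0\}} of the cluster pair:
#' \deqn{J(q, p) = 1 - \sqrt{\sum_{\ell \in N^*} (q_\ell - p_\ell)^2 /
#'   (2|N^*|)}.}
#' Used only for comparison with other tools' scores, never as an
#' alignment objective.
#'
#' @inheritParams cluster_cost
#' @export
jaccard_cluster_similarity <- function(q_col, p_col) {
  q_col <- as.numeric(q_col); p_col <- as.numeric(p_col)
  if (length(q_col) != length(p_col)) stop("cluster columns differ in length")
  supp <- which(q_col + p_col > 0)
  if (!length(supp)) stop("J is undefined for two all-zero cluster columns")
  1 - sqrt(sum((q_col[supp] - p_col[supp])^2) / (2 * length(supp)))
}

#' Jaccard-derived similarity between two replicates
#'
#' Mean of [jaccard_cluster_similarity()] over the source clusters, each
#' compared with the target cluster its alignment points to.
#'
#' @inheritParams replicate_dissimilarity
#' @export
jaccard_replicate_similarity <- function(Q, P, alignment) {
  Q <- as_matrix(Q); P <- as_matrix(P)
  map <- alignment_mapping(alignment)
  if (length(map) != ncol(Q)) stop("alignment does not cover Q's clusters")
  mean(vapply(seq_len(ncol(Q)), function(i) {
    jaccard_cluster_similarity(Q[, i], P[, map[i]])
  }, 0))
}

#' Empirical extremes of the same-K dissimilarity bounds
#'
#' Diagnostic sweep supporting the analytic bounds on equal-K alignment:
#' for row-stochastic N x K matrices and any permutation alignment, each
#' individual's summed squared difference is at most 2, hence D <= 1.
#' Samples random matrix pairs (mixing Dirichlet-like soft rows with hard
#' assignments), evaluates D and the per-individual sums under *every*
#' permutation of the K clusters, and reports the observed maxima.
#'
#' @param n_pairs number of sampled matrix pairs.
#' @param N_max,K_max upper limits for the per-pair dimensions (drawn
#'   uniformly per pair).
#' @param seed RNG seed.
#' @return list with `max_D`, `max_row_sum`, and `n_pairs`.
#' @export
sweep_dissimilarity_bounds <- function(n_pairs = 10000L, N_max = 50L,
                                       K_max = 6L, seed = 0L) {
  perms_by_k <- lapply(seq_len(K_max), all_permutations)
  withr::with_seed(seed, {
    max_D <- 0
    max_row <- 0
    for (b in seq_len(n_pairs)) {
      N <- sample.int(N_max - 1L, 1L) + 1L
      K <- sample.int(K_max - 1L, 1L) + 1L
      Q <- random_membership_rows(N, K)
      P <- random_membership_rows(N, K)
      perms <- perms_by_k[[K]]
      # per-individual squared differences for every (source, target) pair,
      # flattened so one BLAS product covers all permutations at once
      A <- matrix(0, N, K * K)
      for (i in seq_len(K)) for (j in seq_len(K)) {
        A[, (i - 1L) * K + j] <- (Q[, i] - P[, j])^2
      }
      Pi <- matrix(0, K * K, nrow(perms))
      for (s in seq_len(nrow(perms))) {
        Pi[(seq_len(K) - 1L) * K + perms[s, ], s] <- 1
      }
      S <- A %*% Pi                      # N x n_perm per-individual sums
      max_row <- max(max_row, max(S))
      max_D <- max(max_D, max(colSums(S)) / (2 * N))
    }
    list(max_D = max_D, max_row_sum = max_row, n_pairs = n_pairs)
  })
}

# rows mixing soft Dirichlet(1) profiles and hard assignments (the hard rows
# are what attain the bounds)
random_membership_rows <- function(N, K) {
  g <- matrix(stats::rgamma(N * K, shape = 1), N, K)
  m <- g / rowSums(g)
  hard <- stats::runif(N) < 0.5
  if (any(hard)) {
    h <- matrix(0, sum(hard), K)
    h[cbind(seq_len(sum(hard)), sample.int(K, sum(hard), replace = TRUE))] <- 1
    m[hard, ] <- h
  }
  m
}

# all permutations of 1..n, rows in lexicographic order
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(first, rest[sub[s, ]])
    }
  }
  out
}
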