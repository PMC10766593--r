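# Mode detection: replicates sharing a cluster number are nodes of a
# complete weighted graph; edge weights rescale the optimal pairwise
# alignment dissimilarities into [0, 1] (1 = most similar pair observed).
# Louvain community detection on this graph yields the modes, but only
# after a permutation test rejects the null of no community structure.

pair_key <- function(i, j) paste(i, j, sep = " -> ")

#' Build the weighted graph of same-K replicates
#'
#' Aligns every unordered pair of replicates optimally, then rescales each
#' pair's dissimilarity D into a similarity weight
#' \deqn{u_{ij} = (D_{max} - D_{ij}) / (D_{max} - D_{min}),}
#' where the extremes run over distinct pairs. When all pairs are equally
#' dissimilar (including all-identical replicates, and any 2-replicate
#' graph) the rescaling degenerates and every off-diagonal weight is set
#' to 1.
#'
#' @param replicates list of [q_replicate()]s sharing K and N.
#' @return a `replicate_graph`: node ids, symmetric `weights` and
#'   `dissimilarities` matrices, stored pairwise `alignments` (both
#'   orientations), `D_min`, `D_max`, and `K`.
#' @export
build_replicate_graph <- function(replicates) {
  if (!length(replicates)) stop("no replicates supplied")
  Ks <- vapply(replicates, `[[`, 0L, "K")
  if (length(unique(Ks)) > 1L) stop("replicates mix different cluster numbers")
  ids <- vapply(replicates, `[[`, "", "id")
  R <- length(replicates)

  D <- matrix(0, R, R, dimnames = list(ids, ids))
  alignments <- list()
  if (R > 1L) {
    for (i in seq_len(R - 1L)) {
      for (j in (i + 1L):R) {
        al <- align_pair(replicates[[i]], replicates[[j]])
        D[i, j] <- D[j, i] <- al$cost
        alignments[[pair_key(ids[i], ids[j])]] <- al
        alignments[[pair_key(ids[j], ids[i])]] <- invert_alignment(al)
      }
    }
  }

  U <- matrix(1, R, R, dimnames = list(ids, ids))
  d_min <- d_max <- 0
  if (R > 1L) {
    off <- D[upper.tri(D)]
    d_min <- min(off); d_max <- max(off)
    if (d_max - d_min > 1e-12) {
      U <- (d_max - D) / (d_max - d_min)
      diag(U) <- 1
    }
  }
  structure(
    list(node_ids = ids, weights = U, dissimilarities = D,
         alignments = alignments, D_min = d_min, D_max = d_max, K = Ks[1L]),
    class = "replicate_graph"
  )
}

#' @export
print.replicate_graph <- function(x, ...) {
  cat("replicate graph: ", length(x$node_ids), " replicates at K = ", x$K,
      ", D in [", format(x$D_min, digits = 4), ", ",
      format(x$D_max, digits = 4), "]\n", sep = "")
  invisible(x)
}

# extreme eigenvalues of the two screened transforms of a weight matrix:
# (1) the off-diagonal-centered matrix, (2) the degree-normalized matrix
spectral_extremes <- function(U) {
  A <- U
  diag(A) <- 0
  off_mean <- mean(A[upper.tri(A)])
  B <- A - off_mean
  diag(B) <- 0
  e1 <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  d <- rowSums(A)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- A * outer(s, s)
  e2 <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  c(max1 = max(e1), min1 = min(e1), max2 = max(e2), min2 = min(e2))
}

#' Permutation test for community structure in a replicate graph
#'
#' Screens the weight matrix for block (community) signal before any mode
#' splitting is attempted. The statistics are the largest and smallest
#' eigenvalues of two transforms of the weight matrix — the off-diagonal
#' centered matrix and its degree-normalized counterpart — and their null
#' distributions come from symmetric matrices whose off-diagonal entries
#' are random permutations of the observed ones. The null of no structure
#' is rejected when any observed extreme is more extreme than its null at
#' the given significance.
#'
#' Graphs with fewer than three replicates, or with (numerically) constant
#' off-diagonal weights, carry no block signal and return `FALSE`.
#'
#' @param graph a [build_replicate_graph()] result.
#' @param significance rejection level (default 0.01).
#' @param n_perm number of permutation draws (default 199).
#' @param seed RNG seed for the permutation null.
#' @return `TRUE` if the no-structure null is rejected.
#' @export
test_community_structure <- function(graph, significance = 0.01,
                                     n_perm = 199L, seed = 0L) {
  U <- graph$weights
  R <- nrow(U)
  if (R < 3L) return(FALSE)
  off <- U[upper.tri(U)]
  if (max(off) - min(off) < 1e-12) return(FALSE)

  obs <- spectral_extremes(U)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      P <- matrix(0, R, R)
      P[upper.tri(P)] <- sample(off)
      P <- P + t(P)
      diag(P) <- 1
      spectral_extremes(P)
    }, numeric(4L))
  })
  p_vals <- c(
    (1 + sum(null["max1", ] >= obs["max1"])) / (n_perm + 1),
    (1 + sum(null["min1", ] <= obs["min1"])) / (n_perm + 1),
    (1 + sum(null["max2", ] >= obs["max2"])) / (n_perm + 1),
    (1 + sum(null["min2", ] <= obs["min2"])) / (n_perm + 1)
  )
  any(p_vals <= significance)
}

# mean pairwise within-mode similarity (1 - sqrt(D)); 1 for singletons
mode_similarity <- function(graph, members) {
  if (length(members) < 2L) return(1)
  idx <- match(members, graph$node_ids)
  D <- graph$dissimilarities[idx, idx]
  mean(1 - sqrt(D[upper.tri(D)]))
}

#' Partition same-K replicates into modes
#'
#' Runs Louvain community detection on the full weighted replicate graph
#' (no edge thresholding). Detection is gated behind
#' [test_community_structure()]: when the no-structure null is not
#' rejected, all replicates form a single mode. Modes are ordered by
#' decreasing size, ties broken by decreasing within-mode similarity and
#' then by smallest member id.
#'
#' @param graph a [build_replicate_graph()] result.
#' @param resolution Louvain resolution (> 0); larger values produce more,
#'   smaller modes. Default 1.
#' @param seed RNG seed controlling the Louvain sweep and the gate's
#'   permutation null.
#' @param significance significance level of the structure gate.
#' @param test_fn pluggable gate; any function of (graph, significance,
#'   seed) returning a logical. Defaults to [test_community_structure()].
#' @return a `mode_set`: `K`, ordered list `modes` of replicate-id vectors,
#'   mode count `m`, and singleton count `s`.
#' @export
detect_modes <- function(graph, resolution = 1, seed = 0L,
                         significance = 0.01,
                         test_fn = NULL) {
  stopifnot(resolution > 0)
  ids <- graph$node_ids
  if (is.null(test_fn)) {
    test_fn <- function(g, sig, sd) test_community_structure(g, sig, seed = sd)
  }
  has_structure <- isTRUE(test_fn(graph, significance, seed))

  if (!has_structure || length(ids) < 2L) {
    modes <- list(ids)
  } else {
    g <- igraph::graph_from_adjacency_matrix(graph$weights,
                                             mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    comm <- withr::with_seed(seed, {
      igraph::cluster_louvain(g, resolution = resolution)
    })
    modes <- unname(split(ids, igraph::membership(comm)))
  }
  modes <- lapply(modes, sort)
  sizes <- lengths(modes)
  sims <- vapply(modes, function(m) mode_similarity(graph, m), 0)
  first <- vapply(modes, `[[`, "", 1L)
  ord <- order(-sizes, -sims, first)
  modes <- modes[ord]
  structure(
    list(K = graph$K, modes = modes, m = length(modes),
         s = sum(lengths(modes) == 1L)),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode set at K = ", x$K, ": ", x$m, " mode(s), ", x$s,
      " singleton(s)\n", sep = "")
  for (l in seq_along(x$modes)) {
    cat("  M", l, " (", length(x$modes[[l]]), "): ",
        paste(x$modes[[l]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
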