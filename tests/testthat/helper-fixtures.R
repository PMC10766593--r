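# shared fixture builders (all in-code; no data files)

random_q <- function(N, K, seed = NULL) {
  draw <- function() {
    g <- matrix(rgamma(N * K, shape = 1), N, K)
    g / rowSums(g)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# hard-assignment matrix from a vector of cluster labels
hard_q <- function(labels, K = max(labels)) {
  m <- matrix(0, length(labels), K)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

write_q_dir <- function(mats, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  for (i in seq_along(mats)) {
    write_q_file(mats[[i]], file.path(dir, sprintf("rep%03d.Q", i)))
  }
  dir
}

# two well-separated hard-assignment co-clustering patterns on 30
# individuals at K = 3 (between-mode optimal cost 1/6, so a noise scale of
# 0.02 keeps the between/within cost ratio far above 5)
planted_mode_bases <- function() {
  list(hard_q(rep(1:3, each = 10)),
       hard_q(c(rep(1, 10), rep(2, 15), rep(3, 5))))
}

two_mode_fixture <- function(seed, noise = 0.02, per_mode = 5L) {
  spec <- fixture_spec(30, 3, list(`3` = rep(per_mode, 2)),
                       noise_scale = noise, seed = seed,
                       bases = list(`3` = planted_mode_bases()))
  generate_collection(spec)
}

# replicate graph built directly from a weight matrix (for detection tests
# that do not need real alignments behind the weights)
graph_from_weights <- function(U, K = 3L) {
  R <- nrow(U)
  ids <- sprintf("r%02d", seq_len(R))
  dimnames(U) <- list(ids, ids)
  D <- 1 - U
  diag(D) <- 0
  off <- D[upper.tri(D)]
  structure(list(node_ids = ids, weights = U, dissimilarities = D,
                 alignments = list(),
                 D_min = if (length(off)) min(off) else 0,
                 D_max = if (length(off)) max(off) else 0, K = K),
            class = "replicate_graph")
}

planted_block_weights <- function(n1, n2, seed, within = c(0.95, 1),
                                  between = c(0, 0.05)) {
  withr::with_seed(seed, {
    R <- n1 + n2
    U <- matrix(runif(R * R, between[1], between[2]), R, R)
    U[1:n1, 1:n1] <- runif(n1 * n1, within[1], within[2])
    U[(n1 + 1):R, (n1 + 1):R] <- runif(n2 * n2, within[1], within[2])
    U[lower.tri(U)] <- t(U)[lower.tri(U)]
    diag(U) <- 1
    U
  })
}
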