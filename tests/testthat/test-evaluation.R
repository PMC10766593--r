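test_that("per-mode H' is the mean pairwise G' under optimal alignment", {
  # plant pairwise dissimilarities giving G' values {1, 0.8, 0.6}
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 0        # G' = 1
  D[1, 3] <- D[3, 1] <- 0.04     # G' = 0.8
  D[2, 3] <- D[3, 2] <- 0.16     # G' = 0.6
  g <- graph_from_weights(1 - D)
  g$dissimilarities <- D
  expect_equal(mode_h_prime(g, g$node_ids), 0.8)
  expect_equal(mode_h_prime(g, g$node_ids[2]), 1)  # singleton
  expect_error(mode_h_prime(g, character(0)), "empty")

  # identical replicates: every pair has G' = 1
  q <- random_q(15, 3, seed = 24)
  reps <- lapply(1:3, function(i) q_replicate(paste0("r", i), q))
  rg <- build_replicate_graph(reps)
  expect_equal(mode_h_prime(rg, rg$node_ids), 1)
})

test_that("weighted scores follow the size-weighted means and singleton
           exclusion", {
  ms <- structure(list(K = 3L, modes = list(c("a", "b", "c"), "d"),
                       m = 2L, s = 1L), class = "mode_set")
  sc <- weighted_scores(ms, c(0.9, 1))
  expect_equal(sc$weighted_H, (3 * 0.9 + 1 * 1) / 4)
  expect_equal(sc$singleton_excluded_H, 0.9)
  expect_equal(sc$singleton_count, 1L)

  # single mode: both scores collapse to its H'
  ms1 <- structure(list(K = 3L, modes = list(c("a", "b")), m = 1L, s = 0L),
                   class = "mode_set")
  sc1 <- weighted_scores(ms1, 0.77)
  expect_equal(sc1$weighted_H, 0.77)
  expect_equal(sc1$singleton_excluded_H, 0.77)

  # all singletons: H-bar = 1, excluded score undefined
  msS <- structure(list(K = 2L, modes = list("a", "b"), m = 2L, s = 2L),
                   class = "mode_set")
  scS <- weighted_scores(msS, c(1, 1))
  expect_equal(scS$weighted_H, 1)
  expect_true(is.na(scS$singleton_excluded_H))

  # both weighted scores stay between the included extremes
  withr::with_seed(25, {
    for (t in 1:10) {
      sizes <- sample(1:5, 3, replace = TRUE)
      h <- runif(3)
      modes <- lapply(seq_along(sizes), function(l) {
        paste0("m", l, "_", seq_len(sizes[l]))
      })
      ms <- structure(list(K = 3L, modes = modes, m = 3L,
                           s = sum(sizes == 1L)), class = "mode_set")
      sc <- weighted_scores(ms, h)
      expect_gte(sc$weighted_H, min(h) - 1e-12)
      expect_lte(sc$weighted_H, max(h) + 1e-12)
    }
  })
})

test_that("merged-column G' reconstructs splits and matches its oracle", {
  q2 <- random_q(20, 2, seed = 26)
  split <- split_cluster_fixture(q2, 2, c(0.4, 0.6))
  A <- structure(list(K = 2L, member_ids = "a",
                      mean_matrix = membership_matrix(q2),
                      representative_id = "a",
                      representative_matrix = membership_matrix(q2)),
                 class = "mode_consensus")
  B <- structure(list(K = 3L, member_ids = "b",
                      mean_matrix = split, representative_id = "b",
                      representative_matrix = split),
                 class = "mode_consensus")
  al <- align_pair(split, q2)
  expect_equal(across_k_gprime(A, B, al), 1, tolerance = 1e-12)

  # merged rows still sum to one, and an independent merge-then-G' oracle
  withr::with_seed(27, {
    for (t in 1:10) {
      K <- sample(2:4, 1)
      Qm <- random_q(12, K); Pm <- random_q(12, K + 1)
      almt <- align_pair(Pm, Qm)
      A2 <- structure(list(K = K, mean_matrix = membership_matrix(Qm),
                           representative_matrix = membership_matrix(Qm)),
                      class = "mode_consensus")
      B2 <- structure(list(K = K + 1L, mean_matrix = membership_matrix(Pm),
                           representative_matrix = membership_matrix(Pm)),
                      class = "mode_consensus")
      merged <- sapply(seq_len(K), function(k) {
        rowSums(Pm[, almt$mapping == k, drop = FALSE])
      })
      expect_equal(rowSums(merged), rep(1, 12), tolerance = 1e-12)
      expect_equal(across_k_gprime(A2, B2, almt), g_prime(Qm, merged),
                   tolerance = 1e-12)
    }
  })

  # an alignment collapsing everything onto one cluster is rejected
  expect_error(across_k_gprime(A, B, c(1L, 1L, 1L)), "collide")
})
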