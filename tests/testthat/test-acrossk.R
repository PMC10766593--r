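# minimal mode consensus around a bare matrix
stub_mode <- function(m, ids = "r1") {
  structure(list(K = ncol(m), member_ids = ids,
                 mean_matrix = membership_matrix(m, tol = 1e-6),
                 representative_id = ids[1],
                 representative_matrix = membership_matrix(m, tol = 1e-6),
                 member_permutations = list()),
            class = "mode_consensus")
}

test_that("direct mode alignment recovers splits and permutations", {
  q2 <- random_q(20, 2, seed = 16)
  A <- stub_mode(split_cluster_fixture(q2, 1, c(0.5, 0.5)))  # K = 3
  B <- stub_mode(q2)
  r <- align_modes_direct(A, B)
  expect_equal(r$alignment$mapping[2], 2L)
  expect_equal(r$alignment$mapping[1], r$alignment$mapping[3])
  # equals the exhaustive oracle on the same consensus matrices
  oracle <- brute_force_alignment(build_cost_matrix(A$mean_matrix, B$mean_matrix))
  expect_equal(r$cost, oracle$cost, tolerance = 1e-9)
  expect_equal(r$weight, 1 - r$cost)

  q3 <- random_q(20, 3, seed = 17)
  same <- align_modes_direct(stub_mode(q3), stub_mode(q3))
  expect_equal(same$cost, 0, tolerance = 1e-12)
  expect_equal(same$weight, 1)
  perm <- align_modes_direct(stub_mode(q3[, c(3, 1, 2)]), stub_mode(q3))
  expect_equal(perm$alignment$mapping, c(3L, 1L, 2L))
  expect_equal(perm$weight, 1, tolerance = 1e-12)
})

test_that("merge alignment enumerates all column pairs and finds the winner", {
  q2 <- random_q(20, 2, seed = 18)
  B3 <- split_cluster_fixture(q2, 1, c(0.7, 0.3))
  r <- align_modes_merge(stub_mode(q2), stub_mode(B3))
  expect_equal(nrow(r$candidates), 3L)           # choose(3, 2)
  expect_equal(sort(r$merged_pair), c(1L, 3L))   # the planted split
  expect_equal(r$cost, 0, tolerance = 1e-12)
  expect_equal(unclass(r$merged_matrix), unclass(q2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # expanded mapping collides exactly the merged pair
  expect_equal(r$alignment$mapping[1], r$alignment$mapping[3])

  # winner is never beaten by any enumerated candidate
  withr::with_seed(19, {
    for (t in 1:10) {
      K <- sample(2:4, 1)
      A <- stub_mode(random_q(15, K))
      B <- stub_mode(random_q(15, K + 1))
      r <- align_modes_merge(A, B)
      expect_equal(nrow(r$candidates), choose(K + 1, 2))
      expect_true(all(r$cost <= r$candidates$cost + 1e-12))
    }
  })
  expect_error(align_modes_merge(stub_mode(random_q(10, 2)),
                                 stub_mode(random_q(10, 4))), "K")
})

test_that("the across-K graph wires every adjacent mode pair and anchors
           the closest one", {
  q2 <- random_q(20, 2, seed = 20)
  q3a <- split_cluster_fixture(q2, 1, c(0.5, 0.5))
  q3b <- random_q(20, 3, seed = 21)
  layers <- list(`3` = list(stub_mode(q3a, "x"), stub_mode(q3b, "y")),
                 `2` = list(stub_mode(q2, "z")))
  g <- build_across_k_graph(layers, method = "direct")
  expect_equal(g$k_values, c(3L, 2L))
  expect_length(g$edges[[1]], 2L)       # m_3 x m_2
  a <- g$anchors[[1]]
  mus <- vapply(g$edges[[1]], `[[`, 0, "weight")
  expect_equal(a$weight, max(mus))
  expect_equal(a$hi_mode, 1L)           # the split-built mode aligns best

  # single layer: no edges
  g1 <- build_across_k_graph(list(`3` = list(stub_mode(q3a))))
  expect_length(g1$edges, 0L)

  # K gaps: fine for direct, an error for merge
  layers_gap <- list(`5` = list(stub_mode(random_q(20, 5, seed = 22))),
                     `3` = list(stub_mode(q3b)))
  expect_silent(build_across_k_graph(layers_gap, method = "direct"))
  expect_error(build_across_k_graph(layers_gap, method = "merge"),
               "consecutive")

  # merge on consecutive layers carries the expanded many-to-one mapping
  gm <- build_across_k_graph(list(`3` = list(stub_mode(q3a)),
                                  `2` = list(stub_mode(q2))),
                             method = "merge")
  e <- gm$edges[[1]][[1]]
  expect_length(e$alignment$mapping, 3L)
  expect_equal(e$cost, 0, tolerance = 1e-12)
})

test_that("for K vs K+1 the merge winner scores at least the direct
           alignment on the merged-column G'", {
  withr::with_seed(23, {
    for (t in 1:25) {
      K <- sample(2:4, 1)
      A <- stub_mode(random_q(12, K))
      B <- stub_mode(random_q(12, K + 1))
      d <- align_modes_direct(B, A)
      m <- align_modes_merge(A, B)
      hits <- tabulate(d$alignment$mapping, nbins = K)
      if (sum(hits == 2L) == 1L && all(hits >= 1L)) {
        g_direct <- across_k_gprime(A, B, d$alignment)
        g_merge <- across_k_gprime(A, B, m$alignment)
        expect_gte(g_merge, g_direct - 1e-9)
      }
    }
  })
})
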