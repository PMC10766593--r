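test_that("cost matrices agree with the element-wise cluster-cost oracle", {
  q <- random_q(9, 3, seed = 4)
  p <- random_q(9, 2, seed = 5)
  C <- build_cost_matrix(q, p)
  for (i in 1:3) for (j in 1:2) {
    expect_equal(C[i, j], cluster_cost(q[, i], p[, j]), tolerance = 1e-12)
  }
  expect_equal(diag(build_cost_matrix(q, q)), rep(0, 3), tolerance = 1e-12)
  expect_equal(build_cost_matrix(matrix(1), matrix(1))[1, 1], 0)
  expect_error(build_cost_matrix(p, q), "swap")
  expect_error(build_cost_matrix(q, random_q(8, 2)), "individuals")
})

test_that("forced solver cases: zero costs, single target, planted ties", {
  a <- solve_alignment_ilp(matrix(0, 3, 3))
  expect_equal(a$mapping, 1:3)          # lexicographic tie-break
  expect_equal(a$cost, 0)

  C <- matrix(runif(4), 4, 1)
  a <- solve_alignment_ilp(C)
  expect_equal(a$mapping, rep(1L, 4))
  expect_equal(a$cost, sum(C))

  expect_equal(solve_alignment_ilp(rbind(c(0, 1), c(1, 0)))$mapping, 1:2)
  expect_equal(solve_alignment_ilp(rbind(c(1, 0), c(0, 1)))$mapping, 2:1)

  # indicator is consistent with the mapping and constraint system
  C <- matrix(runif(12), 4, 3)
  a <- solve_alignment_ilp(C)
  expect_equal(rowSums(a$indicator), rep(1, 4))
  expect_true(all(colSums(a$indicator) >= 1))
  expect_equal(sum(a$indicator * C), a$cost, tolerance = 1e-12)
})

test_that("exhaustive oracle enumerates exactly the surjections", {
  # 3 -> 2: six surjections; oracle equals a manual scan over them
  C <- matrix(runif(6, 0, 1), 3, 2)
  grid <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  surj <- grid[apply(grid, 1, function(m) length(unique(m)) == 2L), ]
  expect_equal(nrow(surj), 6L)
  costs <- apply(surj, 1, function(m) sum(C[cbind(1:3, m)]))
  b <- brute_force_alignment(C)
  expect_equal(b$cost, min(costs), tolerance = 1e-12)
  expect_error(brute_force_alignment(matrix(0, 30, 10)), "too many")
})

test_that("branch-and-bound equals the exhaustive oracle, ties included", {
  withr::with_seed(7, {
    for (t in 1:150) {
      K2 <- sample(1:5, 1)
      K1 <- K2 + sample(0:2, 1)
      C <- matrix(runif(K1 * K2), K1, K2)
      if (t %% 4 == 0) C <- round(C, 1)  # provoke genuine ties
      a <- solve_alignment_ilp(C)
      b <- brute_force_alignment(C)
      expect_equal(a$cost, b$cost, tolerance = 1e-9)
      expect_identical(a$mapping, b$mapping)
    }
  })
})

test_that("adding a constant to one column shifts the equal-K optimum by it", {
  withr::with_seed(21, {
    for (t in 1:20) {
      K <- sample(2:5, 1)
      C <- matrix(runif(K * K), K, K)
      delta <- runif(1)
      C2 <- C; C2[, 1] <- C2[, 1] + delta
      expect_equal(solve_alignment_ilp(C2)$cost,
                   solve_alignment_ilp(C)$cost + delta, tolerance = 1e-9)
    }
  })
})

test_that("align_pair orients the pair and reproduces its own cost", {
  q <- random_q(20, 3, seed = 9)
  al <- align_pair(q, q)
  expect_equal(al$mapping, 1:3)
  expect_equal(al$cost, 0)

  # planted permutation: swapped columns are inverted at cost zero
  perm <- c(2, 3, 1)
  al <- align_pair(q[, perm], q)
  expect_equal(al$cost, 0, tolerance = 1e-12)
  expect_equal(al$mapping, perm)
  expect_false(al$swapped)
  expect_equal(apply_alignment(q[, perm], al), q, ignore_attr = TRUE)

  # smaller-K first argument: source flips to the second
  p <- random_q(20, 2, seed = 10)
  al <- align_pair(p, q)
  expect_true(al$swapped)
  expect_equal(al$source_K, 3L)
  expect_equal(al$cost, replicate_dissimilarity(q, p, al$mapping),
               tolerance = 1e-12)

  # a parent cluster split in two maps both halves back to the parent
  base <- random_q(20, 2, seed = 11)
  split <- split_cluster_fixture(base, 1, c(0.6, 0.4))
  al <- align_pair(split, base, method = "brute")
  expect_equal(al$mapping[1], al$mapping[3])
  expect_equal(al$mapping[2], 2L)
})

test_that("alignment objective equals the replicate dissimilarity it claims", {
  withr::with_seed(33, {
    for (t in 1:25) {
      K2 <- sample(2:4, 1); K1 <- K2 + sample(0:2, 1)
      q <- random_q(15, K1); p <- random_q(15, K2)
      al <- align_pair(q, p)
      expect_equal(al$cost, replicate_dissimilarity(q, p, al$mapping),
                   tolerance = 1e-9)
    }
  })
})
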