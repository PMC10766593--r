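test_that("replicate graphs normalize weights onto [0, 1]", {
  q <- random_q(20, 3, seed = 1)
  reps <- lapply(1:3, function(i) q_replicate(paste0("r", i), q))
  g <- build_replicate_graph(reps)
  expect_equal(g$weights, matrix(1, 3, 3), ignore_attr = TRUE)

  # two replicates: the only pair attains both extremes, weight 1
  reps2 <- list(q_replicate("a", q), q_replicate("b", random_q(20, 3, seed = 2)))
  g2 <- build_replicate_graph(reps2)
  expect_equal(g2$weights[1, 2], 1)

  # planted groups: within-group weights near 1, between near 0
  fx <- two_mode_fixture(seed = 4)
  g3 <- build_replicate_graph(fx$collection$groups[["3"]])
  truth <- fx$truth$mode[g3$node_ids]
  same <- outer(truth, truth, `==`)
  W <- g3$weights; diag(W) <- NA
  expect_gt(min(W[same], na.rm = TRUE), 0.9)
  expect_lt(max(W[!same]), 0.1)
  off <- W[upper.tri(g3$weights)]
  expect_equal(min(off), 0)  # extremes of the normalization
  expect_equal(max(off), 1)

  # symmetric dissimilarities, stored alignments invert each other
  ids <- g3$node_ids
  expect_equal(g3$dissimilarities, t(g3$dissimilarities))
  al <- g3$alignments[[paste(ids[1], ids[2], sep = " -> ")]]
  rev_al <- g3$alignments[[paste(ids[2], ids[1], sep = " -> ")]]
  expect_equal(rev_al$mapping[al$mapping], seq_along(al$mapping))

  expect_error(build_replicate_graph(list(q_replicate("a", q),
                                          q_replicate("c", random_q(20, 2)))),
               "mix")
})

test_that("the structure gate rejects planted blocks and passes noise", {
  U <- planted_block_weights(10, 10, seed = 5)
  expect_true(test_community_structure(graph_from_weights(U)))

  # constant weights: no signal
  expect_false(test_community_structure(graph_from_weights(matrix(1, 5, 5))))
  # single node / pair: trivially no structure
  expect_false(test_community_structure(graph_from_weights(matrix(1, 1, 1))))
  expect_false(test_community_structure(graph_from_weights(matrix(1, 2, 2))))

  # structureless i.i.d. weights: rejection should be rare; check a fixed
  # draw is not rejected
  U0 <- withr::with_seed(8, {
    R <- 12
    M <- matrix(0, R, R)
    M[upper.tri(M)] <- runif(R * (R - 1) / 2, 0.4, 0.6)
    M <- M + t(M); diag(M) <- 1
    M
  })
  expect_false(test_community_structure(graph_from_weights(U0)))
})

test_that("mode detection recovers planted partitions and orders modes", {
  fx <- two_mode_fixture(seed = 12, per_mode = 5L)
  reps <- fx$collection$groups[["3"]]
  g <- build_replicate_graph(reps)
  ms <- detect_modes(g, seed = 12)
  expect_equal(ms$m, 2L)
  expect_equal(ms$s, 0L)
  detected <- lapply(ms$modes, sort)
  planted <- unname(lapply(split(names(fx$truth$mode), fx$truth$mode), sort))
  expect_setequal(detected, planted)
  # partition validity: disjoint, exhaustive
  expect_equal(sort(unlist(detected)), sort(g$node_ids))

  # gate closed -> a single mode
  q <- random_q(20, 3, seed = 3)
  same <- lapply(1:4, function(i) q_replicate(paste0("r", i), q))
  ms1 <- detect_modes(build_replicate_graph(same), seed = 1)
  expect_equal(ms1$m, 1L)
  expect_equal(ms1$s, 0L)

  # determinism: same graph and seed, same partition
  ms2 <- detect_modes(g, seed = 12)
  expect_identical(ms$modes, ms2$modes)

  # ordering: larger mode first
  spec <- fixture_spec(30, 3, list(`3` = c(7, 3)), noise_scale = 0.02,
                       seed = 30, bases = list(`3` = planted_mode_bases()))
  fx2 <- generate_collection(spec)
  g2 <- build_replicate_graph(fx2$collection$groups[["3"]])
  expect_true(all(diff(lengths(detect_modes(g2, seed = 2)$modes)) <= 0))
})

test_that("higher resolution never coarsens the partition on planted graphs", {
  force_gate <- function(g, sig, sd) TRUE
  for (s in 1:20) {
    U <- planted_block_weights(6, 6, seed = 100 + s,
                               within = c(0.7, 1), between = c(0, 0.3))
    g <- graph_from_weights(U)
    lo <- detect_modes(g, resolution = 0.5, seed = s, test_fn = force_gate)
    hi <- detect_modes(g, resolution = 2.0, seed = s, test_fn = force_gate)
    expect_gte(hi$m, lo$m)
  }
})
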