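test_that("absolute fold change is symmetric, >= 1 and scale-invariant", {
  expect_equal(absolute_fold_change(3.7, 3.7), 1)
  expect_equal(absolute_fold_change(2, 8), 4)
  expect_equal(absolute_fold_change(8, 2), 4)
  a <- runif(20, 0.1, 10); b <- runif(20, 0.1, 10)
  expect_equal(absolute_fold_change(5 * a, 5 * b), absolute_fold_change(a, b))
  expect_true(all(absolute_fold_change(a, b) >= 1))
  expect_error(absolute_fold_change(-1, 2), "positive")
})

test_that("exponentiation maps log values to positive, order-preserving values", {
  expect_equal(exponentiate(0), 1)
  v <- sort(rnorm(10))
  expect_identical(order(exponentiate(v)), order(v))
  expect_equal(exponentiate(v + 2), exp(2) * exponentiate(v))
  expect_error(exponentiate(c(1, NA)), "finite")
})

test_that("neighborhoods contain the representative and obey the afc rule", {
  V <- c(1, 1.1, 10)
  expect_equal(neighborhood(1, V, 1.3), c(1, 1.1))
  expect_equal(neighborhood(2, c(1, 2, 3), 1), 2)          # n = 1: equality only
  expect_equal(neighborhood(5, 5 * V, 1.3), 5 * c(1, 1.1)) # scale invariance
  expect_error(neighborhood(2, V, 1.3), "element")
})

test_that("the pair score rewards separated, balanced, central representatives", {
  # all values within the fold threshold of each other: every pair fails the
  # separation constraint
  V <- exp(c(0, 0.1, 0.2, 0.3))
  u <- sort(unique(V))
  for (i in 1:3) for (j in (i + 1):4) {
    A <- neighborhood(u[i], V, 1.5); B <- neighborhood(u[j], V, 1.5)
    expect_equal(score_pair(u[i], u[j], A, B, V, c(2, 1.5)), 0)
  }
  expect_error(score_pair(1, 4, numeric(0), c(4), c(1, 4), c(2, 1.5)),
               "nonempty")

  # two well-separated equal halves: the pair of half-medians maximizes
  V <- exp(c(0, 0.05, 0.1, 2.0, 2.05, 2.1))
  pair <- c(2, 1.5)
  scores <- matrix(NA_real_, 6, 6)
  u <- sort(V)
  for (i in 1:5) for (j in (i + 1):6) {
    A <- neighborhood(u[i], V, pair[2]); B <- neighborhood(u[j], V, pair[2])
    scores[i, j] <- score_pair(u[i], u[j], A, B, V, pair)
  }
  best <- which(scores == max(scores, na.rm = TRUE), arr.ind = TRUE)
  expect_true(all(best[, 1] <= 3) && all(best[, 2] >= 4))
  # scale invariance of the score
  A <- neighborhood(u[2], V, 1.5); B <- neighborhood(u[5], V, 1.5)
  expect_equal(score_pair(3 * u[2], 3 * u[5], 3 * A, 3 * B, 3 * V, pair),
               score_pair(u[2], u[5], A, B, V, pair))
})

test_that("boundaries are the inner limits of the two sets, switched on overlap", {
  expect_equal(compute_boundaries(c(1, 2), c(8, 10)), c(2, 8))
  expect_equal(compute_boundaries(c(1, 5), c(4, 10)), c(4, 5))  # switched
  expect_equal(compute_boundaries(c(2, 6), c(2, 6)), c(2, 6))   # degenerate
})

test_that("a probe with two planted levels is split into L and H exactly", {
  v <- c(0, 0, 0, 0, 2.3, 2.3, 2.3, 2.3)
  cfg <- cape_config(threshold_pairs = rbind(c(2.0, 1.3)))
  cp <- classify_probe(v, cfg)
  expect_identical(unname(cp$states), rep(c("L", "H"), each = 4))
  expect_equal(cp$best_score, 64)  # coverage 8 x 8, balance 1, no penalty
  orc <- oracle_classify(v, cfg)
  expect_identical(unname(cp$states), unname(orc$states))
  expect_identical(cp$best_score, orc$best_score)
})

test_that("probe states are invariant under constant log-shifts", {
  set.seed(7)
  cfg <- cape_config()
  for (rep in 1:10) {
    v <- random_probe(sample(4:12, 1))
    base <- classify_probe(v, cfg)$states
    for (c_ in c(-3, 0.7, 10))
      expect_identical(classify_probe(v + c_, cfg)$states, base)
  }
})

test_that("constant probes score zero and are removed by the score filter", {
  cp <- classify_probe(rep(1.7, 6))
  expect_equal(cp$best_score, 0)
  expect_identical(unname(cp$states), rep("M", 6))
  mat <- rbind(flat = rep(1.7, 8), bimodal = rep(c(0, 2.3), each = 4))
  colnames(mat) <- paste0("S", 1:8)
  cls <- classify_matrix(mat)
  kept <- filter_probes_by_score(cls, t = 0.5)
  expect_identical(rownames(kept$states), "bimodal")
  expect_identical(rownames(filter_probes_by_score(cls, t = -1)$states),
                   rownames(mat))
})

test_that("an extreme outlier does not disturb the states of the other samples", {
  v <- c(rep(0, 4), rep(2.3, 4))
  with_outlier <- c(v, 10)
  cfg <- cape_config()
  s0 <- classify_probe(v, cfg)$states
  s1 <- classify_probe(with_outlier, cfg)$states
  expect_identical(unname(s1[1:8]), unname(s0))
  expect_identical(unname(s1[9]), "H")
})

test_that("classification matches the exhaustive brute-force search", {
  set.seed(11)
  cfg <- cape_config()
  for (rep in 1:40) {
    v <- random_probe(sample(2:8, 1))
    got <- classify_probe(v, cfg)
    want <- oracle_classify(v, cfg)
    expect_identical(unname(got$states), unname(want$states))
    expect_identical(got$best_score, want$best_score)
    expect_identical(unname(got$chosen_pair), want$chosen_pair)
  }
})

test_that("classification is deterministic", {
  v <- random_probe(10)
  a <- classify_probe(v)
  b <- classify_probe(v)
  expect_identical(a, b)
})
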