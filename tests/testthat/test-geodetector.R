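test_that("stratification handles categorical and natural-breaks drivers", {
  s <- stratify(c("mined", "unmined", "mined"), method = "categorical")
  expect_equal(s$L, 2)
  expect_equal(s$labels, c(1L, 2L, 1L))
  nb <- stratify(c(1, 2, 3, 10, 11, 12), k = 2, method = "natural_breaks")
  expect_equal(nb$L, 2)
  expect_equal(nb$labels, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_error(stratify(c(1, 1, 2), k = 3, method = "natural_breaks"), "distinct")
})

test_that("q matches the hand-computed example and the groupby oracle", {
  fd <- factor_q(c(1, 2, 3, 4), c(1, 1, 2, 2), n_perm = 0)
  expect_equal(fd$sst, 5)
  expect_equal(fd$ssw, 1)
  expect_equal(fd$q, 0.8)
  withr::with_seed(19, {
    for (rep in 1:10) {
      y <- rnorm(60)
      labels <- sample(1:5, 60, TRUE)
      expect_equal(factor_q(y, labels, n_perm = 0)$q, naive_q(y, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("q hits its analytic extremes", {
  y <- rep(c(0, 5, 9), each = 4)
  labels <- rep(1:3, each = 4)
  expect_equal(factor_q(y, labels, n_perm = 0)$q, 1)        # pure strata
  expect_equal(factor_q(rnorm(10), rep(1, 10), n_perm = 0)$q, 0)  # single stratum
  expect_error(factor_q(rep(1, 10), rep(1:2, 5), n_perm = 0), "zero total variance")
})

test_that("q is invariant to stratum relabeling and within-stratum shuffles", {
  withr::with_seed(23, {
    y <- rnorm(80)
    labels <- sample(1:4, 80, TRUE)
    q0 <- factor_q(y, labels, n_perm = 0)$q
    expect_equal(factor_q(y, 5 - labels, n_perm = 0)$q, q0)
    perm <- unlist(lapply(1:4, function(g) sample(which(labels == g))))
    expect_equal(factor_q(y[perm], labels[perm], n_perm = 0)$q, q0)
  })
})

test_that("merging strata never increases q", {
  withr::with_seed(29, {
    for (rep in 1:10) {
      y <- rnorm(50)
      labels <- sample(1:4, 50, TRUE)
      merged <- ifelse(labels == 4, 3, labels)
      expect_lte(factor_q(y, merged, n_perm = 0)$q,
                 factor_q(y, labels, n_perm = 0)$q + 1e-12)
    }
  })
})

test_that("permutation p is small for a real effect and reproducible", {
  withr::with_seed(31, {
    labels <- rep(1:2, each = 50)
    y <- rnorm(100, mean = c(0, 2)[labels])
  })
  a <- factor_q(y, labels, n_perm = 199, seed = 5)
  b <- factor_q(y, labels, n_perm = 199, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_lte(a$p_value, 0.01)
})

test_that("interaction classification covers the five branches exhaustively", {
  expect_equal(maeeq:::classify_interaction(0.3, 0.4, 0.8), "nonlinear enhancement")
  expect_equal(maeeq:::classify_interaction(0.3, 0.4, 0.2), "nonlinear attenuation")
  expect_equal(maeeq:::classify_interaction(0.3, 0.4, 0.65), "bilinear enhancement")
  expect_equal(maeeq:::classify_interaction(0.3, 0.4, 0.35), "single-linear attenuation")
  expect_equal(maeeq:::classify_interaction(0.3, 0.4, 0.7), "mutual independence")
  # exactly one branch fires for any configuration
  withr::with_seed(37, {
    for (rep in 1:50) {
      qs <- runif(3)
      out <- maeeq:::classify_interaction(qs[1], qs[2], qs[3])
      expect_length(out, 1)
      expect_true(out %in% c("nonlinear attenuation", "single-linear attenuation",
                             "bilinear enhancement", "mutual independence",
                             "nonlinear enhancement"))
    }
  })
})

test_that("cross-stratification q dominates each single q when the response is additive", {
  withr::with_seed(41, {
    a <- sample(1:3, 200, TRUE)
    b <- sample(1:2, 200, TRUE)
    y <- a + 10 * b + rnorm(200, sd = 0.3)
  })
  ir <- interaction_detect(y, a, b)
  expect_gte(ir$q12, max(ir$q1, ir$q2) - 1e-12)
  expect_equal(ir$q12, naive_q(y, as.integer(factor(paste(a, b)))),
               tolerance = 1e-12)
})

test_that("risk detection reproduces the textbook Welch t", {
  strat <- rep(1:2, each = 3)
  rd <- risk_detect(c(1, 2, 3, 2, 3, 4), strat)
  expect_equal(rd$pairs$t, -1.2247, tolerance = 1e-4)
  # cross-check the full t/df/p against stats::t.test
  withr::with_seed(43, {
    ya <- rnorm(12); yb <- rnorm(15, 0.8, 2)
  })
  rd2 <- risk_detect(c(ya, yb), c(rep(1, 12), rep(2, 15)))
  tt <- t.test(ya, yb)
  expect_equal(rd2$pairs$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(rd2$pairs$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(rd2$pairs$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("risk detection t is antisymmetric and zero for identical strata", {
  y <- c(1, 2, 3, 1, 2, 3)
  rd <- risk_detect(y, rep(1:2, each = 3))
  expect_equal(rd$pairs$t, 0)
  expect_false(rd$pairs$significant)
  withr::with_seed(47, {
    y2 <- rnorm(30)
    l <- rep(1:2, each = 15)
    t12 <- risk_detect(y2, l)$pairs$t
    t21 <- risk_detect(y2, 3 - l)$pairs$t
    expect_equal(t12, -t21)
  })
})

test_that("clearly separated strata are flagged significant", {
  withr::with_seed(53, {
    y <- c(rnorm(20, 0, 0.01), rnorm(20, 1, 0.01))
  })
  rd <- risk_detect(y, rep(1:2, each = 20))
  expect_true(rd$pairs$significant)
  expect_gt(abs(rd$pairs$t), 50)
})

test_that("singleton strata are excluded from pairwise tests with a warning", {
  y <- c(1, 2, 3, 4, 9)
  expect_warning(rd <- risk_detect(y, c(1, 1, 2, 2, 3)), "fewer than 2")
  expect_equal(nrow(rd$pairs), 1)
  expect_equal(nrow(rd$profile), 3)  # profile still covers every stratum
})

test_that("planted two-stratum response recovers the analytic q", {
  qs <- vapply(1:20, function(s) {
    labels <- rep(1:2, each = 5000)
    resp <- make_stratified_response(labels, means = c(0, 2), sd = 1, seed = 600 + s)
    expect_equal(resp$expected_q, 0.5)
    factor_q(resp$y, labels, n_perm = 0)$q
  }, numeric(1))
  expect_true(all(abs(qs - 0.5) <= 0.05))
})

test_that("stratified response generator hits its degenerate corners", {
  labels <- rep(1:2, each = 100)
  exact <- make_stratified_response(labels, means = c(0, 2), sd = 0, seed = 1)
  expect_equal(factor_q(exact$y, labels, n_perm = 0)$q, 1)
  null <- make_stratified_response(rep(1:2, each = 5000), means = c(1, 1),
                                   sd = 1, seed = 2)
  expect_lt(factor_q(null$y, rep(1:2, each = 5000), n_perm = 0)$q, 0.01)
})
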