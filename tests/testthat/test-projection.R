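test_that("projection onto a basis vector returns that column", {
  x <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(project_samples(x, c(1, 0, 0)), unname(x[, 1]))
  expect_equal(project_samples(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                               c(0.6, 0.8)),
               c(0.6, 0.8))
})

test_that("non-unit directions are rejected", {
  x <- matrix(runif(10), 5, 2)
  expect_error(project_samples(x, c(1, 1)), "unit sphere")
  expect_error(weights_from_direction(c(1, 1)), "unit sphere")
  expect_error(project_samples(x, c(1, 0, 0)), "length")
})

test_that("objective matches hand evaluation on the two-point case", {
  x <- matrix(c(0, 1), 2, 1)
  x <- cbind(x, 0)
  obj <- pp_objective(x, c(1, 0), R = 0.5)
  expect_equal(obj$S, sqrt(0.5), tolerance = 1e-6)
  expect_equal(obj$D, 1.0)          # two diagonal terms of 0.5; cross pairs at r = 1 excluded
  expect_equal(obj$Q, sqrt(0.5), tolerance = 1e-6)
})

test_that("density sum equals the literal double-sum oracle", {
  withr::with_seed(5, {
    for (rep in 1:10) {
      v <- rnorm(40)
      R <- runif(1, 0.05, 2)
      x <- cbind(v, 0)
      expect_equal(pp_objective(x, c(1, 0), R)$D, naive_density_sum(v, R),
                   tolerance = 1e-10)
    }
    # ties at exactly r = R stay excluded (strict step, f(0) = 0)
    v <- c(0, 0.5, 1)
    expect_equal(pp_objective(cbind(v, 0), c(1, 0), 0.5)$D,
                 naive_density_sum(v, 0.5))
  })
})

test_that("constant projections give S = 0 and Q = 0", {
  x <- matrix(1, 5, 2)
  obj <- pp_objective(x, c(1, 0), R = 0.5)
  expect_equal(obj$S, 0)
  expect_equal(obj$Q, 0)
})

test_that("D is non-decreasing in R", {
  withr::with_seed(9, {
    v <- rnorm(30)
    x <- cbind(v, 0)
    Rs <- seq(0.05, 3, length.out = 12)
    Ds <- vapply(Rs, function(R) pp_objective(x, c(1, 0), R)$D, numeric(1))
    expect_true(all(diff(Ds) >= 0))
  })
})

test_that("objective is symmetric under direction sign flip", {
  withr::with_seed(13, {
    x <- matrix(runif(60), 20, 3)
    for (rep in 1:5) {
      c_dir <- rnorm(3); c_dir <- c_dir / sqrt(sum(c_dir^2))
      expect_equal(pp_objective(x, c_dir)$Q, pp_objective(x, -c_dir)$Q)
    }
  })
})

test_that("weights are squared direction components, sign-invariant, sum 1", {
  expect_equal(weights_from_direction(c(0.6, 0.8)), c(0.36, 0.64))
  expect_equal(weights_from_direction(c(-0.6, 0.8)),
               weights_from_direction(c(0.6, -0.8)))
  withr::with_seed(2, {
    c_dir <- rnorm(13); c_dir <- c_dir / sqrt(sum(c_dir^2))
    expect_equal(sum(weights_from_direction(c_dir)), 1, tolerance = 1e-9)
  })
})

test_that("published 13-indicator weight table sums to one", {
  w <- c(0.026, 0.027, 0.069, 0.076, 0.125, 0.076, 0.076,
         0.086, 0.075, 0.084, 0.089, 0.070, 0.121)
  expect_equal(sum(w), 1.000, tolerance = 1e-12)
})

test_that("GA puts nearly all weight on the informative column", {
  withr::with_seed(21, {
    informative <- c(rnorm(60, -1, 0.05), rnorm(60, 1, 0.05))
    x <- cbind(signal = informative, flat = 0.5)
  })
  res <- optimize_direction(
    x, ga_params(population_size = 40, elite_count = 10,
                 max_generations = 40, stall_generations = 40, seed = 4)
  )
  expect_gt(res$weights[["signal"]], 0.99)
})

test_that("GA matches the dense angular sweep at m = 2", {
  withr::with_seed(31, {
    x <- cbind(a = c(rnorm(40, 0, 0.3), rnorm(40, 3, 0.3)),
               b = rnorm(80, 0, 0.5))
  })
  res <- optimize_direction(
    x, ga_params(population_size = 60, elite_count = 15,
                 max_generations = 60, stall_generations = 60, seed = 8)
  )
  oracle <- sweep_best_q(x, n_grid = 10000)
  expect_gte(res$best_Q, 0.999 * oracle)
})

test_that("trace is non-decreasing and a fixed seed reproduces the result", {
  withr::with_seed(17, x <- matrix(runif(120), 40, 3))
  p <- ga_params(population_size = 30, elite_count = 8,
                 max_generations = 25, seed = 99)
  r1 <- optimize_direction(x, p)
  r2 <- optimize_direction(x, p)
  expect_true(all(diff(r1$trace) >= 0))
  expect_identical(r1$direction, r2$direction)
  expect_identical(r1$best_Q, r2$best_Q)
  expect_identical(r1$trace, r2$trace)
})

test_that("degenerate all-constant matrices warn and still return weights", {
  x <- matrix(1, 10, 2)
  expect_warning(
    res <- optimize_direction(x, ga_params(population_size = 10, elite_count = 2,
                                           max_generations = 3, seed = 1)),
    "constant")
  expect_equal(sum(res$weights), 1, tolerance = 1e-9)
})

test_that("tidy and glance summarize a projection result", {
  withr::with_seed(3, x <- matrix(runif(60), 20, 3,
                                  dimnames = list(NULL, c("p", "q", "r"))))
  res <- optimize_direction(x, ga_params(population_size = 20, elite_count = 5,
                                         max_generations = 10, seed = 2))
  td <- tidy(res)
  expect_equal(td$indicator, c("p", "q", "r"))
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(res)
  expect_equal(gl$best_Q, res$best_Q)
})

test_that("large samples trigger seeded search-time subsampling", {
  withr::with_seed(12, x <- matrix(runif(2000 * 2), 2000, 2))
  expect_message(
    optimize_direction(x, ga_params(population_size = 10, elite_count = 2,
                                    max_generations = 2, seed = 5),
                       subsample_above = 500, subsample_size = 100),
    "subsample")
})
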