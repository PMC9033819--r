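lattice_grid <- function(nr, nc, values, cell = 100) {
  resample_to_units(eeq_grid(matrix(values, nr, nc), cell_size = cell),
                    unit_size = cell)
}

test_that("resampling means valid fine cells per unit and applies coverage", {
  v <- matrix(c(1, 2, 3, 4), 2, 2)
  g <- eeq_grid(v, cell_size = 250)
  lat <- resample_to_units(g, unit_size = 500)
  expect_equal(nrow(lat), 1)
  expect_equal(lat$value, 2.5)
  # 1 of 4 cells valid with min_coverage 0.5: dropped
  v2 <- v; v2[c(1, 2, 3)] <- NA
  g2 <- eeq_grid(v2, cell_size = 250)
  expect_error(resample_to_units(g2, unit_size = 500, min_coverage = 0.5),
               "no units retained")
  lat2 <- resample_to_units(g2, unit_size = 500, min_coverage = 0.25)
  expect_equal(lat2$value, v2[2, 2])
  expect_equal(lat2$coverage, 0.25)
})

test_that("unit_size equal to cell size is the identity on valid cells", {
  v <- matrix(runif(12), 3, 4); v[1, 4] <- NA
  g <- eeq_grid(v, cell_size = 100)
  lat <- resample_to_units(g, unit_size = 100)
  expect_equal(nrow(lat), 11)
  expect_equal(lat$value, v[cbind(lat$urow, lat$ucol)])
})

test_that("queen and rook contiguity give the expected neighbour counts", {
  lat <- lattice_grid(3, 3, 1:9)
  Wq <- build_weights(lat, "queen")
  Wr <- build_weights(lat, "rook")
  center <- which(lat$urow == 2 & lat$ucol == 2)
  expect_equal(length(Wq$neighbors[[center]]), 8)
  expect_equal(length(Wr$neighbors[[center]]), 4)
  corner <- which(lat$urow == 1 & lat$ucol == 1)
  expect_equal(length(Wq$neighbors[[corner]]), 3)
  expect_equal(length(Wr$neighbors[[corner]]), 2)
})

test_that("weights are symmetric as a relation, self-free, and row sums are 1", {
  withr::with_seed(3, lat <- lattice_grid(4, 5, runif(20)))
  W <- build_weights(lat, "queen")
  M <- weights_matrix(W)
  expect_true(all(diag(M) == 0))
  expect_true(all((M > 0) == t(M > 0)))
  expect_equal(unname(rowSums(M)), rep(1, W$n))
})

test_that("global Moran's I equals the naive double-loop oracle on random lattices", {
  withr::with_seed(101, {
    for (rep in 1:8) {
      lat <- lattice_grid(5, 5, rnorm(25))
      W <- build_weights(lat, sample(c("queen", "rook"), 1))
      got <- global_moran(lat, W, n_perm = 19, seed = rep)
      expect_equal(got$I, naive_global_moran(lat$value, weights_matrix(W)),
                   tolerance = 1e-12)
    }
  })
})

test_that("two mutually adjacent units with distinct values give I = -1", {
  lat <- lattice_grid(1, 2, c(0, 1))
  W <- build_weights(lat, "rook")
  expect_warning(res <- global_moran(lat, W, n_perm = 9, seed = 1), NA)
  expect_equal(res$I, -1, tolerance = 1e-12)
})

test_that("a rook checkerboard is perfect negative autocorrelation", {
  v <- outer(1:4, 1:4, function(r, c) ifelse((r + c) %% 2 == 0, 1, -1))
  lat <- lattice_grid(4, 4, v)
  W <- build_weights(lat, "rook")
  res <- global_moran(lat, W, n_perm = 99, seed = 2)
  expect_equal(res$I, -1, tolerance = 1e-12)
  lisa <- local_moran(lat, W, n_perm = 99, seed = 2)
  expect_true(all(lisa$local_i < 0))
  expect_true(all(lisa$quadrant %in% c("H-L", "L-H")))
})

test_that("permutation null has mean about -1/(n-1)", {
  withr::with_seed(55, lat <- lattice_grid(5, 5, rnorm(25)))
  W <- build_weights(lat, "queen")
  M <- weights_matrix(W)
  perms <- withr::with_seed(7, {
    vapply(1:999, function(k) naive_global_moran(sample(lat$value), M), numeric(1))
  })
  se <- sd(perms) / sqrt(length(perms))
  expect_lt(abs(mean(perms) - (-1 / 24)), 3 * se)
  expect_equal(global_moran(lat, W, n_perm = 9, seed = 1)$expected_I, -1 / 24)
})

test_that("local Moran matches the naive oracle and averages to the global I", {
  withr::with_seed(202, {
    for (rep in 1:5) {
      lat <- lattice_grid(5, 5, rnorm(25))
      W <- build_weights(lat, "queen")
      lisa <- local_moran(lat, W, n_perm = 19, seed = rep)
      oracle <- naive_local_moran(lat$value, weights_matrix(W))
      expect_equal(lisa$local_i, oracle, tolerance = 1e-12)
      # with row-standardized weights, mean(I_i) = (S0/n) * I * ... reduces to I * S0/n
      I_glob <- naive_global_moran(lat$value, weights_matrix(W))
      S0 <- sum(weights_matrix(W))
      expect_equal(mean(lisa$local_i), I_glob * S0 / W$n, tolerance = 1e-12)
    }
  })
})

test_that("quadrants follow the deviation/lag signs and mean value gives I = 0", {
  lat <- lattice_grid(1, 3, c(0, 1, 2))
  W <- build_weights(lat, "rook")
  lisa <- local_moran(lat, W, n_perm = 49, seed = 3)
  expect_equal(lisa$local_i[2], 0)  # middle unit sits at the mean

  lat2 <- lattice_grid(1, 3, c(0, 0, 10))
  lisa2 <- local_moran(lat2, build_weights(lat2, "rook"), n_perm = 49, seed = 3)
  expect_equal(lisa2$quadrant, c("L-L", "L-H", "H-L"))
})

test_that("permutation p-values are seed-reproducible and relabel-invariant", {
  withr::with_seed(303, lat <- lattice_grid(4, 4, rnorm(16)))
  W <- build_weights(lat, "queen")
  a <- global_moran(lat, W, n_perm = 99, seed = 11)
  b <- global_moran(lat, W, n_perm = 99, seed = 11)
  expect_identical(a$p_value, b$p_value)
  l1 <- local_moran(lat, W, n_perm = 99, seed = 11)
  l2 <- local_moran(lat, W, n_perm = 99, seed = 11)
  expect_identical(l1$p_value, l2$p_value)
})

test_that("constant surfaces are rejected", {
  lat <- lattice_grid(2, 2, rep(1, 4))
  W <- build_weights(lat, "queen")
  expect_error(global_moran(lat, W), "zero variance")
  expect_error(local_moran(lat, W), "zero variance")
})

test_that("smoothed noise fields show positive, significant autocorrelation", {
  hits <- 0
  for (s in 1:20) {
    f <- gaussian_field(c(25, 25), autocorr_range = 3, seed = 1000 + s)
    lat <- resample_to_units(f, unit_size = f$cell_size)
    W <- build_weights(lat, "queen")
    res <- global_moran(lat, W, n_perm = 99, seed = s)
    if (res$I > 0 && res$p_value <= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("unsmoothed white noise has near-zero global Moran's I", {
  f <- gaussian_field(c(50, 50), autocorr_range = 0, seed = 42)
  lat <- resample_to_units(f, unit_size = f$cell_size)
  W <- build_weights(lat, "queen")
  res <- global_moran(lat, W, n_perm = 49, seed = 9)
  expect_lt(abs(res$I), 0.05)
})
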