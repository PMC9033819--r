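# Independent brute-force oracles. These deliberately use the most literal
# formulation of each statistic (double loops, exhaustive search) so they
# share no code path with the package implementations they check.

# literal double sum over all ordered pairs incl. i = j, strict step
naive_density_sum <- function(v, R) {
  n <- length(v)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- abs(v[i] - v[j])
      if (r < R) total <- total + (R - r)
    }
  }
  total
}

naive_pp_q <- function(x, c_dir, R) {
  v <- as.vector(x %*% c_dir)
  S <- sd(v)
  if (identical(R, "auto")) R <- 0.1 * S
  S * naive_density_sum(v, R)
}

# dense weight matrix from a spatial_weights object
weights_matrix <- function(W) {
  M <- matrix(0, W$n, W$n)
  for (i in seq_len(W$n)) {
    nb <- W$neighbors[[i]]
    if (length(nb)) M[i, nb] <- W$weights[[i]]
  }
  M
}

naive_global_moran <- function(y, M) {
  n <- length(y)
  d <- y - mean(y)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + M[i, j] * d[i] * d[j]
  n / sum(M) * num / sum(d^2)
}

naive_local_moran <- function(y, M) {
  n <- length(y)
  d <- y - mean(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lag_i <- 0
    for (j in seq_len(n)) lag_i <- lag_i + M[i, j] * d[j]
    out[i] <- n * d[i] * lag_i / sum(d^2)
  }
  out
}

naive_q <- function(y, labels) {
  sst <- sum((y - mean(y))^2)
  ssw <- 0
  for (g in unique(labels)) {
    yg <- y[labels == g]
    ssw <- ssw + sum((yg - mean(yg))^2)
  }
  1 - ssw / sst
}

# exhaustive search over all ordered partitions of sorted values into k
# contiguous classes; returns minimal total within-class SS and the break
# values (first element of classes 2..k) of a minimizing partition with the
# smallest upper class
exhaustive_jenks <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  wss <- function(g) sum((g - mean(g))^2)
  splits <- utils::combn(n - 1, k - 1)  # split after these indices
  best <- Inf; best_breaks <- NULL
  for (col in seq_len(ncol(splits))) {
    cut <- c(0, splits[, col], n)
    total <- 0
    for (cl in seq_len(k)) total <- total + wss(v[(cut[cl] + 1):cut[cl + 1]])
    better <- total < best - 1e-12
    tie <- abs(total - best) <= 1e-12 &&
      !is.null(best_breaks) &&
      (n - splits[k - 1, col]) < attr(best_breaks, "upper_n")
    if (better || tie) {
      best <- total
      best_breaks <- v[splits[, col] + 1]
      attr(best_breaks, "upper_n") <- n - splits[k - 1, col]
    }
  }
  list(ss = best, breaks = as.numeric(best_breaks))
}

# dense angular sweep oracle for the m = 2 projection objective
sweep_best_q <- function(x, R = "auto", n_grid = 10000) {
  theta <- seq(0, pi, length.out = n_grid)  # Q(c) = Q(-c): half circle suffices
  best <- -Inf
  for (t in theta) {
    q <- pp_objective(x, c(cos(t), sin(t)), R)$Q
    if (q > best) best <- q
  }
  best
}

# tiny fully valid stack of named matrices
tiny_stack <- function(..., cell_size = 100) {
  mats <- list(...)
  align_stack(lapply(mats, eeq_grid, cell_size = cell_size))
}
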