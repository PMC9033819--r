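#' Resample an index surface to coarse analysis units
#'
#' Aggregates the fine raster into square units of `unit_size` metres
#' (a positive integer multiple of the cell size): each unit's value is the
#' mean of its valid fine cells, and units whose fraction of valid cells
#' falls below `min_coverage` are dropped. The retained units form the
#' lattice on which Moran's I / LISA are computed.
#'
#' @param index [eeq_grid] to aggregate.
#' @param unit_size Unit edge in metres (default 500).
#' @param min_coverage Minimum valid-cell fraction to retain a unit
#'   (default 0.5).
#' @return A `unit_lattice`: tibble with `unit`, `urow`, `ucol`, `value`,
#'   `coverage`, plus attributes `unit_size` and `lattice_dim`.
#' @export
resample_to_units <- function(index, unit_size = 500, min_coverage = 0.5) {
  stopifnot(is_eeq_grid(index))
  f <- unit_size / index$cell_size
  if (f < 1 || abs(f - round(f)) > 1e-9) {
    stop("unit_size must be a positive integer multiple of the cell size")
  }
  f <- as.integer(round(f))
  nr <- nrow(index$values); nc <- ncol(index$values)
  ur <- ceiling(nr / f); uc <- ceiling(nc / f)
  cell_ur <- (seq_len(nr) - 1L) %/% f + 1L
  cell_uc <- (seq_len(nc) - 1L) %/% f + 1L
  uid <- outer(cell_ur, cell_uc, function(a, b) (a - 1L) * uc + b)
  valid <- !index$nodata_mask
  n_tot <- tabulate(uid, nbins = ur * uc)
  n_val <- tabulate(uid[valid], nbins = ur * uc)
  sums <- rep(0, ur * uc)
  agg <- tapply(index$values[valid], uid[valid], sum)
  sums[as.integer(names(agg))] <- agg
  coverage <- ifelse(n_tot > 0, n_val / n_tot, 0)
  keep <- n_val > 0 & coverage >= min_coverage
  if (!any(keep)) stop("no units retained; lower min_coverage or check the mask")
  ids <- which(keep)
  out <- tibble::tibble(
    unit = ids,
    urow = (ids - 1L) %/% uc + 1L,
    ucol = (ids - 1L) %% uc + 1L,
    value = sums[ids] / n_val[ids],
    coverage = coverage[ids]
  )
  attr(out, "unit_size") <- unit_size
  attr(out, "lattice_dim") <- c(ur, uc)
  class(out) <- c("unit_lattice", class(out))
  out
}

#' Build a contiguity spatial-weights structure on a unit lattice
#'
#' Queen contiguity joins units sharing an edge or a corner; rook joins
#' edge-sharers only. Weights are 1 for each contiguity link, optionally
#' row-standardized so each unit's weights sum to 1. Self-links never occur
#' and the underlying contiguity relation is symmetric. Units with no
#' neighbour are retained and flagged.
#'
#' @param lattice `unit_lattice` from [resample_to_units()], or any tibble
#'   with `urow`, `ucol`.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @param row_standardize Logical, default `TRUE`.
#' @return A `spatial_weights`: list with `neighbors` (list of integer
#'   indices into the lattice rows), `weights` (parallel list),
#'   `scheme`, `row_standardized`, `n`.
#' @export
build_weights <- function(lattice, scheme = c("queen", "rook"),
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- nrow(lattice)
  if (n < 2) stop("need at least two units")
  offsets <- if (scheme == "queen") {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  key <- paste(lattice$urow, lattice$ucol)
  pos <- stats::setNames(seq_len(n), key)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- paste(lattice$urow[i] + offsets[, "dr"],
                  lattice$ucol[i] + offsets[, "dc"])
    hit <- pos[cand]
    neighbors[[i]] <- sort(unname(hit[!is.na(hit)]))
  }
  isolated <- vapply(neighbors, length, integer(1)) == 0
  if (any(isolated)) {
    warning(sum(isolated), " isolated unit(s) with no neighbours")
  }
  weights <- lapply(neighbors, function(nb) {
    k <- length(nb)
    if (k == 0) numeric(0)
    else if (row_standardize) rep(1 / k, k)
    else rep(1, k)
  })
  structure(list(neighbors = neighbors, weights = weights, scheme = scheme,
                 row_standardized = row_standardize, n = n),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %d units, %s contiguity, %srow-standardized\n",
              x$n, x$scheme, if (x$row_standardized) "" else "not "))
  invisible(x)
}

spatial_lag <- function(y, W) {
  vapply(seq_along(y), function(i) {
    nb <- W$neighbors[[i]]
    if (length(nb) == 0) 0 else sum(W$weights[[i]] * y[nb])
  }, numeric(1))
}

moran_stat <- function(y, W) {
  d <- y - mean(y)
  S0 <- sum(unlist(W$weights))
  num <- sum(d * spatial_lag(d, W))  # sum_i d_i * sum_j w_ij d_j
  length(y) / S0 * num / sum(d^2)
}

#' Global Moran's I with permutation inference
#'
#' The standard statistic
#' `I = (n / S0) * sum_ij w_ij d_i d_j / sum_i d_i^2` with `d_i = x_i - mean`
#' and `S0` the total weight; for row-standardized weights on non-degenerate
#' data it lies in \[-1, 1\] (up to numerical tolerance). Positive I means
#' like values cluster in space. Inference is by random permutation of the
#' values over the units: the pseudo p-value is one-sided in the direction
#' of the observed statistic, `(1 + #{|permuted| as extreme}) / (n_perm + 1)`.
#' The expected value under the null is `-1/(n-1)`.
#'
#' The literal textbook variant with the weight matrix also inside the
#' denominator (and an extra factor n) is reported alongside as `I_literal`
#' for transparency; it is not the statistic tested.
#'
#' @param y Numeric unit values (or a `unit_lattice`, whose `value` column
#'   is used).
#' @param W [build_weights()] result.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `moran_result`: `I`, `I_literal`, `expected_I`, `z_score`,
#'   `p_value`, `n`, `n_perm`, `seed`.
#' @export
global_moran <- function(y, W, n_perm = 999, seed = 1L) {
  if (inherits(y, "unit_lattice") || is.data.frame(y)) y <- y$value
  n <- length(y)
  stopifnot(n == W$n, n >= 2)
  if (stats::sd(y) == 0) stop("constant values: Moran's I undefined (zero variance)")
  I_obs <- moran_stat(y, W)
  d <- y - mean(y)
  lagd <- spatial_lag(d, W)
  denom_lit <- sum(vapply(seq_len(n), function(i) {
    sum(W$weights[[i]] * d[i]^2)
  }, numeric(1)))
  I_literal <- n * sum(d * lagd) / denom_lit
  if (n_perm > 0) {
    perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(k) moran_stat(sample(y), W), numeric(1))
    })
    e_perm <- mean(perm); s_perm <- stats::sd(perm)
    z <- (I_obs - e_perm) / s_perm
    p <- if (I_obs >= e_perm) {
      (1 + sum(perm >= I_obs)) / (n_perm + 1)
    } else {
      (1 + sum(perm <= I_obs)) / (n_perm + 1)
    }
  } else {
    z <- NA_real_; p <- NA_real_
  }
  structure(list(I = I_obs, I_literal = I_literal,
                 expected_I = -1 / (n - 1), z_score = z, p_value = p,
                 n = n, n_perm = n_perm, seed = seed),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("<moran_result> I = %.4f (E[I] = %.4f), z = %.2f, pseudo p = %.4g (%d perms)\n",
              x$I, x$expected_I, x$z_score, x$p_value, x$n_perm))
  invisible(x)
}

#' @describeIn global_moran One-row tidy summary of the global statistic.
#' @param x A `moran_result`.
#' @param ... Unused.
#' @export
glance.moran_result <- function(x, ...) {
  tibble::tibble(I = x$I, expected_I = x$expected_I, z_score = x$z_score,
                 p_value = x$p_value, n = x$n, n_perm = x$n_perm)
}

#' Local Moran's I (LISA) with conditional permutation
#'
#' Per-unit statistic `I_i = n * d_i * sum_j w_ij d_j / sum_k d_k^2`. The
#' Moran-scatter quadrant comes from the signs of the deviation `d_i` and
#' its spatial lag: H-H (both positive), L-L (both negative), H-L and L-H
#' for the discordant cases. Significance is by conditional permutation —
#' unit i's value is held fixed while its neighbours' values are drawn from
#' the remaining units — and a unit is labelled with its quadrant only when
#' its pseudo p-value is at most `alpha`, otherwise "not significant".
#'
#' @param y Unit values or a `unit_lattice` (its `value` column is used; the
#'   lattice's position columns are carried into the result).
#' @param W [build_weights()] result.
#' @param n_perm Conditional permutations per unit (default 999).
#' @param alpha Significance level for cluster labels (default 0.05).
#' @param seed Integer seed.
#' @return A `lisa_result` tibble: `unit`, (`urow`, `ucol` when available),
#'   `value`, `local_i`, `quadrant`, `p_value`, `cluster`.
#' @export
local_moran <- function(y, W, n_perm = 999, alpha = 0.05, seed = 1L) {
  lattice <- NULL
  if (inherits(y, "unit_lattice") || is.data.frame(y)) {
    lattice <- y; y <- y$value
  }
  n <- length(y)
  stopifnot(n == W$n, n >= 2)
  if (stats::sd(y) == 0) stop("constant values: local Moran undefined (zero variance)")
  d <- y - mean(y)
  ss <- sum(d^2)
  lagd <- spatial_lag(d, W)
  local_i <- n * d * lagd / ss
  quadrant <- dplyr::case_when(
    d >= 0 & lagd >= 0 ~ "H-H",
    d < 0 & lagd < 0 ~ "L-L",
    d >= 0 & lagd < 0 ~ "H-L",
    TRUE ~ "L-H"
  )
  p <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      nb <- W$neighbors[[i]]
      k <- length(nb)
      if (k == 0) return(NA_real_)
      others <- d[-i]
      draw <- matrix(0, n_perm, k)
      for (r in seq_len(n_perm)) draw[r, ] <- others[sample.int(n - 1, k)]
      perm_i <- n * d[i] * drop(draw %*% W$weights[[i]]) / ss
      if (local_i[i] >= 0) (1 + sum(perm_i >= local_i[i])) / (n_perm + 1)
      else (1 + sum(perm_i <= local_i[i])) / (n_perm + 1)
    }, numeric(1))
  })
  cluster <- ifelse(!is.na(p) & p <= alpha, quadrant, "not significant")
  out <- tibble::tibble(
    unit = if (!is.null(lattice) && "unit" %in% names(lattice)) lattice$unit else seq_len(n),
    value = y, deviation = d, lag = lagd,
    local_i = local_i, quadrant = quadrant, p_value = p, cluster = cluster
  )
  if (!is.null(lattice)) {
    for (col in intersect(c("urow", "ucol"), names(lattice))) {
      out[[col]] <- lattice[[col]]
    }
    out <- dplyr::relocate(out, dplyr::any_of(c("unit", "urow", "ucol")))
    attr(out, "unit_size") <- attr(lattice, "unit_size")
    attr(out, "lattice_dim") <- attr(lattice, "lattice_dim")
  }
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("lisa_result", class(out))
  out
}
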