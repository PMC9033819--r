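#' Configuration for a synthetic indicator scene
#'
#' Describes the raster scene the generator builds: a rectangular domain of
#' square cells, smooth spatially autocorrelated quantitative fields, four
#' categorical layers (landform, land use, mining intensity, surface
#' subsidence), a contiguous mined block occupying `mined_fraction` of the
#' domain with subsidence discs inside it, and a latent quality field built
#' from known weights. Defaults emulate a ~10 x 20 km arid mining scene at
#' 100 m resolution — the scale of a mid-sized coalfield once resampled to
#' 500 m analysis units.
#'
#' @param shape Integer (rows, cols) of the fine grid.
#' @param cell_size Cell edge, metres.
#' @param autocorr_range Smoothing radius in cells for quantitative fields.
#' @param mined_fraction Fraction of the domain covered by the mined block.
#' @param subsidence_patches Number of subsidence discs inside the block.
#' @param subsidence_radius Disc radius in cells.
#' @param landuse_classes Number of land-use categories (2..6).
#' @param noise_sd Standard deviation of the noise added to the latent
#'   quality field.
#' @param seed Integer seed; the scene is fully deterministic under it.
#' @return A `scene_config` list.
#' @export
scene_config <- function(shape = c(100L, 200L), cell_size = 100,
                         autocorr_range = 5, mined_fraction = 0.2,
                         subsidence_patches = 3, subsidence_radius = 4,
                         landuse_classes = 6, noise_sd = 0.02, seed = 1L) {
  stopifnot(length(shape) == 2, all(shape >= 4), cell_size > 0,
            autocorr_range >= 0, mined_fraction >= 0, mined_fraction <= 1,
            subsidence_patches >= 0, landuse_classes >= 2, landuse_classes <= 6,
            noise_sd >= 0)
  structure(list(shape = as.integer(shape), cell_size = cell_size,
                 autocorr_range = autocorr_range,
                 mined_fraction = mined_fraction,
                 subsidence_patches = as.integer(subsidence_patches),
                 subsidence_radius = subsidence_radius,
                 landuse_classes = as.integer(landuse_classes),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

# moving-average smoother with reflecting edges, radius r cells
smooth_matrix <- function(m, r) {
  if (r <= 0) return(m)
  k <- as.integer(r)
  pad <- function(v, k) c(rev(v[seq_len(k)]), v, rev(v[(length(v) - k + 1):length(v)]))
  run_mean <- function(v, k) {
    p <- pad(v, k)
    cs <- c(0, cumsum(p))
    (cs[(2 * k + 2):length(cs)] - cs[seq_len(length(v))]) / (2 * k + 1)
  }
  m <- apply(m, 2, run_mean, k = k)
  t(apply(t(m), 2, run_mean, k = k))
}

rescale01 <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(m * 0 + 0.5)
  (m - lo) / (hi - lo)
}

#' Generate a smooth random field on the unit interval
#'
#' White Gaussian noise convolved with a square mean filter of the given
#' radius (reflecting edges), then rescaled to \[0,1\]. Radius 0 returns
#' rescaled white noise (no spatial autocorrelation); increasing the radius
#' increases the field's positive spatial autocorrelation.
#'
#' @param shape Integer (rows, cols).
#' @param autocorr_range Smoothing radius in cells (>= 0).
#' @param seed Integer seed.
#' @param cell_size Cell edge in metres for the returned grid.
#' @return An [eeq_grid] with values in \[0,1\] and no masked cells.
#' @export
gaussian_field <- function(shape, autocorr_range, seed = 1L, cell_size = 100) {
  stopifnot(autocorr_range >= 0)
  m <- withr::with_seed(seed, matrix(stats::rnorm(prod(shape)), shape[1], shape[2]))
  eeq_grid(rescale01(smooth_matrix(m, autocorr_range)), cell_size = cell_size)
}

#' Generate a 13-indicator synthetic scene with planted ground truth
#'
#' Builds the full indicator stack an eco-environmental evaluation consumes,
#' with known structure for testing:
#'
#' * nine quantitative layers are correlated smooth fields sharing a latent
#'   elevation surface — precipitation and NDVI load positively on it,
#'   evaporation negatively (arid-region coupling), the rest carry their own
#'   smooth fields;
#' * landform (X4) splits the domain into two elevation bands, land use (X9)
#'   quantizes a smooth field into categories, mining intensity (X11) is a
#'   contiguous mined block in the west of the domain, surface subsidence
#'   (X13) is a set of discs inside the mined block;
#' * a latent quality field is the weighted sum of the standardized layers
#'   under known `latent_weights` (mining intensity carrying the largest
#'   weight, so the mined block depresses quality) plus Gaussian noise.
#'
#' Qualitative layers hold integer category codes; the returned `specs`
#' carry grade maps keyed by those codes, with the mined / subsided /
#' construction codes at grade 1.
#'
#' @param config A [scene_config()].
#' @return List with `stack` (raw `eeq_stack`, ids X1..X13), `specs`
#'   (indicator specs for [standardize_stack()]), `truth` (list:
#'   `latent_weights`, `quality` [eeq_grid], `mined_mask`, `config`), and
#'   `regions` (mined / unmined [region_mask]s).
#' @export
make_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  shp <- config$shape; nr <- shp[1]; nc <- shp[2]
  cs <- config$cell_size
  field <- function(k, r = config$autocorr_range) {
    gaussian_field(shp, r, seed = config$seed * 101L + k, cell_size = cs)$values
  }
  mix <- function(lambda, base, own) rescale01(lambda * base + (1 - lambda) * own)

  elev <- field(1)
  layers <- list(
    X1 = elev,
    X2 = mix(0.3, elev, field(2)),          # slope, mildly terrain-linked
    X3 = field(3),                           # aspect, independent
    X5 = mix(0.7, elev, field(5)),           # precipitation follows elevation
    X6 = mix(0.6, 1 - elev, field(6)),       # evaporation anti-coupled
    X7 = mix(0.3, 1 - elev, field(7)),       # specific yield
    X8 = field(8),                           # river-system distance
    X10 = mix(0.6, elev, field(10)),         # NDVI tracks precipitation belt
    X12 = mix(0.4, 1 - elev, field(12))      # population in the lowlands
  )

  # mined block: contiguous western strip of the requested area fraction
  mined <- matrix(FALSE, nr, nc)
  if (config$mined_fraction > 0) {
    w <- max(1L, round(nc * config$mined_fraction))
    mined[, seq_len(w)] <- TRUE
  }
  x11 <- matrix(2, nr, nc); x11[mined] <- 1   # 1 = high-intensity, 2 = unmined

  # subsidence discs inside the mined block
  x13 <- matrix(2, nr, nc)                    # 1 = subsided, 2 = unsettled
  if (config$subsidence_patches > 0 && any(mined)) {
    centers <- withr::with_seed(config$seed * 101L + 13L, {
      idx <- which(mined)
      idx[sample.int(length(idx), min(config$subsidence_patches, length(idx)))]
    })
    rr <- row(x13); cc <- col(x13)
    for (ct in centers) {
      cr <- (ct - 1) %% nr + 1; ccol <- (ct - 1) %/% nr + 1
      disc <- (rr - cr)^2 + (cc - ccol)^2 <= config$subsidence_radius^2
      x13[disc & mined] <- 1
    }
  }

  # landform: two elevation bands; land use: quantized smooth mosaic
  x4 <- ifelse(elev > stats::median(elev), 2, 1)  # 1 = platform, 2 = low hill
  lu_field <- smooth_matrix(field(9), 2)
  x9 <- matrix(findInterval(lu_field, stats::quantile(
    lu_field, probs = seq_len(config$landuse_classes - 1) / config$landuse_classes
  )) + 1, nr, nc)

  grids <- c(layers, list(X4 = x4, X9 = x9, X11 = x11, X13 = x13))
  order_ids <- paste0("X", 1:13)
  stack <- align_stack(stats::setNames(
    lapply(order_ids, function(id) eeq_grid(grids[[id]], cell_size = cs)),
    order_ids
  ))

  specs <- scene_indicator_specs(config$landuse_classes)
  std <- standardize_stack(stack, specs)

  latent_weights <- c(
    X1 = 0.05, X2 = 0.03, X3 = 0.02, X4 = 0.03, X5 = 0.13, X6 = 0.08,
    X7 = 0.05, X8 = 0.03, X9 = 0.07, X10 = 0.12, X11 = 0.28, X12 = 0.04,
    X13 = 0.07
  )
  quality <- compute_maeeqi(std, latent_weights)
  noise <- withr::with_seed(config$seed * 101L + 99L,
                            matrix(stats::rnorm(nr * nc, sd = config$noise_sd), nr, nc))
  quality_noisy <- eeq_grid(pmin(1, pmax(0, quality$values + noise)),
                            cell_size = cs)

  list(
    stack = stack,
    specs = specs,
    truth = list(latent_weights = latent_weights, quality = quality_noisy,
                 quality_noiseless = quality, mined_mask = mined,
                 config = config),
    regions = list(region_mask("mined area", mined),
                   region_mask("unmined area", !mined))
  )
}

#' Indicator specs matching the synthetic scene's integer category codes
#'
#' @param landuse_classes Number of land-use codes in the scene (2..6).
#' @return Named list of [indicator_spec] for X1..X13 keyed by the scene's
#'   integer codes (as character).
#' @export
scene_indicator_specs <- function(landuse_classes = 6) {
  specs <- default_indicator_specs()
  specs$X4 <- indicator_spec("X4", "geomorphic type", "qualitative",
                             grade_map = c(`1` = 1L, `2` = 5L))
  lu_grades <- c(1L, 2L, 3L, 4L, 5L, 2L)[seq_len(landuse_classes)]
  specs$X9 <- indicator_spec("X9", "land use type", "qualitative",
                             grade_map = stats::setNames(lu_grades,
                                                         as.character(seq_len(landuse_classes))))
  specs$X11 <- indicator_spec("X11", "mining intensity", "qualitative",
                              grade_map = c(`1` = 1L, `2` = 5L))
  specs$X13 <- indicator_spec("X13", "surface subsidence", "qualitative",
                              grade_map = c(`1` = 1L, `2` = 5L))
  specs
}

#' Draw a stratified Gaussian response with known explanatory power
#'
#' For geographic-detector testing: draws `y ~ N(mean_h, sd)` per stratum
#' and stores the analytic expectation of the q statistic,
#' `between-stratum variance / (between + sd^2)`, for assertion.
#'
#' @param strat [stratify()] result (or label vector).
#' @param means Numeric vector of per-stratum means (length = stratum count).
#' @param sd Common within-stratum standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List with `y` and `expected_q`.
#' @export
make_stratified_response <- function(strat, means, sd = 1, seed = 1L) {
  labels <- strat_labels(strat)
  ids <- sort(unique(labels))
  stopifnot(length(means) == length(ids), sd >= 0)
  mu <- means[match(labels, ids)]
  y <- withr::with_seed(seed, stats::rnorm(length(labels), mean = mu, sd = sd))
  p <- as.numeric(table(labels)) / length(labels)
  mbar <- sum(p * means)
  between <- sum(p * (means - mbar)^2)
  list(y = y, expected_q = if (between + sd^2 == 0) 0 else between / (between + sd^2))
}
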