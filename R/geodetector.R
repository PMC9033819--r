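#' Stratify a driver variable for the geographic detector
#'
#' Continuous drivers are discretized into `k` strata with exact Jenks
#' natural breaks ([jenks_breaks()]); categorical drivers get one stratum
#' per distinct label. Strata are non-empty by construction.
#'
#' @param values Numeric or categorical vector (`NA` not allowed).
#' @param k Stratum count for `natural_breaks` (ignored for categorical).
#'   Conventional defaults in this evaluation system: 9 for continuous
#'   indicators, 6 for land use, 2 for mining intensity / subsidence /
#'   landform.
#' @param method `"natural_breaks"` or `"categorical"`.
#' @return A `stratification`: list with integer `labels` (1..L), `L`,
#'   `method`, and `breaks` (natural_breaks only).
#' @export
stratify <- function(values, k = 9, method = c("natural_breaks", "categorical")) {
  method <- match.arg(method)
  if (anyNA(values)) stop("stratify() requires complete values")
  if (method == "categorical") {
    f <- factor(values)
    labels <- as.integer(f)
    breaks <- NULL
    lv <- levels(f)
  } else {
    breaks <- jenks_breaks(values, k)
    labels <- findInterval(values, breaks) + 1L
    lv <- NULL
  }
  structure(list(labels = labels, L = length(unique(labels)),
                 method = method, breaks = breaks, levels = lv),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("<stratification> %d strata (%s), %d samples\n",
              x$L, x$method, length(x$labels)))
  invisible(x)
}

strat_labels <- function(strat) {
  if (inherits(strat, "stratification")) strat$labels else as.integer(factor(strat))
}

# q = 1 - SSW/SST with population variances, so N_h * sigma_h^2 is the
# literal within-stratum sum of squares.
q_statistic <- function(y, labels) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("zero total variance: q undefined")
  ssw <- sum(tapply(y, labels, function(g) sum((g - mean(g))^2)))
  list(q = 1 - ssw / sst, ssw = ssw, sst = sst)
}

#' Factor detection: the geographic-detector q statistic
#'
#' `q = 1 - SSW/SST` measures the share of the response's variance explained
#' by a stratification: 1 when the response is constant within every stratum
#' but differs across strata, 0 when stratification explains nothing.
#' Within-stratum variances are population variances, so the within term is
#' the literal within-group sum of squares. Significance comes from a seeded
#' permutation test (relabelling the response over the strata).
#'
#' @param y Numeric response, aligned with the stratification.
#' @param strat [stratify()] result (or a plain label vector).
#' @param n_perm Permutations for the pseudo p-value; 0 skips inference.
#' @param seed Integer seed.
#' @return A `factor_detection`: `q`, `ssw`, `sst`, `p_value`, and a tibble
#'   `strata` with per-stratum `n`, `mean`, `variance` (population).
#' @export
factor_q <- function(y, strat, n_perm = 999, seed = 1L) {
  labels <- strat_labels(strat)
  stopifnot(length(y) == length(labels))
  obs <- q_statistic(y, labels)
  p <- NA_real_
  if (n_perm > 0) {
    p <- withr::with_seed(seed, {
      perm <- vapply(seq_len(n_perm),
                     function(k) q_statistic(sample(y), labels)$q, numeric(1))
      (1 + sum(perm >= obs$q)) / (n_perm + 1)
    })
  }
  per <- tibble::tibble(
    stratum = sort(unique(labels)),
    n = as.integer(table(labels)),
    mean = as.numeric(tapply(y, labels, mean)),
    variance = as.numeric(tapply(y, labels, function(g) mean((g - mean(g))^2)))
  )
  structure(list(q = obs$q, ssw = obs$ssw, sst = obs$sst, p_value = p,
                 strata = per, n_perm = n_perm, seed = seed),
            class = "factor_detection")
}

#' @export
print.factor_detection <- function(x, ...) {
  cat(sprintf("<factor_detection> q = %.4f, L = %d strata, pseudo p = %s\n",
              x$q, nrow(x$strata),
              if (is.na(x$p_value)) "not computed" else format(x$p_value)))
  invisible(x)
}

#' @describeIn factor_q One-row tidy summary.
#' @param x A `factor_detection`.
#' @param ... Unused.
#' @export
glance.factor_detection <- function(x, ...) {
  tibble::tibble(q = x$q, ssw = x$ssw, sst = x$sst, p_value = x$p_value,
                 L = nrow(x$strata))
}

classify_interaction <- function(q1, q2, q12, tol = 1e-9) {
  lo <- min(q1, q2); hi <- max(q1, q2); s <- q1 + q2
  if (q12 < lo) "nonlinear attenuation"
  else if (q12 <= hi) "single-linear attenuation"
  else if (q12 > s) "nonlinear enhancement"
  else if (abs(q12 - s) <= tol) "mutual independence"
  else "bilinear enhancement"
}

#' Interaction detection between two drivers
#'
#' Computes q for each driver alone and for their cross-stratification
#' (distinct pairs of stratum labels), then classifies the interaction:
#' nonlinear attenuation (q12 below both single q), single-linear
#' attenuation (between them), bilinear enhancement (above both but below
#' their sum), mutual independence (equal to the sum, tolerance 1e-9), or
#' nonlinear enhancement (above the sum). Exactly one class fires.
#'
#' @param y Numeric response.
#' @param strat_a,strat_b [stratify()] results (or label vectors).
#' @return An `interaction_result`: `q1`, `q2`, `q12`, `interaction_type`.
#' @export
interaction_detect <- function(y, strat_a, strat_b) {
  la <- strat_labels(strat_a); lb <- strat_labels(strat_b)
  stopifnot(length(y) == length(la), length(y) == length(lb))
  q1 <- q_statistic(y, la)$q
  q2 <- q_statistic(y, lb)$q
  cross <- as.integer(factor(paste(la, lb)))
  q12 <- q_statistic(y, cross)$q
  structure(list(q1 = q1, q2 = q2, q12 = q12,
                 interaction_type = classify_interaction(q1, q2, q12)),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> q1 = %.4f, q2 = %.4f, q12 = %.4f: %s\n",
              x$q1, x$q2, x$q12, x$interaction_type))
  invisible(x)
}

#' Risk detection: pairwise Welch t-tests between stratum means
#'
#' For every pair of strata with at least two samples each, tests whether
#' the response means differ: `t = (m1 - m2) / sqrt(v1/n1 + v2/n2)` with
#' sample variances and Welch–Satterthwaite degrees of freedom, two-sided at
#' level `alpha`. Also returns the per-stratum mean profile (the
#' quality-versus-stratum curves used to read linear or wavelike responses).
#'
#' @param y Numeric response.
#' @param strat [stratify()] result (or label vector).
#' @param alpha Significance level (default 0.05).
#' @return A `risk_detection`: tibble `pairs` (`stratum_a`, `stratum_b`,
#'   `mean_diff`, `t`, `df`, `p_value`, `significant`) and tibble `profile`
#'   (`stratum`, `n`, `mean`).
#' @export
risk_detect <- function(y, strat, alpha = 0.05) {
  labels <- strat_labels(strat)
  stopifnot(length(y) == length(labels))
  ids <- sort(unique(labels))
  ns <- vapply(ids, function(s) sum(labels == s), integer(1))
  small <- ids[ns < 2]
  if (length(small)) {
    warning("stratum(s) with fewer than 2 samples excluded from pairwise tests: ",
            paste(small, collapse = ", "))
  }
  testable <- ids[ns >= 2]
  pairs <- if (length(testable) >= 2) utils::combn(testable, 2) else
    matrix(integer(0), nrow = 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ya <- y[labels == a]; yb <- y[labels == b]
    n1 <- length(ya); n2 <- length(yb)
    v1 <- stats::var(ya); v2 <- stats::var(yb)
    se2 <- v1 / n1 + v2 / n2
    tt <- if (se2 == 0) 0 else (mean(ya) - mean(yb)) / sqrt(se2)
    df <- if (se2 == 0) n1 + n2 - 2 else
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    pv <- if (se2 == 0) 1 else 2 * stats::pt(-abs(tt), df)
    tibble::tibble(stratum_a = a, stratum_b = b,
                   mean_diff = mean(ya) - mean(yb),
                   t = tt, df = df, p_value = pv,
                   significant = pv <= alpha)
  })
  profile <- tibble::tibble(
    stratum = ids, n = ns,
    mean = as.numeric(tapply(y, labels, mean))[match(ids, sort(unique(labels)))]
  )
  structure(list(pairs = res, profile = profile, alpha = alpha),
            class = "risk_detection")
}

#' @export
print.risk_detection <- function(x, ...) {
  cat(sprintf("<risk_detection> %d stratum pairs tested at alpha = %g, %d significant\n",
              nrow(x$pairs), x$alpha, sum(x$pairs$significant)))
  invisible(x)
}
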