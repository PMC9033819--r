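#' Describe how one indicator is standardized
#'
#' Quantitative indicators carry a polarity: `"positive"` means larger raw
#' values indicate better eco-environmental quality (min-max scaled to
#' \[0,1\]), `"negative"` means the opposite (scale reversed). Qualitative
#' indicators carry a grade map from category labels (or integer codes, as
#' character) to expert grades 1 (worse) through 5 (better); grades are then
#' range-normalized like any other quantity.
#'
#' @param id Indicator id, e.g. `"X5"`.
#' @param name Human-readable name.
#' @param kind `"quantitative"` or `"qualitative"`.
#' @param polarity `"positive"` or `"negative"` (quantitative only).
#' @param grade_map Named integer vector, label -> grade in 1..5
#'   (qualitative only).
#' @return An `indicator_spec` object.
#' @examples
#' indicator_spec("X11", "mining intensity", "qualitative",
#'                grade_map = c(high_intensity = 1L, unmined = 5L))
#' @export
indicator_spec <- function(id, name = id, kind = c("quantitative", "qualitative"),
                           polarity = NULL, grade_map = NULL) {
  kind <- match.arg(kind)
  if (kind == "quantitative") {
    if (is.null(polarity) || !is.null(grade_map)) {
      stop("quantitative indicator ", id, " needs `polarity` and no `grade_map`")
    }
    polarity <- match.arg(polarity, c("positive", "negative"))
  } else {
    if (is.null(grade_map) || !is.null(polarity)) {
      stop("qualitative indicator ", id, " needs `grade_map` and no `polarity`")
    }
    grade_map <- vapply(grade_map, as.integer, integer(1))
    if (is.null(names(grade_map)) || !all(grade_map %in% 1:5)) {
      stop("`grade_map` must be a named vector of grades in 1..5")
    }
  }
  structure(list(id = id, name = name, kind = kind,
                 polarity = polarity, grade_map = grade_map),
            class = "indicator_spec")
}

#' Default specifications for the 13-indicator evaluation system
#'
#' The shipped defaults follow the usual reading of arid-region mining
#' assessments: precipitation, aquifer specific yield and NDVI favour quality
#' (positive); evaporation and population density degrade it (negative);
#' elevation, slope, aspect and river-system distance default to positive.
#' The four qualitative indicators use five-grade expert maps; the land-use
#' map places bare surfaces (desert, unused land) at grade 2. All of this is
#' configuration, not hard-coded behaviour: pass your own list to override.
#'
#' @return Named list of 13 [indicator_spec] objects, ids `X1`..`X13`.
#' @export
default_indicator_specs <- function() {
  q <- function(id, name, pol) indicator_spec(id, name, "quantitative", polarity = pol)
  specs <- list(
    q("X1", "elevation", "positive"),
    q("X2", "terrain slope", "positive"),
    q("X3", "terrain aspect", "positive"),
    indicator_spec("X4", "geomorphic type", "qualitative",
                   grade_map = c(platform = 1L, low_hill = 5L)),
    q("X5", "annual average precipitation", "positive"),
    q("X6", "annual average evaporation", "negative"),
    q("X7", "aquifer specific yield", "positive"),
    q("X8", "river system distance", "positive"),
    indicator_spec("X9", "land use type", "qualitative",
                   grade_map = c(construction = 1L, desert = 2L, unused = 2L,
                                 cultivated = 3L, grassland = 4L, woodland = 5L)),
    q("X10", "NDVI", "positive"),
    indicator_spec("X11", "mining intensity", "qualitative",
                   grade_map = c(high_intensity = 1L, unmined = 5L)),
    q("X12", "population density", "negative"),
    indicator_spec("X13", "surface subsidence", "qualitative",
                   grade_map = c(subsided = 1L, unsettled = 5L))
  )
  stats::setNames(specs, vapply(specs, `[[`, character(1), "id"))
}

#' Min-max standardize a quantitative indicator
#'
#' Positive polarity maps the sample minimum to 0 and maximum to 1 with an
#' affine ramp between; negative polarity reverses the ramp (max -> 0,
#' min -> 1). The range is taken over the supplied values (the valid cells of
#' the scene), not over external constants.
#'
#' @param x Numeric vector; `NA` passes through.
#' @param polarity `"positive"` or `"negative"`.
#' @return Numeric vector in \[0,1\].
#' @export
normalize_quantitative <- function(x, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  v <- x[!is.na(x)]
  if (any(!is.finite(v))) stop("non-finite value among valid cells")
  if (length(v) < 2) stop("need at least two valid values")
  lo <- min(v); hi <- max(v)
  if (hi == lo) stop("constant indicator: zero range, cannot min-max standardize")
  if (polarity == "positive") (x - lo) / (hi - lo) else (hi - x) / (hi - lo)
}

#' Map qualitative categories to expert grades
#'
#' @param categories Character (or factor/integer, coerced to character)
#'   vector of category labels; `NA` passes through.
#' @param grade_map Named vector, label -> grade 1..5.
#' @return Integer vector of grades.
#' @export
grade_qualitative <- function(categories, grade_map) {
  categories <- as.character(categories)
  known <- categories %in% names(grade_map) | is.na(categories)
  if (!all(known)) {
    stop("unknown category label(s): ",
         paste(unique(categories[!known]), collapse = ", "))
  }
  out <- rep(NA_integer_, length(categories))
  ok <- !is.na(categories)
  out[ok] <- as.integer(grade_map[categories[ok]])
  out
}

#' Standardize a raster indicator stack to \[0,1\]
#'
#' Quantitative layers go through [normalize_quantitative()] with their
#' spec's polarity; qualitative layers are graded with [grade_qualitative()]
#' and the observed grades then range-normalized the same way (so a layer
#' whose observed grades are {1, 3, 5} standardizes to {0, 0.5, 1}).
#' Statistics are computed over jointly valid cells only.
#'
#' @param stack `eeq_stack` of raw indicator grids. Qualitative layers hold
#'   integer category codes; their spec's `grade_map` must be keyed by those
#'   codes (as character) or the layer may hold grades directly when the map
#'   is the identity.
#' @param specs Named list of [indicator_spec], one per stack indicator.
#' @return An `eeq_stack` of standardized grids with attribute `specs`.
#' @export
standardize_stack <- function(stack, specs = default_indicator_specs()) {
  stopifnot(inherits(stack, "eeq_stack"))
  missing <- setdiff(stack$indicator_ids, names(specs))
  if (length(missing)) stop("no indicator_spec for: ", paste(missing, collapse = ", "))
  valid <- !stack$joint_mask
  out <- list()
  for (id in stack$indicator_ids) {
    g <- stack$grids[[id]]
    sp <- specs[[id]]
    v <- g$values
    v[!valid] <- NA_real_  # joint mask governs the sample
    if (sp$kind == "quantitative") {
      std <- normalize_quantitative(as.vector(v), sp$polarity)
    } else {
      grades <- grade_qualitative(as.vector(v), sp$grade_map)
      obs <- range(grades, na.rm = TRUE)
      if (obs[1] == obs[2]) {
        # single observed grade: no range to normalize; anchor on the 1..5 scale
        std <- (as.numeric(grades) - 1) / 4
      } else {
        std <- (as.numeric(grades) - obs[1]) / (obs[2] - obs[1])
      }
    }
    out[[id]] <- eeq_grid(matrix(std, nrow(v), ncol(v)),
                          cell_size = g$cell_size, origin = g$origin,
                          crs_label = g$crs_label)
  }
  std_stack <- align_stack(out)
  attr(std_stack, "specs") <- specs[stack$indicator_ids]
  std_stack
}
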