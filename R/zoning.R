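#' Convert significant LISA clusters into management zones
#'
#' Significant L-L units (low quality amid low quality) become the
#' management zone — the area needing intensive ecological rehabilitation.
#' Significant H-H units become the close-attention zone: quality is good
#' but future mining could degrade it. Significant spatial outliers (H-L or
#' L-H) become the protective zone, where localized low quality could
#' propagate. Units without a significant cluster get the explicit zone
#' `"none"` so area accounting covers every retained unit. Zoning is a pure
#' function of the LISA result: rerunning on the same input is identical.
#'
#' @param lisa `lisa_result` tibble from [local_moran()].
#' @return A `zoning_map`: the input tibble with a `zone` column, plus
#'   attribute `counts` (named integer vector per zone).
#' @export
classify_zones <- function(lisa) {
  stopifnot(is.data.frame(lisa), all(c("cluster") %in% names(lisa)))
  zone <- dplyr::case_when(
    lisa$cluster == "L-L" ~ "management",
    lisa$cluster == "H-H" ~ "close_attention",
    lisa$cluster %in% c("H-L", "L-H") ~ "protective",
    TRUE ~ "none"
  )
  out <- dplyr::mutate(tibble::as_tibble(lisa), zone = zone)
  lv <- c("management", "close_attention", "protective", "none")
  counts <- table(factor(zone, levels = lv))
  attr(out, "counts") <- stats::setNames(as.integer(counts), lv)
  for (a in c("unit_size", "lattice_dim")) attr(out, a) <- attr(lisa, a)
  class(out) <- c("zoning_map", class(tibble::tibble()))
  out
}

#' Summarize a zoning map
#'
#' @param zones `zoning_map` from [classify_zones()].
#' @return Tibble with `zone`, `n_units`, and `area_km2` when the lattice
#'   unit size is known.
#' @export
zone_summary <- function(zones) {
  counts <- attr(zones, "counts")
  out <- tibble::tibble(zone = names(counts), n_units = unname(counts))
  us <- attr(zones, "unit_size")
  if (!is.null(us)) out$area_km2 <- out$n_units * (us / 1000)^2
  out
}
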