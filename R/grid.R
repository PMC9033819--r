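#' Construct a single-band raster grid
#'
#' `eeq_grid` is the package's raster container: a numeric matrix of cell
#' values, a logical nodata mask of the same shape, and minimal georeference
#' metadata. Row 1 of the matrix is the northern edge of the scene; cells are
#' square with side `cell_size` metres, so each cell covers `cell_size^2` m².
#'
#' @param values Numeric matrix of cell values. `NA` entries are masked.
#' @param nodata_mask Logical matrix, `TRUE` where the cell carries no data.
#'   Defaults to `is.na(values)`; `NA` values are always added to the mask.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Numeric length-2 vector, (x, y) of the north-west corner.
#' @param crs_label Free-text tag describing the coordinate system.
#' @return An object of class `eeq_grid`.
#' @examples
#' g <- eeq_grid(matrix(runif(12), 3, 4), cell_size = 30)
#' dim(g$values)
#' @export
eeq_grid <- function(values, nodata_mask = NULL, cell_size = 1,
                     origin = c(0, 0), crs_label = "") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  if (!is.matrix(nodata_mask) || !identical(dim(nodata_mask), dim(values))) {
    stop("`nodata_mask` must be a logical matrix with the same shape as `values`")
  }
  nodata_mask <- nodata_mask | is.na(values)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("`cell_size` must be a single positive number")
  }
  values[nodata_mask] <- NA_real_
  structure(
    list(values = values, nodata_mask = nodata_mask,
         cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_label = crs_label),
    class = "eeq_grid"
  )
}

#' @export
print.eeq_grid <- function(x, ...) {
  cat(sprintf(
    "<eeq_grid> %d x %d cells, cell_size %g m, %d valid / %d total\n",
    nrow(x$values), ncol(x$values), x$cell_size,
    sum(!x$nodata_mask), length(x$values)
  ))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  if (all(is.finite(rng))) cat(sprintf("  value range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.eeq_grid <- function(x) dim(x$values)

is_eeq_grid <- function(x) inherits(x, "eeq_grid")

grids_compatible <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Read a raster grid from disk
#'
#' Supports the ESRI ASCII grid format (georeference preserved; the nodata
#' sentinel, -9999 by default, is masked) and float TIFF (single-band, or
#' the value + validity-channel pair written by [write_grid()]). Plain TIFF
#' carries no georeference, so those grids come back with `cell_size = 1` and
#' `origin = c(0, 0)` and a warning; use ASCII grids where georeferencing
#' matters. `NaN` cells in a single-band TIFF are masked.
#'
#' @param path File to read.
#' @param format `"ascii_grid"`, `"geotiff"`, or `"auto"` (from the extension:
#'   `.asc`/`.agr` is ASCII, `.tif`/`.tiff` is TIFF).
#' @return An [eeq_grid].
#' @seealso [write_grid()]
#' @export
read_grid <- function(path, format = c("auto", "ascii_grid", "geotiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      asc = , agr = "ascii_grid",
      tif = , tiff = "geotiff",
      stop("cannot infer raster format from extension: ", ext)
    )
  }
  if (format == "ascii_grid") read_ascii_grid(path) else read_tiff_grid(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr))) stop("not an ESRI ASCII grid (missing ncols/nrows): ", path)
  nc <- hdr$ncols; nr <- hdr$nrows
  body <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(body) != nr * nc) {
    stop(sprintf("ASCII grid body has %d values, expected %d", length(body), nr * nc))
  }
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  mask <- !is.na(vals) & vals == nodata
  vals[mask] <- NA_real_
  cell <- hdr$cellsize
  if (is.null(cell)) {
    warning("ASCII grid without cellsize; defaulting cell_size = 1, origin = (0, 0)")
    cell <- 1; ox <- 0; oy <- 0
  } else {
    # header anchors the lower-left corner; origin here is the NW corner
    ox <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
    yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
    oy <- yll + nr * cell
  }
  eeq_grid(vals, cell_size = cell, origin = c(ox, oy), crs_label = "")
}

read_tiff_grid <- function(path) {
  img <- withCallingHandlers(
    tiff::readTIFF(path, as.is = FALSE),
    # the validity channel is stored as a second grayscale sample; libtiff
    # flags the missing ExtraSamples tag, which is expected and harmless
    warning = function(w) {
      if (grepl("ExtraSamples", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  mask <- NULL
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 2) {
      # second sample is the validity channel written by write_grid()
      mask <- img[, , 2] < 0.5
      img <- img[, , 1]
    } else if (dim(img)[3] == 1) {
      img <- img[, , 1]
    } else {
      stop("multi-band TIFF not supported: ", path)
    }
  }
  if (is.null(mask)) mask <- is.na(img) | is.nan(img)
  img[mask] <- NA_real_
  warning("plain TIFF carries no georeference; defaulting cell_size = 1, origin = (0, 0)")
  eeq_grid(img, cell_size = 1, origin = c(0, 0), crs_label = "")
}

#' Write a raster grid to disk
#'
#' ASCII grids encode masked cells as the -9999 sentinel and preserve the
#' georeference; they are the package's general-purpose format. TIFF output
#' is a float image restricted to unit-interval surfaces (the standardized
#' layers and the quality index) with the nodata mask carried as a second
#' validity sample; georeference is not representable in plain TIFF.
#'
#' @param grid An [eeq_grid].
#' @param path Output file.
#' @param format `"ascii_grid"`, `"geotiff"`, or `"auto"` from the extension.
#' @param digits Significant digits for ASCII output (integers are written
#'   exactly regardless).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("auto", "ascii_grid", "geotiff"),
                       digits = 10) {
  stopifnot(is_eeq_grid(grid))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      asc = , agr = "ascii_grid",
      tif = , tiff = "geotiff",
      stop("cannot infer raster format from extension: ", ext)
    )
  }
  if (format == "ascii_grid") {
    nr <- nrow(grid$values); nc <- ncol(grid$values)
    vals <- grid$values
    vals[grid$nodata_mask] <- -9999
    all_int <- all(vals == round(vals))
    fmt_row <- function(r) {
      if (all_int) paste(format(r, scientific = FALSE, trim = TRUE), collapse = " ")
      else paste(formatC(r, digits = digits, format = "g"), collapse = " ")
    }
    hdr <- c(
      sprintf("ncols %d", nc),
      sprintf("nrows %d", nr),
      sprintf("xllcorner %.10g", grid$origin[1]),
      sprintf("yllcorner %.10g", grid$origin[2] - nr * grid$cell_size),
      sprintf("cellsize %.10g", grid$cell_size),
      "NODATA_value -9999"
    )
    body <- vapply(seq_len(nr), function(i) fmt_row(vals[i, ]), character(1))
    ok <- tryCatch({
      writeLines(c(hdr, body), path); TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write ASCII grid to ", path)
  } else {
    vals <- grid$values
    ok <- !grid$nodata_mask
    if (any(vals[ok] < 0 | vals[ok] > 1)) {
      stop("TIFF output stores unit-interval surfaces only; ",
           "use format = \"ascii_grid\" for unbounded or integer data")
    }
    vals[!ok] <- 0
    arr <- array(c(vals, as.numeric(ok)), dim = c(dim(vals), 2L))
    tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Assemble co-registered grids into an indicator stack
#'
#' All member grids must share shape, cell size and origin (tolerance 1e-6);
#' a mismatch is refused with an error naming the offending indicator rather
#' than silently resampled. The stack's joint valid mask is the intersection
#' of the members' valid masks: a cell missing in any indicator is excluded
#' from the whole analysis.
#'
#' @param grids Named list of [eeq_grid] objects, names are indicator ids.
#' @return An `eeq_stack`: list with `grids`, `indicator_ids`, `joint_mask`
#'   (logical matrix, `TRUE` = invalid in at least one member).
#' @examples
#' g <- eeq_grid(matrix(1, 2, 2))
#' align_stack(list(X1 = g, X2 = g))
#' @export
align_stack <- function(grids) {
  stopifnot(is.list(grids), length(grids) >= 1)
  if (is.null(names(grids)) || any(names(grids) == "")) {
    stop("`grids` must be a fully named list (indicator ids)")
  }
  ref <- grids[[1]]
  for (id in names(grids)) {
    g <- grids[[id]]
    if (!is_eeq_grid(g)) stop("entry ", id, " is not an eeq_grid")
    if (!grids_compatible(ref, g)) {
      stop("indicator ", id, " is not aligned with ", names(grids)[1],
           " (shape, cell_size and origin must match within 1e-6)")
    }
  }
  joint <- Reduce(`|`, lapply(grids, function(g) g$nodata_mask))
  structure(
    list(grids = grids, indicator_ids = names(grids), joint_mask = joint,
         cell_size = ref$cell_size, origin = ref$origin),
    class = "eeq_stack"
  )
}

#' @export
print.eeq_stack <- function(x, ...) {
  cat(sprintf("<eeq_stack> %d indicators (%s), %d x %d cells, %d jointly valid\n",
              length(x$indicator_ids),
              paste(utils::head(x$indicator_ids, 4), collapse = ", "),
              nrow(x$joint_mask), ncol(x$joint_mask), sum(!x$joint_mask)))
  invisible(x)
}

#' Flatten a stack's jointly valid cells into a sample tibble
#'
#' Rows are jointly valid cells in row-major (north-to-south, west-to-east)
#' order; the first two columns record the cell position so values can be
#' rasterized back with [rasterize_values()].
#'
#' @param stack An `eeq_stack` from [align_stack()].
#' @return A tibble with columns `cell_row`, `cell_col`, then one numeric
#'   column per indicator.
#' @export
flatten_valid <- function(stack) {
  stopifnot(inherits(stack, "eeq_stack"))
  keep <- which(t(!stack$joint_mask))  # row-major order over the grid
  nc <- ncol(stack$joint_mask)
  if (length(keep) == 0) stop("stack has no jointly valid cells")
  rows <- (keep - 1L) %/% nc + 1L
  cols <- (keep - 1L) %% nc + 1L
  out <- tibble::tibble(cell_row = rows, cell_col = cols)
  for (id in stack$indicator_ids) {
    out[[id]] <- stack$grids[[id]]$values[cbind(rows, cols)]
  }
  out
}

#' Extract the numeric sample matrix from a flattened stack
#'
#' @param samples Tibble from [flatten_valid()].
#' @return Numeric n x m matrix, one column per indicator.
#' @export
sample_matrix <- function(samples) {
  cols <- setdiff(names(samples), c("cell_row", "cell_col"))
  as.matrix(samples[cols])
}

#' Rasterize per-cell values back onto a grid
#'
#' Inverse of [flatten_valid()]: places `values` at the recorded cell
#' positions on a grid with the template's geometry, masking everything else.
#'
#' @param values Numeric vector, one value per row of `cell_index`.
#' @param cell_index Tibble/data frame with `cell_row`, `cell_col`.
#' @param template An [eeq_grid] or `eeq_stack` supplying shape and
#'   georeference.
#' @return An [eeq_grid].
#' @export
rasterize_values <- function(values, cell_index, template) {
  shp <- if (is_eeq_grid(template)) dim(template$values) else dim(template$joint_mask)
  stopifnot(length(values) == nrow(cell_index))
  m <- matrix(NA_real_, shp[1], shp[2])
  m[cbind(cell_index$cell_row, cell_index$cell_col)] <- values
  cs <- if (is_eeq_grid(template)) template$cell_size else template$cell_size
  org <- if (is_eeq_grid(template)) template$origin else template$origin
  eeq_grid(m, cell_size = cs, origin = org)
}

#' Define a named sub-region of the scene
#'
#' @param name Region label (e.g. "previously mined area").
#' @param mask Logical matrix, `TRUE` inside the region.
#' @return A `region_mask` object.
#' @export
region_mask <- function(name, mask) {
  stopifnot(is.character(name), length(name) == 1, is.matrix(mask), is.logical(mask))
  structure(list(name = name, mask = mask), class = "region_mask")
}
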