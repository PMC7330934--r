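#' Read a calibrated RGB image
#'
#' Reads an 8-bit PNG or uncompressed TIFF and attaches the physical
#' calibration. Greyscale files are promoted to RGB by channel
#' triplication; an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param microns_per_pixel positive number, microns per pixel (isotropic).
#'   Scanner metadata is not read: the calibration is always an explicit
#'   input.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, microns_per_pixel) {
  assert_scalar_number(microns_per_pixel, "microns_per_pixel", positive = TRUE)
  px <- read_pixels(path)
  if (length(dim(px)) == 3L && dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  calibrated_image(px, microns_per_pixel)
}

# decode PNG/TIFF to an integer matrix (grey) or H x W x C array in [0,255]
read_pixels <- function(path) {
  if (!file.exists(path)) io_error("file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- tryCatch(png::readPNG(path), error = function(e)
      io_error("cannot decode %s as PNG: %s", path, conditionMessage(e)))
    px <- round(px * 255)
    if (length(dim(px)) == 2L) matrix(as.integer(px), nrow(px), ncol(px))
    else array(as.integer(px), dim(px))
  } else if (ext %in% c("tif", "tiff")) {
    read_tiff(path)
  } else {
    io_error("unsupported image extension '%s' (use png/tif/tiff): %s",
             ext, path)
  }
}

#' Write a calibrated image (or raw pixel grid) to PNG or TIFF
#'
#' @param image a [calibrated_image()] or an integer array/matrix in
#'   `[0, 255]`.
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "calibrated_image")) image$pixels else image
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    write_tiff(px, path)
  } else {
    io_error("unsupported image extension '%s' (use png/tif/tiff): %s",
             ext, path)
  }
  invisible(path)
}

#' Read an exclusion mask
#'
#' Exclusion masks mark pixels that must not be counted (e.g. stained
#' cutaneous appendages, non-specific foci). Any nonzero pixel is excluded.
#'
#' @param path single-channel 8-bit PNG (or TIFF).
#' @param expected_shape integer vector `c(H, W)` of the image the mask
#'   applies to.
#' @return Logical `H x W` matrix, `TRUE` = excluded.
#' @export
read_mask <- function(path, expected_shape) {
  px <- read_pixels(path)
  if (length(dim(px)) == 3L) {
    chans <- dim(px)[3]
    same <- all(vapply(seq_len(chans)[-1], function(k)
      identical(px[, , k], px[, , 1L]), logical(1)))
    if (!same)
      validation_error("mask %s has %d distinct channels; expected single-channel",
                       path, chans)
    px <- px[, , 1L]
  }
  if (!identical(as.integer(dim(px)), as.integer(expected_shape)))
    validation_error("mask shape (%s) does not match image shape (%s)",
                     paste(dim(px), collapse = "x"),
                     paste(expected_shape, collapse = "x"))
  px != 0L
}

#' Write an exclusion mask as single-channel PNG
#'
#' @param mask logical matrix, `TRUE` = excluded.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Basal-membrane polyline annotation
#'
#' The basal membrane (epidermis-dermis border) is annotated as an ordered
#' polyline; depth bands for region stratification are measured from it on
#' the dermal side.
#'
#' @param vertices numeric `n x 2` matrix of `(row, col)` pixel coordinates,
#'   1-based (R convention). On disk the JSON stores 0-based coordinates.
#' @param tissue_side `"below"` or `"above"`: which side of the polyline is
#'   dermal tissue.
#' @return An object of class `basal_line`.
#' @export
basal_line <- function(vertices, tissue_side = "below") {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L || ncol(vertices) != 2L)
    validation_error("a basal line needs >= 2 (row, col) vertices")
  if (!tissue_side %in% c("below", "above"))
    validation_error("tissue_side must be 'below' or 'above'")
  storage.mode(vertices) <- "double"
  structure(list(vertices = vertices, tissue_side = tissue_side),
            class = "basal_line")
}

#' @rdname basal_line
#' @param path JSON file with fields `vertices` (list of `[row, col]`,
#'   0-based) and `tissue_side`.
#' @export
read_basal_line <- function(path) {
  if (!file.exists(path)) io_error("file does not exist: %s", path)
  obj <- jsonlite::fromJSON(path)
  basal_line(obj$vertices + 1, obj$tissue_side %||% "below")
}

#' @rdname basal_line
#' @param line a `basal_line` object.
#' @export
write_basal_line <- function(line, path) {
  stopifnot(inherits(line, "basal_line"))
  jsonlite::write_json(
    list(vertices = unname(line$vertices - 1), tissue_side = line$tissue_side),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

RESULT_COLUMNS <- c("specimen", "region", "n_cells", "sampled_area_mm2",
                    "density_per_mm2", "area_min_um2", "area_max_um2",
                    "threshold", "seed")

#' Build one quantification result row
#'
#' @param specimen specimen identifier.
#' @param region region name (e.g. `"subepidermal"`, `"deep_dermal"`,
#'   `"granulation"`).
#' @param n_cells non-negative integer count after all filters.
#' @param sampled_area_mm2 positive area actually counted, in \eqn{mm^2}.
#' @param area_interval numeric `c(min, max)` in \eqn{\mu m^2} used for the
#'   area filter.
#' @param threshold threshold descriptor logged with the result (e.g.
#'   `"otsu:0.4321"`).
#' @param seed integer seed used for field sampling (`NA` if none).
#' @return One-row `data.frame` with the canonical result columns; the
#'   density column is `n_cells / sampled_area_mm2`.
#' @export
quant_result_row <- function(specimen, region, n_cells, sampled_area_mm2,
                             area_interval = c(8, 300), threshold = NA,
                             seed = NA) {
  if (n_cells < 0 || n_cells != round(n_cells))
    validation_error("n_cells must be a non-negative integer")
  assert_scalar_number(sampled_area_mm2, "sampled_area_mm2", positive = TRUE)
  data.frame(specimen = as.character(specimen), region = as.character(region),
             n_cells = as.integer(n_cells),
             sampled_area_mm2 = sampled_area_mm2,
             density_per_mm2 = n_cells / sampled_area_mm2,
             area_min_um2 = area_interval[1], area_max_um2 = area_interval[2],
             threshold = as.character(threshold), seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Write / read quantification results
#'
#' Results are written as a plain CSV with a fixed column set and full
#' floating-point precision, so that write/read round-trips are lossless
#' and two runs with identical inputs produce byte-identical files.
#'
#' @param rows `data.frame` of result rows (see [quant_result_row()]), or a
#'   list of such one-row frames.
#' @param path output `.csv` path.
#' @return `path` (write) / `data.frame` (read).
#' @export
write_results <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) rows <- do.call(rbind, rows)
  if (is.null(rows) || !is.data.frame(rows) || nrow(rows) == 0L)
    validation_error("`rows` must contain at least one result row")
  missing <- setdiff(RESULT_COLUMNS, names(rows))
  if (length(missing))
    validation_error("result rows lack columns: %s",
                     paste(missing, collapse = ", "))
  rows <- rows[RESULT_COLUMNS]
  fmt_num <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "NA"
      else if (is.numeric(v) && v == round(v) && abs(v) < 1e15)
        sprintf("%d", as.integer(v))
      else sprintf("%.17g", as.numeric(v))
    }, character(1))
    out
  }
  lines <- paste(RESULT_COLUMNS, collapse = ",")
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    lines <- c(lines, paste(
      r$specimen, r$region, r$n_cells,
      fmt_num(r$sampled_area_mm2), fmt_num(r$density_per_mm2),
      fmt_num(r$area_min_um2), fmt_num(r$area_max_um2),
      r$threshold, ifelse(is.na(r$seed), "NA", r$seed), sep = ","))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error("cannot write results to %s", path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path)) io_error("file does not exist: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(RESULT_COLUMNS, names(df))
  if (length(missing))
    validation_error("%s lacks result columns: %s", path,
                     paste(missing, collapse = ", "))
  df$n_cells <- as.integer(df$n_cells)
  df$seed <- as.integer(df$seed)
  df$threshold <- as.character(df$threshold)
  df
}
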