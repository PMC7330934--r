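#' Region specification
#'
#' A named pixel region with its physical area, used to stratify counts
#' (subepidermal band, deep dermal band, granulation tissue, or the whole
#' image).
#'
#' @param name region name.
#' @param mask logical `H x W`, `TRUE` = inside the region.
#' @param microns_per_pixel calibration of the underlying image.
#' @return Object of class `region_spec` with `$name`, `$mask`,
#'   `$area_mm2 = sum(mask) * microns_per_pixel^2 / 1e6` and the
#'   calibration.
#' @export
region_spec <- function(name, mask, microns_per_pixel) {
  stopifnot(is.logical(mask), is.matrix(mask))
  assert_scalar_number(microns_per_pixel, "microns_per_pixel", positive = TRUE)
  structure(list(name = as.character(name), mask = mask,
                 area_mm2 = sum(mask) * microns_per_pixel^2 / 1e6,
                 microns_per_pixel = microns_per_pixel),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> '%s': %d px, %.4g mm^2\n", x$name,
              sum(x$mask), x$area_mm2))
  invisible(x)
}

# Bresenham rasterization of the polyline onto an H x W logical matrix
rasterize_polyline <- function(vertices, shape) {
  H <- shape[1]; W <- shape[2]
  out <- matrix(FALSE, H, W)
  v <- round(vertices)
  if (any(v[, 1] < 1 | v[, 1] > H | v[, 2] < 1 | v[, 2] > W))
    validation_error("polyline vertex outside image bounds (%d x %d)", H, W)
  for (i in seq_len(nrow(v) - 1L)) {
    r0 <- v[i, 1]; c0 <- v[i, 2]; r1 <- v[i + 1L, 1]; c1 <- v[i + 1L, 2]
    n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
    rr <- round(seq(r0, r1, length.out = n))
    cc <- round(seq(c0, c1, length.out = n))
    out[cbind(rr, cc)] <- TRUE
  }
  out
}

# Which side of the basal line is dermal: interpolate the line's row at
# every column (nearest endpoint beyond the span) and compare pixel rows.
dermal_side_mask <- function(line, shape) {
  H <- shape[1]; W <- shape[2]
  vr <- line$vertices[, 1]; vc <- line$vertices[, 2]
  o <- order(vc)
  line_row <- stats::approx(vc[o], vr[o], xout = seq_len(W), rule = 2,
                            ties = mean)$y
  rows <- matrix(seq_len(H), H, W)
  lr <- matrix(line_row, H, W, byrow = TRUE)
  if (line$tissue_side == "below") rows > lr else rows < lr
}

#' Depth-band regions below the basal membrane
#'
#' Builds one region per depth band, where a pixel's depth is its Euclidean
#' distance (in microns, via the exact distance transform) to the
#' rasterized basal polyline, and only pixels on the dermal side of the
#' line are eligible. A band `(lo, hi)` contains pixels with
#' `lo < depth <= hi`, so consecutive bands partition the dermis with no
#' gap or overlap; for a straight horizontal line at 1 um/px the band
#' `(0, 296)` is exactly the 296 rows below the line.
#'
#' @param line a [basal_line()].
#' @param image a [calibrated_image()] (or anything with `dim()` `c(H, W)`
#'   plus `microns_per_pixel` passed explicitly).
#' @param bands list of numeric pairs `c(lo_um, hi_um)`, non-overlapping,
#'   `lo < hi`. Defaults to the subepidermal (0-296 um) and deep dermal
#'   (296-1184 um) bands.
#' @param band_names names for the regions, same length as `bands`.
#' @return List of [region_spec()] objects.
#' @export
depth_band_regions <- function(line, image,
                               bands = list(c(0, 296), c(296, 1184)),
                               band_names = c("subepidermal", "deep_dermal")) {
  stopifnot(inherits(line, "basal_line"), inherits(image, "calibrated_image"))
  shape <- dim(image$pixels)[1:2]
  mpp <- image$microns_per_pixel
  for (b in bands)
    if (length(b) != 2L || b[1] >= b[2])
      validation_error("each band must be c(lo, hi) with lo < hi")
  if (length(bands) > 1L) {
    m <- do.call(rbind, bands)
    o <- order(m[, 1])
    if (any(m[o, 2][-length(bands)] > m[o, 1][-1] + 1e-9))
      validation_error("depth bands overlap")
  }
  if (length(band_names) != length(bands))
    validation_error("band_names must match bands in length")
  line_mask <- rasterize_polyline(line$vertices, shape)
  depth_um <- sqrt(.edt_sq(line_mask)) * mpp
  dermal <- dermal_side_mask(line, shape)
  lapply(seq_along(bands), function(i) {
    b <- bands[[i]]
    region_spec(band_names[i], dermal & depth_um > b[1] & depth_um <= b[2],
                mpp)
  })
}

#' Randomly sample high-power fields inside a region
#'
#' Draws `n` axis-aligned rectangles of a fixed pixel size whose centre
#' pixel lies inside the region mask and which fit entirely inside the
#' image, uniformly without replacement over all such positions; the draw
#' is deterministic given the seed.
#'
#' @param region a [region_spec()].
#' @param n number of fields (the conventional protocol uses 5).
#' @param field_shape_px integer `c(height, width)` of one field in pixels.
#' @param seed integer seed (recorded in downstream results).
#' @return Object of class `field_sample`: `$rectangles` (data.frame
#'   `row, col, height, width`, top-left based), `$seed`,
#'   `$field_area_mm2` (area of one field).
#' @export
sample_hpfs <- function(region, n = 5L, field_shape_px, seed = 1L) {
  stopifnot(inherits(region, "region_spec"))
  if (n < 1L) validation_error("n must be >= 1")
  h <- as.integer(field_shape_px[1]); w <- as.integer(field_shape_px[2])
  H <- nrow(region$mask); W <- ncol(region$mask)
  if (h < 1L || w < 1L || h > H || w > W)
    validation_error("field (%d x %d) does not fit inside image (%d x %d)",
                     h, w, H, W)
  if (!any(region$mask)) validation_error("region '%s' is empty", region$name)
  # candidate top-left corners whose field centre lies in the region
  cr <- (h - 1L) %/% 2L; cc <- (w - 1L) %/% 2L
  centre_ok <- region$mask[(1L + cr):(H - h + 1L + cr),
                           (1L + cc):(W - w + 1L + cc), drop = FALSE]
  cand <- which(centre_ok)
  if (length(cand) < n)
    validation_error(
      "only %d candidate field positions in region '%s' (need %d)",
      length(cand), region$name, n)
  pick <- with_seed(seed, sample(cand, n))
  nr <- nrow(centre_ok)
  rect <- data.frame(row = (pick - 1L) %% nr + 1L,
                     col = (pick - 1L) %/% nr + 1L,
                     height = h, width = w)
  structure(list(rectangles = rect, seed = as.integer(seed),
                 field_area_mm2 = h * w * region$microns_per_pixel^2 / 1e6),
            class = "field_sample")
}

#' Cell density over a sampled area
#'
#' @param n_cells non-negative particle count after all filters.
#' @param sampled_area_mm2 positive sampled area in \eqn{mm^2}.
#' @return Density in cells/\eqn{mm^2}.
#' @export
compute_density <- function(n_cells, sampled_area_mm2) {
  if (n_cells < 0) validation_error("n_cells must be >= 0")
  assert_scalar_number(sampled_area_mm2, "sampled_area_mm2", positive = TRUE)
  n_cells / sampled_area_mm2
}

# particles whose centroid falls inside any of the sampled rectangles;
# a particle is counted once even if rectangles overlap
particles_in_fields <- function(pset, fields) {
  p <- pset$particles
  if (nrow(p) == 0L) return(logical(0))
  hit <- rep(FALSE, nrow(p))
  for (i in seq_len(nrow(fields$rectangles))) {
    rc <- fields$rectangles[i, ]
    hit <- hit | (p$centroid_row >= rc$row & p$centroid_row < rc$row + rc$height &
                    p$centroid_col >= rc$col & p$centroid_col < rc$col + rc$width)
  }
  hit
}

# particles whose centroid lies inside a region mask
particles_in_region <- function(pset, region) {
  p <- pset$particles
  if (nrow(p) == 0L) return(logical(0))
  r <- pmin(pmax(round(p$centroid_row), 1L), nrow(region$mask))
  c <- pmin(pmax(round(p$centroid_col), 1L), ncol(region$mask))
  region$mask[cbind(r, c)]
}
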