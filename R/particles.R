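#' Apply an exclusion mask to a binary stain mask
#'
#' Removes pixels marked as excluded (stained appendages, non-specific
#' foci) from the stained-pixel mask before any counting.
#'
#' @param mask logical `H x W`, `TRUE` = stained.
#' @param exclusion logical `H x W`, `TRUE` = excluded.
#' @return Logical `H x W`: `mask & !exclusion`.
#' @export
apply_exclusion <- function(mask, exclusion) {
  if (!identical(dim(mask), dim(exclusion)))
    validation_error("mask shape (%s) and exclusion shape (%s) differ",
                     paste(dim(mask), collapse = "x"),
                     paste(dim(exclusion), collapse = "x"))
  mask & !exclusion
}

#' Label connected components as particles
#'
#' Connected-component analysis of the binary stain mask. Components are
#' 8-connected by default (diagonal contact joins), matching the common
#' particle-analysis convention. Each particle carries its pixel count,
#' its physical area `area_px * microns_per_pixel^2`, its centroid, and
#' whether it touches the image border.
#'
#' @param mask logical `H x W` matrix.
#' @param microns_per_pixel positive calibration, microns per pixel.
#' @param connectivity 8 (default) or 4.
#' @return Object of class `particle_set`: `$particles` (data.frame with
#'   columns `label`, `area_px`, `area_um2`, `centroid_row`,
#'   `centroid_col`, `touches_border`, `has_nucleus`), `$labels` (integer
#'   `H x W` label image, 0 = background), `$microns_per_pixel`,
#'   `$connectivity`.
#' @export
label_particles <- function(mask, microns_per_pixel, connectivity = 8L) {
  if (!is.matrix(mask) || !is.logical(mask))
    validation_error("`mask` must be a logical matrix")
  assert_scalar_number(microns_per_pixel, "microns_per_pixel", positive = TRUE)
  if (!connectivity %in% c(4L, 8L))
    validation_error("connectivity must be 4 or 8")
  lab <- .cc_label(mask, as.integer(connectivity))
  n <- attr(lab, "n_labels")
  if (n == 0L) {
    particles <- data.frame(label = integer(), area_px = integer(),
                            area_um2 = numeric(), centroid_row = numeric(),
                            centroid_col = numeric(),
                            touches_border = logical(),
                            has_nucleus = logical())
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    rows <- (idx - 1L) %% nrow(mask) + 1L
    cols <- (idx - 1L) %/% nrow(mask) + 1L
    area_px <- tabulate(l, nbins = n)
    centroid_row <- as.numeric(tapply(rows, l, mean))
    centroid_col <- as.numeric(tapply(cols, l, mean))
    border <- rows == 1L | rows == nrow(mask) | cols == 1L | cols == ncol(mask)
    touches <- as.logical(tapply(border, l, any))
    particles <- data.frame(label = seq_len(n), area_px = area_px,
                            area_um2 = area_px * microns_per_pixel^2,
                            centroid_row = centroid_row,
                            centroid_col = centroid_col,
                            touches_border = touches,
                            has_nucleus = NA)
  }
  structure(list(particles = particles, labels = lab,
                 microns_per_pixel = microns_per_pixel,
                 connectivity = as.integer(connectivity)),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, %d-connected, %.4g um/px\n",
              nrow(x$particles), x$connectivity, x$microns_per_pixel))
  invisible(x)
}

#' Filter particles by physical area
#'
#' Keeps particles whose area in \eqn{\mu m^2} lies inside the interval,
#' both bounds inclusive (a cell of exactly the minimum or maximum area is
#' counted). Order is preserved; the label image is untouched so labels
#' remain resolvable.
#'
#' @param pset a [label_particles()] result.
#' @param interval numeric `c(min_um2, max_um2)` with `min < max`; the
#'   conventional mast-cell interval is `c(8, 300)`.
#' @return A `particle_set` containing only the retained particles.
#' @export
filter_by_area <- function(pset, interval = c(8, 300)) {
  stopifnot(inherits(pset, "particle_set"))
  check_area_interval(interval)
  keep <- pset$particles$area_um2 >= interval[1] &
    pset$particles$area_um2 <= interval[2]
  pset$particles <- pset$particles[keep, , drop = FALSE]
  rownames(pset$particles) <- NULL
  pset
}

check_area_interval <- function(interval) {
  if (length(interval) != 2L || anyNA(interval) || !is.finite(interval[1]) ||
      interval[1] >= interval[2] || interval[1] < 0) # max may be Inf
    validation_error("area interval must be c(min, max) with 0 <= min < max")
  invisible(interval)
}

#' Flag and filter particles by nucleus presence
#'
#' A chromogen-positive particle counts as a cell only if it overlaps a
#' counterstained nucleus. Each particle is dilated by one pixel and the
#' fraction of its (dilated) pixels whose counterstain concentration
#' exceeds the counterstain Otsu threshold is compared to
#' `overlap_fraction_min`. With `overlap_fraction_min = 0` every particle
#' passes (identity). Off by default in the pipeline: the standard area
#' criterion subsumes it when anucleate foci are removed by the exclusion
#' mask.
#'
#' @param pset a [label_particles()] result.
#' @param counterstain numeric `H x W` counterstain concentration plane,
#'   aligned with the mask that produced `pset`.
#' @param overlap_fraction_min fraction in `[0, 1]`.
#' @return `particle_set` with `has_nucleus` filled in and non-nucleated
#'   particles removed.
#' @export
nucleus_filter <- function(pset, counterstain, overlap_fraction_min = 0.1) {
  stopifnot(inherits(pset, "particle_set"))
  if (!identical(dim(counterstain), dim(pset$labels)))
    validation_error("counterstain plane not aligned with particle labels")
  if (overlap_fraction_min < 0 || overlap_fraction_min > 1)
    validation_error("overlap_fraction_min must be in [0, 1]")
  if (nrow(pset$particles) == 0L) return(pset)
  thr <- otsu_threshold(pmax(counterstain, 0))
  nuc <- pmax(counterstain, 0) > thr
  H <- nrow(pset$labels); W <- ncol(pset$labels)
  has_nuc <- vapply(pset$particles$label, function(l) {
    idx <- which(pset$labels == l)
    r <- (idx - 1L) %% H + 1L
    c <- (idx - 1L) %/% H + 1L
    # 1-px dilation of the pixel set
    rr <- pmin(pmax(rep(r, 9L) + rep(c(-1L, 0L, 1L), each = 3L * length(r)), 1L), H)
    cc <- pmin(pmax(rep(c, 9L) + rep(rep(c(-1L, 0L, 1L), each = length(r)), 3L), 1L), W)
    px <- unique((cc - 1L) * H + rr)
    mean(nuc[px]) >= overlap_fraction_min
  }, logical(1))
  pset$particles$has_nucleus <- has_nuc
  pset$particles <- pset$particles[has_nuc, , drop = FALSE]
  rownames(pset$particles) <- NULL
  pset
}

#' Establish an area interval from confirmed cell areas
#'
#' Given areas of cells confirmed by an expert, returns the empirical
#' quantile interval to use as the area filter; quantiles `(0, 1)` give
#' the observed min/max.
#'
#' @param areas_um2 numeric vector of confirmed cell areas (>= 2 values).
#' @param lo_quantile,hi_quantile quantile levels, `0 <= lo < hi <= 1`.
#' @return Numeric `c(min_um2, max_um2)` with `min < max`.
#' @export
calibrate_area_range <- function(areas_um2, lo_quantile = 0,
                                 hi_quantile = 1) {
  if (length(areas_um2) < 2L || anyNA(areas_um2))
    validation_error("need >= 2 confirmed cell areas without missing values")
  if (lo_quantile < 0 || hi_quantile > 1 || lo_quantile >= hi_quantile)
    validation_error("need 0 <= lo_quantile < hi_quantile <= 1")
  q <- unname(stats::quantile(areas_um2, c(lo_quantile, hi_quantile),
                              type = 7))
  if (q[1] >= q[2])
    validation_error(
      "degenerate interval [%g, %g]: supplied areas lack spread", q[1], q[2])
  q
}
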