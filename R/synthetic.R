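#' Specification of a synthetic brightfield IHC scene
#'
#' Describes the stated world the generator renders: chromogen-positive
#' cells of known areas with counterstained nuclei, oversized
#' appendage-like distractors (to be excluded by mask), sub-threshold
#' specks, and optionally anucleate chromogen foci, on a white background,
#' composed additively in optical-density space and converted to 8-bit
#' RGB.
#'
#' @param width,height canvas size in pixels.
#' @param microns_per_pixel calibration; the default 0.5 um/px is a
#'   typical 200x scan resolution.
#' @param n_cells number of in-range cells.
#' @param area_log_mean,area_log_sd lognormal parameters of the cell-area
#'   distribution in \eqn{\mu m^2} (defaults centre the mass around ~60
#'   \eqn{\mu m^2}, mid-range for mast cells).
#' @param area_range truncation range for cell areas, default the counting
#'   interval `c(8, 300)`; rendered pixel areas are guaranteed inside it.
#' @param n_distractors oversized appendage-like blobs (area above
#'   `area_range[2]`), covered by the returned exclusion mask.
#' @param distractor_area_range area range for distractors, \eqn{\mu m^2}.
#' @param n_specks chromogen specks below `area_range[1]`.
#' @param speck_area_range area range for specks, \eqn{\mu m^2}.
#' @param n_anucleate_foci in-range chromogen foci rendered without a
#'   nucleus (exercise the nucleus filter); not covered by the exclusion
#'   mask.
#' @param basal_line `NULL`, or a list `list(type, row_frac, amplitude_um,
#'   period_um)` with `type` in `"straight"`/`"sine"`: the epidermis-dermis
#'   border; objects are only placed on the dermal (lower) side.
#' @param chromogen_intensity,nucleus_intensity OD scaling of the two
#'   stains inside objects (flat profiles, so Otsu recovers object pixels
#'   exactly).
#' @param noise_sd Gaussian noise added per channel in OD space.
#' @param stains a [stain_matrix()]; must name `chromogen` and
#'   `counterstain`.
#' @param seed integer seed; identical specs give byte-identical scenes.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(width = 512L, height = 512L, microns_per_pixel = 0.5,
                       n_cells = 30L, area_log_mean = log(60),
                       area_log_sd = 0.45, area_range = c(8, 300),
                       n_distractors = 5L,
                       distractor_area_range = c(450, 1500),
                       n_specks = 10L, speck_area_range = c(1, 6),
                       n_anucleate_foci = 0L, basal_line = NULL,
                       chromogen_intensity = 1, nucleus_intensity = 0.8,
                       noise_sd = 0.02, stains = default_stain_matrix(),
                       seed = 1L) {
  if (n_cells < 0 || n_distractors < 0 || n_specks < 0 || n_anucleate_foci < 0)
    validation_error("object counts must be >= 0")
  assert_scalar_number(microns_per_pixel, "microns_per_pixel", positive = TRUE)
  if (area_log_sd <= 0) validation_error("area_log_sd must be > 0")
  check_area_interval(area_range)
  if (distractor_area_range[1] <= area_range[2])
    validation_error("distractors must be larger than area_range[2]")
  if (speck_area_range[2] >= area_range[1])
    validation_error("specks must be smaller than area_range[1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 microns_per_pixel = microns_per_pixel,
                 n_cells = as.integer(n_cells),
                 area_log_mean = area_log_mean, area_log_sd = area_log_sd,
                 area_range = area_range,
                 n_distractors = as.integer(n_distractors),
                 distractor_area_range = distractor_area_range,
                 n_specks = as.integer(n_specks),
                 speck_area_range = speck_area_range,
                 n_anucleate_foci = as.integer(n_anucleate_foci),
                 basal_line = basal_line,
                 chromogen_intensity = chromogen_intensity,
                 nucleus_intensity = nucleus_intensity,
                 noise_sd = noise_sd, stains = stains,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# pixel set of an ellipse: centre (r0, c0), semi-axes (a, b) px, angle th
ellipse_pixels <- function(r0, c0, a, b, th, H, W) {
  half <- ceiling(max(a, b)) + 1L
  rr <- max(1L, floor(r0 - half)):min(H, ceiling(r0 + half))
  cc <- max(1L, floor(c0 - half)):min(W, ceiling(c0 + half))
  dr <- rep(rr, times = length(cc)) - r0
  dc <- rep(cc, each = length(rr)) - c0
  u <- (dc * cos(th) + dr * sin(th)) / a
  v <- (-dc * sin(th) + dr * cos(th)) / b
  inside <- u * u + v * v <= 1
  cbind(row = rep(rr, times = length(cc))[inside],
        col = rep(cc, each = length(rr))[inside])
}

# try to place one ellipse of target area (um^2) avoiding `occupied`
# (already dilated by the separation margin); returns pixel matrix or NULL
place_ellipse <- function(target_um2, mpp, H, W, allowed, occupied,
                          max_tries = 200L) {
  a_px <- target_um2 / mpp^2
  for (try in seq_len(max_tries)) {
    q <- stats::runif(1, 1, 2) # axis ratio
    th <- stats::runif(1, 0, pi)
    a <- sqrt(a_px * q / pi); b <- a / q
    r0 <- stats::runif(1, 1 + a, H - a)
    c0 <- stats::runif(1, 1 + a, W - a)
    if (r0 <= 1 || c0 <= 1 || r0 >= H || c0 >= W) next
    px <- ellipse_pixels(r0, c0, a, b, th, H, W)
    if (nrow(px) == 0L) next
    idx <- (px[, "col"] - 1L) * H + px[, "row"]
    if (any(occupied[idx]) || !all(allowed[idx])) next
    return(list(pixels = px, centre = c(r0, c0), axes = c(a, b), angle = th))
  }
  NULL
}

#' Render a synthetic IHC scene with exact ground truth
#'
#' Objects are placed without overlap by rejection sampling (cells keep a
#' 3-pixel separation so 8-connected labelling never merges them), each
#' object adds its stain vector times a flat intensity in OD space, cells
#' receive a concentric counterstained nucleus ellipse of 40% of the cell
#' area, Gaussian OD noise is added, and the scene is converted to 8-bit
#' RGB. The ground truth is derived from the rendered pixels, so
#' ground-truth areas are exact pixel areas.
#'
#' @param spec a [scene_spec()].
#' @return List with elements:
#' \describe{
#'   \item{image}{[calibrated_image()] of the rendered scene.}
#'   \item{truth}{list: `objects` (data.frame with `class`, `label`,
#'     `centroid_row`, `centroid_col`, `area_px`, `area_um2`,
#'     `has_nucleus`), `label_image` (integer matrix), `chromogen_mask`
#'     (logical: every chromogen-stained pixel).}
#'   \item{exclusion_mask}{logical matrix covering the distractors
#'     (dilated by 2 px), ready to pass to [apply_exclusion()].}
#'   \item{basal_line}{[basal_line()] or `NULL`.}
#'   \item{spec}{the input spec (echo).}
#' }
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$height; W <- spec$width; mpp <- spec$microns_per_pixel
  with_seed(spec$seed, {
    allowed <- matrix(TRUE, H, W)
    bl <- NULL
    if (!is.null(spec$basal_line)) {
      blp <- spec$basal_line
      r0 <- blp$row_frac %||% 0.15
      cols <- seq_len(W)
      rows <- if (identical(blp$type, "sine")) {
        amp <- (blp$amplitude_um %||% 20) / mpp
        per <- (blp$period_um %||% 120) / mpp
        round(r0 * H + amp * sin(2 * pi * cols / per))
      } else rep(round(r0 * H), W)
      rows <- pmin(pmax(rows, 1L), H)
      bl <- basal_line(cbind(rows, cols), tissue_side = "below")
      allowed <- dermal_side_mask(bl, c(H, W)) # place objects dermally only
    }
    occupied <- matrix(FALSE, H, W)
    label_image <- matrix(0L, H, W)
    objects <- list()
    margin <- 1L # occupancy is dilated by `margin` after each placement,
                 # plus candidate pixels are rejected against it -> >= 3 px gaps

    draw_area <- function(n, sampler, range) {
      vapply(seq_len(n), function(i) {
        for (t in 1:500) {
          a <- sampler()
          if (a >= range[1] && a <= range[2]) return(a)
        }
        stats::runif(1, range[1], range[2])
      }, numeric(1))
    }

    add_objects <- function(n, areas, class, range_check = NULL) {
      placed <- 0L
      for (i in seq_len(n)) {
        hit <- NULL
        for (t in 1:40) { # resample area if rasterization leaves the range
          hit <- place_ellipse(areas[i], mpp, H, W, allowed, occupied)
          if (is.null(hit)) break
          if (is.null(range_check)) break
          a_um2 <- nrow(hit$pixels) * mpp^2
          if (a_um2 >= range_check[1] && a_um2 <= range_check[2]) break
          hit <- NULL
          areas[i] <- draw_area(1, function()
            stats::rlnorm(1, spec$area_log_mean, spec$area_log_sd),
            range_check)
        }
        if (is.null(hit))
          validation_error(
            "packing failure: placed %d of %d '%s' objects on a %d x %d canvas",
            placed, n, class, H, W)
        lbl <- length(objects) + 1L
        idx <- (hit$pixels[, "col"] - 1L) * H + hit$pixels[, "row"]
        label_image[idx] <<- lbl
        # dilate occupancy only inside the object's (expanded) bounding box
        pad <- margin + 1L
        rr <- max(1L, min(hit$pixels[, "row"]) - pad):
          min(H, max(hit$pixels[, "row"]) + pad)
        cc <- max(1L, min(hit$pixels[, "col"]) - pad):
          min(W, max(hit$pixels[, "col"]) + pad)
        occ <- matrix(FALSE, length(rr), length(cc))
        occ[cbind(hit$pixels[, "row"] - rr[1] + 1L,
                  hit$pixels[, "col"] - cc[1] + 1L)] <- TRUE
        occupied[rr, cc] <<- occupied[rr, cc] | dilate_mask(occ, pad)
        objects[[lbl]] <<- list(class = class, label = lbl,
                                centre = hit$centre, axes = hit$axes,
                                angle = hit$angle, pixels = hit$pixels)
        placed <- placed + 1L
      }
    }

    cell_areas <- draw_area(spec$n_cells, function()
      stats::rlnorm(1, spec$area_log_mean, spec$area_log_sd), spec$area_range)
    add_objects(spec$n_cells, cell_areas, "cell", range_check = spec$area_range)
    if (spec$n_distractors > 0)
      add_objects(spec$n_distractors,
                  stats::runif(spec$n_distractors,
                               spec$distractor_area_range[1],
                               spec$distractor_area_range[2]),
                  "distractor")
    if (spec$n_specks > 0)
      add_objects(spec$n_specks,
                  stats::runif(spec$n_specks, spec$speck_area_range[1],
                               spec$speck_area_range[2]),
                  "speck")
    if (spec$n_anucleate_foci > 0)
      add_objects(spec$n_anucleate_foci,
                  draw_area(spec$n_anucleate_foci, function()
                    stats::rlnorm(1, spec$area_log_mean, spec$area_log_sd),
                    spec$area_range),
                  "anucleate_focus", range_check = spec$area_range)

    # render in OD space
    od <- array(0, c(H, W, 3L))
    chrom_vec <- spec$stains$M[, "chromogen"]
    counter_vec <- spec$stains$M[, "counterstain"]
    chromogen_mask <- matrix(FALSE, H, W)
    has_nucleus <- logical(length(objects))
    for (ob in objects) {
      idx <- (ob$pixels[, "col"] - 1L) * H + ob$pixels[, "row"]
      chromogen_mask[idx] <- TRUE
      for (ch in 1:3)
        od[idx + (ch - 1L) * H * W] <- od[idx + (ch - 1L) * H * W] +
          spec$chromogen_intensity * chrom_vec[ch]
      if (ob$class == "cell") {
        s <- sqrt(0.4) # nucleus = concentric ellipse, 40% of cell area
        npx <- ellipse_pixels(ob$centre[1], ob$centre[2], ob$axes[1] * s,
                              ob$axes[2] * s, ob$angle, H, W)
        if (nrow(npx) > 0) {
          nidx <- (npx[, "col"] - 1L) * H + npx[, "row"]
          for (ch in 1:3)
            od[nidx + (ch - 1L) * H * W] <- od[nidx + (ch - 1L) * H * W] +
              spec$nucleus_intensity * counter_vec[ch]
          has_nucleus[ob$label] <- TRUE
        }
      }
    }
    if (spec$noise_sd > 0) {
      od <- od + stats::rnorm(length(od), 0, spec$noise_sd)
      od[od < 0] <- 0
    }
    image <- calibrated_image(od_to_rgb(od), mpp)

    exclusion <- matrix(FALSE, H, W)
    for (ob in objects) if (ob$class == "distractor")
      exclusion[(ob$pixels[, "col"] - 1L) * H + ob$pixels[, "row"]] <- TRUE
    if (any(exclusion)) exclusion <- dilate_mask(exclusion, 2L)

    obj_df <- do.call(rbind, lapply(objects, function(ob) {
      data.frame(class = ob$class, label = ob$label,
                 centroid_row = mean(ob$pixels[, "row"]),
                 centroid_col = mean(ob$pixels[, "col"]),
                 area_px = nrow(ob$pixels),
                 area_um2 = nrow(ob$pixels) * mpp^2,
                 has_nucleus = has_nucleus[ob$label],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(obj_df))
      obj_df <- data.frame(class = character(), label = integer(),
                           centroid_row = numeric(), centroid_col = numeric(),
                           area_px = integer(), area_um2 = numeric(),
                           has_nucleus = logical())
    list(image = image,
         truth = list(objects = obj_df, label_image = label_image,
                      chromogen_mask = chromogen_mask),
         exclusion_mask = exclusion, basal_line = bl, spec = spec)
  })
}
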