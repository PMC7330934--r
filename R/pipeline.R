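#' Default run configuration
#'
#' All tunable pipeline parameters with their conventional defaults: the
#' counting interval 8-300 \eqn{\mu m^2}, depth bands 0-296 and 296-1184
#' \eqn{\mu m} below the basal membrane, 5 high-power fields, Otsu
#' thresholding on the chromogen channel, 8-connectivity, nucleus filter
#' off. `hpf$n = 0` disables field sampling and quantifies each whole
#' region; enabling it requires an explicit field size in pixels (no
#' silent default magnification).
#'
#' @return Named list (a run config).
#' @export
default_config <- function() {
  list(
    stains = list(counterstain = c(0.650, 0.704, 0.286),
                  chromogen = c(0.214, 0.851, 0.478)),
    threshold = list(method = "otsu", value = NA_real_),
    area_interval = c(8, 300),
    connectivity = 8,
    depth_bands = list(subepidermal = c(0, 296),
                       deep_dermal = c(296, 1184)),
    hpf = list(n = 0, height = NA_real_, width = NA_real_),
    nucleus_filter = list(enabled = FALSE, overlap_fraction_min = 0.1),
    seed = 1
  )
}

# canonical numeric/shape form so that load(save(config)) == config
as_run_config <- function(x) {
  cfg <- utils::modifyList(default_config(), x)
  cfg$stains <- lapply(cfg$stains, as.numeric)
  cfg$threshold$value <- as.numeric(cfg$threshold$value)
  cfg$area_interval <- as.numeric(cfg$area_interval)
  cfg$connectivity <- as.numeric(cfg$connectivity)
  cfg$depth_bands <- lapply(cfg$depth_bands, as.numeric)
  cfg$hpf <- lapply(cfg$hpf, as.numeric)
  cfg$nucleus_filter$overlap_fraction_min <-
    as.numeric(cfg$nucleus_filter$overlap_fraction_min)
  cfg$nucleus_filter$enabled <- isTRUE(cfg$nucleus_filter$enabled)
  cfg$seed <- as.numeric(cfg$seed)
  cfg
}

#' Save / load a run configuration (JSON)
#'
#' The JSON round-trip is lossless: `load_config(save_config(cfg, f))`
#' equals the canonicalized `cfg`.
#'
#' @param config a config list (see [default_config()]).
#' @param path `.json` path.
#' @return `path` (save) / config list (load).
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(as_run_config(config), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) io_error("file does not exist: %s", path)
  as_run_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

config_stain_matrix <- function(config) {
  stain_matrix(do.call(cbind, config$stains))
}

#' Run the full quantification pipeline on one image
#'
#' Fixed stage order: colour deconvolution, binarization of the chromogen
#' channel, mask-based exclusion, connected-component labelling, optional
#' nucleus filter, area filter, region stratification (depth bands from
#' the basal line, or the whole image), optional random high-power-field
#' sampling, and density in cells/\eqn{mm^2}. Every parameter used is
#' echoed in the returned log.
#'
#' @param image a [calibrated_image()].
#' @param config run config (see [default_config()]); partial lists are
#'   completed with defaults.
#' @param exclusion optional logical exclusion mask (`TRUE` = excluded).
#' @param basal optional [basal_line()]; when given, counts are stratified
#'   into the configured depth bands, otherwise the whole image is one
#'   region named `"full"`.
#' @param specimen specimen id written into the result rows.
#' @return List of class `quant_run`: `$results` (data.frame of result
#'   rows: one pooled row per region, plus one row per sampled field when
#'   HPF sampling is on), `$log` (parameter echo), `$particles` (the
#'   filtered [label_particles()] set).
#' @export
run_quantify <- function(image, config = default_config(), exclusion = NULL,
                         basal = NULL, specimen = "specimen1") {
  stopifnot(inherits(image, "calibrated_image"))
  cfg <- as_run_config(config)
  mpp <- image$microns_per_pixel
  stains <- config_stain_matrix(cfg)

  od <- rgb_to_od(image)
  conc <- deconvolve(od, stains)
  bin <- binarize(conc[, , "chromogen"],
                  method = cfg$threshold$method,
                  fixed_threshold = if (identical(cfg$threshold$method, "fixed"))
                    cfg$threshold$value else NULL)
  mask <- if (is.null(exclusion)) bin$mask else
    apply_exclusion(bin$mask, exclusion)
  pset <- label_particles(mask, mpp, connectivity = cfg$connectivity)
  if (isTRUE(cfg$nucleus_filter$enabled))
    pset <- nucleus_filter(pset, conc[, , "counterstain"],
                           cfg$nucleus_filter$overlap_fraction_min)
  n_prefilter <- nrow(pset$particles)
  pset <- filter_by_area(pset, cfg$area_interval)

  regions <- if (is.null(basal)) {
    list(region_spec("full", matrix(TRUE, dim(image)[1], dim(image)[2]), mpp))
  } else {
    depth_band_regions(basal, image, bands = unname(cfg$depth_bands),
                       band_names = names(cfg$depth_bands))
  }

  thr_str <- sprintf("%s:%.10g", bin$method, bin$threshold)
  rows <- list()
  use_hpf <- cfg$hpf$n >= 1 && is.finite(cfg$hpf$height) &&
    is.finite(cfg$hpf$width)
  for (region in regions) {
    in_region <- particles_in_region(pset, region)
    if (use_hpf) {
      fields <- sample_hpfs(region, n = cfg$hpf$n,
                            field_shape_px = c(cfg$hpf$height, cfg$hpf$width),
                            seed = cfg$seed)
      in_any <- particles_in_fields(pset, fields)
      pooled_n <- sum(in_any)
      pooled_area <- nrow(fields$rectangles) * fields$field_area_mm2
      rows[[length(rows) + 1L]] <- quant_result_row(
        specimen, region$name, pooled_n, pooled_area,
        cfg$area_interval, thr_str, cfg$seed)
      for (i in seq_len(nrow(fields$rectangles))) {
        one <- fields[]; one$rectangles <- fields$rectangles[i, , drop = FALSE]
        class(one) <- "field_sample"
        ni <- sum(particles_in_fields(pset, one))
        rows[[length(rows) + 1L]] <- quant_result_row(
          specimen, sprintf("%s/field%d", region$name, i), ni,
          fields$field_area_mm2, cfg$area_interval, thr_str, cfg$seed)
      }
    } else {
      if (region$area_mm2 <= 0)
        validation_error("region '%s' has zero area", region$name)
      rows[[length(rows) + 1L]] <- quant_result_row(
        specimen, region$name, sum(in_region), region$area_mm2,
        cfg$area_interval, thr_str, cfg$seed)
    }
  }
  results <- do.call(rbind, rows)
  log <- list(config = cfg, threshold_applied = bin$threshold,
              stains = unclass(stains$M), n_particles_prefilter = n_prefilter,
              specimen = specimen,
              image = list(height = dim(image)[1], width = dim(image)[2],
                           microns_per_pixel = mpp),
              exclusion_applied = !is.null(exclusion),
              basal_line_used = !is.null(basal))
  structure(list(results = results, log = log, particles = pset),
            class = "quant_run")
}

#' @export
print.quant_run <- function(x, ...) {
  cat("<quant_run>\n")
  print(x$results[, c("specimen", "region", "n_cells", "sampled_area_mm2",
                      "density_per_mm2")])
  invisible(x)
}
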