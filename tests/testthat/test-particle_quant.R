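test_that("apply_exclusion masks out excluded pixels only", {
  m <- matrix(FALSE, 10, 10)
  m[2:3, 2:3] <- TRUE # blob 1
  m[7:8, 7:8] <- TRUE # blob 2
  none <- matrix(FALSE, 10, 10)
  all_ex <- matrix(TRUE, 10, 10)
  expect_identical(apply_exclusion(m, none), m)
  expect_false(any(apply_exclusion(m, all_ex)))
  ex <- none; ex[6:9, 6:9] <- TRUE
  out <- apply_exclusion(m, ex)
  expect_equal(sum(out), 4)
  expect_true(all(out[2:3, 2:3]))
  expect_error(apply_exclusion(m, matrix(FALSE, 5, 5)),
               class = "ihcquant_validation_error")
})

test_that("label_particles uses 8-connectivity and exact areas", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE # diagonal contact
  p8 <- label_particles(m, 1, connectivity = 8)
  expect_equal(nrow(p8$particles), 1L)
  p4 <- label_particles(m, 1, connectivity = 4)
  expect_equal(nrow(p4$particles), 2L)

  empty <- label_particles(matrix(FALSE, 4, 4), 1)
  expect_equal(nrow(empty$particles), 0L)

  # 100 disjoint 5x5 squares at 1 um/px: 100 particles of 25 um^2
  big <- matrix(FALSE, 70, 70)
  for (i in 0:9) for (j in 0:9)
    big[(i * 7 + 1):(i * 7 + 5), (j * 7 + 1):(j * 7 + 5)] <- TRUE
  ps <- label_particles(big, 1)
  expect_equal(nrow(ps$particles), 100L)
  expect_true(all(ps$particles$area_px == 25L))
  expect_true(all(ps$particles$area_um2 == 25))
  expect_equal(ps$particles$area_um2,
               ps$particles$area_px * ps$microns_per_pixel^2)
})

test_that("labelling agrees with the flood-fill oracle on random masks", {
  set.seed(21)
  for (conn in c(4L, 8L)) {
    for (i in 1:5) {
      m <- matrix(runif(40 * 40) < 0.35, 40, 40)
      mine <- label_particles(m, 0.5, connectivity = conn)
      oracle <- flood_fill_label(m, conn)
      expect_equal(nrow(mine$particles), max(oracle))
      # same partition: labels must be a relabelling of each other
      expect_equal(length(unique(paste(mine$labels[m], oracle[m]))),
                   max(oracle))
      o_areas <- sort(as.integer(table(oracle[oracle > 0])))
      expect_equal(sort(mine$particles$area_px), o_areas)
    }
  }
})

test_that("area filter keeps inclusive bounds and preserves order", {
  areas <- c(2, 8, 50, 300, 301, 500) # um^2 at 1 um/px -> px counts
  m <- matrix(FALSE, 40, 1600)
  col <- 1L
  for (a in areas) { # one 1-px-tall run per particle, 2 cols apart
    m[1, col:(col + a - 1L)] <- TRUE
    col <- col + a + 2L
  }
  ps <- label_particles(m, 1)
  expect_equal(sort(ps$particles$area_um2), sort(areas))
  kept <- filter_by_area(ps, c(8, 300))
  expect_equal(nrow(kept$particles), 3L)
  expect_setequal(kept$particles$area_um2, c(8, 50, 300)) # both endpoints in
  expect_equal(kept$particles$area_um2,
               ps$particles$area_um2[ps$particles$area_um2 >= 8 &
                                       ps$particles$area_um2 <= 300])

  expect_equal(nrow(filter_by_area(ps, c(0, Inf))$particles), 6L)
  expect_equal(nrow(filter_by_area(ps, c(1000, 2000))$particles), 0L)
  expect_error(filter_by_area(ps, c(300, 8)),
               class = "ihcquant_validation_error")

  # idempotent, and commutes with exclusion
  expect_identical(filter_by_area(kept, c(8, 300))$particles, kept$particles)
  ex <- matrix(FALSE, 40, 1600); ex[, 1:9] <- TRUE
  a <- filter_by_area(label_particles(apply_exclusion(m, ex), 1), c(8, 300))
  b_ps <- filter_by_area(label_particles(m, 1), c(8, 300))
  b_keep <- vapply(seq_len(nrow(b_ps$particles)), function(i)
    !any(ex[b_ps$labels == b_ps$particles$label[i]]), logical(1))
  expect_equal(sort(a$particles$area_um2),
               sort(b_ps$particles$area_um2[b_keep]))
})

test_that("nucleus filter keeps nucleated particles and is identity at 0", {
  scene <- generate_scene(scene_spec(seed = 9, n_cells = 12,
                                     n_distractors = 0, n_specks = 0,
                                     n_anucleate_foci = 6))
  conc <- deconvolve(rgb_to_od(scene$image), default_stain_matrix())
  mask <- binarize(conc[, , "chromogen"], "otsu")$mask
  ps <- filter_by_area(label_particles(mask, 0.5), c(8, 300))
  expect_equal(nrow(ps$particles), 18L)

  id <- nucleus_filter(ps, conc[, , "counterstain"], 0)
  expect_equal(nrow(id$particles), nrow(ps$particles))

  kept <- nucleus_filter(ps, conc[, , "counterstain"], 0.1)
  expect_equal(nrow(kept$particles), 12L) # anucleate foci removed
  expect_true(all(kept$particles$has_nucleus))
})

test_that("depth bands have exact geometry for a straight horizontal line", {
  img <- calibrated_image(array(255L, c(1300, 50, 3)), 1)
  bl <- basal_line(cbind(c(100, 100), c(1, 50)))
  regions <- depth_band_regions(bl, img)
  expect_equal(vapply(regions, function(r) r$name, ""),
               c("subepidermal", "deep_dermal"))
  sub <- regions[[1]]$mask; deep <- regions[[2]]$mask
  expect_equal(sum(rowSums(sub) > 0), 296) # 296 full rows below the line
  expect_true(all(rowSums(sub)[101:396] == 50))
  expect_equal(sum(rowSums(deep) > 0), 888)
  expect_true(all(rowSums(deep)[397:1284] == 50))
  expect_false(any(sub & deep)) # disjoint
  u <- sub | deep # union contiguous: rows 101..1284
  expect_true(all(rowSums(u)[101:1284] == 50))
  expect_equal(sum(u), (1284 - 101 + 1) * 50)
  expect_equal(regions[[1]]$area_mm2, 296 * 50 / 1e6)
})

test_that("depth bands partition the dermal side for curved lines too", {
  img <- calibrated_image(array(255L, c(200, 120, 3)), 2)
  cols <- seq(1, 120, by = 4)
  bl <- basal_line(cbind(30 + round(8 * sin(cols / 9)), cols))
  regions <- depth_band_regions(bl, img, bands = list(c(0, 100), c(100, 250)),
                                band_names = c("a", "b"))
  both <- depth_band_regions(bl, img, bands = list(c(0, 250)),
                             band_names = "all")[[1]]
  expect_false(any(regions[[1]]$mask & regions[[2]]$mask))
  expect_identical(regions[[1]]$mask | regions[[2]]$mask, both$mask)

  # degenerate thin band: never negative, at most one row of pixels
  thin <- depth_band_regions(bl, img, bands = list(c(0, 0.5)),
                             band_names = "thin")[[1]]
  expect_gte(sum(thin$mask), 0)
  expect_error(depth_band_regions(bl, img, bands = list(c(5, 5))),
               class = "ihcquant_validation_error")
  expect_error(depth_band_regions(bl, img,
                                  bands = list(c(0, 100), c(50, 200)),
                                  band_names = c("x", "y")),
               class = "ihcquant_validation_error")
  expect_error(depth_band_regions(basal_line(cbind(c(500, 500), c(1, 10))),
                                  img),
               class = "ihcquant_validation_error")
})

test_that("HPF sampling is seeded, exact in count, and validates space", {
  mask <- matrix(TRUE, 100, 100)
  region <- region_spec("full", mask, 1)
  s1 <- sample_hpfs(region, n = 5, field_shape_px = c(20, 20), seed = 42)
  s2 <- sample_hpfs(region, n = 5, field_shape_px = c(20, 20), seed = 42)
  expect_identical(s1$rectangles, s2$rectangles)
  expect_equal(nrow(s1$rectangles), 5L)
  s3 <- sample_hpfs(region, n = 5, field_shape_px = c(20, 20), seed = 43)
  expect_false(identical(s1$rectangles, s3$rectangles))
  expect_equal(s1$field_area_mm2, 400 / 1e6)
  # all rectangles inside the image and centred in the region
  expect_true(all(s1$rectangles$row >= 1 & s1$rectangles$row + 19 <= 100))
  expect_true(all(s1$rectangles$col >= 1 & s1$rectangles$col + 19 <= 100))

  small <- region_spec("tiny", rbind(matrix(TRUE, 5, 30),
                                     matrix(FALSE, 25, 30)), 1)
  expect_error(sample_hpfs(small, n = 5000, field_shape_px = c(10, 10)),
               class = "ihcquant_validation_error")
  expect_error(sample_hpfs(region, n = 1, field_shape_px = c(200, 10)),
               class = "ihcquant_validation_error")
})

test_that("compute_density is count over area", {
  expect_equal(compute_density(10, 0.5), 20)
  expect_equal(compute_density(0, 2), 0)
  expect_error(compute_density(5, 0), class = "ihcquant_validation_error")
  expect_error(compute_density(-1, 1), class = "ihcquant_validation_error")
})

test_that("calibrate_area_range matches a sorted-array quantile oracle", {
  expect_equal(calibrate_area_range(c(8, 50, 300), 0, 1), c(8, 300))
  expect_error(calibrate_area_range(c(5, 5, 5), 0, 1),
               class = "ihcquant_validation_error")
  expect_error(calibrate_area_range(numeric(0)),
               class = "ihcquant_validation_error")
  expect_error(calibrate_area_range(c(1, 2), 0.9, 0.1),
               class = "ihcquant_validation_error")

  set.seed(13)
  areas <- rlnorm(1000, log(60), 0.45)
  iv <- calibrate_area_range(areas, 0.01, 0.99)
  inside <- mean(areas >= iv[1] & areas <= iv[2])
  expect_gte(inside, 0.98) # central 98% of the distribution is contained
  s <- sort(areas) # independent recomputation from the sorted array (type 7)
  h <- function(p) { x <- (length(s) - 1) * p; lo <- floor(x)
    s[lo + 1] * (1 - (x - lo)) + s[min(lo + 2, length(s))] * (x - lo) }
  expect_equal(iv, c(h(0.01), h(0.99)))
})
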