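test_that("binarization finds no particles in a uniform image", {
  scan <- scan_image(matrix(0.8, 50, 60))
  mask <- binarize_scan(scan)
  expect_equal(sum(mask), 0)
  # constant image with a manual threshold below the intensity: still empty
  mask2 <- binarize_scan(scan, segmentation_settings("manual", manual_threshold = 0.1))
  expect_equal(sum(mask2), 0)
})

test_that("binarization isolates a single dark disc as one region", {
  scan <- disc_scan(radius = 15, size = 61)
  mask <- binarize_scan(scan)
  parts <- extract_particles(scan, mask, segmentation_settings(crop_size_px = 61))
  expect_length(parts, 1)
})

test_that("non-positive contrast gain is an invalid-settings error", {
  expect_error(segmentation_settings(contrast_gain = 0), "contrast_gain")
  expect_error(segmentation_settings(contrast_gain = -1), "contrast_gain")
})

test_that("extracted crops honour the configured crop size, with padding at edges", {
  scan <- disc_scan(radius = 10, size = 81)
  mask <- binarize_scan(scan)
  parts <- extract_particles(scan, mask)  # default 280 px crop on an 81 px scan
  expect_equal(dim(parts[[1]]$crop), c(280, 280))
  # corner particle: crop still full size, padded with background intensity
  corner <- disc_scan(radius = 10, size = 81, center = c(5, 5))
  pc <- extract_particles(corner, binarize_scan(corner),
                          segmentation_settings(crop_size_px = 64))[[1]]
  expect_equal(dim(pc$crop), c(64, 64))
  expect_equal(pc$crop[64, 64], 0.9, tolerance = 1 / 255)  # modal background pad
})

test_that("morphometry matches closed-form disc geometry", {
  scan <- disc_scan(radius = 25, size = 101, scale = 1)
  parts <- extract_particles(scan, binarize_scan(scan),
                             segmentation_settings(crop_size_px = 101))
  p <- parts[[1]]
  expect_equal(p$equivalent_diameter_um, 50, tolerance = 0.02)
  expect_equal(p$equivalent_diameter_um, 2 * sqrt(p$area_um2 / pi),
               tolerance = 1e-9)
  expect_gt(p$circularity, 0.9)
  expect_lte(p$circularity, 1)
  # scale equivariance: doubling the scale doubles physical measures only
  scan2 <- disc_scan(radius = 25, size = 101, scale = 2)
  p2 <- extract_particles(scan2, binarize_scan(scan2),
                          segmentation_settings(crop_size_px = 101))[[1]]
  expect_equal(p2$equivalent_diameter_um, 2 * p$equivalent_diameter_um)
  expect_equal(p2$area_um2, 4 * p$area_um2)
  expect_equal(p2$centroid_px, p$centroid_px)
  expect_equal(p2$bbox_px, p$bbox_px)
})

test_that("labeling uses 8-connectivity and count conservation holds", {
  m <- matrix(0.9, 30, 30)
  m[5:8, 5:8] <- 0.1        # block A
  m[9:12, 9:12] <- 0.1      # block B touching A only diagonally
  m[20:24, 20:24] <- 0.1    # separate block C
  scan <- scan_image(m)
  settings <- segmentation_settings(min_region_area_px = 1, crop_size_px = 16)
  mask <- binarize_scan(scan, settings)
  parts <- extract_particles(scan, mask, settings)
  expect_length(parts, 2)  # A+B merged diagonally, C separate
  expect_equal(sort(vapply(parts, function(p) p$object_id, numeric(1))),
               seq_along(parts))
})

test_that("small regions are removed by the minimum-area setting", {
  m <- matrix(0.9, 40, 40)
  m[10:20, 10:20] <- 0.1  # 121 px
  m[30, 30] <- 0.1        # 1 px speck
  scan <- scan_image(m)
  mask <- binarize_scan(scan, segmentation_settings(min_region_area_px = 5))
  parts <- extract_particles(scan, mask, segmentation_settings(crop_size_px = 20))
  expect_length(parts, 1)
})

test_that("size filter retains the window, preserves order, reports exclusions", {
  mk <- function(id, d) structure(list(object_id = id, equivalent_diameter_um = d),
                                  class = "particle_object")
  parts <- list(mk(1, 100), mk(2, 50), mk(3, 160), mk(4, 60), mk(5, 200))
  res <- filter_by_size(parts, size_filter(60, 160))
  expect_equal(vapply(res$particles, function(p) p$object_id, numeric(1)),
               c(1, 3, 4))  # bounds inclusive, order preserved
  expect_equal(res$n_excluded, 2)
  expect_equal(res$excluded_fraction, 0.4)
  # monotonicity: shrinking the window never increases the retained count
  wide <- filter_by_size(parts, size_filter(40, 220))
  narrow <- filter_by_size(parts, size_filter(80, 120))
  expect_gte(length(wide$particles), length(res$particles))
  expect_gte(length(res$particles), length(narrow$particles))
  expect_equal(filter_by_size(list(), size_filter())$excluded_fraction, 0)
})

test_that("excluded fraction matches the diameter distribution at scale", {
  withr::with_seed(31, {
    # sigma chosen so ~30% of the population falls outside the 60-160 window
    d <- sample_diameters(1500, median_um = 100, sigma = 0.47)
    parts <- lapply(seq_along(d), function(i) {
      structure(list(object_id = i, equivalent_diameter_um = d[i]),
                class = "particle_object")
    })
    res <- filter_by_size(parts, size_filter(60, 160))
    p_out <- plnorm(60, log(100), 0.47) + plnorm(160, log(100), 0.47,
                                                 lower.tail = FALSE)
    expect_equal(p_out, 0.3, tolerance = 0.01)
    se <- sqrt(p_out * (1 - p_out) / length(d))
    expect_lt(abs(res$excluded_fraction - p_out), 3 * se)
  })
})

test_that("segmentation recovers synthetic ground truth exactly", {
  sl <- generate_slide(slide_spec(seed = 7))
  mask <- binarize_scan(sl$scan)
  parts <- extract_particles(sl$scan, mask)
  expect_length(parts, nrow(sl$truth))  # count conservation vs generator truth
  cx <- vapply(parts, function(p) unname(p$centroid_px["x"]), numeric(1))
  cy <- vapply(parts, function(p) unname(p$centroid_px["y"]), numeric(1))
  err <- vapply(seq_len(nrow(sl$truth)), function(i) {
    min(sqrt((cx - sl$truth$x_px[i])^2 + (cy - sl$truth$y_px[i])^2))
  }, numeric(1))
  expect_lt(max(err), 2)
})

test_that("mask dimension mismatch is rejected", {
  scan <- disc_scan(radius = 5, size = 31)
  expect_error(extract_particles(scan, matrix(FALSE, 10, 10)), "dimensions")
})

test_that("particle gallery and table round-trip to disk", {
  scan <- disc_scan(radius = 8, size = 61)
  parts <- extract_particles(scan, binarize_scan(scan),
                             segmentation_settings(crop_size_px = 32))
  out <- withr::local_tempdir()
  tab <- write_particle_gallery(parts, "disc", out)
  expect_true(file.exists(file.path(out, "disc_1.png")))
  back <- read.csv(file.path(out, "particles.csv"))
  expect_equal(back$equiv_diameter_um, tab$equiv_diameter_um, tolerance = 1e-6)
  crop <- read_scan(file.path(out, "disc_1.png"))
  expect_equal(dim(crop$pixels), c(32, 32))
})
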