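test_that("pearled radius profile evaluates the Gaussian-bump formula", {
  flat <- pearled_radius_profile(0.15, NULL, length_um = 10)
  expect_true(all(flat$r == 0.15))

  p <- pearled_radius_profile(0.15,
         data.frame(center = 5, amplitude = 0.10, width = 1),
         length_um = 10)
  expect_equal(radius_at(p, 5), 0.25, tolerance = 1e-12)
  expect_equal(radius_at(p, 6), 0.15 + 0.10 * exp(-1 / 2),
               tolerance = 1e-6)
  expect_equal(radius_at(p, 4), radius_at(p, 6), tolerance = 1e-6)

  expect_error(pearled_radius_profile(0.10,
    data.frame(center = 5, amplitude = -0.12, width = 1), 10),
    "non-positive")
})

test_that("sinusoidal profile preset stays positive and validates", {
  p <- sinusoidal_radius_profile(0.2, 0.05, period = 3, length_um = 9)
  expect_true(all(p$r > 0))
  expect_equal(max(p$r), 0.25, tolerance = 1e-3)
  expect_error(sinusoidal_radius_profile(0.1, 0.1, 3, 9), "smaller")
})

test_that("rendered intensity ridges sit at the membrane boundaries", {
  # near-delta PSF: the two boundary lines of a d = 0.6 um tube land on
  # rows 0.6 um apart
  cfg <- noiseless_config(psf_fwhm = 0.02)
  tube <- render_tube(0.6, config = cfg)
  img <- tube$frame$pixels
  mid_cols <- 40:60
  rows <- apply(img[, mid_cols], 2, function(v) {
    o <- order(v, decreasing = TRUE)[1:2]
    sort(o)
  })
  sep <- (rows[2, ] - rows[1, ]) * cfg$pixel_size
  expect_true(all(abs(sep - 0.6) <= cfg$pixel_size))
})

test_that("rendered perpendicular profile matches the analytic oracle", {
  cfg <- noiseless_config()
  tube <- render_tube(0.6, config = cfg)
  prof <- extract_profile(tube$frame, c(4, 3), c(0, 1), no_smooth())
  v <- prof$intensities - cfg$background
  v <- v / max(v)
  oracle <- analytic_linescan_profile(0.6, psf_sigma = 0.14 / 2.3548,
                                      prof$offsets)
  rms <- sqrt(mean((v - oracle)^2))
  expect_lt(rms, 0.02)
})

test_that("rendering is deterministic in the seed", {
  tr <- straight_axon_truth(6, radius = 0.25, origin = c(1, 3))
  cfg1 <- scene_config(seed = 5)
  f1 <- render_membrane_frame(tr, cfg1)
  f2 <- render_membrane_frame(tr, cfg1)
  expect_identical(f1$pixels, f2$pixels)
  f3 <- render_membrane_frame(tr, scene_config(seed = 6))
  expect_false(identical(f1$pixels, f3$pixels))
})

test_that("geometry leaving the frame is rejected with the segment name", {
  tr <- straight_axon_truth(30, radius = 0.3, origin = c(1, 3))
  expect_error(render_membrane_frame(tr, noiseless_config()), "seg1")
})

test_that("analytic line-scan profile has the expected peak structure", {
  x <- seq(-0.6, 0.6, by = 1e-4)
  v <- analytic_linescan_profile(0.6, 0.06, x)
  pk <- x[local_peaks_for_test(v)]
  expect_length(pk, 2L)
  expect_equal(pk, c(-0.300, 0.300), tolerance = 1e-4)

  v0 <- analytic_linescan_profile(0, 0.06, x)
  expect_length(local_peaks_for_test(v0), 1L)
  expect_equal(x[which.max(v0)], 0, tolerance = 1e-6)

  # separation below 2 sigma: single merged peak
  v1 <- analytic_linescan_profile(0.10, 0.0595, x)
  expect_length(local_peaks_for_test(v1), 1L)
})

test_that("dynamics scripts produce the scripted r(s,t)", {
  scr <- dynamics_script("traveling_pearl", speed = 0.4, n_frames = 5,
                         start_center = 3)
  centers <- vapply(1:5, function(t) {
    p <- scripted_radius_profile(scr, t, 10)
    p$s[which.max(p$r)]
  }, numeric(1))
  expect_equal(diff(centers), rep(0.4, 4), tolerance = 1e-9)

  null_scr <- dynamics_script("focal_inflation_deflation", amplitude = 0,
                              n_frames = 4)
  profs <- lapply(1:4, scripted_radius_profile, script = null_scr,
                  length_um = 10)
  for (p in profs) expect_equal(p$r, profs[[1]]$r)

  con <- dynamics_script("constriction_point", base_radius = 0.2,
                         amplitude = 0.08, onset = 3, offset = 3,
                         n_frames = 5)
  expect_equal(min(scripted_radius_profile(con, 3, 10)$r), 0.12,
               tolerance = 1e-9)
  expect_equal(min(scripted_radius_profile(con, 2, 10)$r), 0.2)

  wide <- dynamics_script("segment_widening_narrowing", base_radius = 0.15,
                          amplitude = 0.06, onset = 1, offset = 5,
                          n_frames = 5)
  p3 <- scripted_radius_profile(wide, 3, 10)
  expect_equal(diff(range(p3$r)), 0, tolerance = 1e-12)  # uniform widening
  expect_equal(p3$r[1], 0.21, tolerance = 1e-9)
})

test_that("scripted radii stay positive across behaviors and frames", {
  for (b in c("traveling_pearl", "focal_inflation_deflation",
              "segment_widening_narrowing", "constriction_point")) {
    scr <- dynamics_script(b, base_radius = 0.15, amplitude = 0.1,
                           n_frames = 8)
    for (t in 1:8)
      expect_true(all(scripted_radius_profile(scr, t, 10)$r > 0))
  }
})

test_that("division series carries the arc-model path lengths", {
  flat <- rounding_scenario(rounded_height = 0, rounded_extent = 10,
                            flat_length = 12)
  s0 <- make_division_series(flat)
  expect_equal(s0$timecourse$true_path_length[s0$round_frame], 10)

  semi <- rounding_scenario(flat_length = 12, rounded_extent = 10,
                            rounded_height = 5)
  s1 <- make_division_series(semi)
  expect_equal(s1$timecourse$true_path_length[s1$round_frame], 5 * pi,
               tolerance = 1e-9)

  L <- s1$timecourse$border_length
  rf <- s1$round_frame
  expect_true(all(diff(L[1:rf]) < 0))
  expect_true(all(diff(L[rf:length(L)]) > 0))

  expect_error(rounding_scenario(flat_length = 8, rounded_extent = 10),
               "rounded_extent")
})

test_that("scene ground truth round-trips through TIFF + JSON sidecar", {
  cfg <- noiseless_config(image_shape = c(120, 200))
  prof <- pearled_radius_profile(0.2,
            data.frame(center = 3, amplitude = 0.08, width = 0.8), 6)
  tr <- straight_axon_truth(6, profile = prof, origin = c(1, 2))
  fr <- render_membrane_frame(tr, cfg)
  path <- file.path(tempdir(), "roundtrip.tif")
  write_scene(fr, tr, cfg, path)
  back <- read_scene(path)
  expect_equal(back$truths[[1]]$radius_profiles$seg1$r, prof$r)
  expect_equal(back$frames[[1]]$pixel_size, cfg$pixel_size)
  # 16-bit quantization bounds the pixel error
  expect_lt(max(abs(back$frames[[1]]$pixels - fr$pixels)),
            max(fr$pixels) * 1.05 / 65535 + 1e-9)
})
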