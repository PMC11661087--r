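test_that("tangent and normal follow the centerline", {
  seg <- cbind(x = c(0, 10), y = c(0, 0))
  tn <- tangent_and_normal(seg, 5)
  expect_equal(tn$tangent, c(1, 0))
  expect_equal(tn$normal, c(0, 1))

  # circle of radius R: normal within 1 degree of the radial direction
  theta <- seq(0, pi, length.out = 400)
  R <- 5
  circ <- cbind(x = R * cos(theta), y = R * sin(theta))
  s_mid <- polyline_arclength_for_test(circ)
  s_mid <- s_mid[length(s_mid)] / 2
  tn2 <- tangent_and_normal(circ, s_mid, h = 0.05)
  pt <- axoncaliber:::point_at_arclength(circ, s_mid)[1, ]
  radial <- pt / sqrt(sum(pt^2))
  ang <- acos(abs(sum(tn2$normal * radial))) * 180 / pi
  expect_lt(ang, 1)

  expect_error(tangent_and_normal(cbind(1, 1), 0), "degenerate")
})

test_that("profile extraction samples the image correctly", {
  const <- image_frame(matrix(7, 80, 80), 0.04)
  prof <- extract_profile(const, c(1.5, 1.5), c(0, 1), no_smooth())
  expect_true(all(prof$intensities == 7))

  # interpolation identity: steps of one pixel along an axis through a
  # pixel center reproduce the stored pixel values
  img <- matrix(runif(80 * 80), 80, 80)
  fr <- image_frame(img, 0.04)
  cfg <- no_smooth(scan_half_length = 0.2, scan_step = 0.04)
  prof2 <- extract_profile(fr, c(1.2, 1.2), c(0, 1), cfg)
  rows <- round((1.2 + prof2$offsets) / 0.04) + 1
  expect_equal(prof2$intensities, img[cbind(rows, 31)], tolerance = 1e-12)

  expect_error(extract_profile(const, c(0.02, 0.02), c(0, 1),
                               no_smooth()), "exits")
})

test_that("extracted profile through a rendered tube matches the oracle", {
  tube <- render_tube(0.8)
  prof <- extract_profile(tube$frame, c(5, 3), c(0, 1), no_smooth())
  v <- prof$intensities - 10
  v <- v / max(v)
  oracle <- analytic_linescan_profile(0.8, 0.14 / 2.3548, prof$offsets)
  expect_lt(sqrt(mean((v - oracle)^2)), 0.02)
})

test_that("caliber is the distance between the two membrane peaks", {
  off <- seq(-1, 1, by = 0.01)
  sharp <- exp(-(off - 0.25)^2 / (2 * 0.03^2)) +
           exp(-(off + 0.25)^2 / (2 * 0.03^2))
  m <- measure_caliber(as_profile(off, sharp), no_smooth())
  expect_equal(m$caliber, 0.50, tolerance = 1e-3)
  expect_false(m$below_resolution || m$single_peak)

  an <- analytic_linescan_profile(0.6, 0.06, off)
  m2 <- measure_caliber(as_profile(off, an), no_smooth())
  expect_equal(m2$caliber, 0.600, tolerance = 0.005)

  merged <- analytic_linescan_profile(0.10, 0.0595, off)
  m3 <- measure_caliber(as_profile(off, merged), no_smooth())
  expect_true(m3$single_peak)
  expect_true(is.na(m3$caliber))

  expect_error(measure_caliber(as_profile(off, rep(1, length(off))),
                               no_smooth()), "flat")
})

test_that("a similar-height second peak raises the ambiguity flag only", {
  off <- seq(-1.5, 1.5, by = 0.01)
  v <- exp(-(off - 0.3)^2 / (2 * 0.05^2)) +
       exp(-(off + 0.3)^2 / (2 * 0.05^2)) +
       0.95 * exp(-(off + 1.0)^2 / (2 * 0.05^2))  # neighbouring axon
  m <- measure_caliber(as_profile(off, v), no_smooth())
  expect_true(m$ambiguous_peaks)
  expect_equal(m$caliber, 0.6, tolerance = 0.01)  # nearest pair still used
})

test_that("measurements along a segment recover a noiseless tube", {
  tube <- render_tube(0.6, length_um = 12, config = noiseless_config(
    image_shape = c(160, 360)))
  m <- measure_along_segment(tube$frame, tube$truth$segments$seg1,
                             positions = 0:10 + 1, segment_id = "seg1")
  expect_equal(nrow(m), 11L)
  expect_true(all(abs(m$caliber - 0.60) <= 0.01))

  # branch-distance exclusion drops, never errors
  m2 <- measure_along_segment(tube$frame, tube$truth$segments$seg1,
                              positions = c(1, 2, 6),
                              branch_arc_positions = 0)
  expect_equal(m2$arc_pos, 6)

  m3 <- measure_along_segment(tube$frame, tube$truth$segments$seg1,
                              positions = c(1, 2),
                              branch_arc_positions = 0)
  expect_equal(nrow(m3), 0L)
  expect_s3_class(m3, "data.frame")
})

test_that("caliber is invariant under scene rotation", {
  d <- 0.6
  straight <- render_tube(d)
  rotated <- render_tube(d, angle = pi / 7, origin = c(1.5, 1.5))
  m1 <- measure_along_segment(straight$frame,
                              straight$truth$segments$seg1, 2:6)
  m2 <- measure_along_segment(rotated$frame,
                              rotated$truth$segments$seg1, 2:6)
  expect_true(all(abs(m1$caliber - m2$caliber) <= 0.04))
})

test_that("exclusion rules drop axons for the documented reasons", {
  meas <- data.frame(
    axon_id = rep(c("a1", "a2", "a3"), each = 10),
    below_resolution = c(rep(FALSE, 7), rep(TRUE, 3),   # a1: 30% at day 1
                         rep(FALSE, 10),                 # a2: clean
                         rep(FALSE, 10)),                # a3: clean
    day = 1)
  res <- apply_exclusion_rules(meas)
  expect_true("a1" %in% res$log$axon_id)
  expect_false(any(res$retained$axon_id == "a1"))
  expect_true(all(c("a2", "a3") %in% res$retained$axon_id))

  meas$role <- rep(c("P", rep("S1", 9)), 3)
  meas$below_resolution <- FALSE
  meas$below_resolution[meas$axon_id == "a2" & meas$role == "P"] <- TRUE
  res2 <- apply_exclusion_rules(meas)
  expect_equal(unique(res2$log$rule), "primary_below_resolution")
  expect_false(any(res2$retained$axon_id == "a2"))

  meta <- data.frame(axon_id = "a3", branch_spacing = 2)
  res3 <- apply_exclusion_rules(meas[meas$axon_id == "a3", ],
                                axon_meta = meta,
                                min_branch_spacing = 5)
  expect_equal(res3$log$rule, "branch_spacing")

  # everything passing is the identity
  clean <- data.frame(axon_id = "a9", below_resolution = FALSE, day = 1)
  res4 <- apply_exclusion_rules(clean)
  expect_equal(nrow(res4$retained), 1L)
  expect_equal(nrow(res4$log), 0L)
})
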