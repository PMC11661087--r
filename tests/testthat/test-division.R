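test_that("region comparison reports means and rank-sum p-values", {
  lab <- data.frame(caliber = c(5, 6, 7, 1, 2, 3),
                    region = rep(c("dividing", "neighbor1"), each = 3))
  res <- region_comparison(lab)
  expect_equal(unname(res$means["dividing"]), 6)
  expect_equal(res$tests$dividing_vs_neighbor1$p_value, 0.1,
               tolerance = 1e-12)
  expect_true("dividing_vs_neighbor2" %in% res$skipped)

  const <- data.frame(caliber = rep(0.3, 12),
                      region = rep(c("dividing", "neighbor1",
                                     "neighbor2"), each = 4))
  resc <- region_comparison(const)
  for (t in resc$tests) expect_equal(t$p_value, 1)
})

test_that("round/flat frames maximize the border-length increase", {
  sel <- select_round_flat_frames(c(10, 10.2, 9.8, 12.5, 12.6))
  expect_equal(sel$round_frame, 3L)
  expect_equal(sel$flat_frame, 4L)

  expect_error(select_round_flat_frames(c(12, 11, 10, 9)), "never")

  tie <- select_round_flat_frames(c(10, 12, 11, 13))
  expect_equal(tie$round_frame, 1L)  # +2 at (1,2) and (3,4): earliest
})

test_that("paired round/flat comparison matches the sign-flip oracle", {
  same <- rep(0.3, 6)
  expect_equal(paired_round_flat_comparison(same, same)$p_value, 1)

  flat <- c(0.25, 0.28, 0.22, 0.30, 0.26, 0.24)
  res <- paired_round_flat_comparison(flat + 0.05, flat)
  expect_equal(res$p_value, 2 / 2^6, tolerance = 1e-12)
  expect_equal(res$mean_round - res$mean_flat, 0.05, tolerance = 1e-12)

  withNA <- c(flat[1:5], NA)
  res2 <- paired_round_flat_comparison(flat + 0.05, withNA)
  expect_equal(res2$n_pairs, 5L)
  expect_equal(res2$n_dropped, 1L)
})

test_that("arc path model evaluates the circular-segment closed form", {
  flat <- arc_path_length(10, 10, 0)
  expect_equal(flat$arc_length, 10)
  expect_equal(flat$path_ratio, 1)

  semi <- arc_path_length(12, 10, 5)
  expect_equal(semi$arc_length, 5 * pi, tolerance = 1e-12)

  g <- arc_path_length(14.15, 10, 2)
  expect_equal((10^2 + 4 * 2^2) / (8 * 2), 7.25)
  expect_equal(g$arc_length, 11.04, tolerance = 0.01)
  expect_equal(g$path_ratio, 0.78, tolerance = 0.005)

  expect_error(arc_path_length(8, 10, 2), "exceed")

  # strictly increasing in h; ratio invariant under uniform rescaling
  hs <- seq(0.1, 6, length.out = 100)
  arcs <- vapply(hs, function(h) arc_path_length(14, 10, h)$arc_length,
                 numeric(1))
  expect_true(all(diff(arcs) > 0))
  for (k in c(0.5, 2, 7)) {
    expect_equal(arc_path_length(14 * k, 10 * k, 2 * k)$path_ratio,
                 arc_path_length(14, 10, 2)$path_ratio, tolerance = 1e-12)
  }
})

test_that("pearling is the lengthwise caliber SD", {
  expect_equal(pearling(rep(0.3, 10)), 0)

  s <- seq(0, 1, length.out = 1001)[-1001]  # whole periods
  a <- 0.08
  sine <- 0.3 + a * sin(2 * pi * 5 * s)
  expect_equal(pearling(sine), a / sqrt(2), tolerance = 0.02)

  pc <- pearling_change(0.3 + 0.1 * sin(2 * pi * 5 * s),
                        0.3 + 0.05 * sin(2 * pi * 5 * s))
  expect_lt(pc$delta, 0)
  expect_equal(pearling_change(rep(0.3, 5), rep(0.3, 5))$delta, 0)
  expect_error(pearling_change(c(0.3, 0.3), rep(0.3, 5)), "at least 3")
})

test_that("scripted division scenes are analyzed end to end", {
  sim <- run_simulate(list(seed = 9,
    scene = list(type = "division", base_radius = 0.12,
                 dividing_factor = 1.5, round_to_flat_drop = 0.1),
    render = list(poisson_noise = FALSE, read_noise_sd = 0)),
    tempfile("div"), name = "d")
  csv <- file.path(dirname(sim$tiff), "m.csv")
  run_measure(sim$tiff, csv)
  res <- run_division(csv, sim$sidecar)
  expect_equal(res$frames$round_frame, 4L)
  expect_equal(res$frames$flat_frame, 5L)
  # dividing-region diameter 1.5x neighbors: mean strictly greatest and
  # recovered within tolerance away from the blended borders
  expect_gt(res$regions$means["dividing"],
            max(res$regions$means[c("neighbor1", "neighbor2")]))
  expect_equal(unname(res$regions$means["neighbor1"]), 0.24,
               tolerance = 0.04)
  # scripted 10% thinning: round mean exceeds flat mean, paired test
  expect_gt(res$paired$mean_round, res$paired$mean_flat)
})

test_that("round/flat selection recovers the scripted transition in a sweep", {
  set.seed(101)
  hits <- 0L
  for (i in 1:20) {
    rf <- sample(2:7, 1)
    n <- rf + 1 + sample(2:4, 1)
    sc <- rounding_scenario(flat_length = runif(1, 10, 16),
                            rounded_extent = runif(1, 6, 9),
                            rounded_height = runif(1, 2, 5),
                            n_frames = n, round_frame = rf,
                            recovery = if (i %% 5 == 0) "tie" else "smooth")
    ser <- make_division_series(sc)
    sel <- select_round_flat_frames(ser$timecourse$border_length)
    if (sel$round_frame == sc$round_frame) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})
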