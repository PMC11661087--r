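#' Basal-cell division scenario
#'
#' An axon runs across a dividing basal epithelial cell and its two
#' non-dividing neighbors. As the cell enters mitosis it pulls its
#' borders inward (planar extent shrinks from the flat length l to c)
#' and rounds upward (height h); after division the daughters flatten
#' and the border-to-border length recovers, with the largest single
#' increase at the scripted round-to-flat transition.
#'
#' @param flat_length flat (interphase) cell length l (um).
#' @param rounded_extent planar border-to-border extent c at maximal
#'   rounding (um); 0 < c <= l.
#' @param rounded_height apical height h of the rounded cell (um, >= 0).
#' @param n_frames number of frames (5-min interval by default).
#' @param round_frame frame index of maximal rounding; the flat frame is
#'   `round_frame + 1`.
#' @param frame_interval minutes between frames.
#' @param base_radius axon radius over the neighbor cells (um).
#' @param dividing_factor radius multiplier over the dividing cell while
#'   round (thicker axon on the rounded cell).
#' @param round_to_flat_drop fractional caliber drop on the dividing
#'   region after flattening (0 = none).
#' @param neighbor_extent length of axon on each neighbor cell (um).
#' @param recovery "smooth" (unique maximal increase) or "tie" (first two
#'   post-round increments equal, exercising the earliest-first rule).
#' @param pearl_amp_round,pearl_amp_flat,pearl_period optional sinusoidal
#'   radius modulation (um) on the dividing span while round/flat;
#'   period in um (ignored when amplitudes are 0).
#' @return object of class `rounding_scenario`.
#' @export
rounding_scenario <- function(flat_length = 12, rounded_extent = 8,
                              rounded_height = 4, n_frames = 10L,
                              round_frame = 4L, frame_interval = 5,
                              base_radius = 0.12, dividing_factor = 1.5,
                              round_to_flat_drop = 0.1,
                              neighbor_extent = 6,
                              recovery = c("smooth", "tie"),
                              pearl_amp_round = 0, pearl_amp_flat = 0,
                              pearl_period = 2) {
  recovery <- match.arg(recovery)
  if (!(rounded_extent > 0 && rounded_extent <= flat_length))
    stop("need 0 < rounded_extent <= flat_length")
  stopifnot(rounded_height >= 0, n_frames >= 2, round_frame >= 1,
            round_frame + 1 <= n_frames, base_radius > 0,
            dividing_factor > 0, round_to_flat_drop >= 0,
            round_to_flat_drop < 1, neighbor_extent > 0)
  if (recovery == "tie" && round_frame + 2 > n_frames)
    stop("tie recovery needs at least two frames after the round frame")
  structure(list(flat_length = flat_length,
                 rounded_extent = rounded_extent,
                 rounded_height = rounded_height,
                 n_frames = as.integer(n_frames),
                 round_frame = as.integer(round_frame),
                 frame_interval = frame_interval,
                 base_radius = base_radius,
                 dividing_factor = dividing_factor,
                 round_to_flat_drop = round_to_flat_drop,
                 neighbor_extent = neighbor_extent,
                 recovery = recovery,
                 pearl_amp_round = pearl_amp_round,
                 pearl_amp_flat = pearl_amp_flat,
                 pearl_period = pearl_period),
            class = "rounding_scenario")
}

# planar border-to-border length schedule across the time lapse
border_length_schedule <- function(sc) {
  l <- sc$flat_length; cc <- sc$rounded_extent
  n <- sc$n_frames; rf <- sc$round_frame
  L <- numeric(n)
  if (rf == 1) L[1] <- cc
  else L[1:rf] <- seq(l, cc, length.out = rf)
  gap <- l - cc
  if (sc$recovery == "smooth") {
    flat_val <- if (rf + 1 == n) l else cc + 0.75 * gap
    L[rf + 1] <- flat_val
    if (rf + 2 <= n)
      L[(rf + 2):n] <- seq(flat_val, l, length.out = n - rf)[-1]
  } else {
    L[rf + 1] <- cc + 0.45 * gap
    L[rf + 2] <- cc + 0.90 * gap
    if (rf + 3 <= n)
      L[(rf + 3):n] <- seq(cc + 0.90 * gap, l, length.out = n - rf - 1)[-1]
  }
  L
}

#' Generate a basal-cell division time lapse
#'
#' Emits per-frame planar border-to-border lengths, true 3D path lengths
#' (straight chord while flat; circular arc of chord c and sagitta h at
#' the round frame), border positions, ground-truth radius profiles and,
#' optionally, rendered frames. The axon is horizontal; the dividing
#' cell sits between two neighbor cells and its borders move
#' symmetrically about the cell center.
#'
#' @param scenario `rounding_scenario`.
#' @param config `scene_config`; its image shape is overridden to fit the
#'   scene when rendering.
#' @param render logical; FALSE skips rendering (ground truth only).
#' @return list with `timecourse` (data.frame: frame, time_min,
#'   border_length, true_path_length, border_left, border_right, phase),
#'   `round_frame`, `flat_frame`, `truths`, `frames`, `scenario`.
#' @export
make_division_series <- function(scenario, config = scene_config(),
                                 render = FALSE) {
  sc <- scenario
  L <- border_length_schedule(sc)
  n <- sc$n_frames
  xc <- sc$neighbor_extent + sc$flat_length / 2
  scene_len <- 2 * sc$neighbor_extent + sc$flat_length
  bl <- xc - L / 2; br <- xc + L / 2
  true_path <- L
  true_path[sc$round_frame] <-
    arc_path_length(sc$flat_length, sc$rounded_extent,
                    sc$rounded_height)$arc_length
  phase <- rep("recovery", n)
  if (sc$round_frame > 1) phase[1:(sc$round_frame - 1)] <- "rounding"
  phase[sc$round_frame] <- "round"
  phase[sc$round_frame + 1] <- "flat"
  tc <- data.frame(frame = seq_len(n),
                   time_min = (seq_len(n) - 1) * sc$frame_interval,
                   border_length = L, true_path_length = true_path,
                   border_left = bl, border_right = br, phase = phase)

  margin <- 1 + 3 * config$psf_fwhm
  truths <- lapply(seq_len(n), function(t) {
    prof <- division_radius_profile(sc, t, scene_len, bl[t], br[t])
    straight_axon_truth(scene_len, profile = prof,
                        origin = c(margin, 0), angle = 0,
                        frame_time = (t - 1) * sc$frame_interval)
  })

  frames <- NULL
  if (render) {
    px <- config$pixel_size
    rmax <- sc$base_radius * max(1, sc$dividing_factor) +
      max(sc$pearl_amp_round, sc$pearl_amp_flat)
    nc_px <- ceiling((scene_len + 2 * margin) / px) + 2L
    nr_px <- ceiling(2 * (margin + rmax + 0.5) / px) + 2L
    cfg <- config
    cfg$image_shape <- c(nr_px, nc_px)
    y0 <- ((nr_px - 1) / 2) * px
    truths <- lapply(truths, function(tr) {
      tr$segments$seg1[, 2] <- tr$segments$seg1[, 2] + y0
      tr
    })
    frames <- with_seed(config$seed, lapply(truths, function(tr)
      render_membrane_frame(tr, cfg, seed = NULL)))
  }
  list(timecourse = tc, round_frame = sc$round_frame,
       flat_frame = sc$round_frame + 1L, truths = truths,
       frames = frames, scenario = sc)
}

# radius profile along the axon at frame t; s measured from the axon's
# left end (which starts at x = margin, i.e. arc s maps to x = margin + s)
division_radius_profile <- function(sc, t, scene_len, bl, br,
                                    step = 0.05) {
  s <- seq(0, scene_len, by = step)
  x <- s  # borders are expressed in arc length from the axon's left end
  r_div <- sc$base_radius * sc$dividing_factor
  if (t > sc$round_frame) r_div <- r_div * (1 - sc$round_to_flat_drop)
  blend <- 0.4
  # smooth indicator of the dividing span [bl, br]
  w <- stats::plogis((x - bl) / (blend / 4)) *
       stats::plogis((br - x) / (blend / 4))
  r <- sc$base_radius + (r_div - sc$base_radius) * w
  amp <- if (t <= sc$round_frame) sc$pearl_amp_round else sc$pearl_amp_flat
  if (amp > 0)
    r <- r + amp * w * sin(2 * pi * x / sc$pearl_period)
  structure(data.frame(s = s, r = r),
            class = c("radius_profile", "data.frame"))
}

#' Region label for positions along the division-scene axon
#'
#' @param x scene x coordinate(s) (um) of measurement locations.
#' @param border_left,border_right border positions at the relevant frame.
#' @return factor with levels dividing, neighbor1, neighbor2.
#' @export
division_region <- function(x, border_left, border_right) {
  lab <- ifelse(x < border_left, "neighbor1",
         ifelse(x > border_right, "neighbor2", "dividing"))
  factor(lab, levels = c("dividing", "neighbor1", "neighbor2"))
}
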