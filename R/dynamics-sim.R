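#' Script for a scripted caliber-dynamics behavior
#'
#' The four behaviors observed in time-lapse imaging of axon caliber:
#' a pearl traveling along the axon, a focal inflation that later
#' deflates, a whole-segment widening and narrowing, and a transient
#' constriction point. Given a seed the script fully determines r(s, t).
#'
#' @param behavior one of "traveling_pearl", "focal_inflation_deflation",
#'   "segment_widening_narrowing", "constriction_point".
#' @param base_radius baseline radius (um).
#' @param amplitude radius deviation (um); positive. For
#'   "constriction_point" it is applied as a negative bump.
#' @param width Gaussian sd of the pearl/constriction (um).
#' @param speed pearl travel speed (um per frame; traveling_pearl only).
#' @param onset,offset first and last active frame (1-based).
#' @param n_frames number of frames.
#' @param frame_interval minutes between frames (default 5).
#' @param start_center initial lengthwise position of the feature (um).
#' @param span for segment widening: c(s0, s1) range modulated uniformly;
#'   NULL = whole segment.
#' @return object of class `dynamics_script`.
#' @export
dynamics_script <- function(behavior = c("traveling_pearl",
                                         "focal_inflation_deflation",
                                         "segment_widening_narrowing",
                                         "constriction_point"),
                            base_radius = 0.2, amplitude = 0.08,
                            width = 1, speed = 0.4,
                            onset = 1L, offset = NULL, n_frames = 12L,
                            frame_interval = 5, start_center = 3,
                            span = NULL) {
  behavior <- match.arg(behavior)
  if (is.null(offset)) offset <- n_frames
  stopifnot(base_radius > 0, amplitude >= 0, width > 0, n_frames >= 1,
            onset >= 1, offset <= n_frames, onset <= offset,
            frame_interval > 0)
  if (behavior == "constriction_point" && amplitude >= base_radius)
    stop("constriction amplitude must be smaller than the base radius")
  structure(list(behavior = behavior, base_radius = base_radius,
                 amplitude = amplitude, width = width, speed = speed,
                 onset = as.integer(onset), offset = as.integer(offset),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 start_center = start_center, span = span),
            class = "dynamics_script")
}

# triangular ramp: 0 at onset and offset, 1 at their midpoint
ramp01 <- function(t, onset, offset) {
  if (t < onset || t > offset) return(0)
  if (offset == onset) return(1)
  mid <- (onset + offset) / 2
  if (t <= mid) (t - onset) / (mid - onset) else (offset - t) / (offset - mid)
}

#' Scripted radius profile at one frame
#'
#' @param script `dynamics_script`.
#' @param t frame index (1-based).
#' @param length_um segment length (um).
#' @param step sampling step (um).
#' @return `radius_profile` for frame `t`.
#' @export
scripted_radius_profile <- function(script, t, length_um, step = 0.05) {
  stopifnot(t >= 1, t <= script$n_frames)
  base <- script$base_radius
  switch(script$behavior,
    traveling_pearl = {
      ctr <- script$start_center + script$speed * (t - 1)
      pearled_radius_profile(base,
        data.frame(center = ctr, amplitude = script$amplitude,
                   width = script$width), length_um, step)
    },
    focal_inflation_deflation = {
      a <- script$amplitude * ramp01(t, script$onset, script$offset)
      if (a == 0) uniform_radius_profile(base, length_um, step)
      else pearled_radius_profile(base,
        data.frame(center = script$start_center, amplitude = a,
                   width = script$width), length_um, step)
    },
    segment_widening_narrowing = {
      a <- script$amplitude * ramp01(t, script$onset, script$offset)
      prof <- uniform_radius_profile(base, length_um, step)
      span <- if (is.null(script$span)) c(0, length_um) else script$span
      sel <- prof$s >= span[1] & prof$s <= span[2]
      prof$r[sel] <- prof$r[sel] + a
      prof
    },
    constriction_point = {
      active <- t >= script$onset && t <= script$offset
      if (!active) uniform_radius_profile(base, length_um, step)
      else pearled_radius_profile(base,
        data.frame(center = script$start_center,
                   amplitude = -script$amplitude,
                   width = script$width), length_um, step)
    })
}

#' Generate a scripted caliber-dynamics time series
#'
#' Builds per-frame ground truth from the script and renders each frame.
#' Frames share one RNG scope seeded from `config$seed`, so the whole
#' series is reproducible while frames get independent noise.
#'
#' @param script `dynamics_script`.
#' @param config `scene_config`.
#' @param axon_length segment length (um).
#' @param origin,angle placement of the straight test segment.
#' @param render logical; FALSE returns ground truth only.
#' @return list with `frames` (list of `image_frame` or NULL), `truths`
#'   (list of per-frame `axon_truth`), `script`, `config`.
#' @export
make_dynamics_series <- function(script, config, axon_length = 10,
                                 origin = c(1, 2), angle = 0,
                                 render = TRUE) {
  truths <- lapply(seq_len(script$n_frames), function(t) {
    prof <- scripted_radius_profile(script, t, axon_length)
    straight_axon_truth(axon_length, profile = prof, origin = origin,
                        angle = angle,
                        frame_time = (t - 1) * script$frame_interval)
  })
  frames <- NULL
  if (render) {
    frames <- with_seed(config$seed, lapply(truths, function(tr)
      render_membrane_frame(tr, config, seed = NULL)))
  }
  list(frames = frames, truths = truths, script = script, config = config)
}
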