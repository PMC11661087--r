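#' Measurement configuration for line-scan caliber scoring
#'
#' @param scan_half_length half-length of the perpendicular scan (um).
#' @param scan_step sampling step along the scan (um); default half a
#'   pixel, set at measurement time when NULL.
#' @param smoothing_sd Gaussian pre-smoothing sd (um); default one pixel
#'   (set at measurement time when NULL); use 0 to disable.
#' @param peak_prominence_fraction minimum peak prominence as a fraction
#'   of the profile's intensity range.
#' @param resolution_limit calibers below this (um) are flagged
#'   `below_resolution`; they are excluded from means downstream but still
#'   counted for the below-resolution-fraction exclusion rule.
#' @param subpixel logical; refine each peak with a 3-point parabola.
#' @param min_branch_distance positions closer than this (um) to a branch
#'   point are dropped before measuring.
#' @return object of class `measurement_config`.
#' @export
measurement_config <- function(scan_half_length = 1.5, scan_step = NULL,
                               smoothing_sd = NULL,
                               peak_prominence_fraction = 0.1,
                               resolution_limit = 0.14, subpixel = TRUE,
                               min_branch_distance = 3) {
  stopifnot(scan_half_length > 0, peak_prominence_fraction > 0,
            resolution_limit > 0, min_branch_distance >= 0)
  structure(list(scan_half_length = scan_half_length,
                 scan_step = scan_step, smoothing_sd = smoothing_sd,
                 peak_prominence_fraction = peak_prominence_fraction,
                 resolution_limit = resolution_limit,
                 subpixel = isTRUE(subpixel),
                 min_branch_distance = min_branch_distance),
            class = "measurement_config")
}

#' Bilinear interpolation of an image at continuous um coordinates
#'
#' Pixel centers sit at integer multiples of `pixel_size`, origin at the
#' center of pixel (1,1); this makes sampling at pixel centers exact.
#' @keywords internal
bilinear_sample <- function(pixels, pixel_size, x, y) {
  cx <- x / pixel_size; cy <- y / pixel_size
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (any(cx < 0 | cx > nc - 1 | cy < 0 | cy > nr - 1))
    stop("sample point outside the image")
  c0 <- pmin(floor(cx), nc - 2); r0 <- pmin(floor(cy), nr - 2)
  fx <- cx - c0; fy <- cy - r0
  i00 <- pixels[cbind(r0 + 1, c0 + 1)]
  i01 <- pixels[cbind(r0 + 1, c0 + 2)]
  i10 <- pixels[cbind(r0 + 2, c0 + 1)]
  i11 <- pixels[cbind(r0 + 2, c0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Extract a perpendicular intensity profile
#'
#' Samples the image by bilinear interpolation at `center + offset *
#' normal` for symmetric offsets, optionally Gaussian-smoothing the
#' resulting 1D profile.
#'
#' @param frame `image_frame`.
#' @param center c(x, y) in um on the centerline.
#' @param normal unit normal direction.
#' @param config `measurement_config`.
#' @return object of class `linescan_profile`: list with `offsets` (um),
#'   `intensities`, `center`, `direction`.
#' @export
extract_profile <- function(frame, center, normal, config =
                              measurement_config()) {
  px <- frame$pixel_size
  step <- if (is.null(config$scan_step)) px / 2 else config$scan_step
  nv <- sqrt(sum(normal^2))
  if (abs(nv - 1) > 1e-8) normal <- normal / nv
  half <- config$scan_half_length
  offsets <- seq(-half, half, by = step)
  if (offsets[length(offsets)] < half) offsets <- c(offsets, half)
  xs <- center[1] + offsets * normal[1]
  ys <- center[2] + offsets * normal[2]
  xmax <- (ncol(frame$pixels) - 1) * px
  ymax <- (nrow(frame$pixels) - 1) * px
  out <- xs < 0 | xs > xmax | ys < 0 | ys > ymax
  if (any(out))
    stop("scan exits the image at offsets ",
         paste(format(offsets[out], digits = 3), collapse = ", "), " um")
  intens <- bilinear_sample(frame$pixels, px, xs, ys)
  sm <- if (is.null(config$smoothing_sd)) px else config$smoothing_sd
  if (sm > 0) intens <- gaussian_smooth_1d(intens, sm / step)
  structure(list(offsets = offsets, intensities = intens,
                 center = center, direction = normal),
            class = "linescan_profile")
}

# reflect-padded Gaussian smoothing; sd in samples
gaussian_smooth_1d <- function(v, sd_samples) {
  if (sd_samples <= 0) return(v)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- exp(-((-half):half)^2 / (2 * sd_samples^2))
  k <- k / sum(k)
  n <- length(v)
  idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))
  padded <- v[pmin(pmax(idx, 1L), n)]
  as.numeric(stats::filter(padded, k, sides = 2))[half + seq_len(n)]
}

# local maxima indices; plateaus (runs of equal values higher than both
# neighbouring runs) collapse to their central index. Runs touching the
# scan ends are not peaks.
local_peaks <- function(v) {
  if (length(v) < 3L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  j <- which(seq_len(k) > 1L & seq_len(k) < k)
  j <- j[r$values[j - 1L] < r$values[j] & r$values[j + 1L] < r$values[j]]
  as.integer(floor((starts[j] + ends[j]) / 2))
}

peak_prominence <- function(v, i) {
  n <- length(v)
  left_min <- v[i]; j <- i
  while (j > 1L) { j <- j - 1L
    if (v[j] > v[i]) break
    left_min <- min(left_min, v[j]) }
  right_min <- v[i]; j <- i
  while (j < n) { j <- j + 1L
    if (v[j] > v[i]) break
    right_min <- min(right_min, v[j]) }
  v[i] - max(left_min, right_min)
}

# 3-point parabolic sub-sample refinement around index i; returns offset
# in samples within (-0.5, 0.5)
parabolic_refine <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(0)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom >= 0) return(0)
  delta <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  max(-0.5, min(0.5, delta))
}

#' Score caliber from a line-scan profile
#'
#' Caliber is the distance between the two plasma-membrane intensity
#' peaks: the nearest sufficiently prominent local maximum on each side
#' of the centerline crossing (offset 0), optionally refined to
#' sub-sample precision with a 3-point parabola. Measurements below the
#' configured resolution limit are flagged, and profiles whose membrane
#' peaks have merged into one report `single_peak` with no caliber.
#'
#' @param profile `linescan_profile`.
#' @param config `measurement_config`.
#' @return object of class `caliber_measurement`: list with `caliber`
#'   (um, NA when invalid), `peak_positions` (um pair), and logical flags
#'   `below_resolution`, `single_peak`, `ambiguous_peaks`.
#' @export
measure_caliber <- function(profile, config = measurement_config()) {
  v <- profile$intensities
  off <- profile$offsets
  rng <- diff(range(v))
  if (rng <= 0) stop("flat profile: no membrane signal in scan")
  peaks <- local_peaks(v)
  prom <- vapply(peaks, function(i) peak_prominence(v, i), numeric(1))
  peaks <- peaks[prom >= config$peak_prominence_fraction * rng]
  res <- list(caliber = NA_real_, peak_positions = c(NA_real_, NA_real_),
              below_resolution = FALSE, single_peak = FALSE,
              ambiguous_peaks = FALSE)
  class(res) <- "caliber_measurement"
  left <- peaks[off[peaks] < 0]
  right <- peaks[off[peaks] > 0]
  if (length(left) == 0L || length(right) == 0L) {
    res$single_peak <- TRUE
    return(res)
  }
  iL <- left[which.max(off[left])]    # nearest below 0
  iR <- right[which.min(off[right])]  # nearest above 0
  near10 <- function(cand, chosen)
    any(cand != chosen & abs(v[cand] - v[chosen]) < 0.10 * v[chosen])
  res$ambiguous_peaks <- near10(left, iL) || near10(right, iR)
  step_mean <- mean(diff(off))
  refine <- function(i) {
    d <- if (config$subpixel) parabolic_refine(v, i) else 0
    off[i] + d * step_mean
  }
  p <- c(refine(iL), refine(iR))
  res$peak_positions <- p
  res$caliber <- abs(p[2] - p[1])
  if (res$caliber < config$resolution_limit) res$below_resolution <- TRUE
  res
}

#' Measure caliber at arc positions along a segment
#'
#' Performs a perpendicular line scan at each requested arc position
#' (dropping positions within the branch-point exclusion distance) and
#' scores each profile. Arc positions are measured from the segment's
#' first point.
#'
#' @param frame `image_frame`.
#' @param segment two-column matrix of centerline points (um), e.g. from
#'   an `axon_truth` or a centerline annotation.
#' @param positions arc positions (um) to measure at.
#' @param config `measurement_config`.
#' @param branch_arc_positions arc positions (um) of branch points on
#'   this segment; positions closer than `config$min_branch_distance` to
#'   any of them are dropped, not errored.
#' @param segment_id id recorded in the output.
#' @return data.frame with columns segment_id, arc_pos, caliber,
#'   peak_lo, peak_hi, below_resolution, single_peak, ambiguous_peaks.
#' @export
measure_along_segment <- function(frame, segment, positions,
                                  config = measurement_config(),
                                  branch_arc_positions = numeric(0),
                                  segment_id = "seg1") {
  segment <- as.matrix(segment)
  total <- polyline_arclength(segment)
  total <- total[length(total)]
  keep <- positions >= 0 & positions <= total
  positions <- positions[keep]
  if (length(branch_arc_positions) > 0 && config$min_branch_distance > 0) {
    ok <- vapply(positions, function(p)
      all(abs(p - branch_arc_positions) >= config$min_branch_distance),
      logical(1))
    positions <- positions[ok]
  }
  rows <- lapply(positions, function(s) {
    tn <- tangent_and_normal(segment, s)
    ctr <- point_at_arclength(segment, s)[1, ]
    prof <- extract_profile(frame, ctr, tn$normal, config)
    m <- measure_caliber(prof, config)
    data.frame(segment_id = segment_id, arc_pos = s,
               caliber = m$caliber,
               peak_lo = m$peak_positions[1], peak_hi = m$peak_positions[2],
               below_resolution = m$below_resolution,
               single_peak = m$single_peak,
               ambiguous_peaks = m$ambiguous_peaks)
  })
  if (length(rows) == 0L)
    return(data.frame(segment_id = character(0), arc_pos = numeric(0),
                      caliber = numeric(0), peak_lo = numeric(0),
                      peak_hi = numeric(0), below_resolution = logical(0),
                      single_peak = logical(0),
                      ambiguous_peaks = logical(0)))
  do.call(rbind, rows)
}
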