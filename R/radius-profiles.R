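#' Pearled radius profile
#'
#' Builds a lengthwise radius profile r(s) as a constant base radius plus
#' Gaussian "pearls": r(s) = base + sum_k a_k * exp(-(s - s_k)^2 / (2 w_k^2)).
#' Negative amplitudes model constrictions. Pearled (varicose) morphology —
#' alternating thick and thin stretches — is the lengthwise structure this
#' emulates.
#'
#' @param base_radius base radius in um (> 0).
#' @param pearls data.frame with columns `center` (um), `amplitude` (um,
#'   may be negative), `width` (Gaussian sd, um); or NULL for a uniform tube.
#' @param length_um profile extent in um.
#' @param step sampling step in um (default 0.05).
#' @return data.frame with columns `s` (um) and `r` (um), class
#'   `radius_profile`.
#' @export
#' @examples
#' p <- pearled_radius_profile(0.15, data.frame(center = 5, amplitude = 0.1,
#'                                              width = 1), length_um = 10)
#' radius_at(p, 5)  # 0.25
pearled_radius_profile <- function(base_radius, pearls = NULL, length_um,
                                   step = 0.05) {
  stopifnot(is.numeric(base_radius), length(base_radius) == 1L,
            base_radius > 0, length_um > 0, step > 0)
  s <- seq(0, length_um, by = step)
  r <- rep(base_radius, length(s))
  if (!is.null(pearls) && nrow(pearls) > 0) {
    for (k in seq_len(nrow(pearls))) {
      if (pearls$width[k] <= 0) stop("pearl width must be positive")
      r <- r + pearls$amplitude[k] *
        exp(-(s - pearls$center[k])^2 / (2 * pearls$width[k]^2))
    }
  }
  if (any(r <= 0)) {
    bad <- s[which.min(r)]
    stop(sprintf(
      "radius profile is non-positive (min %.4f um at s = %.2f um); %s",
      min(r), bad, "reduce constriction amplitudes"))
  }
  structure(data.frame(s = s, r = r), class = c("radius_profile",
                                                "data.frame"))
}

#' Sinusoidal radius profile
#'
#' Alternative preset for subtle thick/thin stretches without distinct
#' inflection points: r(s) = base + amplitude * sin(2*pi*s/period + phase).
#'
#' @inheritParams pearled_radius_profile
#' @param amplitude peak radius deviation (um); must be < base_radius.
#' @param period lengthwise period (um).
#' @param phase phase offset (radians).
#' @return `radius_profile` data.frame.
#' @export
sinusoidal_radius_profile <- function(base_radius, amplitude, period,
                                      length_um, step = 0.05, phase = 0) {
  stopifnot(base_radius > 0, period > 0, length_um > 0, step > 0)
  if (abs(amplitude) >= base_radius)
    stop("sinusoid amplitude must be smaller than the base radius")
  s <- seq(0, length_um, by = step)
  r <- base_radius + amplitude * sin(2 * pi * s / period + phase)
  structure(data.frame(s = s, r = r), class = c("radius_profile",
                                                "data.frame"))
}

#' Uniform radius profile
#' @inheritParams pearled_radius_profile
#' @return `radius_profile` data.frame.
#' @export
uniform_radius_profile <- function(base_radius, length_um, step = 0.05) {
  pearled_radius_profile(base_radius, NULL, length_um, step)
}

#' Evaluate a radius profile at arbitrary arc lengths
#'
#' Linear interpolation between table samples; constant extrapolation at
#' the ends.
#'
#' @param profile a `radius_profile` (data.frame with `s`, `r`).
#' @param s arc length(s) in um.
#' @return radius value(s) in um.
#' @export
radius_at <- function(profile, s) {
  stats::approx(profile$s, profile$r, xout = s, rule = 2,
                ties = "ordered")$y
}
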