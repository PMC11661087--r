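#' Scene configuration for the synthetic renderer
#'
#' Defaults emulate an Airyscan-class acquisition: 0.04 um pixels and a
#' 0.14 um lateral PSF FWHM, with photon (Poisson) noise plus Gaussian
#' read noise. Intensities are in photons.
#'
#' @param pixel_size um per pixel (> 0).
#' @param image_shape c(rows, cols) in pixels.
#' @param psf_fwhm lateral PSF full width at half maximum (um, > 0).
#' @param membrane_amplitude peak photon count of an isolated membrane
#'   boundary above background.
#' @param background background photon level.
#' @param read_noise_sd Gaussian read noise sd (photons).
#' @param poisson_noise logical; apply shot noise.
#' @param seed integer RNG seed; a fixed seed gives bit-identical frames.
#' @return object of class `scene_config` (a validated list).
#' @export
scene_config <- function(pixel_size = 0.04, image_shape = c(160L, 240L),
                         psf_fwhm = 0.14, membrane_amplitude = 100,
                         background = 10, read_noise_sd = 2,
                         poisson_noise = TRUE, seed = 1L) {
  stopifnot(pixel_size > 0, length(image_shape) == 2L,
            all(image_shape >= 8), psf_fwhm > 0,
            membrane_amplitude > 0, background >= 0, read_noise_sd >= 0)
  structure(list(pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 psf_fwhm = psf_fwhm,
                 membrane_amplitude = membrane_amplitude,
                 background = background,
                 read_noise_sd = read_noise_sd,
                 poisson_noise = isTRUE(poisson_noise),
                 seed = as.integer(seed)),
            class = "scene_config")
}

psf_sigma <- function(config) config$psf_fwhm / (2 * sqrt(2 * log(2)))

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so the generator never
#' perturbs user-level randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
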