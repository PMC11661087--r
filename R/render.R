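#' Image frame container
#'
#' @param pixels numeric matrix (rows = y, cols = x), photons.
#' @param pixel_size um per pixel.
#' @param frame_time minutes.
#' @return object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_size, frame_time = 0) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 frame_time = frame_time), class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("image_frame: %d x %d px, %.3f um/px, t = %g min\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$frame_time))
  invisible(x)
}

#' Render a membrane-labeled axon frame
#'
#' The membrane label (e.g. a prenylated GFP) sits only on the plasma
#' membrane, so a tube seen in a single optical plane shows two bright
#' boundary lines offset +/- r(s) along the centerline normal with a dark
#' lumen. Each boundary curve is rendered as a line source convolved with
#' an isotropic Gaussian PSF: the line integral is discretized at a step
#' of sigma/3 and each sample deposits an analytic Gaussian spot, so the
#' rendered perpendicular profile equals the closed-form two-Gaussian
#' profile up to quadrature error. Background is added, then optional
#' Poisson shot noise and Gaussian read noise.
#'
#' Coordinates are continuous um with the origin at the center of pixel
#' (1,1); pixel centers lie at integer multiples of `pixel_size`.
#'
#' @param truth `axon_truth` geometry; must fit in bounds with a margin of
#'   at least 3 PSF FWHM.
#' @param config `scene_config`.
#' @param seed RNG seed for the noise draw; defaults to `config$seed`.
#'   Use NULL to draw from the current RNG state (for multi-frame series
#'   wrapped in a single seed scope).
#' @return `image_frame`, with the `truth` and `config` attached as
#'   attributes.
#' @export
render_membrane_frame <- function(truth, config, seed = config$seed) {
  sigma <- psf_sigma(config)
  px <- config$pixel_size
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  xmax <- (nc - 1) * px; ymax <- (nr - 1) * px
  margin <- 3 * config$psf_fwhm
  img <- matrix(0, nr, nc)
  xc <- (seq_len(nc) - 1) * px
  yc <- (seq_len(nr) - 1) * px
  win <- max(4 * sigma, 2 * px)

  for (id in names(truth$segments)) {
    seg <- truth$segments[[id]]
    total <- polyline_arclength(seg)
    total <- total[length(total)]
    ds <- min(sigma / 3, px / 2)
    s <- seq(0, total, by = ds)
    ctr <- point_at_arclength(seg, s)
    # tangents from neighbouring fine samples, one-sided at ends
    i0 <- pmax(seq_along(s) - 1L, 1L)
    i1 <- pmin(seq_along(s) + 1L, length(s))
    tx <- ctr[i1, 1] - ctr[i0, 1]; ty <- ctr[i1, 2] - ctr[i0, 2]
    tl <- sqrt(tx^2 + ty^2)
    nxv <- -ty / tl; nyv <- tx / tl
    r <- radius_at(truth$radius_profiles[[id]], s)
    bx <- c(ctr[, 1] + r * nxv, ctr[, 1] - r * nxv)
    by <- c(ctr[, 2] + r * nyv, ctr[, 2] - r * nyv)
    if (any(bx < margin | bx > xmax - margin |
            by < margin | by > ymax - margin))
      stop("segment '", id, "' leaves the image bounds ",
           "(need a margin of 3 PSF FWHM = ", format(margin), " um)")
    w <- config$membrane_amplitude * ds / (sqrt(2 * pi) * sigma)
    for (k in seq_along(bx)) {
      cl <- max(1L, ceiling((bx[k] - win) / px) + 1L)
      cu <- min(nc, floor((bx[k] + win) / px) + 1L)
      rl <- max(1L, ceiling((by[k] - win) / px) + 1L)
      ru <- min(nr, floor((by[k] + win) / px) + 1L)
      gx <- exp(-(xc[cl:cu] - bx[k])^2 / (2 * sigma^2))
      gy <- exp(-(yc[rl:ru] - by[k])^2 / (2 * sigma^2))
      img[rl:ru, cl:cu] <- img[rl:ru, cl:cu] + w * (gy %o% gx)
    }
  }

  img <- img + config$background
  noisy <- config$poisson_noise || config$read_noise_sd > 0
  if (noisy) {
    draw <- function() {
      if (config$poisson_noise)
        img <- matrix(stats::rpois(length(img), lambda = img), nrow(img))
      if (config$read_noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img),
                                         sd = config$read_noise_sd),
                            nrow(img))
      img
    }
    img <- if (is.null(seed)) draw() else with_seed(seed, draw())
  }
  frame <- image_frame(img, px, truth$frame_time)
  attr(frame, "truth") <- truth
  attr(frame, "config") <- config
  frame
}

#' Closed-form line-scan profile of a membrane tube
#'
#' Independent oracle for the measurement module: a tube of diameter d
#' imaged with an isotropic Gaussian PSF of sd `psf_sigma` yields, along a
#' perpendicular scan, I(x) = exp(-(x - d/2)^2 / (2 s^2)) +
#' exp(-(x + d/2)^2 / (2 s^2)), here peak-normalized. When d < 2 s the two
#' Gaussians merge into a single central peak (the resolution limit).
#'
#' @param diameter tube diameter d (um, >= 0).
#' @param psf_sigma PSF sd (um, > 0).
#' @param positions scan offsets x (um).
#' @return numeric intensities, peak-normalized to max 1.
#' @export
analytic_linescan_profile <- function(diameter, psf_sigma, positions) {
  stopifnot(diameter >= 0, psf_sigma > 0)
  f <- function(x) exp(-(x - diameter / 2)^2 / (2 * psf_sigma^2)) +
                   exp(-(x + diameter / 2)^2 / (2 * psf_sigma^2))
  grid <- seq(-diameter / 2 - 5 * psf_sigma, diameter / 2 + 5 * psf_sigma,
              length.out = 4001)
  f(positions) / max(f(grid))
}
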