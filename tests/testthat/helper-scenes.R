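# shared fixture builders -- everything is generated in code

noiseless_config <- function(...) {
  scene_config(poisson_noise = FALSE, read_noise_sd = 0, ...)
}

# straight tube of diameter d rendered noiselessly; returns frame + truth
render_tube <- function(d, length_um = 8, config = noiseless_config(),
                        angle = 0, origin = c(1, 3)) {
  tr <- straight_axon_truth(length_um, radius = d / 2, origin = origin,
                            angle = angle)
  list(frame = render_membrane_frame(tr, config), truth = tr)
}

# wrap an offsets/intensities pair as a linescan_profile
as_profile <- function(offsets, intensities) {
  structure(list(offsets = offsets, intensities = intensities,
                 center = c(0, 0), direction = c(0, 1)),
            class = "linescan_profile")
}

# brute-force sign-flip oracle for the paired permutation test
exhaustive_signflip_p <- function(d) {
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(d))))
  stats <- abs(signs %*% d)
  mean(stats >= abs(sum(d)) - 1e-12)
}

no_smooth <- function(...) measurement_config(smoothing_sd = 0, ...)

local_peaks_for_test <- axoncaliber:::local_peaks
polyline_arclength_for_test <- axoncaliber:::polyline_arclength

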