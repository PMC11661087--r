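#' Caliber time series at a fixed location
#'
#' By convention locations sit 3 um from a branch point and are measured
#' at every frame of a time lapse (5-minute spacing). Flagged frames are
#' recorded as NA and excluded from all summary statistics.
#'
#' @param calibers numeric calibers (um), NA where flagged/missing.
#' @param frame_times minutes, strictly increasing; default 5-min grid.
#' @param location_id,segment_id identifiers.
#' @param arc_pos arc position of the location (um).
#' @return object of class `location_series`.
#' @export
location_series <- function(calibers, frame_times = NULL,
                            location_id = "loc1", segment_id = "seg1",
                            arc_pos = 3) {
  if (is.null(frame_times)) frame_times <- (seq_along(calibers) - 1) * 5
  stopifnot(length(frame_times) == length(calibers),
            all(diff(frame_times) > 0))
  structure(list(location_id = location_id, segment_id = segment_id,
                 arc_pos = arc_pos, frame_times = frame_times,
                 calibers = calibers), class = "location_series")
}

#' Summarize caliber dynamicity at one location
#'
#' Absolute dynamicity is the sample (n-1) standard deviation of the
#' calibers across the movie; relative dynamicity is the percent
#' relative standard deviation, %RSD = (SD / mean caliber) * 100. The
#' fold range max/min captures how much a location varies overall.
#'
#' @param series `location_series`, or a bare numeric vector of calibers.
#' @return object of class `dynamics_summary`: list with `mean_caliber`
#'   (um), `sd` (um), `pct_rsd`, `n_valid`, `fold_range`.
#' @export
summarize_dynamics <- function(series) {
  cal <- if (inherits(series, "location_series")) series$calibers
         else series
  cal <- cal[is.finite(cal)]
  if (length(cal) < 2L)
    stop("need at least 2 valid calibers to summarize dynamicity")
  m <- mean(cal); s <- stats::sd(cal)
  structure(list(mean_caliber = m, sd = s, pct_rsd = 100 * s / m,
                 n_valid = length(cal), fold_range = max(cal) / min(cal)),
            class = "dynamics_summary")
}

#' Dynamicity-versus-caliber regressions across locations
#'
#' Fits absolute dynamicity (SD) and relative dynamicity (%RSD) against
#' mean caliber across a cohort of location summaries.
#'
#' @param summaries list of `dynamics_summary` (>= 3).
#' @return list with `sd_fit` and `rsd_fit`, each a `regression_result`.
#' @export
dynamicity_regressions <- function(summaries) {
  if (length(summaries) < 3L) stop("need at least 3 location summaries")
  m <- vapply(summaries, `[[`, numeric(1), "mean_caliber")
  s <- vapply(summaries, `[[`, numeric(1), "sd")
  r <- vapply(summaries, `[[`, numeric(1), "pct_rsd")
  list(sd_fit = linear_fit(m, s), rsd_fit = linear_fit(m, r))
}

#' Paired comparison of relative dynamicity across development
#'
#' Pairs %RSD values for the same location measured on two days and
#' tests the change with a two-sided paired permutation test. Locations
#' missing either day are dropped with a warning count.
#'
#' @param paired data.frame with columns `location_id`, `pct_rsd_day1`,
#'   `pct_rsd_day2`.
#' @param n_perm Monte Carlo permutations when n exceeds the exhaustive
#'   threshold.
#' @param seed RNG seed for the Monte Carlo path.
#' @return list with `mean_day1`, `mean_day2`, `p_value`, `n_pairs`,
#'   `n_dropped`, `test` (the full `test_result`).
#' @export
compare_days <- function(paired, n_perm = 10000, seed = 1L) {
  stopifnot(all(c("pct_rsd_day1", "pct_rsd_day2") %in% names(paired)))
  ok <- is.finite(paired$pct_rsd_day1) & is.finite(paired$pct_rsd_day2)
  n_drop <- sum(!ok)
  if (n_drop > 0)
    warning(n_drop, " unpaired location(s) dropped")
  paired <- paired[ok, , drop = FALSE]
  if (nrow(paired) < 2L) stop("need at least 2 complete pairs")
  tt <- paired_permutation_test(paired$pct_rsd_day1, paired$pct_rsd_day2,
                                n_perm = n_perm, seed = seed)
  list(mean_day1 = mean(paired$pct_rsd_day1),
       mean_day2 = mean(paired$pct_rsd_day2),
       p_value = tt$p_value, n_pairs = nrow(paired),
       n_dropped = n_drop, test = tt)
}
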