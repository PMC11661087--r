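#' Compare caliber between the dividing cell and its neighbors
#'
#' Means per region (dividing, neighbor1, neighbor2) plus the three
#' pairwise two-sided rank-sum tests, treating measurements as
#' populations. Comparisons involving a region with fewer than two
#' measurements are skipped with a note.
#'
#' @param labeled data.frame with columns `caliber` (um) and `region`
#'   (factor or character: dividing / neighbor1 / neighbor2).
#' @return list with `means` (named numeric), `tests` (named list of
#'   `test_result`), `skipped` (character).
#' @export
region_comparison <- function(labeled) {
  stopifnot(all(c("caliber", "region") %in% names(labeled)))
  labeled <- labeled[is.finite(labeled$caliber), , drop = FALSE]
  regions <- c("dividing", "neighbor1", "neighbor2")
  vals <- lapply(regions, function(r)
    labeled$caliber[labeled$region == r])
  names(vals) <- regions
  means <- vapply(vals, function(v)
    if (length(v)) mean(v) else NA_real_, numeric(1))
  pairs <- utils::combn(regions, 2, simplify = FALSE)
  tests <- list(); skipped <- character(0)
  for (pr in pairs) {
    key <- paste(pr, collapse = "_vs_")
    if (length(vals[[pr[1]]]) < 2L || length(vals[[pr[2]]]) < 2L) {
      skipped <- c(skipped, key)
    } else {
      tests[[key]] <- rank_sum_test(vals[[pr[1]]], vals[[pr[2]]])
    }
  }
  list(means = means, tests = tests, skipped = skipped)
}

#' Select the round and flat frames from border-to-border lengths
#'
#' The round/flat pair is the consecutive pair of frames between which
#' the border-to-border length increases the most (the daughters'
#' flattening). Ties resolve to the earliest pair. A sequence with no
#' increase captured is an error.
#'
#' @param border_lengths per-frame planar border-to-border lengths (um).
#' @return list with `round_frame` and `flat_frame` (= round + 1),
#'   1-based indices.
#' @export
select_round_flat_frames <- function(border_lengths) {
  if (length(border_lengths) < 2L) stop("need at least 2 frames")
  inc <- diff(border_lengths)
  if (all(inc <= 0))
    stop("border-to-border length never increases; no flattening captured")
  # earliest of all increments within numerical tolerance of the maximum
  i <- which(inc >= max(inc) - 1e-9 * max(abs(border_lengths)))[1]
  list(round_frame = i, flat_frame = i + 1L)
}

#' Paired round-versus-flat caliber comparison
#'
#' Calibers measured at 1-um increments are paired by location between
#' the round and flat frames; the drop is tested with a two-sided paired
#' permutation test. Unmatched locations are dropped with a count.
#'
#' @param round_calibers,flat_calibers numeric vectors matched by
#'   location (same order), NA where missing.
#' @param n_perm,seed passed to [paired_permutation_test()].
#' @return list with `mean_round`, `mean_flat`, `p_value`, `n_pairs`,
#'   `n_dropped`, `test`.
#' @export
paired_round_flat_comparison <- function(round_calibers, flat_calibers,
                                         n_perm = 10000, seed = 1L) {
  stopifnot(length(round_calibers) == length(flat_calibers))
  ok <- is.finite(round_calibers) & is.finite(flat_calibers)
  n_drop <- sum(!ok)
  r <- round_calibers[ok]; f <- flat_calibers[ok]
  if (length(r) < 2L) stop("need at least 2 matched locations")
  tt <- paired_permutation_test(r, f, n_perm = n_perm, seed = seed)
  list(mean_round = mean(r), mean_flat = mean(f), p_value = tt$p_value,
       n_pairs = length(r), n_dropped = n_drop, test = tt)
}

#' Circular-arc path-length model for a rounding basal cell
#'
#' While the cell is flat the axon crosses it as a straight chord of
#' length l. When the cell rounds up, the planar extent contracts to c
#' and the axon's path over the apical surface is modeled as the
#' circular arc with chord c and sagitta h: R = (c^2 + 4 h^2) / (8 h),
#' arc = 2 R asin(c / (2R)) for h <= c/2 (major arc for h > c/2); h = 0
#' degenerates to the chord. path_ratio = arc / l compares the round
#' path to the flat path.
#'
#' @param l flat cell length (um), l >= c.
#' @param c rounded planar extent (um), > 0.
#' @param h rounded height / sagitta (um), >= 0.
#' @return object of class `rounding_geometry`: list with l, c, h,
#'   `arc_length` (um), `path_ratio`.
#' @export
#' @examples
#' arc_path_length(12, 10, 5)$arc_length  # 5 * pi (semicircle)
arc_path_length <- function(l, c, h) {
  stopifnot(c > 0, h >= 0)
  if (c > l) stop("rounded planar extent c cannot exceed flat length l")
  if (h == 0) {
    arc <- c
  } else {
    R <- (c^2 + 4 * h^2) / (8 * h)
    half_angle <- asin(min(1, c / (2 * R)))
    if (h > c / 2) half_angle <- pi - half_angle
    arc <- 2 * R * half_angle
  }
  structure(list(l = l, c = c, h = h, arc_length = arc,
                 path_ratio = arc / l),
            class = "rounding_geometry")
}

#' Pearling: lengthwise caliber SD
#'
#' Pearling of a profile measured at 1-um increments is the sample
#' standard deviation of the calibers along the length of the axon.
#'
#' @param calibers numeric calibers (um), NA entries ignored.
#' @return pearling SD (um).
#' @export
pearling <- function(calibers) {
  cal <- calibers[is.finite(calibers)]
  if (length(cal) < 2L) stop("need at least 2 calibers")
  stats::sd(cal)
}

#' Change in pearling from the round to the flat frame
#'
#' @param round_profile,flat_profile caliber vectors (>= 3 locations
#'   each) at 1-um increments.
#' @return list with `pearling_round`, `pearling_flat`, `delta` =
#'   flat - round (um).
#' @export
pearling_change <- function(round_profile, flat_profile) {
  if (sum(is.finite(round_profile)) < 3L ||
      sum(is.finite(flat_profile)) < 3L)
    stop("need at least 3 locations per profile")
  pr <- pearling(round_profile); pf <- pearling(flat_profile)
  list(pearling_round = pr, pearling_flat = pf, delta = pf - pr)
}
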