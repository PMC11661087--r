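#' Mean segment caliber from the three standard positions
#'
#' Each branch segment is measured 3, 4 and 5 um from the branch point
#' and the three calibers are averaged to give the segment's caliber.
#' Any missing or flagged position makes the segment unusable (this
#' feeds the exclusion log).
#'
#' @param measurements data.frame with `arc_pos`, `caliber` and flag
#'   columns as produced by [measure_along_segment()]; or a bare numeric
#'   vector of exactly three calibers.
#' @param positions required positions (um); default c(3, 4, 5).
#' @param tol position matching tolerance (um).
#' @return mean caliber (um).
#' @export
segment_mean_caliber <- function(measurements, positions = c(3, 4, 5),
                                 tol = 0.25) {
  if (is.numeric(measurements) && is.null(dim(measurements))) {
    if (length(measurements) != length(positions) ||
        any(!is.finite(measurements)))
      stop("segment unusable: need one valid caliber per position")
    return(mean(measurements))
  }
  cal <- vapply(positions, function(p) {
    i <- which(abs(measurements$arc_pos - p) <= tol)
    if (length(i) != 1L)
      stop("segment unusable: no measurement at ", p, " um")
    i
  }, integer(1))
  m <- measurements[cal, , drop = FALSE]
  flagged <- m$below_resolution | m$single_peak | !is.finite(m$caliber)
  if (any(flagged))
    stop("segment unusable: flagged or missing measurement at ",
         paste(positions[flagged], collapse = ", "), " um")
  mean(m$caliber)
}

#' Assign P / S1 / S2 roles at a branch point
#'
#' The primary (P) is the segment entering the branch point from the
#' proximal side; of the two secondary branches, the thicker is S1 and
#' the thinner S2. Ties are broken deterministically (lower segment id
#' becomes S1) and give symmetry 1.
#'
#' @param primary mean caliber of the primary segment (um).
#' @param secondaries named numeric vector of exactly two secondary mean
#'   calibers (um), names = segment ids.
#' @return object of class `branch_record`: list with P, S1, S2,
#'   `s1_id`, `s2_id`, `norm_S1` = S1/P, `norm_S2` = S2/P, and
#'   `symmetry` = S2/S1.
#' @export
assign_branch_roles <- function(primary, secondaries) {
  if (length(secondaries) != 2L)
    stop("exactly two secondary branches are required, got ",
         length(secondaries))
  stopifnot(primary > 0, all(secondaries > 0))
  ids <- names(secondaries)
  if (is.null(ids)) ids <- c("S_a", "S_b")
  ord <- order(-secondaries, ids)  # thicker first; tie -> lower id
  s1 <- secondaries[ord[1]]; s2 <- secondaries[ord[2]]
  structure(list(P = unname(primary),
                 S1 = unname(s1), S2 = unname(s2),
                 s1_id = ids[ord[1]], s2_id = ids[ord[2]],
                 norm_S1 = unname(s1 / primary),
                 norm_S2 = unname(s2 / primary),
                 symmetry = unname(s2 / s1)),
            class = "branch_record")
}

#' @export
print.branch_record <- function(x, ...) {
  cat(sprintf("branch_record: P=%.3f S1=%.3f S2=%.3f um, symmetry=%.3f\n",
              x$P, x$S1, x$S2, x$symmetry))
  invisible(x)
}

#' Cross-sectional-area taper and radius scaling ratios
#'
#' Computes per-branch cross-sectional areas pi (caliber/2)^2 and the
#' taper statistics: area_ratio = (area_S1 + area_S2) / area_P, the
#' radius scaling ratios S1/P and S2/P, and the pooled S/P entries (both
#' ratios, for population averaging). The identity area_ratio =
#' (S1/P)^2 + (S2/P)^2 holds exactly.
#'
#' @param record `branch_record`.
#' @return object of class `taper_summary`: list with area_P, area_S1,
#'   area_S2 (um^2), area_ratio, ratio_S1, ratio_S2, pooled (length-2
#'   numeric).
#' @export
taper_ratios <- function(record) {
  area <- function(cal) pi * (cal / 2)^2
  structure(list(area_P = area(record$P), area_S1 = area(record$S1),
                 area_S2 = area(record$S2),
                 area_ratio = (area(record$S1) + area(record$S2)) /
                   area(record$P),
                 ratio_S1 = record$S1 / record$P,
                 ratio_S2 = record$S2 / record$P,
                 pooled = c(record$S1 / record$P, record$S2 / record$P)),
            class = "taper_summary")
}

#' Pooled secondary-to-primary scaling ratio across branch points
#'
#' Population mean over all per-branch-point ratios, each record
#' contributing both S1/P and S2/P.
#'
#' @param records list of `branch_record`.
#' @return mean pooled S/P.
#' @export
pooled_scaling_ratio <- function(records) {
  mean(unlist(lapply(records, function(r) c(r$S1 / r$P, r$S2 / r$P))))
}

#' Ordinary least-squares line fit
#'
#' Thin wrapper over [stats::lm()] returning slope, intercept and R^2.
#' A constant response is given R^2 = 0 by convention.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list with `slope`, `intercept`, `r_squared`, class
#'   `regression_result`.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (diff(range(x)) == 0) stop("x is constant; no line can be fit")
  if (diff(range(y)) == 0)
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0),
                     class = "regression_result"))
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot),
            class = "regression_result")
}
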