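#' Apply dataset-level exclusion rules
#'
#' Implements the technical exclusion criteria used when assembling a
#' caliber dataset:
#' \itemize{
#'   \item branch points spaced closer than the experiment's minimum
#'     (5 um for symmetry analysis, 3 um otherwise) exclude the axon;
#'   \item a primary branch whose caliber is below the resolution limit
#'     excludes that branch point;
#'   \item an axon with more than `below_fraction_limit` of its day-1
#'     measurements below the resolution limit is excluded.
#' }
#' Below-resolution measurements count toward the fraction rule but carry
#' no caliber into downstream means.
#'
#' @param measurements data.frame with at least columns `axon_id`,
#'   `below_resolution` (logical); optionally `role` ("P"/"S1"/"S2"),
#'   `day` (integer; rule 3 uses day 1).
#' @param axon_meta optional data.frame with `axon_id` and
#'   `branch_spacing` (um, distance to the nearest other branch point).
#' @param min_branch_spacing minimum allowed branch spacing (um).
#' @param below_fraction_limit maximum tolerated fraction of
#'   below-resolution measurements at day 1 (default 0.2).
#' @return list with `retained` (filtered measurements), `excluded`
#'   (dropped rows), and `log` (data.frame: axon_id, rule, detail).
#' @export
apply_exclusion_rules <- function(measurements, axon_meta = NULL,
                                  min_branch_spacing = 3,
                                  below_fraction_limit = 0.2) {
  stopifnot(is.data.frame(measurements),
            all(c("axon_id", "below_resolution") %in% names(measurements)))
  log <- data.frame(axon_id = character(0), rule = character(0),
                    detail = character(0))
  drop_axons <- character(0)
  note <- function(axon, rule, detail) {
    log <<- rbind(log, data.frame(axon_id = axon, rule = rule,
                                  detail = detail))
    drop_axons <<- union(drop_axons, axon)
  }
  if (!is.null(axon_meta) && nrow(axon_meta) > 0) {
    bad <- axon_meta$axon_id[axon_meta$branch_spacing < min_branch_spacing]
    for (a in bad)
      note(a, "branch_spacing",
           sprintf("branch points closer than %g um", min_branch_spacing))
  }
  if ("role" %in% names(measurements)) {
    p <- measurements[measurements$role == "P", , drop = FALSE]
    for (a in unique(p$axon_id[p$below_resolution]))
      note(a, "primary_below_resolution",
           "primary branch caliber below the resolution limit")
  }
  if ("day" %in% names(measurements)) {
    d1 <- measurements[measurements$day == 1, , drop = FALSE]
    for (a in unique(d1$axon_id)) {
      f <- mean(d1$below_resolution[d1$axon_id == a])
      if (f > below_fraction_limit)
        note(a, "below_resolution_fraction",
             sprintf("%.0f%% of day-1 measurements below the limit",
                     100 * f))
    }
  }
  keep <- !(measurements$axon_id %in% drop_axons)
  list(retained = measurements[keep, , drop = FALSE],
       excluded = measurements[!keep, , drop = FALSE],
       log = log)
}
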