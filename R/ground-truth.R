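#' Axon ground-truth geometry
#'
#' Container for the generator's truth record: centerline segments,
#' branch points, and a lengthwise radius profile per segment. Rendered
#' scenes keep this record alongside the pixels, so every downstream
#' quantity (true caliber 2*r(s), branch roles, region means) can be
#' recomputed without the images.
#'
#' @param segments named list; each element a two-column matrix of ordered
#'   centerline points (um).
#' @param radius_profiles named list of `radius_profile` tables, one per
#'   segment (names must match `segments`).
#' @param branch_points optional data.frame with columns `x`, `y` (um),
#'   `parent`, and children segment ids in `children` (list column or
#'   comma-separated string). Each child segment must start at its branch
#'   point.
#' @param frame_time acquisition time of this frame (minutes).
#' @return object of class `axon_truth`.
#' @export
axon_truth <- function(segments, radius_profiles, branch_points = NULL,
                       frame_time = 0) {
  stopifnot(is.list(segments), length(segments) > 0,
            !is.null(names(segments)),
            setequal(names(segments), names(radius_profiles)))
  for (id in names(segments)) {
    seg <- as.matrix(segments[[id]])
    if (nrow(seg) < 2L)
      stop("segment '", id, "' needs at least two points")
    len <- polyline_arclength(seg)
    if (any(diff(len) <= 0))
      stop("segment '", id, "' has repeated consecutive points")
    prof <- radius_profiles[[id]]
    if (any(prof$r <= 0))
      stop("segment '", id, "' has a non-positive radius")
    segments[[id]] <- seg
  }
  if (!is.null(branch_points) && nrow(branch_points) > 0) {
    for (i in seq_len(nrow(branch_points))) {
      kids <- branch_children(branch_points, i)
      for (kid in kids) {
        if (!kid %in% names(segments))
          stop("branch point ", i, " references unknown segment '", kid, "'")
        first <- segments[[kid]][1, ]
        d <- sqrt((first[1] - branch_points$x[i])^2 +
                  (first[2] - branch_points$y[i])^2)
        if (d > 1e-6)
          stop("child segment '", kid, "' does not originate at its ",
               "branch point (offset ", format(d), " um)")
      }
    }
  }
  structure(list(segments = segments, radius_profiles = radius_profiles,
                 branch_points = branch_points, frame_time = frame_time),
            class = "axon_truth")
}

branch_children <- function(branch_points, i) {
  kids <- branch_points$children[[i]]
  if (is.character(kids) && length(kids) == 1L && grepl(",", kids))
    kids <- strsplit(kids, ",")[[1]]
  trimws(kids)
}

#' @export
print.axon_truth <- function(x, ...) {
  cat("axon_truth:", length(x$segments), "segment(s),",
      if (is.null(x$branch_points)) 0 else nrow(x$branch_points),
      "branch point(s), t =", x$frame_time, "min\n")
  invisible(x)
}

#' Straight-tube ground truth
#'
#' Convenience constructor: a single straight segment of given length and
#' orientation with an arbitrary radius profile (uniform by default).
#'
#' @param length_um segment length (um).
#' @param radius base radius (um) used when `profile` is NULL.
#' @param origin starting point c(x, y) in um.
#' @param angle orientation in radians (0 = +x axis).
#' @param profile optional `radius_profile`; overrides `radius`.
#' @param frame_time minutes.
#' @return `axon_truth` with one segment named "seg1".
#' @export
straight_axon_truth <- function(length_um, radius = 0.2,
                                origin = c(0, 0), angle = 0,
                                profile = NULL, frame_time = 0) {
  if (is.null(profile))
    profile <- uniform_radius_profile(radius, length_um)
  n <- max(2L, ceiling(length_um / 0.5) + 1L)
  s <- seq(0, length_um, length.out = n)
  pts <- cbind(x = origin[1] + s * cos(angle),
               y = origin[2] + s * sin(angle))
  axon_truth(segments = list(seg1 = pts),
             radius_profiles = list(seg1 = profile),
             frame_time = frame_time)
}

#' Y-branched ground truth
#'
#' A primary segment entering from the left that splits at a branch point
#' into two secondary segments of independent radii. Used for branch
#' symmetry/taper recovery tests.
#'
#' @param primary_length,secondary_length segment lengths (um).
#' @param r_p,r_s1,r_s2 radii (um) of the primary and the two secondaries.
#' @param origin start of the primary (um).
#' @param spread half-angle between the secondaries (radians).
#' @return `axon_truth` with segments "P", "Sa", "Sb" and one branch point.
#' @export
branched_axon_truth <- function(primary_length = 9, secondary_length = 9,
                                r_p = 0.22, r_s1 = 0.16, r_s2 = 0.11,
                                origin = c(1, 0), spread = pi / 5) {
  bp <- origin + c(primary_length, 0)
  mkseg <- function(p0, ang, len) {
    s <- seq(0, len, length.out = max(2L, ceiling(len / 0.5) + 1L))
    cbind(x = p0[1] + s * cos(ang), y = p0[2] + s * sin(ang))
  }
  segs <- list(P  = mkseg(origin, 0, primary_length),
               Sa = mkseg(bp,  spread, secondary_length),
               Sb = mkseg(bp, -spread, secondary_length))
  profs <- list(P  = uniform_radius_profile(r_p, primary_length),
                Sa = uniform_radius_profile(r_s1, secondary_length),
                Sb = uniform_radius_profile(r_s2, secondary_length))
  bps <- data.frame(x = bp[1], y = bp[2], parent = "P")
  bps$children <- list(c("Sa", "Sb"))
  axon_truth(segs, profs, branch_points = bps)
}

#' True caliber (2 r) at an arc position on a segment
#'
#' @param truth `axon_truth`.
#' @param segment_id segment name.
#' @param s arc position(s) in um.
#' @return true diameter(s) in um.
#' @export
true_caliber <- function(truth, segment_id, s) {
  2 * radius_at(truth$radius_profiles[[segment_id]], s)
}
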