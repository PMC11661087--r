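#' MD5 hash of a configuration object
#'
#' Canonical JSON serialization hashed with MD5; embedded in every
#' output file for provenance.
#' @param config any serializable list.
#' @return hex string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

truth_to_list <- function(truth) {
  list(segments = lapply(truth$segments, function(m)
         unname(apply(unname(as.matrix(m)), 1, as.numeric,
                      simplify = FALSE))),
       radius_profiles = lapply(truth$radius_profiles, function(p)
         list(s = p$s, r = p$r)),
       branch_points = if (is.null(truth$branch_points)) NULL else
         lapply(seq_len(nrow(truth$branch_points)), function(i)
           list(x = truth$branch_points$x[i], y = truth$branch_points$y[i],
                parent = truth$branch_points$parent[i],
                children = as.list(branch_children(truth$branch_points,
                                                   i)))),
       frame_time = truth$frame_time)
}

list_to_truth <- function(lst) {
  segs <- lapply(lst$segments, function(pp)
    do.call(rbind, lapply(pp, as.numeric)))
  profs <- lapply(lst$radius_profiles, function(p)
    structure(data.frame(s = unlist(p$s), r = unlist(p$r)),
              class = c("radius_profile", "data.frame")))
  bp <- NULL
  if (!is.null(lst$branch_points) && length(lst$branch_points) > 0) {
    bp <- data.frame(
      x = vapply(lst$branch_points, function(b) b$x, numeric(1)),
      y = vapply(lst$branch_points, function(b) b$y, numeric(1)),
      parent = vapply(lst$branch_points, function(b) b$parent,
                      character(1)))
    bp$children <- lapply(lst$branch_points, function(b)
      unlist(b$children))
  }
  axon_truth(segs, profs, branch_points = bp,
             frame_time = if (is.null(lst$frame_time)) 0 else
               lst$frame_time)
}

#' Write a rendered scene as multi-frame TIFF plus ground-truth sidecar
#'
#' Pixels are stored as 16-bit TIFF scaled by a fixed factor recorded in
#' the JSON sidecar along with the full ground truth, the scene config,
#' its hash, and the seed — enough to recompute any downstream result
#' without the images.
#'
#' @param frames list of `image_frame` (or a single one).
#' @param truths list of `axon_truth`, one per frame.
#' @param config `scene_config`.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @param extra named list merged into the sidecar (e.g. border
#'   positions for division scenes).
#' @return invisibly, the sidecar path.
#' @export
write_scene <- function(frames, truths, config, path, extra = list()) {
  if (inherits(frames, "image_frame")) frames <- list(frames)
  if (inherits(truths, "axon_truth")) truths <- list(truths)
  stopifnot(length(frames) == length(truths))
  peak <- max(vapply(frames, function(f) max(f$pixels), numeric(1)))
  scale <- peak * 1.05
  imgs <- lapply(frames, function(f)
    pmin(pmax(f$pixels / scale, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16, compression = "none")
  side <- c(list(format_version = 1L,
                 intensity_scale = scale,
                 pixel_size = frames[[1]]$pixel_size,
                 frame_times = vapply(frames, function(f) f$frame_time,
                                      numeric(1)),
                 config = unclass(config),
                 config_hash = config_hash(unclass(config)),
                 seed = config$seed,
                 truths = lapply(truths, truth_to_list)),
            extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paste0(path, ".json"))
}

#' Read a scene written by [write_scene()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return list with `frames` (list of `image_frame`, photon scale
#'   restored), `truths`, `config` (list echo), `sidecar` (full parsed
#'   sidecar).
#' @export
read_scene <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = FALSE)
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  px <- side$pixel_size
  scale <- side$intensity_scale
  frames <- lapply(seq_along(imgs), function(i)
    image_frame(imgs[[i]] * scale, px,
                frame_time = unlist(side$frame_times)[i]))
  truths <- lapply(side$truths, list_to_truth)
  list(frames = frames, truths = truths, config = side$config,
       sidecar = side)
}

#' Write a caliber-measurement table as CSV
#'
#' Schema: frame_time_min, segment_id, arc_pos_um, caliber_um,
#' flag_below_resolution, flag_single_peak, flag_ambiguous. Provenance
#' (config hash, seed) is carried in leading comment lines.
#'
#' @param measurements data.frame as returned by
#'   [measure_along_segment()], plus a `frame_time` column (minutes;
#'   added as 0 when absent).
#' @param path output CSV path.
#' @param config optional config list for the hash line.
#' @param seed optional seed echoed in the header.
#' @return invisibly, `path`.
#' @export
write_measurements_csv <- function(measurements, path, config = NULL,
                                   seed = NULL) {
  if (!"frame_time" %in% names(measurements))
    measurements$frame_time <- 0
  out <- data.frame(frame_time_min = measurements$frame_time,
                    segment_id = measurements$segment_id,
                    arc_pos_um = measurements$arc_pos,
                    caliber_um = measurements$caliber,
                    flag_below_resolution = measurements$below_resolution,
                    flag_single_peak = measurements$single_peak,
                    flag_ambiguous = measurements$ambiguous_peaks)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste0("# config_hash: ", config_hash(config)), con)
  if (!is.null(seed))
    writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements_csv()]
#' @param path CSV path.
#' @return data.frame in the internal measurement layout.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  data.frame(frame_time = df$frame_time_min,
             segment_id = df$segment_id,
             arc_pos = df$arc_pos_um,
             caliber = df$caliber_um,
             below_resolution = df$flag_below_resolution,
             single_peak = df$flag_single_peak,
             ambiguous_peaks = df$flag_ambiguous)
}

#' Write / read centerline annotations as JSON
#'
#' Schema: `segments` = list of {id, points: [[x, y], ...] um};
#' `branch_points` = list of {x, y, parent, children: [ids]}.
#'
#' @param truth an `axon_truth` (its radius profiles are not written —
#'   annotations carry geometry only).
#' @param path JSON path.
#' @return invisibly `path`.
#' @export
write_centerline_json <- function(truth, path) {
  lst <- truth_to_list(truth)
  ann <- list(segments = lapply(names(lst$segments), function(id)
                list(id = id, points = lst$segments[[id]])),
              branch_points = lst$branch_points)
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_centerline_json
#' @return for the reader: list with `segments` (named list of point
#'   matrices) and `branch_points` (data.frame or NULL).
#' @export
read_centerline_json <- function(path) {
  if (!file.exists(path)) stop("centerline file not found: ", path)
  ann <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- list()
  for (s in ann$segments)
    segs[[s$id]] <- do.call(rbind, lapply(s$points, as.numeric))
  bp <- NULL
  if (!is.null(ann$branch_points) && length(ann$branch_points) > 0) {
    bp <- data.frame(
      x = vapply(ann$branch_points, function(b) b$x, numeric(1)),
      y = vapply(ann$branch_points, function(b) b$y, numeric(1)),
      parent = vapply(ann$branch_points, function(b)
        if (is.null(b$parent)) NA_character_ else b$parent, character(1)))
    bp$children <- lapply(ann$branch_points, function(b)
      unlist(b$children))
  }
  list(segments = segs, branch_points = bp)
}

#' Import a neuron morphology from SWC as 2D centerline segments
#'
#' Reads the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent), projects to the x-y plane (z dropped, radius ignored) and
#' splits the tree into unbranched segments at branch nodes. Branch
#' points are emitted with their child segment ids.
#'
#' @param path SWC file.
#' @return same structure as [read_centerline_json()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  kids <- split(tab$id, factor(tab$parent, levels = tab$id))
  n_kids <- vapply(kids, length, integer(1))
  is_branch <- n_kids > 1
  node <- function(id) tab[match(id, tab$id), ]
  segs <- list()
  # walk from every segment start (root, or child of a branch node)
  starts <- tab$id[tab$parent == -1 |
                     tab$parent %in% tab$id[is_branch]]
  for (st in starts) {
    pts <- list()
    par <- node(st)$parent
    if (par != -1) {
      pn <- node(par)
      pts[[1]] <- c(pn$x, pn$y)  # child starts at its branch point
    }
    cur <- st
    repeat {
      cn <- node(cur)
      pts[[length(pts) + 1]] <- c(cn$x, cn$y)
      ch <- kids[[as.character(cur)]]
      if (length(ch) != 1L) break
      cur <- ch
    }
    id <- paste0("swc_", st)
    segs[[id]] <- do.call(rbind, pts)
  }
  bp <- NULL
  branch_ids <- tab$id[is_branch]
  if (length(branch_ids) > 0) {
    bp <- do.call(rbind, lapply(branch_ids, function(b) {
      bn <- node(b)
      data.frame(x = bn$x, y = bn$y, parent = NA_character_)
    }))
    bp$children <- lapply(branch_ids, function(b)
      paste0("swc_", kids[[as.character(b)]]))
  }
  list(segments = segs, branch_points = bp)
}
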