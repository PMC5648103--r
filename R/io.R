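#' Write and read frame sequences as PNG image directories
#'
#' Frames are stored as 8-bit grayscale PNGs (`frame_000001.png`, ...) with
#' a sidecar timestamp table `frames.csv` (`frame_index`, `t_seconds`).
#' This is the generator's on-disk format and the only recording format the
#' reader supports (video containers would need an external decoder, which
#' this package does not ship).
#'
#' @param frames A [frame_seq()].
#' @param path Directory (created if needed).
#' @return `write_frames()` returns `path` invisibly; `read_frames()` a
#'   [frame_seq()].
#' @export
write_frames <- function(frames, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames$frames)) {
    png::writePNG(frames$frames[[i]] / 255,
                  file.path(path, sprintf("frame_%06d.png", i)))
  }
  utils::write.csv(
    data.frame(frame_index = seq_along(frames$frames),
               t_seconds = frames$t),
    file.path(path, "frames.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  sidecar <- file.path(path, "frames.csv")
  if (!dir.exists(path)) stop("not a frame directory: ", path)
  if (!file.exists(sidecar))
    stop("missing timestamp sidecar frames.csv in ", path)
  tab <- utils::read.csv(sidecar)
  expected <- seq_len(max(tab$frame_index))
  missing <- setdiff(expected, tab$frame_index)
  if (length(missing))
    stop("gap in frame indices: missing index ", missing[1])
  fl <- file.path(path, sprintf("frame_%06d.png", tab$frame_index))
  absent <- !file.exists(fl)
  if (any(absent))
    stop("gap in frame indices: missing index ",
         tab$frame_index[which(absent)[1]])
  frames <- lapply(fl, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow(m))
  })
  frame_seq(frames, tab$t_seconds)
}

RESULT_SCHEMA_VERSION <- "1"

#' Persist a run's result store
#'
#' A result store groups the per-ROI trajectory tables, behavior tables and
#' event log of one run with its configuration and metadata. On disk it is
#' a directory of CSV files (numeric columns written at 6 decimals, which
#' round-trips bit-exactly at that precision) plus `config.json` and
#' `metadata.json`; the metadata records a hash of the config so tampering
#' is detected on read.
#'
#' @param store List with any of `trajectories` (named list of data
#'   frames), `behavior`, `events` (data frames) and `config` (list).
#' @param path Directory.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   the store.
#' @export
write_results <- function(store, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) {
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) sprintf("%.6f", x))
    d
  }
  for (nm in names(store$trajectories %||% list()))
    utils::write.csv(fmt(store$trajectories[[nm]]),
                     file.path(path, sprintf("trajectory_roi_%s.csv", nm)),
                     row.names = FALSE)
  if (!is.null(store$behavior))
    utils::write.csv(fmt(store$behavior), file.path(path, "behavior.csv"),
                     row.names = FALSE)
  if (!is.null(store$events))
    utils::write.csv(fmt(store$events), file.path(path, "events.csv"),
                     row.names = FALSE)
  cfg_path <- file.path(path, "config.json")
  jsonlite::write_json(store$config %||% list(), cfg_path,
                       auto_unbox = TRUE, digits = NA)
  meta <- list(schema_version = RESULT_SCHEMA_VERSION,
               written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               software = paste0("ethotrack ",
                                 as.character(utils::packageVersion("ethotrack"))),
               config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "metadata.json"))
  if (!identical(as.character(meta$schema_version), RESULT_SCHEMA_VERSION))
    stop(sprintf("result schema version mismatch: store has %s, reader %s",
                 meta$schema_version, RESULT_SCHEMA_VERSION))
  cfg_path <- file.path(path, "config.json")
  if (!identical(unname(tools::md5sum(cfg_path)), meta$config_md5))
    stop("config integrity error: config.json does not match stored hash")
  traj_files <- list.files(path, pattern = "^trajectory_roi_.*\\.csv$")
  trajectories <- lapply(traj_files, function(f)
    utils::read.csv(file.path(path, f)))
  names(trajectories) <- sub("^trajectory_roi_(.*)\\.csv$", "\\1", traj_files)
  read_opt <- function(f)
    if (file.exists(file.path(path, f))) utils::read.csv(file.path(path, f))
  list(trajectories = trajectories,
       behavior = read_opt("behavior.csv"),
       events = read_opt("events.csv"),
       config = jsonlite::fromJSON(cfg_path, simplifyVector = TRUE),
       metadata = meta)
}

#' Export registered ROIs as a table
#'
#' @param rois List of `roi` objects from [build_rois()].
#' @return Data frame with one row per ROI corner.
#' @export
rois_as_table <- function(rois) {
  do.call(rbind, lapply(rois, function(r)
    data.frame(roi = r$index, corner = 1:4,
               x_px = r$corners[, 1], y_px = r$corners[, 2],
               mm_per_px = r$mm_per_px, food_end = r$food_end,
               out_of_frame = r$out_of_frame)))
}
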