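#' Write a frame sequence as a PNG directory with a JSON manifest
#'
#' Frames are written as zero-padded grayscale PNGs (`frame_000001.png`, ...)
#' plus `manifest.json` recording the frame rates and count; any programmed
#' ground truth travels in `truth.json`.
#'
#' @param frames A `frame_sequence`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, dir) {
  if (!inherits(frames, "frame_sequence"))
    rg_error("frames must be a frame_sequence", "rg_parameter")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(frames$frames)
  width <- max(6, nchar(as.character(n)))
  for (i in seq_len(n)) {
    png::writePNG(frames$frames[[i]],
                  file.path(dir, sprintf("frame_%0*d.png", width, i)))
  }
  manifest <- list(source_fps = frames$source_fps,
                   analysis_fps = frames$analysis_fps,
                   frame_count = n,
                   frame_height_px = nrow(frames$frames[[1]]),
                   frame_width_px = ncol(frames$frames[[1]]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(frames$truth))
    jsonlite::write_json(frames$truth, file.path(dir, "truth.json"),
                         digits = NA)
  invisible(dir)
}

#' Read a frame sequence from a PNG directory
#'
#' Reads the PNGs listed by `manifest.json` (sorted by name). Color frames
#' are converted to grayscale by Rec. 709 luminance.
#'
#' @param dir Directory written by [write_frames()] (or any directory of
#'   numbered PNGs plus a manifest).
#' @return A `frame_sequence` (without ground truth unless `truth.json`
#'   exists).
#' @export
read_frames <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    rg_error("manifest.json not found in frame directory", "rg_parameter")
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$", full.names = TRUE))
  if (length(files) != man$frame_count)
    rg_error("frame count does not match manifest", "rg_parameter")
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    }
    img
  })
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(frames = frames, source_fps = man$source_fps,
                 analysis_fps = man$analysis_fps, truth = truth),
            class = "frame_sequence")
}

#' Write LFP recordings as CSV with a JSON sidecar
#'
#' One CSV column per channel; the sidecar records the sampling rate, the
#' channel-to-side layout and the day label.
#'
#' @param recs A single `lfp_recording` or a list of them (equal lengths and
#'   sampling rates).
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_lfp_csv <- function(recs, path) {
  if (inherits(recs, "lfp_recording")) recs <- list(recs)
  fs <- unique(vapply(recs, function(r) r$fs_hz, numeric(1)))
  if (length(fs) != 1)
    rg_error("all channels must share one sampling rate", "rg_parameter")
  cols <- lapply(recs, function(r) r$samples)
  names(cols) <- vapply(recs, function(r) r$channel_id, character(1))
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE)
  sidecar <- list(
    fs_hz = fs,
    channels = lapply(recs, function(r) list(id = r$channel_id, side = r$side)),
    day_label = recs[[1]]$day_label
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read LFP recordings from CSV plus sidecar
#'
#' @param path CSV path written by [write_lfp_csv()]; `<path>.json` must
#'   exist.
#' @return A list of `lfp_recording` objects, one per channel.
#' @export
read_lfp_csv <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    rg_error("JSON sidecar not found next to the LFP CSV", "rg_parameter")
  meta <- jsonlite::read_json(side_path, simplifyVector = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  lapply(meta$channels, function(ch) {
    structure(list(samples = df[[ch$id]], fs_hz = meta$fs_hz,
                   channel_id = ch$id, side = ch$side,
                   day_label = meta$day_label, spec = NULL, seed = NA_integer_),
              class = "lfp_recording")
  })
}

#' Write a per-frame pose table as CSV
#'
#' @param series An [angle_series()] with a pose table (as produced by
#'   [track_video()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(series, path) {
  if (!inherits(series, "angle_series") || is.null(series$poses))
    rg_error("series must be a tracked angle_series with poses", "rg_parameter")
  df <- series$poses
  df$analysis_fps <- series$analysis_fps
  df$source_fps <- series$source_fps
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pose CSV back into an angle series
#'
#' @param path CSV written by [write_pose_csv()].
#' @return An `angle_series`.
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  angle_series(frame_indices = df$frame_index,
               headings_deg = ifelse(is.na(df$heading_deg), NA,
                                     df$heading_deg),
               analysis_fps = df$analysis_fps[1],
               source_fps = df$source_fps[1],
               status = df$status,
               poses = df[, setdiff(names(df), c("analysis_fps", "source_fps"))])
}
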