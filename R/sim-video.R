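#' Arena and body geometry for synthetic top-view videos
#'
#' Describes the imaging geometry used by [render_mouse_video()]: a dark
#' circular arena (emulating a round bowl filmed from above) containing a
#' single bright elongated body (an ellipse whose major axis follows the
#' programmed heading) with a thinner straight tail attached at the back end.
#'
#' @param frame_width_px,frame_height_px Frame size in pixels.
#' @param arena_center_px Arena center `(x, y)` in pixel coordinates
#'   (0-based, x = column, y = row); default frame center.
#' @param arena_radius_px Arena radius in pixels; default fits the frame with
#'   a 10 px margin.
#' @param body_major_px,body_minor_px Ellipse semi-axes in pixels.
#' @param tail_length_px,tail_width_px Tail dimensions in pixels.
#' @param background_level,body_level Intensities in `[0, 1]`; the body must
#'   be brighter than the background.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (clipped to `[0, 1]` after addition); `0` gives bit-reproducible frames.
#'
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(frame_width_px = 640, frame_height_px = 480,
                       arena_center_px = NULL, arena_radius_px = NULL,
                       body_major_px = 40, body_minor_px = 16,
                       tail_length_px = 50, tail_width_px = 4,
                       background_level = 0.1, body_level = 0.9,
                       noise_sd = 0) {
  if (!is_count(frame_width_px) || !is_count(frame_height_px))
    rg_error("frame dimensions must be positive integers", "rg_parameter")
  if (is.null(arena_center_px))
    arena_center_px <- c((frame_width_px - 1) / 2, (frame_height_px - 1) / 2)
  if (is.null(arena_radius_px))
    arena_radius_px <- min(frame_width_px, frame_height_px) / 2 - 10
  if (!(body_level > background_level))
    rg_error("body_level must exceed background_level", "rg_parameter")
  if (noise_sd < 0)
    rg_error("noise_sd must be >= 0", "rg_parameter")
  if (body_major_px + tail_length_px >= arena_radius_px)
    rg_error("body plus tail does not fit inside the arena", "rg_parameter")
  structure(
    list(frame_width_px = frame_width_px, frame_height_px = frame_height_px,
         arena_center_px = arena_center_px, arena_radius_px = arena_radius_px,
         body_major_px = body_major_px, body_minor_px = body_minor_px,
         tail_length_px = tail_length_px, tail_width_px = tail_width_px,
         background_level = background_level, body_level = body_level,
         noise_sd = noise_sd),
    class = "arena_spec"
  )
}

## Rasterize one pose. Frames are matrices (rows = image y, cols = image x),
## intensities in [0,1]. Heading uses arena coordinates (y up): the front
## direction in image terms is (cos h, -sin h) in (col, row).
render_pose_frame <- function(arena, center_xy, heading_deg) {
  w <- arena$frame_width_px; h <- arena$frame_height_px
  xg <- matrix(rep(0:(w - 1), each = h), nrow = h)   # column index per pixel
  yg <- matrix(rep(0:(h - 1), times = w), nrow = h)  # row index per pixel

  th <- heading_deg * pi / 180
  ux <- cos(th); uy <- sin(th)                       # arena coords, y up
  dx <- xg - center_xy[1]
  dy <- -(yg - center_xy[2])                         # flip image row axis
  pmaj <- dx * ux + dy * uy
  pmin <- -dx * uy + dy * ux

  a <- arena$body_major_px; b <- arena$body_minor_px
  in_body <- (pmaj / a)^2 + (pmin / b)^2 <= 1
  in_tail <- pmaj <= -a & pmaj >= -(a + arena$tail_length_px) &
    abs(pmin) <= arena$tail_width_px / 2

  acx <- arena$arena_center_px[1]; acy <- arena$arena_center_px[2]
  in_arena <- (xg - acx)^2 + (yg - acy)^2 <= arena$arena_radius_px^2

  frame <- matrix(0, nrow = h, ncol = w)
  frame[in_arena] <- arena$background_level
  frame[in_body | in_tail] <- arena$body_level
  frame
}

#' Render a synthetic top-view mouse video from a turn trajectory
#'
#' Draws one pose per trajectory heading and replicates it for
#' `source_fps / analysis_fps` consecutive source frames, so that the 5 fps
#' analysis subsampling used by the tracker is lossless by construction. The
#' body center follows a bounded random walk inside the arena, independent of
#' heading; the ellipse major axis follows the programmed heading, the tail
#' extends from the back end. With `noise_sd = 0` frames are bit-reproducible
#' given the seed; otherwise independent Gaussian noise is added per source
#' frame.
#'
#' @param trajectory A [turn_trajectory][simulate_turn_trajectory] object.
#' @param arena An [arena_spec()].
#' @param source_fps,analysis_fps Acquisition and analysis frame rates;
#'   `source_fps` must be an integer multiple of `analysis_fps`.
#' @param walk_step_px Maximum per-analysis-frame displacement of the body
#'   center (uniform in each coordinate).
#' @param seed Integer seed for the position walk and pixel noise.
#'
#' @return An object of class `frame_sequence`: a list with `frames` (list of
#'   intensity matrices), `source_fps`, `analysis_fps`, and `truth`, a data
#'   frame of the programmed heading and body center per analysis frame.
#' @export
render_mouse_video <- function(trajectory, arena = arena_spec(),
                               source_fps = 30, analysis_fps = 5,
                               walk_step_px = 3, seed = 1L) {
  if (!inherits(trajectory, "turn_trajectory"))
    rg_error("trajectory must be a turn_trajectory", "rg_parameter")
  k <- source_fps / analysis_fps
  if (abs(k - round(k)) > 1e-9)
    rg_error("source_fps must be an integer multiple of analysis_fps",
             "rg_parameter")
  k <- as.integer(round(k))
  n_pose <- length(trajectory$headings_deg)

  ## Keep the whole body + tail strictly inside the arena.
  margin <- arena$body_major_px + arena$tail_length_px + 2
  max_r <- arena$arena_radius_px - margin
  if (max_r <= 0)
    rg_error("arena too small to reposition the body inside it", "rg_render")

  centers <- with_rg_seed(seed, {
    pos <- matrix(NA_real_, nrow = n_pose, ncol = 2)
    cur <- arena$arena_center_px
    for (i in seq_len(n_pose)) {
      cur <- cur + stats::runif(2, -walk_step_px, walk_step_px)
      off <- cur - arena$arena_center_px
      r <- sqrt(sum(off^2))
      if (r > max_r) cur <- arena$arena_center_px + off * (max_r / r)
      pos[i, ] <- cur
    }
    pos
  })

  frames <- vector("list", n_pose * k)
  for (i in seq_len(n_pose)) {
    f <- render_pose_frame(arena, centers[i, ], trajectory$headings_deg[i])
    for (j in seq_len(k)) frames[[(i - 1L) * k + j]] <- f
  }
  if (arena$noise_sd > 0) {
    frames <- with_rg_seed(seed + 1L, lapply(frames, function(f) {
      g <- f + stats::rnorm(length(f), sd = arena$noise_sd)
      g[g < 0] <- 0; g[g > 1] <- 1
      g
    }))
  }

  structure(
    list(frames = frames, source_fps = source_fps, analysis_fps = analysis_fps,
         truth = data.frame(pose_index = seq_len(n_pose),
                            heading_deg = trajectory$headings_deg,
                            center_x = centers[, 1], center_y = centers[, 2]),
         arena = arena, seed = as.integer(seed)),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Frame sequence: %d frames of %d x %d px, %g fps (analysis %g fps)\n",
              length(x$frames), d[2], d[1], x$source_fps, x$analysis_fps))
  invisible(x)
}
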