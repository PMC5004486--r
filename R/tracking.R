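#' Tracker configuration
#'
#' Collects the tunable parameters of the video tracker. The pipeline is: threshold each analyzed frame, clean the mask with an opening
#' followed by a closing (disc structuring element), keep the largest
#' connected component as the body, and recover the tail from the raw
#' threshold mask for front/back disambiguation.
#'
#' @param threshold `"auto"` for Otsu's method on the frame histogram, or a
#'   fixed intensity in `(0, 1)`.
#' @param min_area_px Minimum acceptable body-component area in pixels.
#' @param open_radius_px Radius of the disc structuring element used for the
#'   opening/closing pair; the opening also strips the thin tail from the
#'   body mask.
#' @param dilate_radius_px Dilation radius used to build the tail-inclusive
#'   region around the body.
#' @param step_lo_deg,step_hi_deg Turn-magnitude filter bounds (degrees).
#' @param max_fail_frac Maximum tolerated fraction of failed analysis frames
#'   before [track_video()] aborts.
#' @param seed Seed for the k-means restarts.
#'
#' @return A list of class `track_config`.
#' @export
track_config <- function(threshold = "auto", min_area_px = 50,
                         open_radius_px = 2, dilate_radius_px = 5,
                         step_lo_deg = 4, step_hi_deg = 120,
                         max_fail_frac = 0.5, seed = 0L) {
  if (is.numeric(threshold) && !(threshold > 0 && threshold < 1))
    rg_error("fixed threshold must lie in (0, 1)", "rg_parameter")
  structure(list(threshold = threshold, min_area_px = min_area_px,
                 open_radius_px = open_radius_px,
                 dilate_radius_px = dilate_radius_px,
                 step_lo_deg = step_lo_deg, step_hi_deg = step_hi_deg,
                 max_fail_frac = max_fail_frac, seed = as.integer(seed)),
            class = "track_config")
}

disc_brush <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")

#' Segment the animal body in one frame
#'
#' Thresholds the frame (Otsu or fixed intensity), applies a binary opening
#' followed by a closing with a disc structuring element, and retains the
#' largest connected component. The opening removes speckle and the thin
#' tail; the closing fills holes inside the body.
#'
#' @param frame Numeric matrix of intensities in `[0, 1]` (rows x cols).
#' @param threshold `"auto"` (Otsu) or a fixed intensity in `(0, 1)`.
#' @param min_area_px Minimum component area; smaller detections raise a
#'   `rg_no_animal` error.
#' @param open_radius_px Structuring-element radius.
#' @param prev_center Optional `(x, y)` of the previous frame's body center,
#'   used to break near-ties between two similar-sized components.
#'
#' @return An object of class `binary_mask`: list with `pixels` (logical
#'   matrix), `area_px`, and the numeric `threshold` actually applied.
#' @export
segment_body <- function(frame, threshold = "auto", min_area_px = 50,
                         open_radius_px = 2, prev_center = NULL) {
  if (!is.matrix(frame) || !all(is.finite(frame)))
    rg_error("frame must be a finite numeric matrix", "rg_parameter")
  thr <- if (identical(threshold, "auto")) {
    EBImage::otsu(EBImage::Image(frame), range = c(0, 1))
  } else threshold
  raw <- frame > thr
  if (!any(raw)) rg_error("no pixels above threshold", "rg_no_animal")

  brush <- disc_brush(open_radius_px)
  cleaned <- EBImage::closing(EBImage::opening(raw + 0, brush), brush) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(cleaned + 0))
  areas <- tabulate(as.integer(lab[lab > 0]))
  if (length(areas) == 0 || max(areas) < min_area_px)
    rg_error("no component of at least min_area_px pixels", "rg_no_animal")

  ord <- order(areas, decreasing = TRUE)
  pick <- ord[1]
  if (length(ord) >= 2 && areas[ord[2]] >= 0.9 * areas[ord[1]]) {
    if (!is.null(prev_center)) {
      cands <- ord[areas[ord] >= 0.9 * areas[ord[1]]]
      d <- vapply(cands, function(id) {
        idx <- which(imageData(lab) == id, arr.ind = TRUE)
        ctr <- c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)  # (x, y), 0-based
        sum((ctr - prev_center)^2)
      }, numeric(1))
      pick <- cands[which.min(d)]
    }
    rg_warn("two components of similar area; tie broken by size/history",
            "rg_component_tie")
  }
  mask <- imageData(lab) == pick
  structure(list(pixels = mask, area_px = sum(mask), threshold = thr),
            class = "binary_mask")
}

#' Tail-inclusive region around a segmented body
#'
#' Builds the "slightly larger region including body and tail": the body mask
#' dilated by `dilate_radius_px`, united with every raw-threshold connected
#' component that touches the dilated body (this captures the tail, which the
#' opening removed from the body mask).
#'
#' @param frame Intensity matrix.
#' @param body_mask A [segment_body()] result.
#' @param dilate_radius_px Dilation radius in pixels.
#'
#' @return A `binary_mask` whose pixels are a superset of the body mask.
#' @export
segment_tail_inclusive <- function(frame, body_mask, dilate_radius_px = 5) {
  raw <- frame > body_mask$threshold
  dil <- EBImage::dilate(body_mask$pixels + 0, disc_brush(dilate_radius_px)) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(raw + 0))
  labm <- imageData(lab)
  touching <- setdiff(unique(labm[dil & labm > 0]), 0)
  region <- (labm %in% touching)
  dim(region) <- dim(labm)
  region <- region | body_mask$pixels
  structure(list(pixels = region, area_px = sum(region),
                 threshold = body_mask$threshold),
            class = "binary_mask")
}

## Pixel coordinates of a mask as (x = col, y = row), 0-based.
mask_coords <- function(mask_pixels) {
  idx <- which(mask_pixels, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

## First principal axis (unit vector) of a 2-column coordinate matrix.
principal_axis <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  ev$vectors[, 1]
}

#' Heading angle from front and back body points
#'
#' Angle of the back-to-front vector in arena coordinates (x rightward, y
#' upward, i.e. the image row axis negated), counterclockwise-positive,
#' mapped to `[0, 360)`.
#'
#' @param front_px,back_px Points `(x, y)` in image pixel coordinates
#'   (x = column, y = row).
#' @return Heading in degrees, in `[0, 360)`.
#' @examples
#' heading_from_points(c(10, 0), c(0, 0))  # 0
#' heading_from_points(c(0, 0), c(0, 10))  # 90 (front above back)
#' @export
heading_from_points <- function(front_px, back_px) {
  dx <- front_px[1] - back_px[1]
  dy <- -(front_px[2] - back_px[2])
  if (dx == 0 && dy == 0)
    rg_error("front and back points coincide", "rg_degenerate_body")
  wrap_360(atan2(dy, dx) * 180 / pi)
}

#' Extract the three-point body model from a segmented frame
#'
#' Runs k-means (k = 3) on the body-mask pixel coordinates, initialized with
#' the three centers obtained by cutting the tail-inclusive region into
#' thirds along its principal axis. The three converged centers are ordered
#' along the body's principal axis; the tail anchor (centroid of the
#' tail-inclusive region minus the body) designates the back end, the
#' opposite end is the front, and the heading is the back-to-front angle in
#' arena coordinates.
#'
#' @param body_mask A [segment_body()] mask (>= 3 pixels).
#' @param tail_inclusive_mask A [segment_tail_inclusive()] mask (superset of
#'   the body mask).
#' @param prev_pose Previous frame's `body_pose`, used to disambiguate
#'   front/back when no tail pixels are visible (the assignment within 90
#'   degrees of the previous heading is chosen and `degenerate_flag` is set).
#' @param frame_index Index recorded in the returned pose.
#' @param seed Seed for the jittered k-means restart.
#'
#' @return An object of class `body_pose`: list with `front_px`, `center_px`,
#'   `back_px`, `tail_px`, `heading_deg`, `frame_index`, `degenerate_flag`.
#' @export
extract_body_points <- function(body_mask, tail_inclusive_mask,
                                prev_pose = NULL, frame_index = 0L, seed = 0L) {
  coords <- mask_coords(body_mask$pixels)
  if (nrow(coords) < 3)
    rg_error("body mask has fewer than 3 pixels", "rg_degenerate_body")

  ## The tail-inclusive region supplies the initialization axis (its
  ## principal axis runs body-to-tail); the initial centers are the
  ## body-pixel tertile centroids along that axis, so all three start on
  ## the body and the converged partition stays an axis-aligned slab split.
  region_coords <- mask_coords(tail_inclusive_mask$pixels)
  axis0 <- principal_axis(region_coords)
  bc <- colMeans(coords)
  proj0 <- as.vector(sweep(coords, 2, bc) %*% axis0)
  qs <- stats::quantile(proj0, c(1 / 3, 2 / 3), names = FALSE)
  thirds <- findInterval(proj0, qs) + 1L
  ## Three collinear points on the initialization axis, one per projected
  ## body tertile, so the first assignment is a perpendicular slab split.
  init <- do.call(rbind, lapply(1:3, function(g) {
    bc + mean(proj0[thirds == g]) * axis0
  }))
  if (anyNA(init) || nrow(unique(init)) < 3) {
    init <- rbind(bc + c(-1, 0), bc, bc + c(1, 0))
  }

  ## Lloyd iterations keep the converged partition aligned with the
  ## axis-slab initialization; swap-phase refinements tend to tilt it.
  run_km <- function(ctrs) tryCatch(
    suppressWarnings(stats::kmeans(coords, centers = ctrs, iter.max = 200,
                                   algorithm = "Lloyd")),
    error = function(e) NULL
  )
  km <- run_km(init)
  if (is.null(km)) {
    km <- with_rg_seed(seed,
      run_km(init + matrix(stats::rnorm(6, sd = 0.5), 3, 2)))
  }
  if (is.null(km))
    rg_error("k-means failed to partition the body pixels", "rg_degenerate_body")

  axis_body <- principal_axis(coords)
  centers <- km$centers
  ord <- order(as.vector(centers %*% axis_body))
  end_a <- centers[ord[1], ]
  middle <- centers[ord[2], ]
  end_b <- centers[ord[3], ]

  tail_pixels <- tail_inclusive_mask$pixels & !body_mask$pixels
  degenerate <- FALSE
  if (any(tail_pixels)) {
    tc <- mask_coords(tail_pixels)
    tail_px <- colMeans(tc)
    da <- sum((end_a - tail_px)^2)
    db <- sum((end_b - tail_px)^2)
    if (da >= db) { front <- end_a; back <- end_b } else { front <- end_b; back <- end_a }
  } else if (!is.null(prev_pose)) {
    tail_px <- c(NA_real_, NA_real_)
    h1 <- heading_from_points(end_a, end_b)
    if (abs(wrap_diff(prev_pose$heading_deg, h1)) <= 90) {
      front <- end_a; back <- end_b
    } else {
      front <- end_b; back <- end_a
    }
    degenerate <- TRUE
  } else {
    rg_error("no tail pixels and no previous pose to orient the body",
             "rg_ambiguous_heading")
  }

  structure(
    list(front_px = unname(front), center_px = unname(middle),
         back_px = unname(back), tail_px = unname(tail_px),
         heading_deg = heading_from_points(front, back),
         frame_index = as.integer(frame_index),
         degenerate_flag = degenerate),
    class = "body_pose"
  )
}

#' Track a video and return the heading time series
#'
#' Analyzes frames `0, k, 2k, ...` with `k = round(source_fps /
#' analysis_fps)`: each analyzed frame is segmented, the three-point body
#' model is extracted, and the heading recorded. Per-frame failures (no
#' animal detected, degenerate body) are recorded as gaps, never
#' interpolated.
#'
#' @param frames A [render_mouse_video()] / [read_frames()] `frame_sequence`.
#' @param config A [track_config()].
#'
#' @return An object of class `angle_series`: list with `frame_indices`
#'   (0-based source-frame indices), `headings_deg` (`NA` at gaps), `status`
#'   (`"ok"`, `"no_animal"`, `"degenerate"`, `"ambiguous"`), the frame rates,
#'   and `poses`, a per-frame data frame suitable for [write_pose_csv()].
#' @export
track_video <- function(frames, config = track_config()) {
  if (!inherits(frames, "frame_sequence"))
    rg_error("frames must be a frame_sequence", "rg_parameter")
  k <- frames$source_fps / frames$analysis_fps
  if (abs(k - round(k)) > 1e-9)
    rg_warn("source_fps not an integer multiple of analysis_fps; using nearest stride",
            "rg_stride")
  k <- max(1L, as.integer(round(k)))
  idx <- seq(1L, length(frames$frames), by = k)

  n <- length(idx)
  poses <- data.frame(frame_index = idx - 1L,
                      front_x = NA_real_, front_y = NA_real_,
                      center_x = NA_real_, center_y = NA_real_,
                      back_x = NA_real_, back_y = NA_real_,
                      tail_x = NA_real_, tail_y = NA_real_,
                      heading_deg = NA_real_,
                      status = "ok", stringsAsFactors = FALSE)
  prev_pose <- NULL
  prev_center <- NULL
  for (i in seq_len(n)) {
    fr <- frames$frames[[idx[i]]]
    res <- tryCatch({
      bm <- segment_body(fr, threshold = config$threshold,
                         min_area_px = config$min_area_px,
                         open_radius_px = config$open_radius_px,
                         prev_center = prev_center)
      tm <- segment_tail_inclusive(fr, bm, config$dilate_radius_px)
      extract_body_points(bm, tm, prev_pose = prev_pose,
                          frame_index = idx[i] - 1L, seed = config$seed)
    },
    rg_no_animal = function(e) "no_animal",
    rg_degenerate_body = function(e) "degenerate",
    rg_ambiguous_heading = function(e) "ambiguous")
    if (inherits(res, "body_pose")) {
      poses[i, c("front_x", "front_y")] <- res$front_px
      poses[i, c("center_x", "center_y")] <- res$center_px
      poses[i, c("back_x", "back_y")] <- res$back_px
      poses[i, c("tail_x", "tail_y")] <- res$tail_px
      poses$heading_deg[i] <- res$heading_deg
      prev_pose <- res
      prev_center <- res$center_px
    } else {
      poses$status[i] <- res
    }
  }

  fail_frac <- mean(poses$status != "ok")
  if (fail_frac > config$max_fail_frac)
    rg_error(sprintf("tracking failed on %.0f%% of analyzed frames", 100 * fail_frac),
             "rg_tracking_failed")

  angle_series(frame_indices = poses$frame_index,
               headings_deg = poses$heading_deg,
               analysis_fps = frames$analysis_fps,
               source_fps = frames$source_fps,
               status = poses$status,
               poses = poses)
}

#' Heading time series at the analysis frame rate
#'
#' @param frame_indices Strictly increasing 0-based source-frame indices.
#' @param headings_deg Headings in `[0, 360)`; `NA` marks tracking gaps.
#' @param analysis_fps,source_fps Frame rates.
#' @param status Optional per-frame status strings (default `"ok"` where the
#'   heading is present).
#' @param poses Optional per-frame pose table.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(frame_indices, headings_deg, analysis_fps = 5,
                         source_fps = 30, status = NULL, poses = NULL) {
  if (length(frame_indices) != length(headings_deg))
    rg_error("frame_indices and headings_deg lengths differ", "rg_parameter")
  if (is.unsorted(frame_indices, strictly = TRUE))
    rg_error("frame_indices must be strictly increasing", "rg_parameter")
  if (is.null(status)) status <- ifelse(is.na(headings_deg), "no_animal", "ok")
  structure(list(frame_indices = as.integer(frame_indices),
                 headings_deg = wrap_360(headings_deg),
                 analysis_fps = analysis_fps, source_fps = source_fps,
                 status = status, poses = poses),
            class = "angle_series")
}

#' Angle series directly from a programmed trajectory
#'
#' Bypasses rendering and tracking: maps a [simulate_turn_trajectory()]
#' result onto the analysis frame grid. Useful for testing the turn-filter
#' and bias stages in isolation.
#'
#' @param trajectory A `turn_trajectory`.
#' @param analysis_fps,source_fps Frame rates defining the frame-index grid.
#' @return An `angle_series`.
#' @export
trajectory_angle_series <- function(trajectory, analysis_fps = 5,
                                    source_fps = 30) {
  k <- as.integer(round(source_fps / analysis_fps))
  n <- length(trajectory$headings_deg)
  angle_series(frame_indices = (seq_len(n) - 1L) * k,
               headings_deg = trajectory$headings_deg,
               analysis_fps = analysis_fps, source_fps = source_fps)
}

#' @export
print.angle_series <- function(x, ...) {
  ok <- sum(x$status == "ok")
  cat(sprintf("Angle series: %d analysis frames (%d tracked, %d gaps) at %g fps\n",
              length(x$frame_indices), ok, length(x$frame_indices) - ok,
              x$analysis_fps))
  invisible(x)
}

#' @export
plot.angle_series <- function(x, ...) {
  graphics::plot(x$frame_indices / x$source_fps, x$headings_deg,
                 type = "p", pch = 16, cex = 0.4,
                 xlab = "time (s)", ylab = "heading (deg)",
                 ylim = c(0, 360), ...)
  invisible(x)
}
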