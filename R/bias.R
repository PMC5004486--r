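#' Wrap-aware heading steps from an angle series
#'
#' Computes the signed difference between rotation angles of subsequent
#' analysis frames, mapped to `(-180, 180]`. Positive differences are left
#' (counterclockwise) turns under the package's sign convention. Pairs of
#' valid frames separated by a tracking gap are emitted with
#' `direction = "none"` and `kept = FALSE` so that step counts stay conserved.
#'
#' @param series An [angle_series()] with at least two valid entries.
#'
#' @return A data frame of class `angle_steps` with columns `from_frame`,
#'   `to_frame`, `delta_deg`, `magnitude_deg`, `direction`
#'   (`"left"`/`"right"`/`"none"`), `gap`, and `kept` (`NA` until
#'   [filter_steps()] is applied).
#' @examples
#' s <- angle_series(c(0, 6, 12), c(350, 10, 30))
#' angle_steps(s)$delta_deg  # +20, +20 (wraparound handled)
#' @export
angle_steps <- function(series) {
  if (!inherits(series, "angle_series"))
    rg_error("series must be an angle_series", "rg_parameter")
  valid <- series$status == "ok" & !is.na(series$headings_deg)
  if (sum(valid) < 2)
    rg_error("fewer than 2 valid heading entries", "rg_insufficient_data")

  vi <- which(valid)
  from <- vi[-length(vi)]
  to <- vi[-1]
  gap <- (to - from) > 1L
  delta <- wrap_diff(series$headings_deg[from], series$headings_deg[to])
  delta[gap] <- NA_real_
  mag <- abs(delta)
  direction <- ifelse(gap, "none",
                      ifelse(delta > 0, "left",
                             ifelse(delta < 0, "right", "none")))
  out <- data.frame(from_frame = series$frame_indices[from],
                    to_frame = series$frame_indices[to],
                    delta_deg = delta, magnitude_deg = mag,
                    direction = direction, gap = gap,
                    kept = NA, stringsAsFactors = FALSE)
  class(out) <- c("angle_steps", "data.frame")
  out
}

#' Filter heading steps to the plausible-turn band
#'
#' Keeps steps whose magnitude lies within `[step_lo_deg, step_hi_deg]`
#' (inclusive at both bounds). Sub-threshold magnitudes are treated as
#' tracking noise, super-threshold ones as head-tail reversal artifacts, and
#' zero-magnitude steps (baseline crossings) are always dropped; steps
#' spanning tracking gaps are never kept.
#'
#' @param steps An [angle_steps()] data frame.
#' @param step_lo_deg,step_hi_deg Inclusive magnitude bounds in degrees,
#'   defaults 4 and 120.
#'
#' @return The same data frame with `kept` filled in and the bounds stored in
#'   attributes `step_lo_deg` / `step_hi_deg`.
#' @export
filter_steps <- function(steps, step_lo_deg = 4, step_hi_deg = 120) {
  if (!(step_lo_deg > 0 && step_lo_deg < step_hi_deg && step_hi_deg <= 180))
    rg_error("need 0 < step_lo_deg < step_hi_deg <= 180", "rg_parameter")
  mag <- steps$magnitude_deg
  steps$kept <- !steps$gap & !is.na(mag) & mag > 0 &
    mag >= step_lo_deg & mag <= step_hi_deg
  attr(steps, "step_lo_deg") <- step_lo_deg
  attr(steps, "step_hi_deg") <- step_hi_deg
  steps
}

step_counts <- function(steps) {
  lo <- attr(steps, "step_lo_deg")
  hi <- attr(steps, "step_hi_deg")
  mag <- steps$magnitude_deg
  real <- !steps$gap & !is.na(mag)
  list(
    n_left = sum(steps$kept & steps$direction == "left"),
    n_right = sum(steps$kept & steps$direction == "right"),
    n_dropped_low = sum(real & mag > 0 & mag < lo),
    n_dropped_high = sum(real & mag > hi),
    n_dropped_gap = sum(steps$gap),
    n_zero = sum(real & mag == 0),
    n_total = nrow(steps)
  )
}

#' Rotational bias of a session
#'
#' The bias is the relative amount of left turns over all turns,
#' `n_left / (n_left + n_right)`, counting only steps kept by
#' [filter_steps()]. A degree-weighted variant (summed left magnitude over
#' summed kept magnitude) is reported alongside for reference; the count
#' ratio is the primary statistic.
#'
#' @param steps A filtered [angle_steps()] data frame (`kept` set).
#' @param session_id Label attached to the result.
#'
#' @return An object of class `bias_result`: list with `n_left`, `n_right`,
#'   `bias`, `bias_degree_weighted`, the drop counters
#'   (`n_dropped_low`, `n_dropped_high`, `n_dropped_gap`, `n_zero`),
#'   `n_total`, `session_id` and the sign `convention`.
#' @export
rotational_bias <- function(steps, session_id = "session") {
  if (all(is.na(steps$kept)))
    steps <- filter_steps(steps)
  cnt <- step_counts(steps)
  if (cnt$n_left + cnt$n_right == 0)
    rg_error("no turns survive the magnitude filter", "rg_no_turns")
  kept <- steps[which(steps$kept), , drop = FALSE]
  left_deg <- sum(kept$magnitude_deg[kept$direction == "left"])
  structure(
    c(cnt,
      list(bias = cnt$n_left / (cnt$n_left + cnt$n_right),
           bias_degree_weighted = left_deg / sum(kept$magnitude_deg),
           step_lo_deg = attr(steps, "step_lo_deg"),
           step_hi_deg = attr(steps, "step_hi_deg"),
           session_id = session_id,
           convention = "left = counterclockwise in arena coordinates (y up)")),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("Rotational bias [%s]: %.4f (%d left / %d turns)\n",
              x$session_id, x$bias, x$n_left, x$n_left + x$n_right))
  cat(sprintf("  dropped: %d below %g deg, %d above %g deg, %d gaps, %d zero\n",
              x$n_dropped_low, x$step_lo_deg, x$n_dropped_high, x$step_hi_deg,
              x$n_dropped_gap, x$n_zero))
  invisible(x)
}

#' Change of rotational bias from baseline
#'
#' The modulus of the difference between a post-treatment session's bias and
#' the same animal's baseline bias.
#'
#' @param post_bias,baseline_bias Values in `[0, 1]` or [rotational_bias()]
#'   results.
#' @return An object of class `delta_rotation`: list with `baseline_bias`,
#'   `post_bias`, and `delta = |post - baseline|`.
#' @examples
#' delta_rotation(0.75, 0.50)$delta  # 0.25
#' @export
delta_rotation <- function(post_bias, baseline_bias) {
  pb <- if (inherits(post_bias, "bias_result")) post_bias$bias else post_bias
  bb <- if (inherits(baseline_bias, "bias_result")) baseline_bias$bias else baseline_bias
  if (!is_prob(pb) || !is_prob(bb))
    rg_error("biases must be single values in [0, 1]", "rg_parameter")
  structure(list(baseline_bias = bb, post_bias = pb, delta = abs(pb - bb)),
            class = "delta_rotation")
}

#' @export
print.delta_rotation <- function(x, ...) {
  cat(sprintf("Delta rotation: |%.4f - %.4f| = %.4f\n",
              x$post_bias, x$baseline_bias, x$delta))
  invisible(x)
}

#' Per-session bias summary
#'
#' Chains [angle_steps()], [filter_steps()] and [rotational_bias()] for one
#' session and returns the bias result together with a one-row report table.
#'
#' @param x An [angle_series()], or the path of a pose CSV written by
#'   [write_pose_csv()].
#' @param step_lo_deg,step_hi_deg Magnitude-filter bounds.
#' @param session_id Session label for the report row.
#'
#' @return A list with `bias` (a `bias_result`) and `report` (one-row data
#'   frame with counts, bias, drop statistics and the sign convention).
#' @export
session_summary <- function(x, step_lo_deg = 4, step_hi_deg = 120,
                            session_id = "session") {
  series <- if (inherits(x, "angle_series")) x else read_pose_csv(x)
  steps <- filter_steps(angle_steps(series), step_lo_deg, step_hi_deg)
  b <- rotational_bias(steps, session_id = session_id)
  report <- data.frame(
    session_id = session_id, n_left = b$n_left, n_right = b$n_right,
    bias = b$bias, bias_degree_weighted = b$bias_degree_weighted,
    n_dropped_low = b$n_dropped_low, n_dropped_high = b$n_dropped_high,
    n_dropped_gap = b$n_dropped_gap, n_zero = b$n_zero,
    n_total = b$n_total, step_lo_deg = step_lo_deg,
    step_hi_deg = step_hi_deg, convention = b$convention,
    stringsAsFactors = FALSE
  )
  list(bias = b, report = report)
}
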