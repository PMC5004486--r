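#' Simulate a turning trajectory with a programmed left-turn fraction
#'
#' Generates a heading-angle time series at the analysis frame rate by drawing
#' independent turn steps: each step goes left (counterclockwise, positive
#' heading change) with probability `p_left` and has a magnitude drawn
#' uniformly from `[step_lo_deg, step_hi_deg]`. The realized left fraction is
#' recorded as ground truth so that downstream bias estimators can be tested
#' by parameter recovery.
#'
#' @param n_steps Number of turn steps (the trajectory has `n_steps + 1`
#'   headings).
#' @param p_left Probability in `[0, 1]` that a step is a left turn.
#' @param step_lo_deg,step_hi_deg Step-magnitude bounds in degrees;
#'   `0 < step_lo_deg <= step_hi_deg < 180`.
#' @param heading0_deg Initial heading in degrees (wrapped into `[0, 360)`).
#' @param seed Integer seed; the trajectory is reproducible given the seed.
#'
#' @return An object of class `turn_trajectory`: a list with `headings_deg`
#'   (length `n_steps + 1`, all in `[0, 360)`), `step_signs` (character,
#'   `"left"`/`"right"`), `step_magnitudes_deg`, the programmed `p_left`, the
#'   realized `left_fraction` (`#left / n_steps`), and `seed`.
#' @examples
#' tr <- simulate_turn_trajectory(50, p_left = 0.8, seed = 1)
#' tr$left_fraction
#' @export
simulate_turn_trajectory <- function(n_steps, p_left,
                                     step_lo_deg = 10, step_hi_deg = 60,
                                     heading0_deg = 0, seed = 1L) {
  if (!is_count(n_steps))
    rg_error("n_steps must be a positive integer", "rg_parameter")
  if (!is_prob(p_left))
    rg_error("p_left must be a probability in [0, 1]", "rg_parameter")
  if (!(step_lo_deg > 0 && step_lo_deg <= step_hi_deg && step_hi_deg < 180))
    rg_error("need 0 < step_lo_deg <= step_hi_deg < 180", "rg_parameter")

  res <- with_rg_seed(seed, {
    signs <- ifelse(stats::runif(n_steps) < p_left, "left", "right")
    mags <- stats::runif(n_steps, step_lo_deg, step_hi_deg)
    list(signs = signs, mags = mags)
  })
  deltas <- ifelse(res$signs == "left", res$mags, -res$mags)
  headings <- wrap_360(heading0_deg + cumsum(c(0, deltas)))

  structure(
    list(
      headings_deg = headings,
      step_signs = res$signs,
      step_magnitudes_deg = res$mags,
      p_left = p_left,
      left_fraction = mean(res$signs == "left"),
      step_lo_deg = step_lo_deg,
      step_hi_deg = step_hi_deg,
      seed = as.integer(seed)
    ),
    class = "turn_trajectory"
  )
}

#' @export
print.turn_trajectory <- function(x, ...) {
  cat("Turn trajectory:", length(x$step_signs), "steps,",
      sprintf("programmed p_left = %.3f, realized left fraction = %.3f\n",
              x$p_left, x$left_fraction))
  cat(sprintf("  step magnitudes in [%.1f, %.1f] deg, seed %d\n",
              x$step_lo_deg, x$step_hi_deg, x$seed))
  invisible(x)
}
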