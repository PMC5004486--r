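## Internal helpers: classed errors, angle arithmetic, seeded evaluation.

rg_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rg_error"), call = call))
}

rg_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "rg_warning")))
}

#' @importFrom withr with_seed
with_rg_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## Map any angle (degrees) into [0, 360).
wrap_360 <- function(deg) {
  out <- deg %% 360
  out[out == 360] <- 0
  out
}

## Signed wrap-aware difference to - from, mapped to (-180, 180].
wrap_diff <- function(from_deg, to_deg) {
  d <- (to_deg - from_deg) %% 360
  ifelse(d > 180, d - 360, d)
}

is_prob <- function(p) is.numeric(p) && length(p) == 1L && !is.na(p) && p >= 0 && p <= 1

is_count <- function(n) is.numeric(n) && length(n) == 1L && !is.na(n) && n >= 1 && n == floor(n)
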