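#' Exact and approximate Mann-Whitney U test
#'
#' Rank-sum test for two independent samples. For small problems
#' (`n_x * n_y <= exact_cap`) the p value is exact: the null distribution of
#' the U statistic is computed over all equally likely assignments of the
#' pooled mid-ranks to the two groups (a counting recursion that enumerates
#' the full arrangement distribution, so ties are handled exactly). Larger
#' problems use the normal approximation with tie correction and a 0.5
#' continuity correction. Two-sided p is `min(1, 2 * min(tail p))`.
#'
#' @param x,y Numeric vectors (non-empty, finite).
#' @param alternative `"two_sided"`, `"less"` (x tends smaller) or
#'   `"greater"`.
#' @param exact_cap Largest `n_x * n_y` for which the exact distribution is
#'   used (default 400).
#'
#' @return An object of class `rg_test` with fields `statistic` (U for x),
#'   `p_value`, `method`, `alternative`, `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value          # 1/3, exact
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$p_value # 0.1, exact
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "less", "greater"),
                           exact_cap = 400) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0 || !all(is.finite(c(x, y))))
    rg_error("both groups must be non-empty with finite values", "rg_parameter")
  nx <- length(x); ny <- length(y); n <- nx + ny

  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  if (length(unique(pooled)) == 1L) {
    rg_warn("all values tied across both groups; p set to 1", "rg_degenerate_data")
    return(rg_test(u, 1, "mann_whitney_exact", alternative, nx, ny))
  }

  if (nx * ny <= exact_cap) {
    dist <- ranksum_distribution(r, nx)    # counts over 2x-scaled rank sums
    obs <- round(2 * sum(r[seq_len(nx)]))
    total <- sum(dist$count)
    p_le <- sum(dist$count[dist$sum2 <= obs]) / total
    p_ge <- sum(dist$count[dist$sum2 >= obs]) / total
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two_sided = min(1, 2 * min(p_le, p_ge)))
    return(rg_test(u, p, "mann_whitney_exact", alternative, nx, ny))
  }

  mu <- nx * ny / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
  z_le <- (u - mu + 0.5) / sigma
  z_ge <- (u - mu - 0.5) / sigma
  p_le <- stats::pnorm(z_le)
  p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
  p <- switch(alternative,
              less = p_le, greater = p_ge,
              two_sided = min(1, 2 * min(p_le, p_ge)))
  rg_test(u, p, "mann_whitney_normal", alternative, nx, ny)
}

## Exact null distribution of the x-group rank sum: counts of nx-subsets of
## the pooled mid-ranks by subset sum. Mid-ranks are half-integers, so sums
## are tracked at twice their value to stay integral. Counts can exceed
## 2^31 but stay exact in doubles (< 2^53 for any n <= 40).
ranksum_distribution <- function(ranks, nx) {
  r2 <- round(2 * ranks)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  ## counts[k + 1, s + 1] = number of k-subsets with 2x-sum s
  counts <- matrix(0, nrow = nx + 1, ncol = smax + 1)
  counts[1, 1] <- 1
  for (v in r2) {
    kmax <- nx
    for (k in kmax:1) {
      nz <- which(counts[k, ] > 0)
      nz <- nz[nz - 1 + v <= smax]
      if (length(nz))
        counts[k + 1, nz + v] <- counts[k + 1, nz + v] + counts[k, nz]
    }
  }
  sums <- which(counts[nx + 1, ] > 0) - 1L
  list(sum2 = sums, count = counts[nx + 1, sums + 1])
}

rg_test <- function(statistic, p_value, method, alternative, n_x, n_y = NA_integer_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, alternative = alternative,
                 n_x = n_x, n_y = n_y),
            class = "rg_test")
}

#' @export
print.rg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s; n = %s)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              if (is.na(x$n_y)) x$n_x else paste(x$n_x, x$n_y, sep = ", ")))
  invisible(x)
}

#' One-sample t test against a theoretical mean
#'
#' `t = (mean(x) - mu0) / (sd(x) / sqrt(n))`, two-sided p from the t
#' distribution with `n - 1` degrees of freedom. Used e.g. to test task
#' performance against the 50% chance level.
#'
#' @param x Numeric vector, `n >= 2`, nonzero variance.
#' @param mu0 Theoretical mean.
#' @return An `rg_test` (method `"one_sample_t"`).
#' @export
one_sample_t <- function(x, mu0) {
  x <- as.numeric(x)
  if (length(x) < 2 || !all(is.finite(x)))
    rg_error("need at least 2 finite values", "rg_parameter")
  s <- stats::sd(x)
  if (s == 0)
    rg_error("zero sample variance", "rg_degenerate_data")
  n <- length(x)
  t <- (mean(x) - mu0) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  rg_test(t, p, "one_sample_t", "two_sided", n)
}

#' Paired t test
#'
#' One-sample t test of the paired differences (`post - pre`) against zero.
#'
#' @param pre_values,post_values Numeric vectors of equal length, matched by
#'   position (same animal order).
#' @return An `rg_test` (method `"paired_t"`).
#' @export
paired_t <- function(pre_values, post_values) {
  if (length(pre_values) != length(post_values))
    rg_error("pre and post vectors have different lengths", "rg_pairing")
  d <- as.numeric(post_values) - as.numeric(pre_values)
  out <- one_sample_t(d, 0)
  out$method <- "paired_t"
  out
}

#' Olfactory-discrimination learning criterion
#'
#' Returns the 1-based index of the first day completing a run of at least
#' `consecutive_days` days with at least `threshold` correct trials out of
#' `trials_per_day`, or `NA` if the criterion is never reached.
#'
#' @param daily_correct Integer vector of correct-trial counts per day.
#' @param threshold Minimum correct trials per qualifying day (default 7).
#' @param consecutive_days Required run length (default 2).
#' @param trials_per_day Trials per day (default 8); counts must not exceed
#'   it.
#' @return Integer day index or `NA_integer_`.
#' @examples
#' discrimination_criterion(c(5, 6, 7, 7))  # 4
#' discrimination_criterion(c(8, 6, 8, 6))  # NA
#' @export
discrimination_criterion <- function(daily_correct, threshold = 7,
                                     consecutive_days = 2,
                                     trials_per_day = 8) {
  dc <- as.integer(daily_correct)
  if (any(is.na(dc)) || any(dc < 0) || any(dc > trials_per_day))
    rg_error("daily counts must lie in [0, trials_per_day]", "rg_parameter")
  run <- 0L
  for (i in seq_along(dc)) {
    run <- if (dc[i] >= threshold) run + 1L else 0L
    if (run >= consecutive_days) return(i)
  }
  NA_integer_
}
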