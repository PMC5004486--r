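#' Specification for a synthetic local field potential
#'
#' Parameters of the LFP simulator: 1/f^alpha ("pink") background noise of
#' unit variance plus a narrowband gamma component centered at
#' `gamma_freq_hz`, plus an optional slow (theta-range) sinusoid. The gamma
#' component is by default band-limited Gaussian noise (a Gaussian spectral
#' envelope around the center frequency), which gives the spectrum a peak of
#' realistic, finite width; a pure-sinusoid mode is available for exact-bin
#' spectral tests.
#'
#' @param duration_s Recording duration in seconds.
#' @param fs_hz Sampling rate in Hz (acquisition-scale recordings use 25 kHz;
#'   1 kHz is ample for gamma-band analysis).
#' @param gamma_freq_hz Gamma center frequency, within 50-90 Hz.
#' @param gamma_bandwidth_hz Spectral full width of the gamma component
#'   (Gaussian envelope sigma = bandwidth / 2). Must be positive and smaller
#'   than `gamma_freq_hz`.
#' @param gamma_snr Ratio of gamma-component power to background power within
#'   the 50-90 Hz detection band; `0` adds no gamma component.
#' @param pink_alpha Exponent of the 1/f^alpha background.
#' @param theta_freq_hz Optional slow-rhythm frequency (`NULL` for none).
#' @param theta_amp Amplitude of the slow sinusoid (signal units).
#' @param gamma_waveform `"bandpass"` (default) or `"sine"`.
#' @param seed Integer seed.
#'
#' @return An object of class `lfp_sim_spec`.
#' @export
lfp_sim_spec <- function(duration_s = 120, fs_hz = 25000,
                         gamma_freq_hz = 70, gamma_bandwidth_hz = 0.5,
                         gamma_snr = 4, pink_alpha = 1,
                         theta_freq_hz = NULL, theta_amp = 1,
                         gamma_waveform = c("bandpass", "sine"),
                         seed = 1L) {
  gamma_waveform <- match.arg(gamma_waveform)
  if (!(gamma_bandwidth_hz > 0 && gamma_bandwidth_hz < gamma_freq_hz))
    rg_error("need 0 < gamma_bandwidth_hz < gamma_freq_hz", "rg_parameter")
  if (!(fs_hz > 2 * (gamma_freq_hz + gamma_bandwidth_hz)))
    rg_error("sampling rate violates the Nyquist condition for the gamma component",
             "rg_parameter")
  if (gamma_snr < 0)
    rg_error("gamma_snr must be >= 0", "rg_parameter")
  if (duration_s <= 0)
    rg_error("duration_s must be positive", "rg_parameter")
  structure(
    list(duration_s = duration_s, fs_hz = fs_hz,
         gamma_freq_hz = gamma_freq_hz,
         gamma_bandwidth_hz = gamma_bandwidth_hz, gamma_snr = gamma_snr,
         pink_alpha = pink_alpha, theta_freq_hz = theta_freq_hz,
         theta_amp = theta_amp, gamma_waveform = gamma_waveform,
         seed = as.integer(seed)),
    class = "lfp_sim_spec"
  )
}

## Unit-variance 1/f^alpha noise by spectral shaping of white Gaussian noise.
pink_noise <- function(n, alpha) {
  wh <- stats::rnorm(n)
  sp <- stats::fft(wh)
  f <- c(1, seq_len(n - 1))            # avoid dividing the DC bin by zero
  f <- pmin(f, n - f + 1)              # mirror so shaping is Hermitian
  sp <- sp / f^(alpha / 2)
  sp[1] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x)
}

## Narrowband Gaussian noise: white noise shaped by a Gaussian spectral
## envelope around f0, returned with unit variance.
narrowband_noise <- function(n, fs, f0, sigma_f) {
  wh <- stats::rnorm(n)
  sp <- stats::fft(wh)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                 # two-sided (Hermitian) frequency axis
  env <- exp(-(f - f0)^2 / (2 * sigma_f^2))
  x <- Re(stats::fft(sp * env, inverse = TRUE)) / n
  x / stats::sd(x)
}

## Power of `x` within [lo, hi] Hz from its one-sided periodogram.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n^2     # two-sided power per bin, sums to mean square
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f <= hi
  mirror <- f >= fs - hi & f <= fs - lo
  sum(sp[sel | mirror])
}

#' Simulate a local field potential recording
#'
#' Generates `duration_s * fs_hz` samples of pink background noise plus a
#' gamma component whose power within the 50-90 Hz detection band equals
#' `gamma_snr` times the background power in the same band (measured on the
#' realized background), plus an optional theta sinusoid. Deterministic given
#' the spec and its seed.
#'
#' @param spec An [lfp_sim_spec()].
#' @param channel_id,side,day_label Metadata attached to the recording.
#' @param seed Optional seed overriding `spec$seed`.
#'
#' @return An object of class `lfp_recording`: list with `samples`, `fs_hz`,
#'   `channel_id`, `side`, `day_label` and the generating `spec`.
#' @examples
#' rec <- simulate_lfp(lfp_sim_spec(duration_s = 8, fs_hz = 1000,
#'                                  gamma_freq_hz = 68, seed = 2))
#' @export
simulate_lfp <- function(spec, channel_id = "ch1", side = "left",
                         day_label = 0, seed = NULL) {
  if (!inherits(spec, "lfp_sim_spec"))
    rg_error("spec must be an lfp_sim_spec", "rg_parameter")
  if (is.null(seed)) seed <- spec$seed
  n <- round(spec$duration_s * spec$fs_hz)

  samples <- with_rg_seed(seed, {
    bg <- pink_noise(n, spec$pink_alpha)
    x <- bg
    if (spec$gamma_snr > 0) {
      p_bg <- band_power(bg, spec$fs_hz, 50, 90)
      p_target <- spec$gamma_snr * p_bg
      if (spec$gamma_waveform == "sine") {
        amp <- sqrt(2 * p_target)
        t <- (seq_len(n) - 1) / spec$fs_hz
        g <- amp * sin(2 * pi * spec$gamma_freq_hz * t)
      } else {
        g <- narrowband_noise(n, spec$fs_hz, spec$gamma_freq_hz,
                              spec$gamma_bandwidth_hz / 2)
        g <- g * sqrt(p_target)        # unit variance -> target power
      }
      x <- x + g
    }
    if (!is.null(spec$theta_freq_hz)) {
      t <- (seq_len(n) - 1) / spec$fs_hz
      x <- x + spec$theta_amp * sin(2 * pi * spec$theta_freq_hz * t)
    }
    x
  })

  structure(
    list(samples = samples, fs_hz = spec$fs_hz, channel_id = channel_id,
         side = side, day_label = day_label, spec = spec,
         seed = as.integer(seed)),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("LFP recording: %d samples at %g Hz (%.1f s), channel %s, side %s, day %s\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz,
              x$channel_id, x$side, format(x$day_label)))
  invisible(x)
}

#' Simulate a day-structured gamma-frequency timecourse
#'
#' Generates one recording per (side, day): on days in `shifted_days` the
#' gamma component sits at `baseline_freq_hz - shift_hz` (a downward shift as
#' produced by enhanced network inhibition), on all other days at
#' `baseline_freq_hz`. The two sides receive independent seeds derived from
#' the master seed; `shift_hz` may be a single value or a named vector
#' `c(left = ..., right = ...)` to program side-specific response strengths.
#'
#' @param baseline_freq_hz Baseline gamma peak frequency (within 50-90 Hz).
#' @param shift_hz Downward shift on shifted days; scalar or named
#'   `c(left=, right=)`.
#' @param day_labels Numeric day labels (e.g. `c(-0.5, 0.5, 1.5, 3, 7)`).
#' @param shifted_days Subset of `day_labels` carrying the shifted frequency.
#' @param spec An [lfp_sim_spec()] providing duration, sampling rate,
#'   bandwidth, SNR and background parameters (its `gamma_freq_hz` is
#'   overridden per day).
#' @param seed Master seed.
#'
#' @return A list with `recordings` (nested: `recordings[[side]][[day]]`) and
#'   `truth`, a data frame of the programmed frequency per (side, day).
#' @export
simulate_gamma_timecourse <- function(baseline_freq_hz, shift_hz, day_labels,
                                      shifted_days, spec, seed = 1L) {
  sides <- c("left", "right")
  shifts <- if (length(shift_hz) == 1L && is.null(names(shift_hz))) {
    stats::setNames(rep(shift_hz, 2), sides)
  } else {
    if (!all(sides %in% names(shift_hz)))
      rg_error("shift_hz must be scalar or named c(left=, right=)", "rg_parameter")
    shift_hz[sides]
  }
  if (!all(shifted_days %in% day_labels))
    rg_error("shifted_days must be a subset of day_labels", "rg_parameter")
  for (s in sides) {
    f_lo <- baseline_freq_hz - shifts[[s]]
    if (baseline_freq_hz < 50 || baseline_freq_hz > 90 ||
        f_lo < 50 || f_lo > 90)
      rg_error("baseline and shifted frequencies must lie within 50-90 Hz",
               "rg_parameter")
  }

  recordings <- list()
  truth <- NULL
  for (si in seq_along(sides)) {
    s <- sides[si]
    recordings[[s]] <- list()
    for (di in seq_along(day_labels)) {
      d <- day_labels[di]
      f <- if (d %in% shifted_days) baseline_freq_hz - shifts[[s]] else baseline_freq_hz
      day_spec <- spec
      day_spec$gamma_freq_hz <- f
      sub_seed <- (as.integer(seed) * 1009L + si * 101L + di) %% 2147483647L
      recordings[[s]][[format(d)]] <-
        simulate_lfp(day_spec, channel_id = paste0(s, "_ch"), side = s,
                     day_label = d, seed = sub_seed)
      truth <- rbind(truth, data.frame(side = s, day_label = d,
                                       gamma_freq_hz = f))
    }
  }
  list(recordings = recordings, truth = truth,
       baseline_freq_hz = baseline_freq_hz, shifts = shifts,
       day_labels = day_labels, shifted_days = shifted_days,
       seed = as.integer(seed))
}
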