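#' Welch power spectral density estimate
#'
#' Averaged periodograms of Hamming-windowed, 50%-overlapping segments, with
#' density normalization: the integral of the one-sided spectrum over
#' frequency approximates the signal's mean square power. No demeaning,
#' down-sampling or other corrective routine is applied. Frequency resolution
#' is `1 / window_s`.
#'
#' @param rec An [lfp_recording][simulate_lfp] or a numeric vector (then
#'   `fs_hz` is required).
#' @param window_s Segment length in seconds (default 4).
#' @param overlap_frac Segment overlap fraction (default 0.5).
#' @param fs_hz Sampling rate, needed only when `rec` is a bare vector.
#'
#' @return An object of class `power_spectrum`: list with `freqs_hz`
#'   (ascending, spacing `1/window_s`), `power`, `detrended = FALSE`,
#'   `window_s`, `overlap_frac`, `fs_hz`, `n_segments`.
#' @export
welch_psd <- function(rec, window_s = 4, overlap_frac = 0.5, fs_hz = NULL) {
  if (inherits(rec, "lfp_recording")) {
    x <- rec$samples
    fs <- rec$fs_hz
  } else {
    x <- as.numeric(rec)
    if (is.null(fs_hz)) rg_error("fs_hz required for a bare signal", "rg_parameter")
    fs <- fs_hz
  }
  nwin <- round(window_s * fs)
  if (length(x) < nwin)
    rg_error("recording shorter than one analysis window", "rg_insufficient_data")
  if (!(overlap_frac >= 0 && overlap_frac < 1))
    rg_error("overlap_frac must be in [0, 1)", "rg_parameter")

  step <- max(1L, round(nwin * (1 - overlap_frac)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  k <- 0:(nwin - 1)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (nwin - 1))   # symmetric Hamming
  scale <- fs * sum(w^2)
  half <- nwin %/% 2 + 1L                           # one-sided bins, DC..Nyquist

  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)] * w
    p2 <- Mod(stats::fft(seg))^2 / scale
    p1 <- p2[seq_len(half)]
    if (nwin %% 2 == 0) {
      p1[2:(half - 1L)] <- 2 * p1[2:(half - 1L)]    # double all but DC/Nyquist
    } else {
      p1[2:half] <- 2 * p1[2:half]
    }
    acc <- acc + p1
  }

  structure(
    list(freqs_hz = (seq_len(half) - 1) * fs / nwin,
         power = acc / length(starts),
         detrended = FALSE, window_s = window_s,
         overlap_frac = overlap_frac, fs_hz = fs,
         n_segments = length(starts)),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("%s Welch spectrum: %d bins, %g-%g Hz (res %.4g Hz), %d segments\n",
              if (x$detrended) "Detrended" else "Raw",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              x$freqs_hz[2] - x$freqs_hz[1], x$n_segments))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, xlim = c(4, 200), ...) {
  graphics::plot(x$freqs_hz, x$power, type = "l", xlim = xlim,
                 xlab = "frequency (Hz)",
                 ylab = if (x$detrended) "detrended power" else "power density",
                 ...)
  invisible(x)
}

#' Remove a linear trend from a power spectrum
#'
#' Fits an ordinary least-squares line to power versus frequency over
#' `fit_band_hz` and subtracts it, flattening the 1/f background before peak
#' picking. The returned spectrum is restricted to the fit band and its
#' values may be negative. Log-domain detrending (fit and subtraction on
#' `log10` power) is available as an option.
#'
#' @param spec A raw [welch_psd()] `power_spectrum`.
#' @param fit_band_hz Two-element band over which the line is fit (default
#'   `c(4, 200)`, matching the analyzed frequency range).
#' @param log_power Fit in `log10(power)` instead of linear power.
#'
#' @return A `power_spectrum` with `detrended = TRUE`, restricted to the fit
#'   band.
#' @export
detrend_power <- function(spec, fit_band_hz = c(4, 200), log_power = FALSE) {
  if (!inherits(spec, "power_spectrum"))
    rg_error("spec must be a power_spectrum", "rg_parameter")
  if (isTRUE(spec$detrended))
    rg_error("spectrum is already detrended", "rg_parameter")
  sel <- spec$freqs_hz >= fit_band_hz[1] & spec$freqs_hz <= fit_band_hz[2]
  if (sum(sel) < 3)
    rg_error("fewer than 3 frequency bins in the fit band", "rg_insufficient_data")
  f <- spec$freqs_hz[sel]
  p <- spec$power[sel]
  if (log_power) p <- log10(pmax(p, .Machine$double.xmin))
  fit <- stats::lm.fit(cbind(1, f), p)
  out <- spec
  out$freqs_hz <- f
  out$power <- unname(fit$residuals)
  out$detrended <- TRUE
  out$fit_band_hz <- fit_band_hz
  out
}

#' Gamma peak of a detrended spectrum
#'
#' The gamma peak frequency is the frequency of the maximum detrended power
#' within the detection band (default 50-90 Hz, inclusive). Ties break toward
#' the lower frequency. When the band is essentially flat (max minus median
#' below `flat_eps`) the peak is not interpretable and `flat_flag` is set.
#'
#' @param spec A detrended `power_spectrum` (see [detrend_power()]).
#' @param band_hz Detection band, default `c(50, 90)`.
#' @param flat_eps Flatness floor on `max - median` of in-band power.
#'
#' @return An object of class `gamma_peak`: list with `peak_freq_hz`,
#'   `peak_power`, `flat_flag`, `band_hz`, and `relative_freq` (`NA` until
#'   normalized by [relative_gamma()]).
#' @export
gamma_peak <- function(spec, band_hz = c(50, 90),
                       flat_eps = sqrt(.Machine$double.eps)) {
  if (!inherits(spec, "power_spectrum") || !isTRUE(spec$detrended))
    rg_error("spec must be a detrended power_spectrum", "rg_parameter")
  sel <- which(spec$freqs_hz >= band_hz[1] & spec$freqs_hz <= band_hz[2])
  if (length(sel) == 0)
    rg_error("detection band contains no frequency bins", "rg_parameter")
  p <- spec$power[sel]
  i <- which.max(p)                     # first maximum = lowest-frequency tie
  structure(
    list(peak_freq_hz = spec$freqs_hz[sel[i]],
         peak_power = p[i],
         flat_flag = (max(p) - stats::median(p)) < flat_eps,
         band_hz = band_hz,
         relative_freq = NA_real_),
    class = "gamma_peak"
  )
}

#' @export
print.gamma_peak <- function(x, ...) {
  cat(sprintf("Gamma peak: %.4g Hz (band %g-%g Hz)%s\n",
              x$peak_freq_hz, x$band_hz[1], x$band_hz[2],
              if (x$flat_flag) " [flat band]" else ""))
  invisible(x)
}

#' Average the two channels of a stereotrode
#'
#' Bin-wise arithmetic mean of two power spectra on identical frequency
#' grids. Averaging spectra (rather than raw signals) is phase-insensitive
#' and robust to inter-electrode lags; to average in the time domain instead,
#' mean the raw samples before [welch_psd()].
#'
#' @param spec_a,spec_b `power_spectrum` objects with identical grids and
#'   detrended status.
#' @return A `power_spectrum` of the same shape.
#' @export
average_stereotrode <- function(spec_a, spec_b) {
  if (!isTRUE(all.equal(spec_a$freqs_hz, spec_b$freqs_hz)) ||
      !identical(spec_a$detrended, spec_b$detrended))
    rg_error("spectra have mismatched frequency grids or detrended status",
             "rg_grid_mismatch")
  out <- spec_a
  out$power <- (spec_a$power + spec_b$power) / 2
  out
}

#' Normalize gamma peak frequencies to a baseline day
#'
#' Divides each day's gamma peak frequency by the same side's baseline-day
#' value; the baseline maps to exactly 1.
#'
#' @param peaks_by_day Named numeric vector (names are day labels) of peak
#'   frequencies in Hz.
#' @param baseline_day Day label of the baseline session.
#' @return Named numeric vector of relative peak frequencies.
#' @examples
#' relative_gamma(c(`-0.5` = 72, `0.5` = 66), "-0.5")
#' @export
relative_gamma <- function(peaks_by_day, baseline_day) {
  key <- format(baseline_day)
  peaks <- unlist(peaks_by_day)
  if (!(key %in% names(peaks)) || !is.finite(peaks[[key]]) || peaks[[key]] == 0)
    rg_error("baseline day missing or has no usable peak", "rg_missing_baseline")
  peaks / peaks[[key]]
}

#' Sort bulb sides into weak and strong responders
#'
#' Within each animal, the side with the larger downward gamma-peak shift
#' (baseline frequency minus the frequency on `sort_day`) is labelled
#' `"strong"`, the other `"weak"`. Ties go to the left side by default. The
#' same rule is applied to every cohort, treated or control.
#'
#' @param peaks Data frame with columns `animal`, `side` (`"left"`/`"right"`),
#'   `day_label`, `peak_freq_hz`.
#' @param baseline_day,sort_day Day labels of the baseline session and the
#'   sorting session (default `0.5` days after injection).
#' @param tie_strong Side labelled strong on an exact tie.
#' @param incomplete `"exclude"` (drop animals lacking a usable pair of
#'   sides, with a warning) or a group name to assign lone sides to.
#'
#' @return Data frame with columns `animal`, `side`, `shift_hz`
#'   (baseline minus sort-day peak; positive = downward shift) and
#'   `sort_group` (`"weak"`/`"strong"`).
#' @export
sort_responses <- function(peaks, baseline_day, sort_day = 0.5,
                           tie_strong = "left", incomplete = "exclude") {
  need <- c("animal", "side", "day_label", "peak_freq_hz")
  if (!all(need %in% names(peaks)))
    rg_error("peaks must have columns animal, side, day_label, peak_freq_hz",
             "rg_parameter")
  out <- NULL
  for (a in unique(peaks$animal)) {
    pa <- peaks[peaks$animal == a, ]
    shifts <- sapply(c("left", "right"), function(s) {
      base <- pa$peak_freq_hz[pa$side == s & pa$day_label == baseline_day]
      post <- pa$peak_freq_hz[pa$side == s & pa$day_label == sort_day]
      if (length(base) == 1 && length(post) == 1) base - post else NA_real_
    })
    usable <- names(shifts)[is.finite(shifts)]
    if (length(usable) < 2) {
      if (identical(incomplete, "exclude")) {
        if (length(usable) == 1)
          rg_warn(sprintf("animal %s has only one usable side; excluded", a),
                  "rg_incomplete_animal")
        next
      }
      if (length(usable) == 1)
        out <- rbind(out, data.frame(animal = a, side = usable,
                                     shift_hz = shifts[[usable]],
                                     sort_group = incomplete))
      next
    }
    strong <- if (shifts[["left"]] > shifts[["right"]]) "left"
              else if (shifts[["right"]] > shifts[["left"]]) "right"
              else tie_strong
    for (s in c("left", "right")) {
      out <- rbind(out, data.frame(
        animal = a, side = s, shift_hz = shifts[[s]],
        sort_group = if (s == strong) "strong" else "weak"))
    }
  }
  if (is.null(out))
    rg_error("no animal had a usable pair of sides", "rg_insufficient_data")
  rownames(out) <- NULL
  out
}

#' End-to-end gamma peak for one recording
#'
#' Convenience chain: [welch_psd()] then [detrend_power()] then
#' [gamma_peak()].
#'
#' @param rec An `lfp_recording` or numeric vector.
#' @param window_s,overlap_frac Welch parameters.
#' @param fit_band_hz Detrend band.
#' @param band_hz Gamma detection band.
#' @param fs_hz Sampling rate for bare vectors.
#' @return A `gamma_peak`.
#' @export
recording_gamma_peak <- function(rec, window_s = 4, overlap_frac = 0.5,
                                 fit_band_hz = c(4, 200), band_hz = c(50, 90),
                                 fs_hz = NULL) {
  spec <- welch_psd(rec, window_s = window_s, overlap_frac = overlap_frac,
                    fs_hz = fs_hz)
  gamma_peak(detrend_power(spec, fit_band_hz), band_hz)
}
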