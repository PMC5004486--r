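test_that("Welch spectra satisfy Parseval and spectral identities", {
  fs <- 1000
  t <- (0:(120 * fs - 1)) / fs
  df <- 1 / 4                                    # bin width at 4 s windows

  # unit sinusoid at a bin center: integral ~ 1/2, argmax at 60 Hz
  s <- sin(2 * pi * 60 * t)
  ws <- welch_psd(s, fs_hz = fs)
  expect_equal(ws$freqs_hz[2] - ws$freqs_hz[1], df)
  expect_lt(abs(sum(ws$power) * df - 0.5) / 0.5, 0.05)
  expect_equal(ws$freqs_hz[which.max(ws$power)], 60)
  # agrees with the direct-FFT periodogram oracle on the same realization
  pg <- fft_periodogram(s, fs)
  expect_equal(pg$freqs_hz[which.max(pg$power)], 60)

  # white noise: integral within 10% of the sample variance
  x <- withr::with_seed(8, rnorm(60 * fs))
  wx <- welch_psd(x, fs_hz = fs)
  expect_lt(abs(sum(wx$power) * df - mean(x^2)) / mean(x^2), 0.1)

  # DC signal: power concentrates at the 0 Hz bin (the Hamming window
  # spreads it over its mainlobe; beyond that only -40 dB sidelobes remain)
  wd <- welch_psd(rep(2, 8 * fs), fs_hz = fs)
  expect_equal(wd$freqs_hz[which.max(wd$power)], 0)
  beyond <- wd$freqs_hz > 2 * df
  expect_lt(sum(wd$power[beyond]) / sum(wd$power), 1e-3)

  expect_error(welch_psd(rnorm(100), fs_hz = fs),
               class = "rg_insufficient_data")
})

test_that("linear spectral detrending flattens trends and preserves bumps", {
  freqs <- seq(0, 250, by = 0.25)
  mk <- function(p) structure(
    list(freqs_hz = freqs, power = p, detrended = FALSE, window_s = 4,
         overlap_frac = 0.5, fs_hz = 1000, n_segments = 1),
    class = "power_spectrum")

  # exactly linear power: residuals vanish
  d1 <- detrend_power(mk(5 - 0.01 * freqs))
  expect_lt(max(abs(d1$power)), 1e-9)
  expect_true(all(d1$freqs_hz >= 4 & d1$freqs_hz <= 200))

  # constant power: slope-zero line, residuals vanish
  d2 <- detrend_power(mk(rep(3, length(freqs))))
  expect_lt(max(abs(d2$power)), 1e-9)

  # linear trend plus a single bump at 68 Hz: residual maximum at 68
  p <- 5 - 0.01 * freqs
  p[freqs == 68] <- p[freqs == 68] + 2
  d3 <- detrend_power(mk(p))
  expect_equal(d3$freqs_hz[which.max(d3$power)], 68)
  # residual slope and mean are zero within tolerance
  expect_lt(abs(mean(d3$power)), 1e-9)
  expect_lt(abs(coef(lm(d3$power ~ d3$freqs_hz))[2]), 1e-9)

  expect_error(detrend_power(d3), class = "rg_parameter")
  expect_error(detrend_power(mk(freqs), fit_band_hz = c(4, 4.2)),
               class = "rg_insufficient_data")
})

test_that("gamma peak is the band-restricted argmax with stated tie-breaks", {
  freqs <- seq(4, 200, by = 0.25)
  mk <- function(p) structure(
    list(freqs_hz = freqs, power = p, detrended = TRUE, window_s = 4,
         overlap_frac = 0.5, fs_hz = 1000, n_segments = 1),
    class = "power_spectrum")

  p <- rep(0, length(freqs))
  p[freqs == 68] <- 1
  expect_equal(gamma_peak(mk(p))$peak_freq_hz, 68)

  # out-of-band maxima are ignored
  p2 <- rep(0, length(freqs))
  p2[freqs == 30] <- 5
  p2[freqs == 75] <- 1
  expect_equal(gamma_peak(mk(p2))$peak_freq_hz, 75)

  # flat band: lower edge with the flat flag
  g <- gamma_peak(mk(rep(1, length(freqs))))
  expect_equal(g$peak_freq_hz, 50)
  expect_true(g$flat_flag)

  # band guarantee holds whatever lies outside
  p3 <- withr::with_seed(4, rnorm(length(freqs), sd = 10))
  g3 <- gamma_peak(mk(p3))
  expect_gte(g3$peak_freq_hz, 50)
  expect_lte(g3$peak_freq_hz, 90)

  expect_error(gamma_peak(mk(p), band_hz = c(300, 400)),
               class = "rg_parameter")
})

test_that("stereotrode averaging is bin-wise, idempotent, linear", {
  spec <- lfp_sim_spec(duration_s = 20, fs_hz = 500, gamma_freq_hz = 70,
                       seed = 5)
  w <- welch_psd(simulate_lfp(spec))
  expect_equal(average_stereotrode(w, w), w)

  z <- w; z$power <- rep(0, length(w$power))
  half <- average_stereotrode(w, z)
  expect_equal(half$power, w$power / 2)

  short <- w; short$freqs_hz <- w$freqs_hz[-1]; short$power <- w$power[-1]
  expect_error(average_stereotrode(w, short), class = "rg_grid_mismatch")
})

test_that("relative gamma normalizes to the baseline day", {
  r <- relative_gamma(c(`-0.5` = 72, `0.5` = 66), "-0.5")
  expect_identical(unname(r[["-0.5"]]), 1)
  expect_equal(unname(r[["0.5"]]), 66 / 72)

  expect_equal(unname(relative_gamma(c(`-0.5` = 70, `3` = 70), -0.5)[["3"]]), 1)
  # single baseline-only series normalizes to itself
  expect_identical(unname(relative_gamma(c(`-0.5` = 64), -0.5)[["-0.5"]]), 1)
  expect_error(relative_gamma(c(`0.5` = 66), -0.5),
               class = "rg_missing_baseline")

  # invariant to a common rescaling of all raw frequencies
  pk <- c(`-0.5` = 72, `0.5` = 66, `7` = 71)
  expect_equal(relative_gamma(pk * 1.37, -0.5), relative_gamma(pk, -0.5))
})

test_that("weak/strong sorting follows the larger-downshift rule", {
  pk <- data.frame(
    animal = rep(c("m1", "m2"), each = 4),
    side = rep(rep(c("left", "right"), each = 2), 2),
    day_label = rep(c(-0.5, 0.5), 4),
    peak_freq_hz = c(72, 66, 72, 71,    # m1: left shift 6, right shift 1
                     70, 70, 70, 65))   # m2: left shift 0, right shift 5
  out <- sort_responses(pk, baseline_day = -0.5, sort_day = 0.5)
  expect_identical(out$sort_group[out$animal == "m1" & out$side == "left"],
                   "strong")
  expect_identical(out$sort_group[out$animal == "m2" & out$side == "right"],
                   "strong")

  # exact tie goes to the left side
  tie <- pk[pk$animal == "m1", ]
  tie$peak_freq_hz <- c(72, 69, 72, 69)
  expect_identical(
    sort_responses(tie, -0.5)$sort_group,
    c("strong", "weak"))

  # an animal with one usable side is excluded with a warning
  lone <- pk[1:2, ]
  lone <- rbind(lone, pk[5:8, ])
  expect_warning(out2 <- sort_responses(lone, -0.5),
                 class = "rg_incomplete_animal")
  expect_false("m1" %in% out2$animal)
})

test_that("gamma peaks are recovered end-to-end from simulated recordings", {
  hits <- 0
  for (seed in 1:12) {
    spec <- lfp_sim_spec(duration_s = 120, fs_hz = 1000, gamma_freq_hz = 68,
                         gamma_snr = 4, seed = seed)
    pk <- recording_gamma_peak(simulate_lfp(spec))
    if (abs(pk$peak_freq_hz - 68) <= 0.25 + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 11)  # one miss allowed in 12, matching a 95% floor
})
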