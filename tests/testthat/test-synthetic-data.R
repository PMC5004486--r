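test_that("turn trajectories honor programmed probabilities and bounds", {
  # degenerate probability: every step left
  tr1 <- simulate_turn_trajectory(25, p_left = 1, seed = 4)
  expect_true(all(tr1$step_signs == "left"))
  expect_identical(tr1$left_fraction, 1)

  # realized fraction within 3 binomial SEs at n = 10000
  tr2 <- simulate_turn_trajectory(10000, p_left = 0.5, step_lo_deg = 10,
                                  step_hi_deg = 60, seed = 7)
  expect_lt(abs(tr2$left_fraction - 0.5), 0.015)
  expect_true(all(tr2$step_magnitudes_deg >= 10 &
                    tr2$step_magnitudes_deg <= 60))
  expect_true(all(tr2$headings_deg >= 0 & tr2$headings_deg < 360))

  expect_error(simulate_turn_trajectory(10, 0.5, step_lo_deg = 0),
               class = "rg_parameter")
  expect_error(simulate_turn_trajectory(10, 1.5), class = "rg_parameter")
})

test_that("trajectory steps reconstruct exactly from the headings (wrap-aware)", {
  tr <- simulate_turn_trajectory(500, p_left = 0.3, step_lo_deg = 5,
                                 step_hi_deg = 170, seed = 11)
  h <- tr$headings_deg
  d <- (diff(h) + 180) %% 360 - 180
  d[d == -180] <- 180
  expect_equal(abs(d), tr$step_magnitudes_deg, tolerance = 1e-10)
  expect_identical(ifelse(d > 0, "left", "right"), tr$step_signs)
})

test_that("generators are bit-reproducible given the seed", {
  expect_identical(simulate_turn_trajectory(40, 0.6, seed = 9),
                   simulate_turn_trajectory(40, 0.6, seed = 9))

  tr <- simulate_turn_trajectory(5, 0.5, seed = 2)
  v1 <- render_mouse_video(tr, test_arena(noise_sd = 0.05), seed = 3)
  v2 <- render_mouse_video(tr, test_arena(noise_sd = 0.05), seed = 3)
  expect_identical(v1$frames, v2$frames)

  spec <- lfp_sim_spec(duration_s = 4, fs_hz = 500, gamma_freq_hz = 68,
                       gamma_bandwidth_hz = 2, seed = 5)
  expect_identical(simulate_lfp(spec)$samples, simulate_lfp(spec)$samples)
})

test_that("rendered frames have the programmed structure", {
  tr <- simulate_turn_trajectory(49, p_left = 0.5, seed = 6)
  vid <- render_mouse_video(tr, test_arena(), source_fps = 30,
                            analysis_fps = 5, seed = 6)
  expect_length(vid$frames, 50 * 6)
  # pose constant within each block of 6 source frames
  expect_identical(vid$frames[[1]], vid$frames[[6]])
  expect_false(identical(vid$frames[[6]], vid$frames[[7]]))

  # exactly one connected component above half intensity, area near analytic
  ar <- test_arena()
  f <- vid$frames[[1]]
  lab <- EBImage::bwlabel(EBImage::Image((f > 0.5) + 0))
  expect_equal(max(lab), 1)
  analytic <- pi * ar$body_major_px * ar$body_minor_px +
    ar$tail_length_px * ar$tail_width_px
  expect_lt(abs(sum(f > 0.5) - analytic) / analytic, 0.03)

  expect_error(render_mouse_video(tr, test_arena(), source_fps = 30,
                                  analysis_fps = 7),
               class = "rg_parameter")
})

test_that("simulated LFP carries the programmed gamma component", {
  # no gamma: in-band maximum of the detrended spectrum stays near the band
  # spread of the background (no injected peak)
  spec0 <- lfp_sim_spec(duration_s = 60, fs_hz = 1000, gamma_freq_hz = 68,
                        gamma_snr = 0, seed = 3)
  d0 <- detrend_power(welch_psd(simulate_lfp(spec0)))
  sel <- d0$freqs_hz >= 50 & d0$freqs_hz <= 90
  spread <- stats::IQR(d0$power[sel])
  expect_lt(max(d0$power[sel]) - stats::median(d0$power[sel]), 10 * spread)

  # with gamma at 68 Hz the peak towers over the band and sits on the bin
  spec1 <- lfp_sim_spec(duration_s = 120, fs_hz = 1000, gamma_freq_hz = 68,
                        gamma_snr = 4, seed = 3)
  rec <- simulate_lfp(spec1)
  pk <- recording_gamma_peak(rec)
  expect_lt(abs(pk$peak_freq_hz - 68), 0.25 + 1e-9)
  expect_false(pk$flat_flag)

  # cross-check against the direct-FFT periodogram oracle
  pg <- fft_periodogram(rec$samples, 1000)
  in_band <- pg$freqs_hz >= 50 & pg$freqs_hz <= 90
  f_oracle <- pg$freqs_hz[in_band][which.max(pg$power[in_band])]
  expect_lt(abs(f_oracle - 68), 1)

  # Nyquist violation rejected
  expect_error(lfp_sim_spec(fs_hz = 120, gamma_freq_hz = 68),
               class = "rg_parameter")
})

test_that("sine-mode gamma puts its power at the programmed bin", {
  spec <- lfp_sim_spec(duration_s = 60, fs_hz = 1000, gamma_freq_hz = 68,
                       gamma_snr = 8, gamma_waveform = "sine", seed = 12)
  d <- detrend_power(welch_psd(simulate_lfp(spec)))
  sel <- which(d$freqs_hz >= 50 & d$freqs_hz <= 90)
  expect_equal(d$freqs_hz[sel][which.max(d$power[sel])], 68)
})

test_that("gamma timecourse programs frequencies by day and side", {
  spec <- lfp_sim_spec(duration_s = 30, fs_hz = 500, gamma_snr = 6, seed = 1)
  tc <- simulate_gamma_timecourse(72, 6, day_labels = c(-0.5, 0.5, 7),
                                  shifted_days = 0.5, spec = spec, seed = 2)
  expect_identical(
    tc$truth$gamma_freq_hz[tc$truth$side == "left"], c(72, 66, 72))
  # the two sides get different sample paths
  expect_false(identical(tc$recordings$left[["-0.5"]]$samples,
                         tc$recordings$right[["-0.5"]]$samples))

  # zero shift: all days share the recovered peak within one bin
  tc0 <- simulate_gamma_timecourse(72, 0, day_labels = c(-0.5, 0.5),
                                   shifted_days = 0.5, spec = spec, seed = 3)
  pks <- sapply(tc0$recordings$left,
                function(r) recording_gamma_peak(r)$peak_freq_hz)
  expect_lt(max(pks) - min(pks), 0.25 + 1e-9)

  expect_error(
    simulate_gamma_timecourse(52, 6, c(-0.5, 0.5), 0.5, spec),
    class = "rg_parameter")
})
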