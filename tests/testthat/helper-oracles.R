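# Independent oracles and small fixture builders used across the suite.

# Test-scale arena: small frames keep rendering and tracking fast.
test_arena <- function(noise_sd = 0, body_major = 18, body_minor = 8,
                       tail_length = 25, tail_width = 3) {
  arena_spec(320, 240, body_major_px = body_major, body_minor_px = body_minor,
             tail_length_px = tail_length, tail_width_px = tail_width,
             noise_sd = noise_sd)
}

# Smallest wrapped angular distance between two headings, degrees.
ang_err <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# Second-moments heading oracle: principal axis of the body-mask pixel
# second-moment matrix, oriented away from the tail centroid, in arena
# coordinates (y up). Independent of the k-means path.
second_moments_heading <- function(mask_pixels, tail_centroid_xy) {
  idx <- which(mask_pixels, arr.ind = TRUE)
  co <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  cc <- sweep(co, 2, colMeans(co))
  v <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors[, 1]
  v <- c(v[1], -v[2])                    # arena coords
  bc <- colMeans(co)
  d <- c(bc[1] - tail_centroid_xy[1], -(bc[2] - tail_centroid_xy[2]))
  if (sum(v * d) < 0) v <- -v
  (atan2(v[2], v[1]) * 180 / pi) %% 360
}

# Tail centroid (x, y) from the two masks, for the oracle above.
tail_centroid <- function(body_mask, tail_mask) {
  tp <- which(tail_mask$pixels & !body_mask$pixels, arr.ind = TRUE)
  c(mean(tp[, 2]) - 1, mean(tp[, 1]) - 1)
}

# Brute-force exact Mann-Whitney two-sided p: literal enumeration of all
# C(n, nx) assignments of the pooled mid-ranks.
brute_force_mwu_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(nx)])
  sums <- combn(length(r), nx, function(i) sum(r[i]))
  p_le <- mean(sums <= obs + 1e-9)
  p_ge <- mean(sums >= obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Direct-FFT periodogram of a full signal (one-sided density), the
# independent spectral oracle for the Welch path.
fft_periodogram <- function(x, fs) {
  n <- length(x)
  p2 <- Mod(stats::fft(x))^2 / (fs * n)
  half <- n %/% 2 + 1
  p1 <- p2[seq_len(half)]
  p1[2:(half - 1)] <- 2 * p1[2:(half - 1)]
  list(freqs_hz = (seq_len(half) - 1) * fs / n, power = p1)
}

# One rendered single-pose frame at a given heading, plus its masks.
render_single_pose <- function(heading, arena = test_arena(), seed = 1) {
  tr <- simulate_turn_trajectory(1, 1, heading0_deg = heading, seed = seed)
  vid <- render_mouse_video(tr, arena, source_fps = 5, analysis_fps = 5,
                            seed = seed)
  f <- vid$frames[[1]]
  bm <- segment_body(f, threshold = 0.5)
  tm <- segment_tail_inclusive(f, bm)
  list(frame = f, body = bm, tail = tm)
}
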