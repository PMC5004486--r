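test_that("segmentation isolates the animal and rejects empty scenes", {
  expect_error(segment_body(matrix(0, 60, 80), threshold = 0.5),
               class = "rg_no_animal")

  # noiseless ellipse: mask equals the thresholded component
  sp <- render_single_pose(0, test_arena(tail_length = 0, tail_width = 1))
  raw_area <- sum(sp$frame > 0.5)
  expect_lt(abs(sp$body$area_px - raw_area), 0.02 * raw_area)

  # bright speck is removed by largest-component selection
  f <- sp$frame
  f[5:6, 5:7] <- 0.95
  bm <- segment_body(f, threshold = 0.5)
  expect_false(any(bm$pixels[1:10, 1:10]))
  expect_identical(bm$area_px, sp$body$area_px)

  # Otsu auto-threshold finds the same body
  bm_auto <- segment_body(sp$frame, threshold = "auto")
  expect_gt(sum(bm_auto$pixels & sp$body$pixels) / sp$body$area_px, 0.95)
})

test_that("tail-inclusive region is a superset capturing the tail", {
  sp <- render_single_pose(30)
  expect_true(all(sp$tail$pixels[sp$body$pixels]))  # superset of the body
  expect_gt(sp$tail$area_px, sp$body$area_px + 30)  # the tail pixels
})

test_that("heading follows the stated arena-coordinate convention", {
  expect_equal(heading_from_points(c(10, 0), c(0, 0)), 0)
  expect_equal(heading_from_points(c(0, 0), c(0, 10)), 90)  # front above back
  expect_equal(heading_from_points(c(0, 10), c(0, 0)), 270)
  expect_equal(heading_from_points(c(-3, 0), c(0, 0)), 180)
  expect_error(heading_from_points(c(1, 1), c(1, 1)),
               class = "rg_degenerate_body")
})

test_that("three-point extraction recovers programmed headings", {
  for (h in c(0, 30, 117, 201, 333)) {
    sp <- render_single_pose(h, seed = h + 1)
    pose <- extract_body_points(sp$body, sp$tail)
    expect_lt(ang_err(pose$heading_deg, h), 2)
    expect_false(pose$degenerate_flag)
    # middle cluster sits near the front/back midpoint
    mid <- (pose$front_px + pose$back_px) / 2
    expect_lt(sqrt(sum((pose$center_px - mid)^2)), 8)
  }
})

test_that("heading error stays within 2 degrees down to elongation 1.6", {
  for (el in c(1.6, 2.0, 3.0)) {
    ar <- test_arena(body_major = round(10 * el), body_minor = 10,
                     tail_length = 20)
    for (h in c(14, 154, 280)) {
      sp <- render_single_pose(h, ar, seed = h)
      pose <- extract_body_points(sp$body, sp$tail)
      expect_lt(ang_err(pose$heading_deg, h), 2)
    }
  }
  # at elongation 1.5 the k-means slab optimum itself tilts slightly; the
  # axis still agrees with the second-moments oracle bound
  ar <- test_arena(body_major = 15, body_minor = 10, tail_length = 20)
  for (h in c(14, 154, 280)) {
    sp <- render_single_pose(h, ar, seed = h)
    pose <- extract_body_points(sp$body, sp$tail)
    expect_lt(ang_err(pose$heading_deg, h), 3)
  }
})

test_that("degenerate bodies are flagged or resolved by temporal continuity", {
  expect_error(
    extract_body_points(structure(list(pixels = matrix(FALSE, 4, 4),
                                       area_px = 0), class = "binary_mask"),
                        structure(list(pixels = matrix(FALSE, 4, 4),
                                       area_px = 0), class = "binary_mask")),
    class = "rg_degenerate_body")

  # a perfect circle with no tail and no history is ambiguous
  f <- matrix(0.1, 120, 120)
  xg <- matrix(rep(0:119, each = 120), 120)
  yg <- matrix(rep(0:119, 120), 120)
  f[(xg - 60)^2 + (yg - 60)^2 <= 20^2] <- 0.9
  bm <- segment_body(f, threshold = 0.5)
  tm <- bm                               # no tail region at all
  expect_error(extract_body_points(bm, tm), class = "rg_ambiguous_heading")

  # with a previous pose the assignment within 90 degrees is chosen
  prev <- structure(list(heading_deg = 10), class = "body_pose")
  pose <- extract_body_points(bm, tm, prev_pose = prev)
  expect_true(pose$degenerate_flag)
  expect_lt(ang_err(pose$heading_deg, 10), 90)
})

test_that("track_video subsamples to the analysis rate and records gaps", {
  tr <- simulate_turn_trajectory(49, p_left = 0.7, seed = 21)
  vid <- render_mouse_video(tr, test_arena(), source_fps = 30,
                            analysis_fps = 5, seed = 21)
  series <- track_video(vid)
  expect_length(series$headings_deg, 50)
  expect_identical(series$frame_indices, seq(0L, 294L, by = 6L))
  err <- ang_err(series$headings_deg, tr$headings_deg)
  expect_lt(max(err), 1)

  # blank out some source frames: those analysis frames become gaps
  vid2 <- vid
  vid2$frames[[13]] <- matrix(0, 240, 320)  # analysis frame index 2 (0-based)
  s2 <- track_video(vid2)
  expect_identical(s2$status[3], "no_animal")
  expect_true(is.na(s2$headings_deg[3]))
  expect_identical(sum(s2$status == "ok"), 49L)

  # identical input and config give identical output
  expect_identical(track_video(vid), series)
})

test_that("tracking aborts when most frames fail", {
  tr <- simulate_turn_trajectory(9, p_left = 0.5, seed = 2)
  vid <- render_mouse_video(tr, test_arena(), source_fps = 5,
                            analysis_fps = 5, seed = 2)
  for (i in 1:8) vid$frames[[i]] <- matrix(0, 240, 320)
  expect_error(track_video(vid), class = "rg_tracking_failed")
})
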