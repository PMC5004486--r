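---
title: "Quantifying reversible silencing: rotational bias and gamma peak frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reversible silencing: rotational bias and gamma peak frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotagamma)
```

## What the package measures

Reversible chemogenetic silencing experiments (an engineered
ivermectin-gated chloride channel expressed in a target structure) need
behavioral and electrophysiological readouts that are sensitive to a
transient, drug-locked change and return to baseline when the drug washes
out. This package implements two such readouts:

1. **Rotational bias.** A mouse with one silenced striatum turns
   preferentially toward one side. From a top-view video of the animal in a
   small round arena, the tracker extracts a per-frame body heading and the
   session statistic is the fraction of left turns among all turns,
   $B = n_L / (n_L + n_R)$, together with the change from the animal's own
   baseline session, $\Delta = |B_{\mathrm{post}} - B_{\mathrm{base}}|$.
2. **Gamma peak frequency.** Silencing part of the olfactory-bulb granule
   cell network slows the bulb's gamma oscillation. From intracranial LFP
   recordings, the analysis estimates a Welch power spectrum, removes a
   linear spectral trend, and reads off the frequency of the 50–90 Hz power
   maximum. Day-by-day peak frequencies, normalized to the pre-injection
   baseline, trace the slowing and its recovery; the two bulb sides are
   treated as independent samples and sorted per animal into weak and
   strong responders by their downshift half a day after injection.

Because raw recordings of this kind are rarely deposited, the package ships
seeded generators for both modalities. Every generated object carries its
programmed ground truth, so each stage is validated by parameter recovery
rather than against stored reference files.

## The video tracker

Each analyzed frame (every sixth source frame: 30 fps acquisition, 5 fps
analysis) passes through:

1. **Threshold** — Otsu's method on the frame histogram by default, or a
   fixed intensity. The synthetic arena is dark and the body bright, so
   either works; real footage should use `"auto"`.
2. **Morphological cleanup** — a binary opening then closing with a disc
   structuring element (radius 2 px by default), then retention of the
   largest connected component. The opening removes speckle *and* the thin
   tail, which is what makes the body mask a clean ellipse-like region; the
   closing fills interior holes. If two components are within 10% of each
   other in area, the one nearer the previous frame's body center wins and
   a warning is logged.
3. **Three-point body model** — k-means with $k = 3$ on the body-mask pixel
   coordinates. The initialization axis comes from the *tail-inclusive*
   region (the body mask dilated by 5 px united with every raw-threshold
   component touching it): its principal axis runs body-to-tail and fixes
   the split direction. The three initial centers are placed collinearly on
   that axis, one per projected body-pixel tertile, and Lloyd iterations
   refine them. We chose this variant after observing that literal
   tertile-centroid initialization combined with swap-phase refinements
   (Hartigan–Wong) lets the converged partition tilt by up to ~4° for
   rounder bodies; collinear initialization with Lloyd updates keeps the
   slab structure and the worst-case tilt at ~2.4° at elongation 1.5 and
   under 1.5° at elongation ≥ 1.6. For bodies at the default elongation
   (2.25) the recovered heading is accurate to well under 1°.
4. **Front/back disambiguation** — the tail anchor is the centroid of the
   tail-inclusive region minus the body; the body end farther from it is
   the front. When no tail pixel is visible (e.g. tail tucked under the
   body) the assignment within 90° of the previous frame's heading is used
   and the pose is flagged degenerate. The primary rule is geometric on
   purpose: the downstream 120° step filter exists to catch residual
   head–tail reversals, so it must not be asked to catch systematic ones.
5. **Heading** — the angle of the back→front vector in arena coordinates
   (x rightward, y upward, counterclockwise positive, wrapped to
   [0°, 360°)). Left turns are counterclockwise in these coordinates; the
   convention string is recorded in every output because the bias is a
   within-animal contrast and any fixed convention is equally valid.

Frames that fail segmentation or pose extraction become recorded gaps —
never interpolated — and the session aborts if more than half its frames
fail.

## From headings to bias

Consecutive valid headings give signed, wrap-aware steps in (−180°, 180°].
Steps are kept when their magnitude lies in **[4°, 120°]**, both bounds
inclusive: magnitudes under 4° are tracking noise, magnitudes over 120° do
not occur as genuine single-interval turns and flag head–tail reversals,
and exact 0° steps (baseline crossings) are always dropped. The bounds were
set empirically in the original behavioral work; inclusivity at the bounds
is our reading (the choice is immaterial for continuous heading data and
both bounds are configurable). Steps spanning a tracking gap are emitted
with `direction = "none"` and never counted, so that
kept + dropped-low + dropped-high + gap + zero always equals the total —
an invariant the tests enforce on every session.

The bias counts turns; it does not sum degrees. A degree-weighted variant
is reported alongside (`bias_degree_weighted`) for users who want it, but
the count ratio is the primary statistic and the only one used in
downstream deltas.

## The LFP analysis

- **Welch PSD**: 4 s Hamming windows, 50% overlap, density-normalized so
  the spectrum integrates to the signal's mean square; frequency resolution
  1/4 s = 0.25 Hz. No demeaning, down-sampling or artifact correction is
  applied. The estimator is validated against Parseval identities (white
  noise integral vs variance; bin-centered sinusoid integral vs $A^2/2$)
  and a direct-FFT periodogram oracle.
- **Detrend**: an ordinary least-squares line in linear power vs linear
  frequency, fit and subtracted over 4–200 Hz (the analyzed range). The
  returned spectrum is restricted to the fit band; its values may be
  negative. Log-domain detrending is available behind an option but is not
  the default.
- **Gamma peak**: argmax of detrended power within 50–90 Hz inclusive,
  ties to the lower frequency. A flatness floor (band max − median below a
  small epsilon) flags uninterpretable peaks instead of erroring, because
  the argmax of noise is always defined but means nothing.
- **Stereotrode averaging** is applied to the two channels' *spectra*, not
  their raw samples: spectral averaging is insensitive to inter-electrode
  phase lags. Time-domain averaging remains possible by averaging samples
  before `welch_psd()`.
- **Normalization and sorting**: each side's daily peak frequency is
  divided by the same side's baseline-day value (the baseline is exactly
  1 by construction and the relative series is invariant to a common
  rescaling of all frequencies). Within each animal, the side with the
  larger downward shift at the sorting day (+0.5 by default) is labelled
  strong, the other weak, ties to the left side; the same rule applies to
  treated and control cohorts.

## What the generators emulate — and what they do not

`render_mouse_video()` draws a bright ellipse (semi-axes 40 × 16 px at
640 × 480; tests use 18 × 8 px at 320 × 240) with a thin straight tail on a
dark circular arena, the major axis following the programmed heading and
the body center following a bounded random walk independent of heading
(the bias statistic uses heading only). The pose is held constant within
each block of six source frames so the 5 fps subsampling is lossless and
tracker error is attributable to vision, not sampling. It does **not**
emulate limb or whisker detail, body bending, occlusions, shadows, lighting
gradients or multi-animal scenes — so passing recovery tests demonstrate
the correctness of the algorithmic chain, not robustness to every artifact
of real footage.

`simulate_lfp()` sums unit-variance 1/f background noise, a narrowband
gamma component and an optional theta sinusoid. The gamma component is
band-limited Gaussian noise (Gaussian spectral envelope), giving the
spectrum a peak of finite width as in biological LFP; a pure-sinusoid mode
exists for exact-bin tests. Its in-band power is scaled to `gamma_snr`
times the realized background power in 50–90 Hz. The default envelope is
narrow (`gamma_bandwidth_hz = 0.5`), chosen so that a single 120 s session
determines the peak to the 0.25 Hz bin — the regime the recovery tests
specify; biological peaks are often broader, and wider bandwidths are a
parameter away (at the cost of bin-exact single-session recovery).
Electrode drift, line noise and movement artifacts are not simulated.

Test-scale defaults (320 × 240 video, 10 s sessions, 1 kHz LFP sampling)
were chosen because correctness of the estimators does not depend on
acquisition-scale inputs (45 min video, 25 kHz sampling); the exported
defaults for `arena_spec()` and `lfp_sim_spec()` keep the nominal
acquisition geometry.

## Numerical choices and degenerate inputs

- Heading wrap: signed differences map to (−180°, 180°], so a 180° flip
  counts as +180 (left) deterministically.
- k-means: Lloyd, at most 200 iterations, one jittered restart, then a
  degenerate-body error; seed 0 by default, so tracking is reproducible.
- Mann–Whitney: exact p by the full arrangement distribution of pooled
  mid-ranks whenever $n_x n_y \le 400$ (computed by a counting recursion
  mathematically identical to enumerating all $\binom{n}{n_x}$
  assignments, so ties are exact); otherwise normal approximation with tie
  and continuity corrections. Two-sided p is $\min(1, 2\,p_{\min\text{-tail}})$.
  Fully tied data yield p = 1 with a warning rather than an error.
- Zero-variance t tests, coincident front/back points, empty masks, a
  missing baseline day, and mismatched spectral grids all raise classed
  errors (`rg_*`) that callers can trap individually.

## Known limitations

- The three-point heading is intrinsically less accurate for rounder
  bodies: at elongation 1.5 the k-means slab optimum on a rasterized
  ellipse can tilt by up to ~2.5° even noiselessly. The bias statistic is
  insensitive to this (a 10°–60° turn cannot flip sign), but users tracking
  near-round animals should not over-interpret single-frame headings.
- Peak-frequency resolution is fixed by the window length (0.25 Hz at
  4 s); day-to-day shifts smaller than one bin are not detectable by the
  argmax, by design.
- The discrete argmax makes no attempt at sub-bin interpolation, matching
  the original analysis style.

## Worked example

```{r example, eval = FALSE}
# Video pipeline: programmed 80% left turns, noiseless rendering
tr <- simulate_turn_trajectory(49, p_left = 0.8, step_lo_deg = 10,
                               step_hi_deg = 60, seed = 1)
arena <- arena_spec(320, 240, body_major_px = 18, body_minor_px = 8,
                    tail_length_px = 25, tail_width_px = 3)
video <- render_mouse_video(tr, arena, seed = 1)
bias <- session_summary(track_video(video))$bias
bias$bias == tr$left_fraction   # exact recovery

# LFP pipeline: gamma programmed at 68 Hz
spec <- lfp_sim_spec(duration_s = 120, fs_hz = 1000, gamma_freq_hz = 68,
                     gamma_snr = 4, seed = 1)
recording_gamma_peak(simulate_lfp(spec))$peak_freq_hz  # 68
```
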