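---
title: "Quantifying spontaneous quiescence from dual-reporter movies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spontaneous quiescence from dual-reporter movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quietrack)
```

## The biological readout

`quietrack` analyses time-lapse movies of cells carrying two fluorescent
cell-cycle reporters: a G0 reporter (mVenus fused to a CDK-binding-defective
p27 mutant, "Venus") that accumulates in quiescent cells and is degraded at
the G0–G1 transition and in S/G2/M, and the G0/G1 FUCCI reporter
(mCherry-hCdt1(30/120), "Cherry") that marks G0/G1 and is degraded at
S-phase entry. After cytokinesis a newborn cell is dark in both channels,
Venus rises first, Cherry follows a few hours later, and the cell sits in a
Venus/Cherry **double-positive (DP)** window while it decides between
proliferation and quiescence. Cells that commit to the cycle degrade Venus
(G1 entry, Cherry-only), then degrade Cherry (S-phase entry, dark), and
divide. Cells that stay double positive are quiescent; a DP window
**prolonged beyond 14 h** is scored as *spontaneous G0*, and a DP window of
**more than 4 h** that still ends in G1 entry is *transient G0*. Because the
two daughters of one mitosis can decide differently, the package also scores
*daughter-pair synchrony*: synchronous G0, synchronous G1 (entry times
within a 1 h tolerance), or asynchronous decisions.

## The generative model

`simulate_population()` draws single-cell event histories from a
`kinetic_profile()`:

* **Onset delays.** Venus onset after cytokinesis and the additional
  Cherry delay are uniform over ranges appropriate to the condition
  (fibroblasts: 2–4 h and 3–4 h; prostate-cancer cells: ~2 h and ~2 h).
* **Ramp kinetics.** Reporter levels follow piecewise-linear (trapezoid)
  rise/fall ramps; rises of 2–3 h and falls of 3–4 h. Only the ordering and
  approximate durations of these transitions are established for real
  reporters, so linear ramps are the minimal shape with the right
  boundaries. During prolonged G0 the level plateaus rather than
  accumulating further; this is a deliberate simplification.
* **The fate law.** At every division the *pair* of daughters draws one of
  three categories with probabilities `(p_sync_g0, p_sync_g1, p_async)`:
  both prolonged-DP (dwell drawn above the 14 h threshold, no G0 exit
  within the simulation), both transient-DP with the same dwell up to a
  < 0.5 h jitter, or asynchronous — one transient dwell, the sibling that
  dwell plus a delay drawn from the condition's asynchrony-delta
  distribution. Asynchronous slow siblings whose total dwell crosses 14 h
  are genuinely spontaneous-G0 cells that later exit; the marginal
  probability that a post-mitotic cell's dwell exceeds the threshold is
  therefore

  $$p_{G0} \;=\; p_{syncG0} + \tfrac12\,p_{async}\,
    P(D_{transient} + \Delta > 14\,h),$$

  and profile construction inverts this identity in closed form (the
  uniform-sum tail is exact, see `dist_sum_tail()`), so a profile's
  `p_spontaneous_g0` is the population fraction the full pipeline should
  recover.
* **Censoring.** Everything is truncated at the movie end (default 72 h at
  0.5 h/frame, within the 20–30 min intervals typical of such
  experiments). A record carries either a division time or a censoring
  time, never both.
* **Founders.** Founders of cycling profiles are sampled from the
  proliferating subpopulation: with probability `p_divide` a founder
  divides at a uniform time within roughly one doubling time, with its
  earlier history reconstructed backwards (so the movie opens on an
  asynchronous population in all phases); the remainder are G0-arrested,
  double positive throughout. Founder tracks start mid-cycle and are
  excluded from post-mitotic statistics by construction.
* **Motion.** Cells perform an isotropic Gaussian random walk (per-frame
  step `motility_sigma`) with pairwise volume exclusion at six spot sigmas
  — cell bodies cannot overlap, which is what makes sister cells
  separable by segmentation. Daughters start one spot radius from the
  parent on opposite sides. Confined ("cell hotel") profiles use low
  motility; plate profiles more.

Shipped profiles encode the studied conditions: `t3t3_fullserum` (64.4%
spontaneous G0; 30% asynchronous pairs with deltas of 1–15 h),
`pc3_hotel` (27.5% spontaneous G0; 30% asynchronous pairs, deltas 1–6 h),
`pc3_plate` (20%), serum-free cohorts sorted from G1 or S/G2/M (90% / 85%
double positive at 72 h, the remainder modelled as reporter-silent clones),
and dormancy-signal presets (`pc3_gas6`, `pc3_tgfb2`, `pc3_gmcsf`) that
encode directional effects only: fewer and earlier divisions under all
three; more synchronous-G0 pairs under Gas6/TGF-beta-2; more synchronous-G1
pairs among dividers under GM-CSF; longer transient-G0 dwells and larger
asynchrony deltas under Gas6. Phase durations that are not published
(prostate-cancer G1 ≈ 10 h, S/G2/M ≈ 12 h, giving a doubling time of about
25–30 h) are package defaults and fully configurable.

## Rendering

`render_movie()` draws each live cell as an isotropic Gaussian spot
(`psf_sigma`, default 3 px) with amplitude `basal + level × peak` per
channel. The basal term (3% of peak) keeps double-negative cells visible,
which is the minimal assumption that lets segmentation and tracking work
without a constitutive nuclear marker. Uniform background (100 counts) is
added, then shot noise plus read noise, drawn jointly as Gaussian noise
with variance `signal + read_sd²`; with a floor of ~100 counts everywhere
the Poisson-to-Gaussian approximation is numerically indistinguishable and
considerably faster for 10⁷-pixel stacks. Stacks are quantized to 16 bits
and written as frame-major, channel-minor multi-page TIFF with a YAML
sidecar carrying the frame interval.

## Segmentation, tracking, classification

**Segmentation** (`segment_frame()`): per-channel background subtraction
(median of the pixels at or below the 25th percentile — deliberately a
low-order statistic, so the subtracted image keeps a small positive
pedestal that the threshold accounts for), channel sum, Gaussian smoothing
with replicate boundaries (circular FFT boundaries would wrap bright cells
into ghost objects at the opposite edge), then a threshold. The default
rule computes Otsu's threshold on the log1p-transformed image: bright
reporter-positive and dim basal-only cells differ by ~30-fold, and
linear-domain Otsu tends to separate bright-versus-rest, dropping the dim
newborn cells that division detection depends on. Every rule is floored at
the image median plus `k_noise` (default 3) noise sigmas so blank frames
yield nothing. Masks are hole-filled, split by watershed on the distance
transform, area-filtered (defaults derived from the spot size), and
measured (intensity-weighted sub-pixel centroids; background-subtracted
channel means clamped at zero).

**Tracking** (`link_detections()`, `detect_divisions()`): frame-to-frame
optimal assignment (Hungarian, via `clue::solve_LSAP`; a tiny label-ordered
epsilon makes equal-distance ties deterministic) with links rejected above
`max_displacement` (10 px/frame); gap closing joins a track end to a later
start within `max_gap` (4 frames ≈ 2 h — newborn cells are dim only
briefly) and `max_displacement × gap` distance. Division detection
processes orphan track starts chronologically: the nearest childless track
with a detection on the preceding frames within `division_radius`
(4 × `psf_sigma`) is the candidate parent; if that track continues through
the division (the optimal linker almost always follows the parent into one
daughter) it is split at the daughter's first frame, otherwise the ended
track adopts up to two starts. Parents left with a single child are
reverted — a lone nearby appearance is more likely a detection dropout
than a division — and no parent ever has more than two children.

**Classification** (`classify_trace()`): per-channel moving-median
smoothing (1.5 h window), normalization by the per-trace 95th percentile
(reporter expression varies from cell to cell even in clonal lines, so
absolute thresholds are not transferable), hysteresis on/off calling
(0.25/0.15 of the robust maximum) and merging of sub-1 h state runs. The
four states follow from the two binary channels (dark, Venus-only, DP,
Cherry-only); any run sequence that is not an in-order subsequence of
`DN → V_ONLY → DP → C_ONLY → DN` is flagged as an order violation and the
trace's call is withheld rather than silently fixed. Because hysteresis
switch times are quantized to the frame grid and biased by the ramp shape,
segment boundaries used for *measurement* are refined: around each switch
the interpolated crossing times of 0.25 and 0.75 of the local plateau are
extrapolated linearly to level zero (onsets) or to the plateau (fall
starts). On noiseless piecewise-linear traces this recovers event times
exactly — which is what lets the test suite require 100% agreement between
classifier calls and generator fate labels — and under noise it is
approximately unbiased. `g1_entry_h` is the refined Venus fall-start time
(the same event for both daughters of a pair, so pair deltas are
convention-free).

Two thresholds generate the calls: a DP window strictly longer than 14 h
is spontaneous G0 (the boundary case of exactly 14 h is *not*, and the
inequality is configurable); an exiting DP window strictly longer than 4 h
is transient G0. A DP window still open at the movie end is censored: it
counts as spontaneous if the observed dwell already exceeds 14 h, and is
otherwise *undetermined* and excluded from fraction denominators.
Additionally, post-mitotic cells first observed later than
`min_classifiable_window_h` (24 h) before the movie end are not scored at
all: with less remaining observation a prolonged dwell cannot be told from
a pending G1 entry, and scoring such cells censors the two fates
asymmetrically (transient cells would still be counted while spontaneous
ones fell out, biasing the spontaneous fraction downward). With the
24 h window both fates are always resolvable and the estimate is unbiased;
this window is the package's reading of scoring quiescence only in cells
observable "for 20 h or more".

**Pair scoring** (`classify_daughter_pair()`): both spontaneous (including
censored-prolonged) — synchronous G0; both entered G1 — synchronous if the
entry difference is at most 1 h (asynchronous deltas below 1 h are not
reported in this system, hence the tolerance), asynchronous otherwise;
exactly one entered while the sibling is in prolonged G0 — asynchronous
with a right-censored delta. When the non-entering sibling is undetermined
(censored early), asynchrony is declared only if that sibling had already
dwelt in DP at least the transient threshold when its sister entered —
otherwise a tracking dropout could masquerade as asynchrony. Dwell-time
distributions are compared with the Mann-Whitney U test
(`compare_duration_distributions()`: exact for two samples of at most 20
without ties, otherwise the midrank/continuity-corrected normal
approximation).

## What the synthetic data does and does not show

The generator reproduces the reporter logic, the censoring structure, the
fate heterogeneity and the crowding/motion nuisances of the real assay; it
does not model photobleaching, focus drift, cell-shape deformation,
uneven illumination, reporter-intensity drift during prolonged G0, or the
microfluidic chamber geometry beyond low motility. Passing the recovery
experiments therefore shows that the measurement pipeline is an unbiased,
correctly-calibrated estimator of the quiescence statistics *under the
stated imaging physics* — not that segmentation or tracking would reach
the same fidelity on arbitrary real microscopy.

## Numerical choices and degenerate inputs

Seeded runs are bit-reproducible (`simulate → render → pipeline` under
fixed seeds); all randomness flows from the seeds. Traces shorter than 3
samples, empty masks, empty lineages, blank frames and zero-founder
populations all return well-defined empty results or explicit errors, and
assignment ties are broken toward lower detection labels. The classifier's
absolute signal floor is set adaptively per channel (10% of the pooled
99th-percentile trace intensity) so basal-only and reporter-silent cells
are never called "on" regardless of per-trace normalization.

One structural deviation from a single shared record schema deserves
mention: cells sorted in G1 and starved of serum re-enter G0 from G1, so
Venus rises *after* Cherry — the only condition that inverts the canonical
onset order. Such records carry a `reentry` flag, and their traces are
deliberately flagged as order violations by the classifier (their
state at the final frame, which is what the serum-free snapshot statistic
uses, is unaffected).

## Problem sizes

The packaged recovery experiments use fields of view of 14 founder cells
on 256 × 256 px frames, 72 h at 0.5 h/frame, pooling 10–12 fields per seed
group and one to three seed groups per condition — several hundred to
~1,500 classifiable post-mitotic cells, at which the sampling error of a
recovered percentage is one to two points. One statistical subtlety
matters when interpreting such runs: the two daughters of a division share
their pair-fate draw, so per-cell quiescence indicators are correlated
within sibling pairs (a design effect of roughly two). Confidence
intervals for recovered fractions should therefore be computed over
division-level clusters, not per-cell counts — the test suite does exactly
that. The serum-free snapshot cohorts are trace-level studies of 1,000
cells × 3 seeds. These sizes were chosen once as a compromise between
sampling error and a desk-scale runtime; all counts are parameters of the
exported functions and scale linearly.
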