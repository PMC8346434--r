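---
title: "Methods: from leaf-disk image stacks to behavioural statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from leaf-disk image stacks to behavioural statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvafeed)
```

## The measurement problem

A leaf-disk feeding bioassay quantifies insect herbivory as the area of an
excised leaf disk eaten over time. In the high-throughput variant this
package targets, each plate is a 10 x 5 array of small cages, each holding
one leaf disk and one larva, filmed from below at one frame per minute for
up to 48 h. The analysis has four stages, each exposed as package
functions and orchestrated by `run_pipeline()`:

1. **grid** — locate each cage as a polygonal region of interest (ROI)
   inside a user-drawn parallelogram;
2. **area** — classify leaf pixels per frame and count them per ROI;
3. **curves / typology** — standardize the per-cage area series into
   fraction-of-intact-disk consumption curves and classify their shapes
   into six behavioural types A–F;
4. **stats** — compare the type distribution across treatments with
   multinomial logistic models.

A fifth module, **simulate**, renders ground-truthed synthetic plate
stacks and curves. It is first-class, tested code: every quantitative
claim in the test suite is checked against quantities this generator
knows exactly.

## Grid detection

Lines parallel to a plate border are nearly uniform when they run along a
cage wall and highly variable when they cross cages (wall, background,
leaf, larva). `line_variance_profile()` sweeps such lines across the quad
at sub-pixel offsets (step at most 1 px), sampling each line by bilinear
interpolation at unit steps and recording the population variance.
`detect_grid()` places separators at the local minima of the smoothed
profile and builds one convex quadrilateral per cage.

Numerical choices, made where the procedure itself leaves them open:

* the profile is smoothed with a centered moving average of 5 samples
  before minima detection; plateaus (uniform walls several pixels wide)
  are collapsed to their center;
* only *deep* minima qualify: below the midpoint of the profile minimum
  and the profile median. Since walls are thin, most lines cross cages, so
  the median tracks the cage-crossing variance level; mid-cage mixture
  minima (lines grazing the disk edge vary *more* than lines through disk
  centers) sit far above this cut while wall minima sit at the noise
  floor;
* accepted minima must be at least 60% of the median candidate pitch
  apart (rejects double detections), and at least 30% of the pitch away
  from the quad borders (rejects the border walls themselves);
* the cage count per axis is inferred as interior minima + 1; an
  `expected_shape` argument turns a mismatch into an error.

On noiseless synthetic renders the detected separators sit within 1 px of
the true wall centers; the tests require 2 px, up to 5 degrees of plate
rotation.

Pixel membership uses the half-open convention: a pixel belongs to the
cell that strictly contains its center after a +1e-6 nudge in x and y, so
two adjacent cells can never share a pixel. ROI arrays persist to a small
XML schema (`save_rois()` / `load_rois()`), with coordinates at 2
decimals.

## Leaf-pixel classification

Two filter families, selectable per experiment:

* **arithmetic filters** on the RGB planes — single channels, 2R-(G+B),
  2G-(R+B), 2B-(R+G), (R+G+B)/3 — or one HSB component. Arithmetic is
  done in signed integers and clamped to [0, 255]; HSB components are
  rescaled to 0–255 so one threshold scale serves all modes. A pixel is
  accepted iff its filtered value is **strictly greater** than the
  threshold. The workhorse default is 2G-(R+B) > 35, which separates green
  leaf tissue from a bright background;
* **reference-colour filters** — the user supplies a handful of leaf
  colours; a pixel is accepted iff its minimum L1 or L2 distance in RGB
  space to any reference is **strictly below** the distance threshold.

Both strictness choices follow the acceptance wording ("over the
threshold", "lower than a threshold"). Per-ROI leaf area is then the
count of accepted pixels, smoothed with a centered running average and
running median over (by default) 10 retained frames; windows shrink at the
series edges. The running median is what makes single-frame occlusions (a
larva crossing a disk) invisible downstream. Stacks may be subsampled
(one frame in 10 or 60) when 1-min resolution is not needed.

## Standardization and quality control

Curves are standardized by dividing each area by the area at the first
retained time point, so the working quantity is the fraction of intact
leaf disk; 1 - fraction is consumption. The denominator is always taken
from the running-median series so a single-frame artifact cannot define
the scale; a cage whose disk is absent at t0 becomes an excluded curve.
Only data strictly before tmax = 2500 min (about 40 h) are retained:
beyond that, disk desiccation and colour drift make area an unreliable
proxy for consumption.

Anomalous curves (a leaf rolling onto itself, a disk pushed by the larva)
are *flagged*, not silently removed: after a running median over 9
samples, a curve is flagged if any single step changes the fraction by
more than 0.15, or if it rises more than 0.10 above its running minimum —
leaf area cannot regrow, so a sustained rise is physical nonsense. The
tolerances are configurable; at the simulator's default noise (sigma =
0.02, well below half of either tolerance) 200 simulated curves produce
zero false flags in the test suite. Exclusion remains an explicit user
decision, which keeps the pipeline reproducible where the original
workflow relied on manual curation.

## Two-fold clustering into behavioural types

Clustering operates on curves linearly interpolated onto a common 10-min
grid covering 0–2490 min (250 points; the strict before-tmax truncation
excludes the 2500-min point itself).

**Stage 1 — SOTA.** A self-organizing tree algorithm grows a binary tree
of SOM-like nodes: the root holds the global centroid; each growth cycle
trains the leaves online (each presented curve pulls its winning leaf by
alpha_w = 0.01, the winner's sibling by alpha_s = 0.001 and its parent by
alpha_p = 0.005) until the total resource — the mean member-to-centroid
distance — changes by less than 1e-4 relative, then splits the leaf with
the largest resource. Growth stops at 14 leaves by default, a count
chosen empirically to avoid near-empty clusters and exposed as a
parameter. Distances are Euclidean on the standardized curves by default
(correlation distance is available as an option). Two robustness details
matter in practice and are deliberate design choices: split children are
seeded at the parent centroid plus/minus half the offset to the parent's
farthest member (a pure tiny-jitter split collapses both children onto
the same side of a tight bundle), and a leaf that ends a cycle with no
members is re-seeded on the farthest member of the highest-resource leaf
(the classic dead-unit rescue of competitive learning). Everything is
deterministic given the seed, and the per-cycle resource trace is
non-increasing.

**Stage 2 — features and K-means.** Each curve is reduced to four
features: t20, t50, t80 — the earliest times at which 20/50/80% of the
disk has been consumed, linearly interpolated between samples and capped
at tmax when never reached — and the total fraction consumed. Each SOTA
cluster is summarized by its member medians, and the 14 medians are
grouped into 6 behavioural groups by Hartigan–Wong K-means with 50
restarts. Features are z-scored first; otherwise times in minutes (up to
2500) would dwarf the 0–1 consumed fraction.

**Letters.** The six groups are labelled deterministically from their
centroid features, encoding the verbal type descriptions: F is the group
with the lowest total consumption (non-feeders); among the rest, A has
the lowest t50 (immediate fast feeders); E has the highest t20 (the most
reluctant starters, t50 breaking ties); C has the largest t80 - t50
spread (fast start, long tail); of the remaining two, B has the lower t50
(fast after a wait) and D is the intermediate leftover. Ties fall back to
group index, and six groups with identical features are an error. An
obvious alternative rule — assigning B by "t20 above the median" —
mislabels archetypes whose t20 ranks differ from their t50 ranks (a slow
late feeder would steal the B label from a fast late feeder), which is
why the selection order above anchors each letter on the feature that
defines it.

## Multinomial analysis

Each cage contributes a one-hot outcome vector over the types A–F. For a
product, the type probabilities are modelled on the log-odds scale
against a reference type W: log(p^w / p^W) = mu^w + alpha_i^w with
treatment effects alpha (the control is the baseline, alpha_control = 0),
or mu^w + gamma_k^w with plate effects instead. The two models are
compared by AIC; the full model with batch effects and plate-within-
treatment interactions is expressible but deliberately refuses to fit
when the design cannot identify it (two plates per treatment cannot
separate plate from treatment-by-plate).

Fitting is by Newton iterations on the multinomial log-likelihood with
step-halving, so the likelihood never decreases; the covariance is the
inverse observed information. The treatment-only model is saturated for
the treatment x type table, so its fitted probabilities must equal the
empirical proportions — the test suite checks this to 1e-6, and
cross-checks the log-likelihood and coefficients against an independent
optimizer. Probabilities per treatment follow the softmax form
p-hat = e^(mu+alpha) / (1 + sum e^(mu+alpha)), with the reference taking
the complement; rows sum to 1 to 1e-10 and are invariant to the choice of
reference.

Treatments are compared by Wald contrasts alpha_i^w - alpha_i'^w with
standard errors from the coefficient covariance and two-sided normal
p-values; a positive contrast means type w (relative to W) is more
frequent under i than i'. No multiple-testing correction is applied by
default (raw contrasts are reported); Holm adjustment is available via
`all_contrasts(fit, adjust = "holm")`. The reference is chosen as the
category whose counts are most uniform across treatments (smallest
chi-square against uniformity, among categories with no zero cell) —
a lopsided reference makes every contrast noisy. Zero cells in the
treatment x type table trigger a quasi-separation warning; a ridge
penalty of about 1e-6 stabilizes such fits at a negligible bias, which
matters for real dose-response data where the highest dose can drive one
type towards 100%.

## What the simulator emulates — and what it does not

`simulate_curve()` draws behavioural archetypes with delayed exponential
kinetics, consumed(t) = c_total (1 - exp(-(t - L)/tau)) for t past the
latency L, plus Gaussian noise clipped to [0, 1.05]:

```{r archetypes, echo = FALSE}
do.call(rbind, lapply(archetype_params(), function(p)
  data.frame(L_min = p$L, tau_min = p$tau, c_total = p$c_total,
             two_phase = !is.na(p$slow_after))))
```

Type C slows to 15% of its initial rate once 40% of the disk is consumed
(taken as an absolute fraction of the disk), producing its signature low
t50 / high t80. These parameters realise the verbal type descriptions
with clearly separated features; their closed-form t20/t50/t80 agree with
`extract_features()` within one grid step on noiseless curves.

`render_plate_stack()` draws plates with bright walls, agar-filled cages,
green disks whose pixel area tracks fraction-intact *exactly* (pixels are
eaten from the rim as an angular sweep, and the ground-truth area is the
remaining mask count), an illumination ramp, per-pixel Gaussian noise,
and rare single-frame dark blobs that exercise the running-median
robustness. Default test geometry is a 614 x 319 px plate with 55 px
cages and 22 px disks — deliberately smaller than real 1920 x 1080
frames so tests run in seconds.

The simulator does **not** emulate leaf texture, colour drift and
desiccation, frass accumulation, condensation, or larvae resting on
disks for many consecutive frames. Passing tests therefore demonstrate
the correctness of the measurement and inference machinery under
controlled conditions, not robustness to every nuisance of real
recordings; real data still warrant inspecting the per-plate curve-grid
PDFs that the pipeline emits.

## Problem sizes used by the test suite

Simulations are sized to what the properties need: typology recovery
uses 300 curves (50 per archetype, sigma = 0.02) through the full
SOTA(14) to K-means(6) pipeline; multinomial calibration uses 1000
null replicates at 100 cages per treatment; AIC model discrimination
uses 100 replicates per scenario; brute-force counting oracles run on
100 random frames. Rendered fixtures use 2 x 2 to 5 x 10 plates of 1–30
frames, generated at test time — nothing is stored on disk.

## Known limitations

* Grid detection assumes walls brighter-or-darker than the *mixture* of
  cage contents; a plate whose cages are uniformly empty (all walls, no
  contrast) is rejected rather than guessed.
* SOTA's online updates make cluster boundaries seed-dependent for
  curves lying between archetypes; the letter of a borderline curve can
  change with the seed even though aggregate type frequencies are stable.
* The multinomial model treats cages as independent; plate-level
  overdispersion shows up only through the plate model's AIC, not as a
  variance correction.
* `choose_reference()` needs every category observed in every treatment;
  heavily separated designs fall back to the most frequent category with
  a warning.
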