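---
title: "Methods: quantifying heterogeneous ERK reactivation after BRAF inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying heterogeneous ERK reactivation after BRAF inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ktrdyn)
```

## The scientific question

Melanoma cells carrying the BRAF^V600E^ mutation respond to the BRAF
inhibitor vemurafenib with a rapid shutdown of MAPK signaling, read out as
dephosphorylation of ERK. In bulk assays the shutdown looks complete and
uniform, yet a small fraction of cells ultimately resumes proliferating
under drug. `ktrdyn` implements a single-cell analysis that asks *when* and
*in which cells* ERK signaling reactivates: a kinase-translocation reporter
(KTR) is imaged every 10 minutes for 4 hours after drug addition, each
cell's activity trace is reduced to a three-parameter two-phase linear
model, the distribution of reactivation slopes is tested for bimodality,
and the early signaling class of each cell is linked to the size of the
lineage it founds over the following week.

Because the original microscopy data are not publicly deposited, the
package pairs every analysis stage with a seedable synthetic-data generator
that emulates the study's statistical structure with known ground truth.
All validation statements in the test suite are statements about this
synthetic world; agreement there demonstrates correctness of the
algorithms, not performance on real microscopy.

## Reporter quantification

ERK activity is inferred from the subcellular localization of the KTR:
active ERK drives the reporter to the cytoplasm, inhibited ERK lets it
accumulate in the nucleus. Per frame:

1. **Illumination correction** — a grayscale white top-hat with a disk
   structuring element (`tophat_radius`, default 15 px, chosen to exceed
   the nucleus radius) removes smooth background. The grayscale
   erosion/dilation pair is implemented in compiled code; flat fields map
   to zero.
2. **Segmentation** — Otsu thresholding of the corrected nuclear-tag
   channel (a fixed threshold is available as an override), connected-
   component labeling, then area (`min_area`–`max_area`, default 20–500
   px²) and eccentricity (default ≤ 0.95) filters remove debris and merged
   objects. Touching nuclei are *not* split by watershed; merged blobs are
   filtered out instead, trading recall for precision.
3. **Ring quantification** — background is the 25th percentile of reporter
   pixels away from all cells and is subtracted (clipped at zero). The
   nuclear statistic is the 80th-percentile reporter intensity inside the
   nucleus label. The cytoplasm ring spans distances
   (`ring_gap`, `ring_gap + ring_width`] = (1, 4] px from the nucleus
   boundary, excluding every other nucleus and its gap zone; its summary is
   also the 80th percentile by default (the ring statistic is configurable
   because only the nuclear percentile is pinned down by the protocol the
   package follows). Activity is the ring/nucleus ratio; an empty ring or
   zero nuclear intensity flags the observation invalid rather than
   erroring.

Coordinates in all tables are 0-based (x = column, y = row); frames are
0-based.

## Tracking

Consecutive frames are registered by the integer translation that
maximizes the FFT cross-correlation of the binary nucleus masks —
systematic stage drift is translational, so no feature-point machinery is
needed. After drift correction, each nucleus is greedily assigned to the
spatially closest nucleus of the next frame (ascending distance; ties
broken by lowest previous id, then lowest next id; one-to-one). Links
longer than `max_displacement` (20 px/frame) or with a relative area
change above `max_area_change` (0.3, typically mitosis) are dropped; these
thresholds are deliberately conservative calibration choices, not
published values. Tracks are the transitive closure of the links; by
default only tracks spanning every frame are kept, which on default
synthetic movies retains well over half of all detected nuclei.

## The two-phase linear model

Each trace of relative activity $y(t) \in [0,1]$ is fitted with

$$ y(t) = y_0 + s_{\mathrm{inh}} \min(t, t_b) + s_{\mathrm{rec}} \max(0, t - t_b), $$

a continuous piecewise-linear curve with an inhibition slope
$s_{\mathrm{inh}}$ (per hour, expected negative), a reactivation slope
$s_{\mathrm{rec}}$, and one breakpoint $t_b$. $y_0$ is anchored to the
first observation, so three parameters are free. The breakpoint is
searched over the observation grid (every candidate leaving at least two
points per segment); at each candidate the slopes solve a 2×2 least-squares
system in closed form, and the candidate with minimal residual sum of
squares wins, ties going to the earliest breakpoint. This makes the fit
deterministic, exactly reproducible, and directly checkable against an
exhaustive generic-solver oracle (the test suite does this on 100 noisy
traces). Richer kinetic models are deliberately out of scope.

**Normalization.** Raw ring/nucleus ratios are normalized per cell to the
range observed during the experiment (`normalize_trace(method =
"per_cell")`); per-experiment scaling is available. Traces produced by the
generator are *already* in relative units, and for them the pipeline uses
`method = "none"`: re-applying a per-cell min–max to an already-relative
trace divides each cell's slopes by its own noisy observed range, which
(i) maps every shallow-inhibition cell's slope to roughly $-1/t_b$ and
(ii) truncates noise at the floor if values are clipped — both visibly
distort the slope distributions. Pass-through also leaves noise excursions
below 0 and above 1 untouched, which is essential for unbiased slopes at
the activity floor.

## Bimodality analysis

The population structure of a slope sample is decided by comparing a
single-Gaussian fit with a two-component Gaussian mixture:

* the Gaussian fit is the ML estimate (mean, population sd);
* the mixture is fitted by EM (compiled hot loop) with restarts from
  quantile splits (0.5, 0.25, 0.75) plus random initializations, a
  variance floor of $10^{-4}\,\mathrm{var}(x)$, a weight floor of 0.01,
  at most 500 iterations and a log-likelihood tolerance of $10^{-8}$;
  components are ordered by mean, so component 2 is the reactivating one;
* each model is tested with a Kolmogorov–Smirnov statistic against its
  fitted CDF and a **parametric bootstrap** p-value (default $B = 200$):
  samples are simulated from the fitted model, the model is *refitted* to
  each, and the p-value is the fraction of bootstrap statistics at least
  as large as the observed one. Refitting is what accounts for estimated
  parameters (the Lilliefors problem); the asymptotic KS distribution
  would be badly conservative here. Bootstrap mixture refits use the
  deterministic quantile-split starts with a short-run initialization
  stage (emEM); the extra random restarts of the main fit are omitted
  there for speed.

The verdict is **bimodal** when the unimodal fit is rejected
(`p_uni < alpha`) and the mixture is not (`p_bi >= alpha`); **unimodal**
when the unimodal fit stands; **neither** (flagged) when both are
rejected — the underlying study leaves this case undefined, so it is
surfaced rather than silently resolved. A pure statistic-comparison rule
is available via `rule = "statistic"`. Because the verdict cannot depend
on `p_bi` when the unimodal fit already stands, `decide_modality()`
computes the mixture bootstrap lazily by default and reports `p_bi = NA`
in that branch (`lazy = FALSE` restores the full record); verdicts are
identical either way.

When the verdict is bimodal, the weight of the higher-mean component is
the estimated reactivating fraction, and cells are classified by posterior
responsibility (> 0.5 for the reactivating component; exact ties go to the
majority component).

A structural note on power: on truly bimodal data a *calibrated* mixture
bootstrap still rejects about $\alpha$ of samples, so the verdict's power
is capped near $(1-\alpha)$ times the power of the unimodal-rejection
test. The test suite therefore tracks both quantities separately.

## Lineage analysis

Lineages are parent–child event tables (two child rows per division; a
parent ceases to exist when it divides). `count_descendants()` validates
the forest property (single parent, no cycles, with offending rows named)
and counts, per ancestor, the cells alive at the horizon.
`compare_groups()` contrasts reactivating versus pooled non-reactivating
ancestors with a two-sided Wilcoxon rank-sum test (mid-ranks, tie-corrected
normal approximation; exact enumeration of all group assignments when the
combined sample is ≤ 20) and a Welch two-tailed t-test (the variance
assumption of the original analysis is unstated; Welch is the safer
default). Dead or detached ancestors (size 0) are retained by default and
can be dropped via `drop_dead = TRUE`.

The 180-cell follow-up design — 60 reactivating cells plus the
non-reactivating pool split at its median reactivation slope into 60
strongly and 60 weakly inhibited cells — is reproduced by
`sample_signaling_strata()`.

## In-cell-western quantification

Per well, the phospho-ERK signal (800 nm) is divided by the CellTag
whole-cell signal (700 nm); condition means of this ratio are rescaled to
[0, 1] against the minimum and maximum across conditions of one experiment
(condition means by default; pooled wells via `scale_on`), with replicate
sds propagated by the same factor. Reactivation calls use one-tailed Welch
t-tests of each condition against the maximum-inhibition reference with a
Bonferroni-corrected threshold `family_alpha / n_tests` (0.01 for five
tests, 0.005 for ten, at family alpha 0.05).

## The synthetic-data generator

`simulate_traces()` draws, per cell: a class label
(Bernoulli, `frac_recovering` = 0.15), an inhibition slope
$\mathcal N(-1.0, 0.15^2)$ per hour (full inhibition in about an hour), a
breakpoint $\mathcal N(1.0, 0.15^2)$ hours, and a reactivation slope from
the class component — $\mathcal N(0.15, 0.03^2)$ for reactivating cells,
$\mathcal N(0, 0.005^2)$ for flat ones; the components are separated by
far more than three pooled sds. The noiseless curve starts at 1.0, is
continuous at the breakpoint, and lives in [0, 1]; i.i.d. Gaussian
observation noise (sd 0.03, about 3% of the dynamic range — typical for
ratiometric reporter quantification) is added on top. Sampling is every
10 minutes over 4 hours (25 points).

Two generator conventions keep the synthetic world inside the model class
the analysis assumes, and both are deliberate definitions rather than
conveniences:

* **The breakpoint is the decline-arrest time.** A cell whose inhibition
  slope would carry it below the activity floor before its drawn
  breakpoint stops declining when it reaches the floor, i.e.
  $t_b \leftarrow \min(t_b, 1/|s_{\mathrm{inh}}|)$. With the default means
  ($-1.0$/h, 1.0 h) about half of all cells reach the floor, and without
  this coupling their curves would have a third (floor) segment that the
  two-phase model cannot represent, breaking the Gaussianity of the
  fitted-slope components that the mixture analysis rests on.
* **Breakpoints live on the sampling grid** (snapped down to the nearest
  frame time): a breakpoint between frames is not identifiable at the
  data's resolution, and the fit searches the same grid. At zero noise
  every generated curve is then recovered exactly.

The flat component's intrinsic spread (0.005/h) sits below the slope
estimation noise, so the fitted flat component is noise-dominated and
Gaussian; a much wider intrinsic spread would interact with the activity
floor and pile probability at exactly zero slope, a feature the
two-Gaussian mixture cannot represent.

`render_timelapse()` rasterizes a cohort into two-channel movies: nuclei
are 2-D Gaussian blobs (sd = radius/2, unit amplitude) in the nuclear-tag
channel; the reporter channel splits a fixed per-cell total intensity
between a nuclear disk (radius 0.8 × nucleus radius) and a 5-px cytoplasm
annulus, with cytoplasmic fraction $0.3 + 0.5 \cdot \mathrm{activity}$ —
both compartments always carry signal, so ring quantification never
divides by zero, and the summed per-cell intensity is exactly conserved
before noise. Global stage drift, per-cell Brownian motion, detachment and
division events (daughters rendered smaller so the conservative area
filter terminates tracks at mitosis, as in the real analysis), a smooth
background gradient and Poisson-like pixel noise (sd ∝ √signal) complete
the camera model. Photorealism (PSF, bleaching, autofluorescence) is a
non-goal. The pipeline's imaging path converts measured ratios back to
activity through the inverse of the localization map using the nominal
compartment geometry; because rasterized pixel counts vary with subpixel
position, the imaging and direct trace paths agree closely but not
bit-for-bit, and the path-equivalence test asserts matching verdicts and
near-equal slopes.

`simulate_lineages()` implements the growth model. Under the default
*delayed-arrest* model, every cell — ancestor or newborn — completes a
further in-progress division with probability $p_0$ before arresting
(drug-induced arrest happens in G1, so cells already past it finish their
cycle); cells of reactivating ancestors then divide as a Poisson (Yule)
process at rate $\lambda$ until the horizon. The flat-class mean is
$(1-p_0)/(1-2p_0)$ and the reactivating mean multiplies it by
$e^{\lambda T}$, so $(p_0, \lambda)$ are solved from the target means
(defaults 2.7 and 6.6 cells at 7 days; $p_0 = 0.386$,
$\lambda = 0.128$/day) before simulation; an infeasible combination —
reactivating target below flat target — raises a parameter error.
Residual divisions are recorded at event time 0 (mitoses already under way
complete at the start of observation), which keeps the calibration exact.
A *rate-switch* model (pure birth at $\log(\mathrm{target})/T$ per class)
is available. The per-cell residual-division rule generalizes a
one-division-per-ancestor reading, which caps the flat mean at 2 and
could not reach the 2.7-cell default.

`simulate_icw_plate()` draws per-well CellTag levels and sets the 800 nm
signal to `gain × celltag × (baseline + span × mean)` plus noise, so the
well ratio is affine in the true condition mean: orderings are preserved,
and noiseless plates round-trip through `relative_perk()` exactly when the
condition means span [0, 1].

## Problem sizes and numerical choices

The test suite validates at the study's own scales: cohorts of 1000
traces for the modality analysis, 2000 ancestors per class for the
lineage means, a 200-cell 512×512 movie over 25 frames for
segmentation/tracking recovery, 500 trials of 500 samples for the type-I
calibration of the bimodality decision (with $B = 200$ bootstrap
replicates), and 60 trials for its power at three-sd component
separation. Determinism is enforced throughout: every stochastic function
takes a `seed` and restores the caller's RNG state, and the pipeline
derives per-stage child seeds from one master seed, so identical
configurations yield byte-identical reports.

Floating-point ties in the breakpoint search are resolved with a relative
tolerance of $10^{-12}$ toward the earlier breakpoint. The EM weight and
variance floors above guard against singular components; EM failures on
all restarts raise an error rather than returning a degenerate fit.

## Limitations

* The synthetic generator is the validation substrate; it emulates the
  assumed statistical structure (piecewise-linear dynamics, Gaussian
  mixtures, uniform-intensity compartments) and therefore cannot expose
  model misspecification on real data — e.g. gradual (non-piecewise)
  reactivation, intensity-dependent noise in the reporter, or segmentation
  bias under dense growth.
* Lineages here come from provided or simulated event tables; automated
  mitosis detection and daughter assignment from images are out of scope,
  matching the by-eye tracing of the original workflow.
* The bimodality machinery fits exactly two components; more complex
  population structure would surface as the flagged "neither" verdict.
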