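---
title: "Methods: memory-strategy scoring, theta coherence, and standardized source localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: memory-strategy scoring, theta coherence, and standardized source localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetamem)
```

## Overview

`thetamem` implements the computational chain of a three-arm randomized
pre/post intervention design in which children perform an array-based
visual recognition memory task while 19-channel scalp EEG is recorded
during encoding. The chain has five stages, each usable on its own:

1. **Task model** — scoring of recall-order data for total recall and
   two retrieval strategies (semantic clustering, visual scanning).
2. **EEG preprocessing** — amplitude-threshold artifact rejection,
   clean-segment selection, splicing, and 2-s epoching.
3. **Spectral connectivity** — Welch cross-spectral estimation and
   theta-band (4–7.5 Hz) magnitude-squared coherence over all 171
   electrode pairs, with eight named frontoposterior cluster means and
   per-pair pre/post change maps.
4. **Source localization** — an sLORETA-style standardized minimum-norm
   inverse on a spherical toy head model, with voxel-wise paired
   t-maps, ROI counts, and per-subject sign tallies.
5. **Group statistics** — one-way ANOVA from raw or summary data, the
   2×3 mixed repeated-measures ANOVA, paired t with Cohen's dz
   (t/√n), Pearson χ² tests, and Pearson correlation.

A synthetic-cohort generator drives every stage, so the full pipeline
is exercised without any recorded data.

## The memory task and its scores

The task presents 24 line drawings — six from each of four semantic
categories (animals, tools, food, clothing) — in a grid of 4 rows × 6
columns. We store the grid 0-based and row-major; the layout is either
*randomized* (a seeded uniform permutation of the 24 cells) or
*organized* (each row holds a single category, an external
organization cue). Twelve of the items (three per category) are
probed as targets on a recognition sheet that also carries 12
distracters; the order in which the child circles items is the raw
behavioural datum.

Three measures are computed on that order:

* **Total recall** — the number of distinct targets circled (max 12).
* **Semantic clustering** — the number of consecutive pairs of
  correctly identified targets sharing a category (max 8: four
  categories × two within-category transitions each).
* **Visual scanning** — the number of consecutive pairs of correctly
  identified targets whose *learning-array* positions share an edge
  horizontally or vertically (max 11, attained when the 12 target
  cells admit a Hamiltonian path in the grid 4-adjacency graph).

Two definitional choices were genuinely open and are worth making
explicit. First, whether a circled distracter interrupts a cluster:
the scores are defined on target items consecutively identified, so by
default the strategy scores are computed on the distracter-free
subsequence (a circled distracter does not break a run); the
alternative is available via `drop_distracters = FALSE`. Second,
adjacency for visual scanning is defined on the learning array, not
the scattered recognition sheet, because the spatial structure worth
scanning exists only in the learning array and the maximum of 11 is
attainable there; diagonal adjacency is excluded (horizontal/vertical
only). The 4-row × 6-column orientation puts categories in rows under
the organized condition.

`brute_force_max_scores()` verifies the printed maxima by exhaustive
depth-first search over recall orders; it is the oracle behind the
score ceilings asserted in the test suite.

## EEG preprocessing

The preprocessing constants are the standard clinical qEEG settings:
data acquired at 256 Hz on the 19-electrode 10–20 montage, referenced
to linked ears, band-passed 1–40 Hz (zero-phase forward–backward
Butterworth, order 4); artifact rejection at ±150 μV (a sample is bad
iff any channel *strictly* exceeds 150 μV in absolute value — the
reject levels are read as bounds of acceptance); artifact-free
segments of at least 600 ms retained; at least 60 s of clean data
required, sampled at random (seeded, with the seed recorded) when more
is available; retained segments spliced and cut into non-overlapping
2-s epochs.

One numeric discrepancy is worth documenting: a 2-s epoch at 256 Hz
has 512 samples, not 256; we keep the native rate and derive the epoch
sample count from `fs`. Splice joints need not align with epoch
boundaries; their positions are recorded in the epoch-set metadata,
and because spectral windows are confined within epochs and Hann
tapered, a joint only ever sits at a window edge where the taper
attenuates it. (The artifact-minimization method of the original
acquisition software is proprietary; this tapering behaviour is our
documented approximation.)

## Coherence

For channels $x, y$ with averaged cross-spectral density $S_{xy}(f)$,
the magnitude-squared coherence is

$$C_{xy}(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1],$$

band-averaged over the bins whose centres fall in 4–7.5 Hz (edges
inclusive). "Normalized cross-spectral power" could also be read as
the non-squared coherency magnitude; we use the magnitude-squared form,
which is the standard qEEG quantity. Cross-spectra are averaged before
normalization (standard Welch practice); averaging per-window
coherence instead is possible but not default. Per-bin coherence is
averaged over the band rather than forming coherence of band-summed
spectra.

Windows default to the full 2-s epoch length with a Hann taper, one
window per epoch; shorter windows slide within epochs at 75 % overlap.
When a long spliced record is supplied as a single epoch, 2-s windows
at 75 % overlap reproduce the sliding-FFT-average estimator; this
configuration roughly quadruples the window count and is what the
closed-form recovery tests use, since the coherence estimator's bias
under independence is approximately $1/n_\text{windows}$.

With 19 channels there are $19 \cdot 18 / 2 = 171$ unordered pairs.
Eight named clusters summarize frontoposterior coupling — intra-frontal
(F3–F7, F4–F8), intra-posterior (P3–O1, P4–O2), intra-left and
intra-right frontoposterior (4 pairs each), and their four
inter-hemispheric counterparts — 28 distinct pairs in total. Cluster
means are arithmetic means of constituent pair coherences. The change
map runs a paired t-test per pair on post − pre and flags significant
*increases* (p < α and positive mean change); no multiplicity
adjustment is applied anywhere in the package, matching the
planned-comparison analysis style, so under the null about α/2 of
pairs are flagged.

## Source localization

The inverse is the standardized minimum-norm family: with
average-referenced lead field $K$, centering matrix $H$, and Tikhonov
parameter $\alpha \ge 0$,

$$T = K^\top (K K^\top + \alpha H)^{+}, \qquad
  \hat{s} = T\,\varphi,$$

and each node's 3-vector moment is standardized by the corresponding
3×3 diagonal block of the resolution matrix $R = T K$ (pseudo-inverted
when singular):

$$P_j = \hat{s}_j^\top \big([R]_{jj}\big)^{+} \hat{s}_j.$$

This standardization is what gives the method its defining property:
for noiseless data from a single point source, the power map peaks
exactly at the true node, for any $\alpha \ge 0$. The test suite
asserts this for every node of a 30-node grid. A second consequence,
also tested: with $\alpha = 0$ and spatially white *source* activity
propagated through the forward model, the expected standardized power
is identical (namely 3, the moment dimension) at every node.

The head model is a deliberately simple stand-in for realistic
template anatomy: a homogeneous unit conducting sphere with the 19
electrodes at idealized 10–20 positions and the classical Legendre
series for the surface potential of an interior dipole (radial and
tangential terms, truncated when the eccentricity power underflows;
a central dipole reduces to the known $3(m \cdot \hat r)/4\pi\sigma R^2$
field, which the tests check). Free 3-D dipole orientations are used,
with power the squared norm of the standardized moment vector; ties at
the peak break to the lowest node index. Sensor data are re-referenced
from linked ears to average reference before inversion, since inverse
theory requires a reference-free formulation. The default
regularization is $\alpha = 10^{-2} \times \text{mean diag}(KK^\top)$;
the localization property is exact at any $\alpha$, so the default only
matters under noise. Source nodes are
placed on a Fibonacci lattice at 0.7 of the scalp radius with coarse
ROI labels (prefrontal, parietal, medial-inferior-temporal, other)
assigned from position. Voxel-wise paired t-maps count significantly
increased/decreased nodes per ROI and, at the node of maximal |t|,
tally subjects with increased versus decreased power, tested against
an equal split with a 2-cell goodness-of-fit χ². The sign of change is
taken on standardized power differences, since the maps themselves are
non-negative. Band-power localization filters the sensor time series
into the band and averages standardized power over samples; a
cross-spectral variant would be a reasonable alternative and is noted
as future work.

## Group statistics

* `oneway_anova_summary()` reconstructs a one-way ANOVA from published
  group means, SDs and sizes: between-group SS from means and sizes,
  within-group SS as $\sum_i (n_i - 1)\,sd_i^2$. It is exactly
  equivalent to `aov()` on raw data matching those moments (tested via
  moment-matched samples).
* `mixed_anova_2x3()` implements the univariate mixed-design
  decomposition directly (subject means carry the between stratum,
  within-subject differences carry time and time × group); with a
  2-level within factor sphericity is trivial, so no
  Greenhouse–Geisser machinery is included. It agrees with
  `aov(y ~ group*time + Error(subject))` to numerical precision on
  random unbalanced datasets; the closed form exists because the
  2,000-replicate type-I calibration in the test suite needs it to be
  fast. The interaction is reported on $(g-1, N-g)$ degrees of
  freedom.
* `paired_t()` reports Cohen's dz as $t/\sqrt{n}$, identically
  `mean(diff)/sd(diff)`. This convention exactly reproduces printed
  (t, d) pairs such as (2.44, 18) → 0.575 and (3.11, 18) → 0.733.
* χ² tests are Pearson's without continuity correction — the attrition
  statistic 3.21 is only reproduced without the Yates correction.
  Counts reconstructed from printed percentages round half away from
  zero and are validated to re-yield the printed percentage at one
  decimal place.
* Baseline rows that are *not* exactly recoverable from rounded
  summary statistics (independent recomputation differs in the second
  decimal) are documented as such in the test suite rather than
  forced.

## The synthetic cohort

The generator's job is to emulate the *structure* of the study, with
enough control to give every pipeline stage a ground truth.

**Recall behaviour** is a sequential softmax sampler: the next circled
item is drawn from the remaining sheet items with weight
$\exp(\gamma_\text{sem}\,[\text{same category as previous}] +
\gamma_\text{spa}\,[\text{array-adjacent to previous}])$; each draw is
a target with probability `hit_probability`, else a distracter
intrusion; recall stops with probability `stop_probability` per step.
This is the minimal process whose parameters the two strategy scores
estimate: at $\gamma = 0$ the expected clustering equals the
exchangeable-order value (verified against exhaustive enumeration on a
reduced array), and expected clustering is increasing in
$\gamma_\text{sem}$.

**EEG** is a shared-source mixing model: each channel receives
band-limited (4–7.5 Hz) Gaussian shared sources scaled by per-group
gains, an *identically filtered* independent in-band background, and a
small broadband sensor floor. Because the shared and independent
band components have the same spectral shape, the in-band coherence of
a channel pair sharing one source has the closed form

$$C = \frac{g_1^2\, g_2^2}{(g_1^2 + \sigma_\text{ind}^2)
      (g_2^2 + \sigma_\text{ind}^2)},$$

independent of the filter's exact roll-off; with equal shared and
background variance this is 1/4. Had the per-channel background been
purely broadband, equal *total* variances would concentrate very
different power densities inside the band and the closed form would
not hold — this is why the background is modelled as in-band activity
with a separate broadband floor. Defaults (shared gain 10 μV,
background 10 μV, floor 2 μV, 120 s at 256 Hz) put the floor's in-band
density two orders of magnitude below the band sources. Square
artifact bursts above the ±150 μV reject level can be injected for
preprocessing tests.

**Study geometry** defaults to the three-arm design retaining 18/17/13
participants (from three groups of 22 with dropout); covariates (age,
IQ, ADI-R subscores) are drawn to match the published baseline
distributions. Training effects are injected at post only, for
designated groups, as additive changes to the strategy parameters
and/or to the frontoposterior shared-source gains. The coupling
topology pairs each frontal electrode with a posterior partner
(F3–P3, F7–O1, F4–P4, F8–O2), so an injected gain boost has its locus
exactly in the intra-hemispheric frontoposterior clusters.

Pre and post draws are independent given the parameters — the
generator has no stable per-subject traits — so within-subject
differences carry the full trait variance and detection is *harder*
than in real paired data at the same mean effect. The demonstration
effect used by the end-to-end recovery test and the pipeline default
($\Delta\gamma_\text{sem} = 2.5$, $\Delta$hit = 0.25, $\Delta$gain = 6
μV, NGT group only) was calibrated once so that the time × group
interaction on clustering scores is detected with power ≈ 0.95 at the
18/17/13 group sizes, and then frozen.

What passing these tests shows — and does not show: the pipeline
recovers the sign and locus of effects under its own generative
assumptions (Gaussian band-limited sources, instantaneous mixing, no
volume-conduction confounds, no alpha rhythm or ocular morphology, no
developmental covariate structure). It does not validate the
physiological interpretation of coherence changes in real recordings.

## Numerical choices and problem sizes

* Coherence values are clamped to [0, 1]; clamping only ever corrects
  floating-point overshoot.
* Band edges are inclusive; bins are assigned by centre frequency.
* Zero-variance difference vectors in paired tests report t = 0 (no
  change) or ±∞ (constant nonzero change, flagged with a warning).
* Effects with zero sum of squares report F = 0 rather than NaN.
* The test suite runs at desk scale: 120-s single-subject records for
  the closed-form checks, a 30-node source grid, 40 replicate studies
  for the behavioural power check, 2,000 replicates for the
  mixed-ANOVA type-I calibration, and one full synthetic study
  (96 one-minute EEG records) for the end-to-end locus recovery.
  These sizes were chosen so the whole suite completes in a few
  minutes while keeping Monte-Carlo error well inside the asserted
  tolerances.

## Known limitations

* The spherical single-layer head model is a toy; no skull/scalp
  conductivity layers, no realistic anatomy, no Talairach/Brodmann
  labelling. ROI voxel counts on the toy grid are structural
  analogues, not anatomical claims.
* Only the amplitude criterion of artifact rejection is automated;
  morphological (ocular/muscle) rejection was a visual step in the
  original workflow and is out of scope.
* EDF reading is not built in; recordings enter as plain numeric
  matrices (CSV) with a JSON sidecar, or directly as R matrices.
* The pipeline's statistics inherit the no-adjustment policy; users
  running many exploratory comparisons should apply their own
  multiplicity control.
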