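---
title: "Staging spawning progression from oocyte size structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging spawning progression from oocyte size structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultrametric)
```

## The staging problem

Serial-spawning fish such as Atlantic cod release their annual fecundity in
batches over a spawning season of weeks. Survey programs sample each fish
once, so spawning progression must be read from a single ovarian sample.
Classical readouts struggle exactly when they are needed most: the
previtellogenic/vitellogenic size gap ("hiatus") becomes subjective when
oocytes occupy it, vitellogenic mean/SD/skewness statistics break down when
cohorts are bimodal or trail long tails, and free hydrated ova bias any
whole-ovary count.

The ultrametric approach sidesteps these failure modes with a ratio of two
pools. In a determinate spawner the previtellogenic oocyte (PVO) pool is
approximately constant through the season, while the developing pool
(vitellogenic + final-maturation oocytes, VO + FOM) is progressively spawned
out. The oocyte ratio

$$\mathrm{OR} = \frac{\sum \mathrm{PVO}}{\sum(\mathrm{VO} + \mathrm{FOM})}$$

therefore increases monotonically with spawning progression, and cutting it
at 1, 3 and 15 yields a four-level oocyte ratio category (ORC): 1 pre/early,
2 mid, 3 late, 4 very late/post-spawning. PVOs are counted in
[100, 250) µm, developing oocytes in [250, 1200] µm; anything larger is a
hydrated or ovulated egg and is excluded because its sampled proportion is an
artefact of how running fish are pipetted. When the developing count is zero
the denominator is replaced by 1 so an OR exists; such fish are deep in
category 4 by construction.

Boundary semantics deserve one note: 250 µm itself is developing (the PVO
window is half-open) and 1200 µm itself is developing (hydrated means
strictly larger). A 200 µm lower split, historically used for maturity
classification, is available via `class_bounds(dev_min_um = 200)` but 250 µm
separates developmental stages more cleanly and is the default.

## Whole-mount detection

Stained whole-mount micrographs show dark oocytes on a light background, so
segmentation is a global grey-level threshold (8-bit grey < 111) followed by
hole filling and connected-component labelling (`EBImage`; the labelling is
4-connectivity, which coincides with 8-connectivity for the smooth filled
blobs this pipeline segments). Components touching the image border are
discarded — their size cannot be measured. Per component we fit the moment
ellipse (axes = 4·√eigenvalue of the second central moments) and report:

* diameter = √(major · minor) µm — the equivalent-area diameter, stable for
  near-circular profiles;
* roundness = 4·area / (π·major²) — 1 for a circle, b/a for an ellipse;
* ellipticity = area / (π/4 · major · minor), capped at 1 — how completely
  the object fills its own moment ellipse, low for concave debris and fused
  blobs.

Acceptance thresholds are size 100–1600 µm, mean grey < 111, roundness
0.8–1.0 and ellipticity ≥ 0.91, at a default resolution of 0.1803 px/µm;
size/roundness/ellipticity bounds are inclusive, the grey bound strict.
The reference image-analysis plugin this replaces does not publish its exact
roundness/ellipticity formulas, so the definitions above are documented
substitutes, not asserted equivalents. Touching oocytes are not split by
watershed in this version; fused blobs fail the roundness/ellipticity gates
and are rejected, which mirrors manual cleaning practice. Rejected records
are retained with the first failing criterion, so counts remain auditable.

Quality control follows the sampling protocol: three micrographs per fish
and at least 200 accepted oocytes; `merge_fish_detections()` flags
shortfalls rather than failing.

## OSFD smoothing and annotation

Oocyte size frequency distributions (OSFDs) are binned at 20 µm (half-open
bins from 100 µm) and smoothed with a Gaussian KDE on a 1-µm grid over
[100, 1600] µm, renormalized to integrate to one on that grid. The bandwidth
is Silverman's rule bounded to [10, 40] µm: unbounded Silverman on a full
PVO + VO mixture over-smooths to 50–60 µm and merges genuinely separate
cohorts, while anything below 10 µm chases sampling noise at realistic
per-fish counts.

Cohort modes are local maxima with topographic prominence at least 5% of the
global maximum. Within the developing window the annotation reports the mode
count, flags clearly separable bimodal VO cohorts (valley below 50% of the
lower peak), flags a "budding" secondary peak when the upper of two modes
lies in [850, 1200] µm (oocytes entering final maturation near 875 µm — an
annotation marker only, never used in classification), and flags an
exceptionally long tail when more than 5% of non-hydrated oocytes lie more
than two cohort standard deviations above the largest developing mode. The
cohort SD is estimated from the left flank of that cohort only (diameters in
the 200 µm below the mode), deliberately blind to the tail being tested;
estimating it from the full cohort would let the tail inflate its own
yardstick.

### Hiatus limits and the ambiguity flag

The hiatus is the empty interval between the PVO cohort and the smallest
developing cohort. Its limits are placed where the smoothed density falls
below 10% of the respective flanking peak height, and the placement is
declared *ambiguous* when the mean density inside the candidate gap exceeds
3% of the PVO peak height — i.e. when oocytes occupy the gap and any
placement would be subjective. Two numerical choices matter here and were
calibrated on simulated scenarios (clean gaps of varying width versus gaps
with ~10% uniform contamination):

* the hiatus density uses a bandwidth capped at 20 µm regardless of the
  cohort-level bandwidth, because 40 µm kernel tails bleed far enough into a
  genuinely empty gap to mimic occupancy;
* at that bandwidth the occupancy statistic of clean narrow gaps stays below
  ~0.025 while 10%-contaminated gaps sit above ~0.04, so the 0.03 threshold
  separates the two regimes with margin on both sides.

If no developing cohort exists the fish has no hiatus (a result, not an
error); if the limits cannot be placed at all the placement is reported as
ambiguous. On deterministic depletion sequences the detected width is
non-decreasing, matching the field observation that the gap widens as
spawning proceeds.

## PVO fecundity

`pvo_fecundity()` implements F_PVO = OW × OR × OPD_VO — ovary weight (g)
times the oocyte ratio times the vitellogenic oocyte packing density
(oocytes g⁻¹). The packing-density calibration (directly, or as a power law
of mean VO diameter) is stock-specific and must be supplied by the user;
there is deliberately no default, and its absence is an explicit error
rather than a silent fallback.

## Histology metrics

Atresia is consumed as human-scored counts: prevalence is the fraction of
females with any α-atretic oocytes, intensity is
I~α~ = N~i~/(N~i~ + N~j~). Post-ovulatory follicle (POF) number uses
point-count stereology with the study protocol's geometry (a 256-point grid
over ten 6 mm² fields): volume fraction Vv from pooled point counts, profile
density Na from pooled profile counts, and the Weibel–Gómez number density

$$N_v = \frac{k}{\beta}\,\frac{N_a^{3/2}}{V_v^{1/2}}$$

with β = 1.38 (spherical profiles) and k = 1 (narrow size distribution),
both configurable. The protocol names the Weibel method without printing the
estimator, so this standard follicle-counting form is a documented design
choice; the test suite checks it against a brute-force sphere-sectioning
simulation (Poisson spheres, exact plane section, the same grid scoring) and
recovers true number density within ±15%. Fields are pooled before
estimation rather than averaged per field, which is the lower-variance
choice when field counts are small. Whole-ovary POF number is Nv times ovary
volume, converting ovary weight at a specific gravity of 1.0464 g cm⁻³.
POF size (POF_XSA) is the largest cross-sectional area per fish, assuming an
equatorial transection — a documented caveat, not modelled. Recent-spawner
flags use strict thresholds (> 0.10 and > 0.11 mm²).

## Condition and gonadosomatic indices

Length–weight allometry is fitted by OLS on ln-transformed data; the 95% CI
of the exponent is reported as a t-based half-width so the lower limit is
exponent − half-width. Because the ovary dominates weight changes during
spawning, somatic weight (BW − OW) is the preferred response. The default
expected-weight calibration is SW = e^−5.82^·TL^3.23^ (g, cm). Three
condition indices are emitted so users can replicate the standard three-way
comparison: Fulton's K (exponent 3, with the ovary), K_SW (without), and the
relative somatic condition C_SW = SW_obs/SW_exp (unit-consistent under any
unit convention as long as fit and observation share units). GSI uses
OW/TL^3.23^ × 10⁴; the exponent is stock-specific and exposed —
reusing it across stocks or environments calls for re-fitting.

## Validation statistics

Metrics are compared across ORCs with a Kruskal–Wallis test
(tie-corrected, χ² approximation) and, when significant at α = 0.05,
two-sided pairwise Wilcoxon rank-sum tests with Benjamini–Hochberg
adjustment over the k(k−1)/2 family, summarized as a compact letter display
(insert-and-absorb on the adjusted-p matrix). Paired comparisons (e.g.
before/after ultrasonication) use the signed-rank test, exact for ≤ 25
non-zero tie-free differences and the normal approximation beyond. Ties take
mid-ranks throughout; alternatives are two-sided — the source protocol does
not document its choices, so conventional conservative defaults are fixed
here. Under a simulated four-group global null the gatekept procedure's
family-wise error stays at or below nominal.

## The synthetic generator

`simulate_cohort()` draws oocyte diameters from truncated-normal cohorts —
PVO 160 ± 35 µm, developing modes 500 ± 60 and 800 ± 70 µm, hydrated
1300 ± 80 µm — calibrated visually to published spawning OSFDs. Each
component is truncated to its own class window, so realized class counts
equal component counts and intended categories are constructed exactly.
`depletion` scales the developing counts (1 = intact pre-spawning pool,
0 = spawned out); `gap_contamination` and `tail_fraction` inject the
hiatus-occupancy and long-tail phenotypes. The generator and the classifier
share `class_bounds()`, so windows cannot drift apart.

`render_micrograph()` turns diameters into 8-bit micrographs: anti-aliased
dark filled ellipses (axis ratio 0.85–1.0, grey 15–40 on background 230)
placed by dart-throwing without overlap (500 attempts, overflow carried to
extra images), plus concave debris blobs built from crossed elongated lobes
whose roundness falls below 0.8 by construction. Pixel coverage is computed
from the signed distance to the ellipse boundary, which keeps the
threshold-crossing bias below ~0.15 px; measured diameters of isolated
oocytes land within ~1% of ground truth, and mean absolute error stays
within the 2% the detection contract promises.

`simulate_study()` assembles whole-study fixtures: per-fish diameters at
stage-targeted oocyte ratios (mid-category values 0.5/2/8/30 with lognormal
jitter, multinomial draws of 400 oocytes), biometry with a capital-breeder
drawdown (stage median GSI 12/7/3.5/1.5; stage median C_SW
1.05/1.0/0.95/0.9), Poisson POF field counts with an inverted-U number
pattern across stages, decreasing new-POF probability (0.34 → 0.02), and
α-atresia concentrated in early-spawning fish at ~8% overall prevalence.
With the biometry noise set to zero, C_SW reproduces the stage medians
exactly — the generator embeds the drawdown, so condition is 1 only for the
mid-spawning stage, and tests assert the stage value rather than unity.

What the generator does **not** emulate: staining texture and uneven
illumination, oocyte crowding and fusion in PVO-dense samples, nucleus
visibility, atretic morphology in the micrographs themselves, and 3-D ovary
geometry. Passing tests therefore demonstrate that the measurement and
classification chain is correct on well-formed fields, not that segmentation
is robust to every real-world staining artefact; the thresholds' behaviour
on marginal real material still needs the usual manual spot checks.

## Problem sizes and determinism

The test suite favours deterministic oracles (quantile cohorts, exhaustive
sign-flip enumeration, closed forms) and fixed-seed simulations sized for
tight feedback: end-to-end staging recovery uses 20 seeded studies of four
fish (one per category) at 400 oocytes per fish through full rendering and
detection; the detection benchmark uses six scenes of 60 oocytes with
3 debris objects each; the stereology oracle uses 100 sectioning replicates;
the type-I-error simulation uses 2000 replicates of four groups of 18. All
randomness funnels through explicit seeds, and identical seeds reproduce
identical datasets bit for bit.

## Known limitations

* No watershed splitting: heavily crowded PVO fields undercount, as flagged
  by the low-count QC rather than corrected.
* Whether border-touching oocytes should be redistributed rather than
  dropped is unresolved; dropping is unbiased for diameters but loses count
  efficiency on small fields.
* The ORC breaks (1, 3, 15) and all window edges are stock-calibrated
  constants exposed in `class_bounds()`; applying them unchanged to other
  species or stocks is not recommended.
* OR values near a break are classified hard, with no hysteresis for
  measurement noise; fish sitting exactly at a break belong to the lower
  category by definition.
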