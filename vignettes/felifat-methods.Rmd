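---
title: "Methods: CT body-fat quantification and the falciform fat ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT body-fat quantification and the falciform fat ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felifat)
```

## The problem

At routine postmortem examination of cats, the amount of total body fat is
usually judged visually, which makes classifications of overweight and
obesity subjective and evaluator-dependent. felifat implements an
objective alternative built from two measurements:

* **CT body composition.** Whole-body CT resolves fat, lean soft tissue,
  and bone by their attenuation (Hounsfield units, HU). From voxel counts
  the package computes the body-fat percentage (%BF), body-fat volume
  (BFV), total body bone volume (TBBV), and the size-normalized body-fat
  volume nBFV = BFV / TBBV.
* **The falciform fat ratio (FFR).** The falciform fat pad is weighed at
  necropsy (FFPW, g) and divided by femur length (FL, cm, recorded to 2
  decimals). The FFR is a size-normalized adiposity index that needs no
  imaging.

The package links the two: nBFV cutoffs for overweight and obesity are
derived from fat-category medians and mapped through regression onto the
FFR scale, where they support a simple necropsy-room test.

## CT segmentation model

All measurements operate on integer-HU volumes in which everything that is
not part of the animal's body composition has been set to the background
value −1024 HU. Exclusion masks carry that information: label 1 marks the
examination table and external objects, 2 non-aerated lung, 3
gastrointestinal and bladder contents, and 4 dense non-skeletal objects
(microchips, implants, mineralization, calculi). Labels 1–3 are masked for
soft-tissue measurements; label 4 is masked in addition for bone
measurements. Masks are inputs: the variability of gut filling and
postmortem atelectasis defeats simple automated segmentation, so the
package does not attempt it.

Fat and lean are separated inside the soft-tissue window [−250, 250] HU.
The integer-binned frequency histogram of that window is bimodal in
normal-to-obese animals: a fat peak (around −100 HU) and a lean peak
(around +60 HU). The classification threshold is the midpoint of the two
peak locations; voxels at or below the midpoint are fat (the fat interval
is closed at the midpoint, so a half-integer midpoint sends the floor bin
to fat). Bone is every voxel at or above 350 HU after bone-purpose
exclusions. With voxel volume VV = pixel width × pixel length × slice
thickness (cm³; for overlapping reconstructions the effective slice
spacing must be supplied in place of thickness):

$$\%BF = 100 \cdot \frac{n_{fat}}{n_{fat} + n_{lean}}, \qquad
BFV = n_{fat} \cdot VV, \qquad TBBV = n_{bone} \cdot VV, \qquad
nBFV = \frac{BFV}{TBBV}.$$

nBFV is dimensionless and exactly invariant to isotropic voxel rescaling,
which is why it travels well across scanners and reconstruction settings,
and — unlike %BF — it is not distorted by muscle atrophy or hypertrophy,
because its denominator is bone rather than lean tissue.

### Peak detection

How the two tissue peaks are "identified" is a methodological gap in the
source procedure (plausibly done by eye). felifat fixes a deterministic
rule, with every parameter exposed:

* counts are smoothed with a centred moving average, window 11 HU;
* local maxima are kept if their topographic prominence is at least 0.2%
  of the total in-window count (`min_prominence_frac = 0.002`);
* retained peaks must be at least 30 HU apart (`min_separation`); the two
  tallest survivors, ordered by HU, are the fat and lean peaks.

The prominence floor was set from the two scales it must separate: a
genuine fat compartment of 10–15% of soft tissue contributes a smoothed
peak on the order of 0.5% of the total count (Gaussian spread of SD ≈ 10
HU puts roughly 4% of a compartment in its modal bin), whereas smoothed
counting fluctuations sit one to two orders of magnitude below 0.2%. A
stricter floor (for example 1% of total) silently misses real fat peaks in
lean animals; 0.2% keeps them while still rejecting noise. When fewer
than two maxima qualify — the typical underweight pattern — the package
raises a classed error (`felifat_error_undefined_fat_peak`) instead of
guessing a threshold, and `run_pipeline()` records such animals as
excluded, which mirrors how underweight cats drop out of CT fat estimation
in practice.

## Cutoffs and diagnostic performance

The lower nBFV cutoff for overweight is the midpoint of the median nBFV of
normal-weight and overweight animals; the obesity cutoff is the midpoint
of the overweight and obese medians (`derive_nbfv_cutoffs()`). Medians of
even-sized groups average the two central order statistics. Cutoffs are
then chained through fixed reference regressions
(`reference_fits()`):

* ln(FFR) = −1.459 + 1.356 · ln(nBFV), giving FFR cutoffs
  exp(−1.459 + 1.356 · ln x);
* %BF = 10.697 + 3.655 · nBFV (estimated with muscle-atrophic and
  -hypertrophic animals excluded), giving %BF cutoffs by direct
  evaluation.

With the reference nBFV cutoffs 4.180 and 7.322 this yields FFR 1.6
(overweight) and 3.5 (obesity) after rounding to 1 decimal — the scale on
which classification operates. Classification uses left-closed intervals:
FFR ≥ 3.5 is obese, 1.6 ≤ FFR < 3.5 overweight, anything lower
`not_overweight` (the FFR cannot separate normal from underweight, and no
underweight animal in the validation cohort reached 1.6). A borderline
FFR of exactly 1.6 therefore classifies as overweight, and exactly 3.5 as
obese. Note the reference %BF cutoffs evaluate to 26.0 and 37.5 under
this chaining; the package reports what the equations give.

Diagnostic performance against the visual fat category is tallied as a
2×2 table per condition — for obesity, disease-positive means visually
obese and test-positive FFR ≥ 3.5; for overweight, disease-positive means
visually overweight and test-positive FFR in [1.6, 3.5) — with
sensitivity tp/(tp+fn), specificity tn/(tn+fp), and two-sided
Clopper–Pearson exact binomial 95% intervals (via `stats::binom.test`;
the test suite checks the endpoints against a brute-force tail-test
inversion on a 10⁻⁴ probability grid). Values are banded low (< 0.5),
moderate (0.5–0.69), high (0.7–0.89), and very high (0.9–1), left-closed.

FFR values are kept at full precision internally; the reporting
convention is 1 decimal (`round_ffr()`), with all rounding
half-away-from-zero, matching how measurement devices print. An FFPW of
0 g (below scale resolution) is a valid observation, kept and flagged
rather than treated as missing.

## Cohort statistics

`correlate()` fits ordinary least squares and reports Pearson r, r², and
the slope's two-sided p. With `transform = "auto"` a Shapiro–Wilk check
of the residuals at α = 0.05 decides whether both variables are
natural-log transformed before refitting; the source procedure states
only that a log transform was applied when normality or constant-variance
checks failed, so the test and level are declared here rather than
inferred. `compare_fc_groups()` is the Kruskal–Wallis rank test with tie
correction (`stats::kruskal.test`) followed by Dunn's pairwise z tests on
mean ranks. The Dunn variance uses the standard tie-corrected form
N(N+1)/12 − Σ(t³−t)/(12(N−1)), and the family correction is
Bonferroni across all retained pairs — the exact multiplicity variant in
the original SigmaPlot analysis is unstated, so the most conservative
standard choice is fixed and documented. Groups below `min_n = 4` are
dropped with a warning before testing, as tiny groups (typically the
underweight category, thinned by fat-peak exclusions) contribute unstable
medians.

## What the phantom generator emulates

`generate_phantom()` builds a synthetic cat CT study with exact ground
truth: an ellipsoidal soft-tissue body, a cylindrical spine-like bone
column sized to ~5% of the body (putting nBFV in the observed feline
range), fat and lean voxels interleaved by seeded sampling to hit a target
fat fraction within ±0.01, optional excludable contents (lung, GI/bladder,
implant) and a table slab, Gaussian HU noise rounded half-away-from-zero
to integer HU, and background air at exactly −1024 HU.

Defaults, chosen once to emulate the validation study's conditions:

| parameter | default | why |
|---|---|---|
| body extent | 64³ voxels | smallest grid whose compartments give stable histograms |
| voxel spacing | (0.35, 0.35, 0.45) cm | a ~4.5 kg body; BFV spans the observed 375–3,790 cm³ |
| fat / lean / bone HU | −100 / +60 / +600 | textbook attenuation; feline-specific values are unpublished |
| HU noise SD | 10 | realistic soft-kernel CT noise |
| lung HU | −30 | atelectatic lung attenuates between the fat and lean peaks, which is exactly why it must be excluded |
| GI contents HU | +20 | fluid-range, corrupts the lean count if unmasked |
| `ffpw_slope` | 0.024 g/cm³ | mean FFPW 34 g at mean BFV 1,410 cm³ |
| `ffpw_noise_sd` | 9.5 g | puts the analytic FFPW–BFV correlation at r ≈ 0.888 under default cohort settings |
| `fl_base` | 11.4 cm | mean feline femur length; FL scales linearly with phantom size |

`generate_cohort()` draws target fractions uniformly over a requested
range, jitters body size by ±15% (so FL and TBBV covary), rounds FFPW to
integer grams with a floor at 0 g (below-scale weights are kept and
flagged), rounds FL to 2 decimals, and assigns a visual fat category from
the true fat fraction via fixed bands (< 0.15 underweight, < 0.27 normal,
< 0.40 overweight, else obese — loose analogues of the %BF cutoffs, used
only to exercise the agreement machinery). Compartment counts are
deterministic given the spec, so `voxels = FALSE` returns identical truth
and records without synthesizing HU volumes, which keeps large
record-level simulations cheap. Each cat draws from a substream derived
from the cohort seed, so cohorts are bitwise reproducible and stable
under subsetting.

The phantoms deliberately do **not** model scanner physics: no partial
volume averaging, beam hardening, or anatomical realism. Passing recovery
tests on phantoms therefore demonstrates that the computational chain is
correct and unbiased under its own assumptions — clean bimodal mixtures
with known truth — not that segmentation is accurate on real animals,
where partial-volume voxels and imperfect manual masks add errors the
generator does not imitate.

## Numerical choices and degenerate inputs

* HU are stored as integers after rounding half-away-from-zero, because
  CT data are integer HU and the histogram is integer-indexed.
* A phantom spec whose fat/lean means are closer than 6 noise SDs is
  rejected unless explicitly flagged `degenerate = TRUE`; bone means must
  sit at least 3 SDs above 350 HU.
* `compute_composition()` raises classed errors on empty compartments
  (no soft tissue, or no bone) instead of returning NaN.
* Cutoff sets require overweight < obese on the nBFV scale and preserve
  that ordering on every derived scale.
* Reproducing the reference nBFV cutoffs 4.180/7.322 exactly requires the
  unrounded per-animal medians; from the rounded published medians (2.7,
  5.6, 9.0) the same rule gives 4.15/7.30. The package computes from
  whatever values it is given and does not adjust toward either pair.

## Problem sizes in the test suite

The suite validates parameter recovery end-to-end on 64³-voxel phantoms
(target fat fractions 0.15–0.60, five seeds each, %BF recovered within 2
percentage points), uses 32³ phantoms for unit-level checks, 200
simulated 39-animal cohorts for regression-coefficient recovery, 300
replicates for Kruskal–Wallis/Dunn behaviour at the observed group effect
sizes, and exhaustive enumeration (all k ≤ n ≤ 12) for the exact-interval
oracle. The full suite runs in well under a minute.

## Known limitations

* Exclusion masks are trusted as given; there is no automated organ
  segmentation and no mask-quality check.
* The FFR cannot distinguish normal from underweight animals, and its
  cutoffs were derived from one cohort's medians; other populations may
  need re-derivation (`cutoff_mode = "derived"` in `run_pipeline()`).
* At the observed group effect sizes, Dunn comparisons between adjacent
  fat categories have replicate-level power around 0.8, so "all pairs
  significant" should not be expected in every re-analysis of a cohort
  this size.
* The %BF cutoffs obtained by chaining (26.0 / 37.5) are what the
  reference equation yields at the reference nBFV cutoffs; they are
  reported as computed.
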