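---
title: "Imaging-based prescreening for geographic atrophy trials: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging-based prescreening for geographic atrophy trials: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gascreenr)
```

## The problem

Clinical trials in geographic atrophy (GA) select participants on imaging
features: the atrophic lesion's area must fall in a trial-specific range
(e.g. 1.25–17.5 mm² inclusive for the HORIZON-style rule set shipped with
this package), choroidal neovascularization (CNV) may be exclusionary in
the study eye or either eye, and some trials restrict the lesion's position
relative to the fovea. A keyword search of clinical letters can flag
patients whose records *mention* GA, but cannot check any of these imaging
criteria; most flagged patients fail screening. An imaging-based pipeline
evaluates the criteria directly on routinely collected OCT, and a
stratified validation design quantifies how much better it does.

`gascreenr` implements that pipeline — lesion quantification, fovea
localisation, location classification, a declarative eligibility engine,
the EHR keyword search, and the validation statistics — together with a
synthetic-cohort generator that plants the ground truth every stage is
tested against.

## Lesion area from RPE absence

GA is operationalised as loss of the retinal pigment epithelium (RPE). The
input is a per-eye boolean en-face map of RPE presence on the scan grid
(one row per B-scan, one column per A-scan). The atrophy mask is its
complement, and

$$A_{AI} = n_{absent} \cdot \frac{w}{n_{ascans}} \cdot \frac{h}{n_{bscans}} \; \mathrm{mm}^2$$

for a $w \times h$ mm field. Two numerical choices matter:

- **Speckle filter** (`min_component_mm2`, default 0.05 mm²). Columnwise
  RPE absence is noise-sensitive; isolated dropouts would otherwise count
  as atrophy. Connected components (4-connectivity) smaller than the
  threshold are discarded before summation. The threshold sits well below
  the smallest plantable lesion (0.25 mm²) and well above single-pixel
  noise (~0.00055 mm² on the default grid), so it is insensitive over two
  orders of magnitude.
- **Diagnosis gating.** The GA flag from the (stand-in) classification
  network gates *eligibility*, not the computation: the area is always
  computed, mirroring a two-step confirm-then-quantify order.

Component labelling is done by run-length encoding each row and merging
overlapping runs of adjacent rows with union–find — linear in pixels, with
no dependence on an image-processing package (none that provides labelling
is available in the supported dependency set).

## Fovea localisation and location criteria

Scans are fixated on the preferred retinal locus, which in macular disease
need not coincide with the anatomical fovea, so the fovea must be found,
not assumed at the grid center. The exact production algorithm is not
public; the surrogate here is deliberately simple and reproducible:

1. smooth the neurosensory-retina thickness map with a separable Gaussian
   (default $\sigma$ = 0.25 mm; the kernel is built per axis because row
   pitch is ~4× column pitch on the default 128×512 grid over 6×6 mm);
2. take the argmin within the central 50% window of the grid (the pit is a
   macular feature; the window excludes peripheral thinning artefacts);
3. break ties to the smallest (row, col) lexicographically; a constant map
   returns the window center with a warning.

Location criteria follow the trial definitions: *central* GA means some
atrophic pixel center lies within 1500 µm (Euclidean, anisotropic pitch
respected) of the fovea pixel center; *fovea-involving* GA means the fovea
pixel itself is atrophic. Pixel-presence distance is used rather than
subpixel boundary distance — at the default pitch the difference is below
one B-scan spacing (46.9 µm). `fovea_involving` implies `central_ga` by
construction, and a zero-area profile forces both flags false.

## Eligibility engine

`trial_criteria()` encodes a rule set: optional age bounds (the lower
bound's operator is part of the config — the shipped HORIZON file uses
strict "> 55"), inclusive area bounds, study-eye and fellow-eye CNV
exclusions, and the two location requirements. Each eye is evaluated as
the study eye with the other as fellow; a patient qualifies through either
eye. When fellow-eye data are missing and a fellow-eye rule is enabled, the
default policy is strict (ineligible), configurable to lenient. Only the
HORIZON numbers are fully public; the DERBY/GATHER2/Janssen configs encode
the structural differences that are public (a 2.5 mm² area floor,
fellow-eye CNV exclusions, central and non-fovea-involving location
requirements) with placeholder values and are marked `"unverified"` in the
JSON.

Three shortlisting modes mirror the screening strategies compared:
`ai` (≥ 1 eligible eye), `ehr` (keyword match), and `combined` (imaging
criteria applied to the EHR-matched patients, i.e. the intersection).

## EHR keyword search

A plain case-insensitive substring search for "geographic atrophy" after
whitespace normalisation — no stemming, no negation handling, by design
(the method being modelled is a plain keyword search). The earliest
matching letter's date flags all scans on or after that date; the same-day
boundary is inclusive because letters follow the visit that produced the
scan.

## Validation statistics

Patients flagged by either route fall into three disjoint strata:
A1 (AI ∩ EHR), A2 (AI only), B1 (EHR only). A validation sample of size
$n_s$ from stratum $s$ yields $x_s$ truly eligible patients, giving
$\widehat{PPV}_s = x_s/n_s$ with a percentile-bootstrap CI (binomial
resampling of the graded outcomes; default 10 000 resamples, seeded).
Sampling eligibility requires an FAF image within 90 days of the OCT for
both eyes, inclusive at exactly 90.

The expected eligible yield of a shortlist is the stratified weighted sum
$\widehat{E} = \sum_{s} N_s \widehat{PPV}_s$ over the strata the shortlist
covers (AI: A1+A2; EHR: A1+B1; combined: A1), and the rate divides by the
shortlist size $\sum_s N_s$. The CI resamples each stratum's outcomes
independently and propagates through the sum, matching the stratified
design. When the validation is a census ($n_s = N_s$), the estimate equals
the true eligible count exactly — this closure property is asserted in the
tests. Percentages are reported half-up to whole percents alongside the
unrounded values; rounding never enters machine outputs.

Agreement between two area measurements uses Bland–Altman limits
($\bar d \pm 1.96\, s_d$, $s_d$ with $n-1$ denominator) and the
single-measure absolute-agreement ICC from the two-way decomposition

$$ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},$$

with a subject-level bootstrap CI. The agreement (not consistency) form is
used, so a constant inter-rater bias lowers the coefficient; a zero
between-subject-variance matrix reports 0 with a warning. Group
comparisons use a two-sided bootstrap under a null of zero difference:
mean comparisons shift both groups to the pooled mean and resample;
proportion comparisons resample from the pooled data; the p-value carries
a $+1/(B+1)$ continuity adjustment so it is never exactly 0. All bootstrap
routines draw from named substreams of a single master seed, so each stage
is independently reproducible.

## The synthetic generator's stated world

`cohort_config()` fixes the world the tests live in:

| parameter | default | why |
|---|---|---|
| grid | 128 × 512 over 6 × 6 mm | typical Topcon macular cube |
| lesion area | log-normal, median 8.5 mm², truncated [0.25, 35] | matches the shortlisted population's reported median area and exercises every trial's bounds |
| lesion shapes | disc, ellipse, ring, multifocal | spans the location-criterion cases |
| foveal pit | depth 120 µm, σ 0.35 mm on a 250 µm baseline, 5 µm noise | recoverable but non-trivial signal for fovea search |
| misfixation | uniform ± 0.75 mm per axis | preferred retinal locus ≠ anatomical fovea |
| speckle noise | 10 isolated absent pixels/eye | exercises the speckle filter |
| graders | bias ± 0.3 mm², sd 1.5 mm² | non-trivial Bland–Altman/ICC surfaces |
| keyword rate | 0.6 given GA, 0.02 otherwise | letters under-report GA; EHR search has false positives |
| FAF offsets | uniform ± 120 days | both sides of the 90-day window occur |
| prevalence GA/CNV/drusen | 0.35 / 0.15 / 0.40 | GA-enriched screening clinic mix |

Planted areas are recorded as the *rendered* pixel-counted area, so
field-of-view clipping of large lesions never breaks ground-truth
consistency; rasterisation error is bounded by one boundary-pixel band
(`rendering_tolerance_mm2()`), and the conservation property is tested for
every shape.

What the generator does **not** emulate: raw B-scan voxels, FAF images,
segmentation-network failure modes (beyond speckle), peripapillary
atrophy, or classification errors in the GA/CNV flags. A green test
therefore establishes that the *post-segmentation* pipeline is correct and
internally consistent — not that any segmentation network is accurate.
Likewise, because the synthetic "validation graders" for the census
closure are the planted truth, synthetic PPVs are near 1 by construction;
realistic PPV levels enter through the published-table worked examples,
not the simulator.

## Numerical choices and degenerate inputs

- Areas serialise at 4 decimals; dates ISO-8601; laterality "L"/"R";
  decimal separator fixed (locale-independent).
- Percentile bootstrap throughout (not BCa): with 10 000 resamples and the
  sample sizes involved, the simpler estimator is adequate and matches the
  method description being modelled.
- Degenerate cases: zero-sized geometry, negative areas, inverted area
  bounds, empty validation samples, constant rating matrices and constant
  thickness maps all error or warn explicitly rather than returning silent
  values.
- Bootstrap resample counts are scaled down (100–2000) inside the test
  suite and pipeline defaults to keep runtimes in seconds; the statistical
  functions default to the reference 10 000.

## Known limitations

- The fovea surrogate is not the production algorithm; it recovers planted
  pits within 3 px in ≥ 95% of well-fixated synthetic eyes (tested), but no
  claim is made about diseased real-world thickness maps with disrupted
  pits.
- Non-HORIZON criteria values are placeholders pending the trials' full
  public specifications.
- Lesions extending beyond the field of view are measured as clipped; no
  extrapolation is attempted.
- The published eligible *counts* are not asserted anywhere: the exact
  weighted sums differ from the printed counts by 1–2 patients, so only
  whole-percent rates are reproduced.
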