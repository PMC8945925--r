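---
title: "Quantifying early metabolic response and tumor burden from FDG-PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying early metabolic response and tumor burden from FDG-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petburden)
```

## The problem

Patients with advanced EGFR-mutant lung adenocarcinoma receive tyrosine
kinase inhibitors as first-line therapy, but a substantial minority do not
respond, and CT often cannot show this early because the drugs are largely
cytostatic. FDG-PET measures glucose metabolism directly: an effective drug
suppresses tumor uptake within days to weeks, well before any structural
change. The workflow this package implements asks whether a PET scan taken
about two weeks into therapy — compared against the pretreatment scan —
predicts (a) non-progression on the 3-month CT (RECIST 1.1), and (b)
progression-free and overall survival.

Two families of PET read-outs are computed. The PERCIST 1.0 categorical
response uses only the single hottest lesion per scan. The tumor-burden
metrics sum SUL~max~, metabolic tumor volume (MTV) and total lesion
glycolysis (TLG) over up to five target lesions, capturing how much
metabolically active tumor there is and how much of it disappears.

## SUL quantification and thresholds

All intensities are SUL — standardized uptake value normalized to lean body
mass: `SUL = activity [MBq/g] / (dose [MBq] / LBM [g])`. Lean body mass is
computed with the Janmahasatian formula by default (`lean_body_mass()`); the
James formula is available behind a flag. The source imaging protocol never
states which formula its workstation used, so the choice is pinned here for
reproducibility, and because the synthetic pipeline passes SUL volumes
directly, the choice does not propagate into any other result.

Normal liver defines the reference background: mean `mu` and sample (n−1)
standard deviation `sigma` of SUL in a 3-cm-diameter sphere placed in
disease-free liver (`liver_background()`). From it:

* **measurability gate** `1.5*mu + 2*sigma`: a lesion is analyzed only if
  its SUL~max~ reaches this. We read the rule as `1.5*mu + 2*sigma` rather
  than `1.5*(mu + 2*sigma)` — the wording is genuinely ambiguous, but the
  former is the PERCIST 1.0 reading; the alternative grouping is exposed as
  `measurability_parse = "grouped"` for sensitivity analyses.
* **segmentation threshold** `mu + 2*sigma`: the lower bound of the lesion
  volumes of interest.

## Lesion segmentation and target selection

`find_lesions()` takes the 26-connected components of voxels at or above
the segmentation threshold (blob-like PET lesions make face-edge-corner
connectivity the natural choice; it is pinned so results are exactly
reproducible), drops components failing the measurability gate, and
computes per lesion: SUL~max~, SUL~mean~, `MTV = n_voxels x voxel volume`
and `TLG = SUL_mean x MTV`. The last two identities hold exactly by
construction and the tests assert them exactly. A voxel belongs to a region
(lesion ellipsoid, liver sphere, VOI) if and only if its center does; world
coordinates are mm with 0-based voxel indices — one unambiguous
voxelization rule used everywhere.

"Hottest" ordering is by descending SUL~max~ with deterministic tie-breaks
(larger MTV, then smallest centroid lexicographically). Target selection
(`select_targets()`) scans in this order, skipping lesions whose organ
already holds two targets, stopping at five. Greedy selection here is
provably optimal in the lexicographic sense (the constraint is a partition
matroid), and the test suite checks it against a brute-force subset
enumeration oracle on random instances.

Organ granularity is whatever the label map encodes — paired organs are
distinct labels; the map externalizes a decision the source protocol leaves
to the reader. Physiologic-uptake organs (brain, bladder) can be excluded
via `exclude_labels`; phantoms default to none.

## Response assessment

`classify_percist()` implements the category rules with precedence: a new
lesion always means progressive metabolic disease (PMD); otherwise a rise
of the hottest-lesion SUL by more than 30% is PMD; complete resolution of
measurable uptake is CMR; a drop of at least 30% is PMR; anything else is
SMD. The boundaries are exactly −30% (PMR) and +30% (SMD, not PMD). The
percentage-only rule is the default because that is how the analysis this
package reproduces was run; `strict_percist = TRUE` adds PERCIST's
0.8-SUL-unit absolute-change requirement. CMR is operationalized as "no
measurable lesion on follow-up" — complete resolution needs a computable
form.

For burden change, the baseline targets are re-identified on the follow-up
scan by greedy nearest-centroid matching (`match_lesions()`, 20 mm default
radius, organ label must agree) — a deterministic proxy for the human
re-identification the protocol assumes. The follow-up sums run over matched
lesions only; a resolved lesion contributes zero (`matched_target_set()`).
Whether the original analysis re-selected the hottest follow-up lesions or
tracked the baseline ones is not decidable from its description; "measured
the same five lesions" points to tracking, which is what we adopt. An
important consequence, visible in the worked demo: a lesion that falls
below the measurability gate contributes zero even though some faint uptake
remains, so `DsumMTV` can be a large negative number while the voxels are
merely dimmed.

## The phantom generator

`make_phantom()` builds the SUL substrate the quantification stages are
validated on: uniform background (default 0.5 SUL), a spherical liver with
voxel values drawn from `N(2.2, 0.3)` — typical normal-liver SUL — and
ellipsoidal lesions with a uniform plateau at `peak_sul`. The plateau
profile is chosen for testability: SUL~mean~ equals the plateau and MTV
equals the voxelized ellipsoid volume, so every metric has a closed-form
truth. Real tumors are heterogeneous; nothing is claimed about texture, and
a Gaussian falloff profile (half the peak at the boundary) exists behind a
flag for threshold-monotonicity tests. Noise is additive Gaussian clamped
at zero, keeping SUL non-negative. `make_followup()` scales each lesion's
peak by a non-negative response factor (0 = complete resolution) and can
inject new lesions, giving ground-truth correspondences for the matching
stage.

What passing phantom tests shows: the thresholds, connectivity, metrics,
selection, matching and classification rules are implemented exactly. What
it does not show: robustness to scanner physics (no point-spread function,
scatter, attenuation or motion is modeled — deliberately out of scope) or
to real intratumoral heterogeneity.

## The cohort generator

`make_cohort()` simulates the statistical structure the outcome stage is
exercised on. Defaults are the study conditions:

* n = 30 patients; dCt (the mutant-allele delta cycle threshold, cycles)
  normal with mean 5, SD 2, putting a realistic fraction above the
  prognostic boundary of 6 cycles.
* log baseline sumMTV centered on log(40 cm³) with coupling
  `burden_link = 0.25` to dCt — positive coupling reproduces the observed
  positive Spearman correlation between dCt and baseline burden.
* 70% metabolic responders; the 3-month non-progression label is logistic
  with `logit P(nPD) = logit(4/9) + log(25) x responder`, i.e. the
  responder and non-responder non-progression rates (20/21 and 4/9) and the
  odds ratio of 25 reported for the real cohort.
* event times from a proportional-hazards model over the dichotomized
  predictors (dCt ≥ 6, bsumMTV ≥ 40 cm³, DsumMTV ≥ −60%), with log-HRs
  ln(4.85) and ln(5.60) on PFS and ln(9.84) and ln(13.1) on OS — the
  reported multivariate effect sizes. The baseline (all-predictors-zero)
  distribution is exponential with median 12 months for PFS and 25.3 for
  OS: `median = ln 2 / lambda` gives closed-form expectations for KM
  tests, and a Weibull shape is available behind a flag. Because the
  reference group carries the stated median, a cohort with positive
  effects has a shorter marginal median than the scale parameter — the
  generator makes the reported medians exact for the reference group, not
  marginally.
* independent uniform censoring on [0, 33] months, emulating a
  fixed-horizon follow-up without modeling accrual.

## Statistics stage

Standard machinery is delegated: `survival` for KM, log-rank and Cox
(Efron ties), `stats` for Mann-Whitney (exact enumeration when both groups
are ≤ 10), chi-square with a Fisher fallback when any expected cell is
below 5, logistic regression and Spearman correlation, `pROC` for ROC/AUC.
The package authors the parts specific to this workflow:

* `confusion_metrics()` / `odds_ratio()`: direct enumeration with Woolf
  intervals; undefined metrics (zero denominators) are `NA`, never 0.
* `km_fit()`: the median is the first time S(t) ≤ 0.5 (the flat-region
  midpoint some software reports is not used); CIs are the inverted-band
  construction.
* `optimal_cutoff()`: the median-outward search. Candidates are the
  distinct observed marker values; starting from the value closest to the
  median, the search steps alternately to the next distinct value above
  and below, evaluating the log-rank p of `< c` vs `≥ c`, and returns the
  most significant eligible cutoff. Eligibility requires both groups to
  hold at least 15% of the cohort (`min_group`) — a floor, not in the
  original description, that prevents one-patient groups on a 30-patient
  cohort; it is exposed as a parameter. Ties in p keep the cutoff closest
  to the median. Because the search visits every eligible candidate, its
  result provably equals exhaustive minimization; the tests assert this
  against an independent exhaustive oracle anyway.
* Cox and logistic fits convert non-convergence, monotone likelihood and
  separation into explicit errors rather than returning divergent
  estimates.

No multiple-testing correction is applied anywhere, matching the analysis
being reproduced; with ~14 predictors screened univariately on 30
patients, the per-comparison p values should be read accordingly.

## Problem sizes and numerical choices

The test and acceptance workloads use: 48³–64³ voxel phantoms at 2 mm
spacing (a 10 mm sphere then holds ~524 voxels, and voxelization error
stays within 15% of the analytic volume); 200 random instances for the
selection oracle; 100 cohorts of n = 60 for the cutoff search; 200
replicates of n = 500 for Cox recovery; 400–500 replicates at n = 30–40
for type-I calibration. Percentages are carried at full precision
internally and rounded to one decimal only when a report is serialized;
SUL values serialize at two decimals.

## Limitations

* SUL~max~ is used for hotness, as in the analysis being reproduced;
  SUL~peak~ (1.2-cm sphere average) is known to be more reproducible and is
  not implemented.
* No DICOM ingestion, no image registration: baseline and follow-up grids
  are assumed rigidly aligned, and matching is centroid-based.
* The RECIST 3-month label is an input; CT measurement is out of scope.
* The phantom emulates measurement geometry, not emission physics; results
  on real scanners additionally depend on reconstruction and partial-volume
  effects that are not modeled.
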