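---
title: "Methods: quantifying and comparing amyloid and tau PET patterns in TBI cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and comparing amyloid and tau PET patterns in TBI cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbipet)
```

# The scientific problem

Traumatic brain injury (TBI) is an established dementia risk factor, but
whether it promotes the hallmark Alzheimer's disease proteinopathies —
amyloid-β plaques and tau neurofibrillary tangles — is unresolved. Because
head trauma produces spatially heterogeneous damage, the interesting
question is not only *how much* amyloid and tau a person with a TBI history
accumulates, but *where*: does a TBI history push the spatial pattern of
PET signal away from the stereotypical temporo-parietal Alzheimer topography,
and does it change the regional coupling between amyloid and tau?

`tbipet` implements an end-to-end, testable pipeline for this question in
an aging veteran cohort design with three groups — no TBI, mild TBI, and
moderate/severe TBI — measured with amyloid PET and tau PET over a
200-region cortical parcellation:

1. **Quantification** (`extract_roi_suvr`, `compute_global_suvr`,
   `classify_abeta`): regional standardized uptake value ratios (SUVRs)
   from labelled uptake volumes, global burden, amyloid positivity.
2. **TBI classification** (`classify_event_severity`,
   `classify_subject_tbi`, `reconcile_events`): rule-based severity
   grading of interview-reported head injuries.
3. **Cohort statistics** (`anova_oneway`, `tukey_hsd`, `fisher_exact_2x2`,
   `chi_square_independence`, `two_sample_t`, `ancova_global`):
   demographics and global-burden group comparisons.
4. **Regional contrast maps** (`roiwise_ancova`, `fdr_bh`): ROI-wise
   group differences adjusted for global burden, with Benjamini–Hochberg
   false-discovery-rate control.
5. **Tau epicenters** (`rank_rois`, `select_epicenters`,
   `epicenter_probability`): per-subject top-SUVR regions mapped to
   group-level probabilities.
6. **Coupling moderation** (`roiwise_interaction`,
   `summarize_significant`): ROI-wise amyloid-by-group interactions on
   tau.

Because subject-level PET data of this kind are access-controlled, the
package ships a first-class synthetic-cohort generator
(`sim_config()`/`generate_cohort()`) whose defaults encode the published
cohort's summary structure, so every estimator can be validated against
known injected ground truth.

# The generative model

For subject $i$ in group $g$ and ROI $r$, the generator draws

$$A_{ir} = \mu_A + a_i + \delta_A(g, r) + \epsilon_{ir}, \qquad
  T_{ir} = \mu_T + t_i + \delta_T(g, r) + \beta(g, r)\,(A_{ir} - \mu_A) + \eta_{ir},$$

with $(a_i, t_i)$ correlated per-subject latent global levels,
$\delta$ the per-group regional offset templates, $\beta(g,r)$ the
regional amyloid-to-tau coupling slopes, and iid Gaussian ROI noise
$\epsilon, \eta$. This additive Gaussian form is the simplest model that
matches mean ± SD reporting of global SUVRs while exposing exactly the
three effect families the downstream analyses target: global shifts
(latent levels), regional pattern differences (offsets), and coupling
moderation (slopes).

## Defaults and their rationale

| Parameter | Default | Why |
|---|---|---|
| `group_sizes` | 38 / 40 / 25 | published cohort sizes (no / mild / moderate-severe TBI) |
| `n_rois` | 200 | resolution of the cortical parcellation used throughout |
| `baseline_abeta_mean`, `baseline_tau_mean` | 1.12, 1.08 SUVR | published global means |
| `subject_global_sd` | 0.15 (amyloid), 0.08 (tau) | published global SDs; the tau value is the latent component only — coupling propagates amyloid variance into tau, so the realized global tau SD is $\sqrt{0.08^2 + (0.3\cdot 0.15)^2} \approx 0.09$ as published |
| `global_correlation` | 0.3 | modest amyloid–tau global correlation so "global-adjusted" models face realistic collinearity |
| `roi_noise_sd` | 0.05 SUVR | regional measurement noise at a scale that keeps ROI SUVRs positive and group effects of 0.05–0.10 SUVR detectable at these sample sizes |
| offset template | temporal tau +0.12 (all groups); fronto-parietal amyloid +0.04 (mild) / +0.08 (moderate-severe); frontal tau +0.06 (moderate-severe) | reproduces the qualitative findings the pipeline is designed to detect: temporal epicenters everywhere, stepwise fronto-parietal amyloid elevation, frontal tau elevation in moderate/severe TBI |
| coupling template | 0.3 everywhere | positive amyloid–tau coupling with no group moderation (a clean interaction null) |
| covariates | per-group age, APOE ε4, MCI and scan-lag distributions from the published demographics table | |
| `missing_apoe_count` | 0 / 3 / 2 | the published APOE missingness split, yielding the 98 complete cases used by all APOE-adjusted models |

Synthetic lobe labels (ids 1–50 frontal, 51–90 parietal, 91–140 temporal,
141–200 occipital/other) are a deterministic stand-in for atlas lobe
metadata; they make "frontal" or "temporal" injections reproducible
without shipping atlas files.

## What the generator does *not* emulate

No spatial autocorrelation between neighbouring ROIs, no longitudinal
accumulation, no connectome-mediated spreading, no off-target tracer
binding, no realistic anatomy in the voxel phantoms (ROIs are cubic
blocks). Passing tests therefore demonstrate the *estimators* are correct
and calibrated under the declared model — not that real PET data satisfy
that model.

# TBI severity classification

Severity follows military/veterans-affairs-style guideline rules on three
interview fields per event: loss of consciousness (mild ≤ 30 min;
moderate > 30 min and < 24 h; severe > 24 h), alteration of consciousness
(mild < 24 h; moderate/severe > 24 h) and post-traumatic amnesia (same
cut). An event is moderate/severe when **any** field reaches a
moderate/severe category; a reported event with no qualifying symptom
duration grades mild. Subject-level status is the worst included event;
events dated after the tau-PET scan are excluded before anything is
counted. The amnesia moderate (>1 day) vs severe (>7 days) distinction is
deliberately collapsed into one moderate/severe bucket, mirroring
interview instruments that top-code amnesia at >1 day.

Interview reconciliation (`reconcile_events`) resolves internal
contradictions with a fixed precedence — explicit year > year derived
from age and birth year > reported period bucket — because calendar years
are the least ambiguous field. The period is corrected from the winning
year against a configurable service window (default 1964–1975); every
adjustment is logged, and rows with no recoverable timing are flagged
unresolvable and excluded from frequency counts rather than dropped
silently.

# Statistical design choices

Several choices were genuinely open and are recorded here as package
decisions:

* **Post-hoc procedure**: Tukey HSD on the studentized range. This is an
  inference, not something the source reporting states: the published
  pairwise CI (−2.13, −0.67) is numerically consistent with Tukey
  intervals computed from the group summaries. The procedure stays
  configurable through its `alpha` and pair arguments.
* **Two-sample t**: pooled-variance Student t by default (the plain
  reading of "two-sample t-test"); Welch via `var_equal = FALSE`.
* **Odds ratio**: the conditional maximum-likelihood estimator from the
  exact test (5.50 on the MCI-by-TBI table), not the sample cross-product
  ratio (5.67 on the same table). Both are surfaced in the result row.
* **Global SUVR**: unweighted mean over the 200 ROIs, because it is
  reproducible when an analysis starts from ROI tables without voxel
  counts; a volume-weighted variant is available by passing weights.
* **Reference region**: not grey-matter-masked (atlas ROIs are), since
  cerebellar reference regions conventionally include white matter.
* **Amyloid positivity cutoff**: default 1.11 global SUVR. This is an
  implementer default standing in for externally calibrated cohort
  cutoffs — it is configuration, and a subject exactly at the cutoff is
  positive (a boundary rule one must simply fix and document).
* **Covariate sets**: global models adjust for age, cognitive diagnosis,
  APOE ε4 and the PET-to-diagnosis lag (the tau model also for global
  amyloid and the amyloid-to-tau scan lag); regional models adjust for
  age, APOE ε4 and the same-tracer global level (tau additionally for
  the ROI's amyloid SUVR and the scan lag) — diagnosis deliberately
  appears only in the global models, following the described methods
  verbatim. Listwise deletion handles missing APOE.
* **Pairwise fits**: each regional contrast refits the model on the
  two-group subset (complete-case n = 75 / 61 / 60), rather than taking
  contrasts inside a three-group model; the per-pair residual degrees of
  freedom (70/56/55 for amyloid; 54/53 for tau) are the checkable
  consequence.
* **FDR family**: the 200 ROIs of one contrast-by-modality map, not
  pooled across maps, matching per-map reporting. Rejection is `q <
  level` (strict).
* **Epicenters**: `k = round(0.10 · N)` with a floor of 1 (halves round
  up); ties in the SUVR ranking break by ascending ROI id so results are
  deterministic; maps use raw SUVRs without covariate adjustment.
* **Moderation sign convention**: the less severe group of each pair is
  the reference level, so positive interaction t-values always mean
  stronger amyloid–tau coupling under (more severe) TBI. Swapping the
  reference flips every sign exactly — a property the suite tests.

# What global-burden adjustment does to injected effects

Two subtleties discovered while validating against generator ground truth
deserve explicit documentation, because they are properties of the
*estimands*, not bugs:

**Regional maps.** Conditioning on the global SUVR means the map asks
"is this ROI high *for this subject's overall burden*". Injecting +0.08
SUVR into 30 of 200 ROIs of one group raises that group's global mean by
0.08·30/200 = 0.012, so every non-injected ROI becomes a genuine
*relative decrease* of about −0.012 at fixed global burden. At the
default sample sizes a minority of those reach FDR significance — with a
negative adjusted coefficient. The contrast map therefore reports
`adj_diff`, the signed adjusted group coefficient, alongside the raw
difference; rejections should be interpreted jointly with their sign. A
corollary (also tested): adding a constant to one group's entire SUVR
matrix produces *no* significant ROIs, because a pure global shift is
absorbed entirely by the global covariate.

**Coupling moderation.** Injecting a coupling-slope difference of +0.6
in 25 of 200 ROIs raises the affected group's *mean* coupling by
0.6·25/200 = 0.075. The global tau covariate carries this group-dependent
component (it rides on the latent amyloid global), and absorbs it with
weight equal to the latent share of regional amyloid variance
($0.15^2/(0.15^2+0.05^2) = 0.9$), attenuating the adjusted interaction
estimate to a predicted $0.6 - 0.075\cdot0.9 \approx 0.53$. The
unadjusted estimator (`adjust_global_tau = FALSE`) is unbiased for the
injected 0.6. The test suite checks both: unadjusted recovery of 0.6 and
adjusted agreement with the predicted attenuated value, each within two
Monte-Carlo standard errors over replicate cohorts. When the injected
moderation leaves group mean coupling unchanged — the strictly "purely
regional" case — adjustment provably changes nothing, which the suite
verifies exactly (to 1e-8) on a noise-free fixture.

# Numerical choices

* ROI extraction uses a single grouped pass (`rowsum`) and is verified
  against a naive per-voxel loop to 1e-12; SUVRs are scale- and
  voxel-order-invariant by construction.
* Summary-statistic ANOVA/Tukey/t reconstruct sums of squares from
  means, SDs and group sizes; with exact summaries they agree with the
  raw-data fits to 1e-10.
* A design with zero within-group variance everywhere yields an explicit
  infinite F (flagged, p = 0), not an error; rank-deficient ANCOVA
  designs raise an error naming the collinear columns.
* Tabular outputs print doubles with 17 significant digits so
  write-then-read round-trips are bit-exact; readers parse numerics
  strictly (C locale) and name the offending line on failure.
* All simulation is reproducible from a single integer seed; the
  pipeline writes an MD5 manifest so whole-run determinism is checkable.

# Problem sizes used by the validation suite

The suite exercises the estimators at the published group sizes
(38/40/25, 200 ROIs) for degrees-of-freedom accounting and effect
recovery; calibration checks use 50 replicate cohorts for the regional
null (FDR budget), 10 replicates for the interaction null and the
coupling recovery, 10^4 replicates at reduced n (24) for the global
ANCOVA type-I error and for p-value uniformity, and 5·10^5 draws for the
Monte-Carlo studentized-range oracle. These sizes were chosen so each
check has enough resolution to detect a miscalibrated estimator while the
whole suite stays quick to run.

# Known limitations

* The voxel phantom exercises extraction logic, not registration,
  segmentation or partial-volume effects — all out of scope.
* The severity rules cannot distinguish moderate from severe amnesia
  (collapsed bucket) and know nothing about injury type (blast vs
  impact) or penetrating injury.
* Epicenter probabilities are descriptive; no inferential machinery is
  attached to them beyond the exact combinatorial invariants.
* The synthetic covariate model draws each covariate independently
  within group; real cohorts have correlated covariates (age with
  diagnosis, APOE with amyloid), so covariate-adjustment behaviour on
  real data may differ from the simulated calibration.
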