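# tbipet

Amyloid-β and tau PET quantification and spatial analysis for traumatic
brain injury (TBI) cohorts.

## The problem this package addresses

TBI is a recognised dementia risk factor, yet studies disagree on whether
it raises amyloid-β or tau burden. Because head trauma damages the brain
heterogeneously, the sharper question is *spatial*: does a TBI history
shift **where** amyloid and tau accumulate, away from the stereotypical
temporo-parietal Alzheimer pattern, and does it change the regional
coupling between the two proteins? `tbipet` is for neuroimaging analysts
who want that full analysis as reusable, tested functions rather than a
one-off script: SUVR quantification, rule-based TBI severity grading,
cohort statistics, global-burden-adjusted regional contrast maps,
tau-epicenter probability mapping, and amyloid×TBI moderation maps — plus
a synthetic-cohort generator with known ground truth so every stage is
verifiable without access-controlled subject data.

## The models at the core

For subject *i*, group *g*, ROI *r* (of a 200-region cortical
parcellation), regional SUVR is mean uptake in the grey-matter-masked ROI
divided by mean uptake in the reference region, and the global level is
the unweighted ROI mean. The three analysis layers are:

* **Regional contrasts** — per ROI, the ANCOVA
  `SUVR_r ~ group + age + APOEε4 + global` (the tau model adds the ROI's
  amyloid SUVR and the amyloid-to-tau scan lag), partial F for `group`,
  Benjamini–Hochberg FDR over the 200 ROIs of the map; raw mean
  differences are reported everywhere and masked to significant ROIs for
  display.
* **Tau epicenters** — each subject's top 10% of ROIs by tau SUVR
  (k = 20 of 200); a group's epicenter probability per ROI is the
  fraction of subjects whose set contains it.
* **Coupling moderation** — per ROI, the regression
  `tau_r ~ Aβ_r × group + age + APOEε4 + global_tau + lag`, with the less
  severe group as reference so positive interaction *t* means stronger
  amyloid–tau coupling under (more severe) TBI.

TBI severity follows military/VA-style guideline rules: an event is
moderate/severe if loss of consciousness exceeds 30 min, or alteration of
consciousness or post-traumatic amnesia exceeds 24 h; otherwise mild.
Subject status is the worst event before the tau-PET scan.

## Worked example

Reproduce the cohort's scan-lag group comparison from its published
summaries (means 2.34/0.94/0.76 y, SDs 1.38/1.42/1.21, n 38/40/25):

```r
library(tbipet)
lag <- data.frame(mean = c(2.34, 0.94, 0.76), sd = c(1.38, 1.42, 1.21),
                  n = c(38, 40, 25), row.names = c("no", "mild", "modsev"))
anova_oneway(lag)
#>   statistic    value df1 df2            p ...
#> 1         F 14.18358   2 100 3.778359e-06
tukey_hsd(lag, c("mild", "no"))
#>   statistic    value df1 df2            p estimate    ci_low    ci_high
#> 1         q 6.439092   3 100 4.414855e-05     -1.4 -2.131532 -0.6684681
fisher_exact_2x2(matrix(c(10, 4, 15, 34), 2, 2))
#>    statistic    value ...          p estimate   ci_low  ci_high
#> 1 odds_ratio 5.666667    0.01144206 5.495364 1.324408 27.98614
```

The ANOVA recovers F(2,100) = 14.18: the amyloid-to-tau scan lag differs
strongly between groups, with the mild-TBI group scanned 1.40 y closer
together (95% CI −2.13 to −0.67) than the no-TBI group — which is why the
lag enters the tau models as a covariate. The Fisher row shows both odds
ratios for the MCI-by-TBI table: the sample cross-product ratio (5.67,
`value`) and the conditional-MLE estimate (5.50, `estimate`) with its
exact CI (1.32–27.99).

Run the whole pipeline on the default synthetic cohort (38/40/25
subjects, effects injected fronto-parietally as the generator documents):

```r
res <- run_pipeline(analysis_config(seed = 1), quiet = TRUE)
res
#> <pipeline_result>
#>   subjects: 103 | global ANCOVA F(amyloid)=0.51 p=0.603, F(tau)=0.58 p=0.561
#>   significant ROIs per regional map:
#>     no_mild_amyloid      29
#>     no_mild_tau          0
#>     no_modsev_amyloid    165
#>     no_modsev_tau        60
#>     mild_modsev_amyloid  6
#>     mild_modsev_tau      53
```

Global burden does not differ between groups (both ANCOVAs
non-significant), yet the adjusted regional maps light up — the signature
pattern the pipeline is built to detect: spatial redistribution without a
global increase. Epicenter maps confirm temporal-lobe dominance, e.g. the
moderate/severe group's top ROIs:

```r
ep <- res$epicenters$modsev
head(ep[order(-ep$probability), ], 3)
#>     roi_id count probability
#> 126    126    13        0.52
#> 136    136    13        0.52
#> 118    118    12        0.48
```

(ROIs 91–140 are the synthetic temporal lobe.) Supplying `out_dir =`
writes every table plus an MD5 manifest for reproducibility.

## Package layout

| Area | Functions |
|---|---|
| Synthetic cohorts | `sim_config`, `generate_cohort`, `generate_tbi_records`, `generate_voxel_phantom` |
| Quantification | `extract_roi_suvr`, `compute_global_suvr`, `classify_abeta`, `parcellation` |
| TBI classification | `classify_event_severity`, `classify_subject_tbi`, `reconcile_events`, `tbi_frequency_table` |
| Cohort statistics | `anova_oneway`, `tukey_hsd`, `fisher_exact_2x2`, `chi_square_independence`, `two_sample_t`, `ancova_global` |
| Regional maps | `roiwise_ancova`, `fdr_bh`, `combine_tbi_groups` |
| Epicenters | `rank_rois`, `select_epicenters`, `epicenter_probability` |
| Coupling | `roiwise_interaction`, `summarize_significant` |
| Orchestration & I/O | `run_pipeline`, `analysis_config`, `read_/write_*` (TSV/CSV/JSON/YAML/NIfTI) |

See `vignettes/tbipet-methods.Rmd` for the generative model, default
calibration, design decisions, and known limitations (including what
global-burden adjustment does to localized injected effects).
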