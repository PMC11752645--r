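Package: tbipet
Title: Amyloid and Tau PET Quantification and Spatial Analysis for
    Traumatic Brain Injury Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how a history of traumatic brain injury
    (TBI) relates to amyloid-beta and tau PET signal in aging cohorts.
    Implements regional SUVR extraction from labelled uptake volumes,
    DoD/VA-guideline TBI severity classification from interview records,
    group demographic statistics (ANOVA, Tukey HSD, Fisher exact,
    chi-square, t-tests, global ANCOVAs), global-burden-adjusted
    ROI-wise contrast maps with Benjamini-Hochberg FDR, subject-level
    tau epicenter probability mapping, and amyloid-by-TBI moderation
    analysis of regional amyloid-tau coupling. A synthetic-cohort
    generator with known ground truth makes the full pipeline testable
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
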