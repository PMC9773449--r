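# chemosig

Selection and evaluation of a protein biomarker signature of platinum
**chemoresistance** in high-grade serous ovarian carcinoma (HGSC), from
targeted-proteomics quantification to a clinically combined classifier.

Patients are grouped by their treatment-free interval to platinum (TFIp):
TFIp < 6 months is *chemoresistant*, TFIp > 6 months *chemosensitive*.
The package implements the three analysis stages such a study needs:

1. **Discovery** — peptide tables are summarized to protein level as the
   mean of the three most intense peptides, log2-transformed, normalized
   by equalized medians, filtered to proteins quantified in ≥ 4 of 7
   patients per group, and tested with two-sided Welch t tests and
   Benjamini–Hochberg q-values (q < 0.05). Candidates add
   presence/absence patterns and a literature list.
2. **PRM verification** — transition-level quality control against the
   heavy internal-standard pattern (retention-time window, leave-one-out
   interference screen, minimum trace count), fragment summation,
   below-LOD background replacement, per-run internal-standard median
   normalization, technical CV, best-peptide protein rollup and
   minimum-abundance imputation.
3. **Signature selection** — the cohort is repeatedly split 8:10
   (training:validation, stratified); on each training part a forward
   logistic search starts from the best single protein by training AUC
   and accepts additions only while the refitted model's AUC gain
   exceeds 0.02; after 500 repeats the most frequently selected
   combination is refit on the whole cohort and summarized by ROC —
   AUC with DeLong confidence interval and the Youden-optimal
   sensitivity/specificity — alone, with clinical covariates (age,
   menopausal status, log CA125, primary treatment), and on the
   chemoresistant vs *partially chemosensitive* (TFIp 6–12 months)
   subset.

A synthetic-data generator reproduces the statistical structure of every
stage (cohort covariates, run biases, intensity-dependent missingness,
interfered transitions, planted multi-protein effects), so the whole
pipeline runs and is tested without any external download.

## Worked example

```r
library(chemosig)

cohort      <- generate_cohort(cohort_spec(seed = 11))
panel       <- prm_sim_spec(n_proteins = 29,
                            signal_proteins = c("PROT04", "PROT11", "PROT23"),
                            effect_size = 1.5, seed = 12)
transitions <- generate_prm_dataset(cohort, panel)

verdict <- qc_transitions(transitions)
areas   <- sum_peptide_area(transitions, verdict)
std     <- areas[areas$channel == "standard", ]
ref     <- tapply(log2(std$area), std$run_id, median)
areas   <- replace_below_lod(areas, run_reference = ref)
quant   <- drop_failed(normalize_by_standards(areas))
pm      <- impute_min(best_peptide_rollup(quant,
             groups = setNames(cohort$group, cohort$patient_id)))
pm
#> protein_matrix: 29 proteins x 88 samples (0.0% missing)
#> group
#> chemoresistant chemosensitive
#>             25             63

x    <- t(unclass(pm)); y <- attr(pm, "groups")
reps <- run_repeats(x, y, selection_config(n_repeats = 500, seed = 13))
cons <- consensus(reps, x, y)
cons
#> Consensus signature: PROT04 + PROT11
#>   selected in 190 of 500 repeats
#> ROC summary: AUC 0.981 (95% CI 0.935-0.995, delong)
#>   Youden cutoff 0.2149: sensitivity 0.960, specificity 0.921
#>   n = 25 positive / 63 negative

ev <- evaluate_with_clinical(x, cons$proteins, cohort, y)
sprintf("proteins %.3f | clinical %.3f | combined %.3f (p = %.3f)",
        ev$proteins$auc, ev$clinical$auc, ev$combined$auc, ev$p_value)
#> "proteins 0.981 | clinical 0.839 | combined 1.000 (p = 0.115)"
```

Reading the output: two of the three planted signature proteins carry
enough joint signal that the 500-repeat tally settles on the pair
(selected in 190 repeats; the third protein's incremental training-AUC
gain rarely clears the 0.02 gate — see the vignette's limitations
section). The whole-cohort refit of the consensus separates resistant
from sensitive patients with AUC 0.981; at the Youden-optimal cutoff the
classifier finds 96% of resistant patients while calling 92% of
sensitive patients correctly. Clinical covariates alone reach 0.839 and
the combined model 1.000; the paired DeLong comparison of the
proteins-only and combined curves gives p = 0.115.

The same analysis runs end to end, with every artifact and a manifest
written to disk, via:

```r
run_pipeline(pipeline_config(seed = 11,
  prm = list(n_proteins = 29,
             signal_proteins = c("PROT04", "PROT11", "PROT23"),
             effect_size = 1.5)), "out")
```

or from a shell through `inst/scripts/chemosig.R`. Real transition
reports (e.g. Skyline exports) enter through
`read_transitions(column_map = ...)` and clinical tables through
`read_clinical()`; `inst/scripts/evaluate_published.R` documents the
mapping for the published study's supplementary per-patient tables.

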