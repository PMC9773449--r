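---
title: "Deriving a chemoresistance protein signature from targeted proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a chemoresistance protein signature from targeted proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosig)
```

## The problem

In newly diagnosed advanced high-grade serous ovarian carcinoma (HGSC),
roughly a quarter of patients relapse within six months of the last
platinum dose (treatment-free interval to platinum, TFIp < 6 months:
*chemoresistant*), while the rest respond for longer (TFIp > 6 months:
*chemosensitive*). A pre-treatment predictor of this outcome would let
resistant patients be routed to alternative regimens. `chemosig`
implements the full analysis arc for deriving such a predictor from
archival (FFPE) tumour proteomics:

1. **Discovery**: label-free protein quantification across small patient
   groups, candidate filtering and differential testing;
2. **Verification**: targeted parallel reaction monitoring (PRM)
   quantification of the candidates with stable-isotope internal
   standards;
3. **Signature selection**: repeated train/validation resampling with an
   AUC-gain forward logistic search and a frequency consensus, then ROC
   evaluation alone and combined with clinical covariates.

Because the raw study data live in external repositories, the package
ships a synthetic-data generator that reproduces the *statistical
structure* of each stage, so the entire pipeline is exercised end to end
by code alone.

## Discovery model

Peptide areas are summarized to protein level as the mean of the three
most intense peptides per protein (`top3_summarize()`), log2-transformed,
and column-shifted so every sample's median matches the global median of
sample medians (`equalize_median_normalize()` — idempotent, median
deviations < 1e-9). Only proteins with at least 4 quantified values out of
7 patients per group enter testing (`presence_filter()`). Group
differences use a two-sided Welch t test per protein
(`differential_test()`; pooled variance is a config option) with
Benjamini–Hochberg adjustment reported as a q-value, significant at
q < 0.05. The adjustment method is configurable because the discovery
protocol only fixes "correction for multiple testing"; BH is the common
default. Each pairwise comparison is adjusted within its own p-value pool.

Candidates are the union of significant proteins with
(`select_candidates()`):

* **criterion A** — present in ≥ 4 patients of one group and completely
  absent in a compared group (presence/absence patterns escape the t
  test);
* **criterion B** — completely present or completely absent in the
  chemoresistant group;
* an explicit **literature** list (kept, with a flag, even when outside
  the quantified panel).

## PRM quantification model

The unit of measurement is a *transition*: one fragment ion of one
peptide, quantified in two channels — endogenous and a spiked heavy
internal standard that co-elutes with it. The verification steps are:

* `qc_transitions()` — a numeric surrogate for expert trace review. A
  fragment is rejected when its endogenous/standard retention times
  disagree by more than `rt_window` (default 1 min), or when removing it
  improves the Pearson correlation between the endogenous and standard
  fragment-intensity patterns by more than `interference_margin` (default
  0.1; the leave-one-out screen iterates while ≥ 4 fragments remain — with
  only 3 fragments a leave-one-out correlation on 2 points is always ±1,
  so no interference call is attributable). A peptide fails in a run with
  fewer than `min_fragments` (default 3) surviving fragments or a final
  pattern correlation below `min_correlation` (default 0.5). These
  defaults replace judgment calls made in review software with explicit,
  reproducible rules; they are stand-ins, not reconstructions of reviewer
  judgment.
* `sum_peptide_area()` — peptide area = sum of accepted fragment areas
  per channel.
* `replace_below_lod()` — endogenous areas under a per-peptide background
  estimate (default: the 5th percentile of that peptide's observed areas,
  or a supplied floor) are set to the background and flagged. When a
  per-run reference level (the run's internal-standard median) is passed,
  estimation and comparison happen on the run-adjusted scale so that
  per-run intensity biases are not mistaken for detection-limit censoring;
  the pipeline driver always does this.
* `normalize_by_standards()` — one additive log2 shift per run equalizes
  the internal-standard medians across runs and is applied to both
  channels. The default target is the fixed constant 0, i.e. quantities
  are expressed relative to the run's standard median. A fixed target
  makes the output *exactly* invariant to per-run biases (the shift
  cancels the bias term algebraically), which is also how the pipeline's
  bias-removal test can demand agreement to 1e-6 between a biased dataset
  and its bias-free regeneration. `target = "median"` preserves the
  absolute log2-area scale instead, at the cost of a cohort-level
  constant that depends on the realized biases.
* `compute_cv()` — percent CV (sd/mean on linear areas) across technical
  replicate runs, summarized per peptide as the median over patients.
  Assay precision is meaningful after internal-standard normalization;
  computed on raw areas it simply restates the run-bias magnitude.
* `drop_failed()` — peptides missing in more than half their runs are
  removed, then samples missing more than half the surviving peptides.
  The study this emulates discarded 7 of 59 peptides and 8 of 88 samples;
  the thresholds express that attrition as a rule rather than a count.
* `best_peptide_rollup()` — one surrogate peptide per protein: lowest
  technical CV, ties to higher mean abundance, then peptide id; without
  CVs, highest mean abundance. "Best" is not defined in the source
  protocol, so the criterion is explicit and logged.
* `impute_min()` — remaining gaps are filled with the protein's minimum
  observed log2 value (a conservative low-abundance assumption).

## Signature selection model

The verification cohort is split 8:10 (training:validation — the training
part is the *smaller* one; the unusual ratio is read literally, with a
config switch for 10:8). Splits are stratified by response group by
default: with 25 resistant vs 63 sensitive patients an unstratified split
can lose a class from one part. Rounding: training size =
`round(n * 8/18)` per class, clamped so both classes appear in both parts.

On the training part, `forward_select()` starts from the single protein
with the highest in-sample AUC of a univariate logistic fit and greedily
adds the protein whose inclusion most increases the refitted model's
training AUC, accepting only gains strictly above `delta_auc` (default
0.02). A single-feature univariate step is computed without an explicit
fit: the fitted probability is monotone in the feature, so its AUC equals
the feature's AUC oriented by the sign of its covariance with the label
(the sign of the profile score at zero — exact, not an approximation).
Logistic fits are unpenalized maximum likelihood (Newton/IRLS); under
quasi-separation, where the likelihood diverges, the fit falls back to a
small ridge (1e-4, intercept unpenalized) and flags it.

`run_repeats()` repeats split + selection + validation-AUC measurement
`n_repeats` times (default 500), with per-repeat sub-seeds drawn
deterministically from the master seed; results are bit-reproducible.
`consensus()` tallies the selected combinations as *unordered sets*, the
most frequent set wins (ties: fewer proteins, then lexicographic), and
the winner is refit on the whole cohort and summarized by ROC. Tallying
sets (rather than merging frequent individual proteins) mirrors how the
combination frequencies are reported in this analysis tradition; the
per-protein reading is noted as an open alternative.

Clinical covariates — age (years), menopausal status (post = 1), serum
CA125 at diagnosis, primary treatment (neoadjuvant = 1) — are combined
with the signature in `evaluate_with_clinical()`, which fits
proteins-only, clinical-only and combined models on identical samples and
compares the proteins-only and combined curves with a paired DeLong test.
CA125 spans two orders of magnitude and is log-transformed by default.
`partial_sensitivity_subset()` restricts the cohort to chemoresistant
patients plus the *partially chemosensitive* (recurrence in the half-open
window (6, 12] months; the boundary month 12 is included) for the harder
near-boundary discrimination.

## ROC module

`roc_auc()` is the Mann–Whitney pair statistic (ties count ½), computed
via midranks and exactly equal to brute-force pair counting. Score
orientation is fixed — higher score means chemoresistant — and never
auto-flipped, a classic silent-bug source. Thresholds are midpoints
between consecutive distinct scores plus infinite sentinels, which makes
the step-curve area identity with the pair statistic exact.
`roc_auc_ci()` uses the DeLong placement-value variance; the default
interval is built on the logit scale and back-transformed, because the
plain Wald interval on the AUC scale undercovers at moderate n (in the
package's own calibration experiment at n = 30/30 and true AUC 0.75,
logit-scale coverage is ~0.95 where the AUC-scale interval sits at
~0.93); `method = "delong_wald"` provides the AUC-scale variant, and a
stratified bootstrap is both an option and the automatic fallback when
the placement variance degenerates (e.g. AUC = 1 at small n).
`roc_youden()` maximizes J = sensitivity + specificity − 1, resolving
ties toward higher specificity.

## The synthetic generators

`generate_cohort()` emulates the verification cohort: 25 chemoresistant
(TFIp uniform on 1–5 months) vs 63 chemosensitive (TFIp log-uniform on
6.5–63 months, mimicking the long right tail of recurrence times); age
truncated-normal on [35, 85] (means 63 vs 59); CA125 log-normal with a
+0.5 log-unit shift in the resistant group; postmenopausal probabilities
0.96 vs 0.71; neoadjuvant treatment 0.72 vs 0.30; FIGO stage frequencies
per group. These defaults are fixed once from the cohort tables the
design emulates; exact covariate distributions are deliberately not used
as acceptance evidence.

`generate_prm_dataset()` draws log2 areas as protein baseline (uniform
16–23) + peptide and fragment offsets + a per-(patient, protein)
biological residual (`residual_sd`, default 1) + the planted group effect
for signal proteins, with fragment-level measurement noise (0.15 log2).
Internal standards share the baseline and fragment pattern but carry no
biological term (0.1 log2 noise). A per-run bias (`run_bias_sd`, default
0.5 log2) multiplies both channels. Missingness (mean rate 0.05) is
intensity-dependent — the drop probability decreases linearly with the
abundance rank, mimicking censoring near the detection limit — and is
decided on the bias-free abundances; biases are drawn as
`run_bias_sd * N(0,1)`. Together these two choices make a regeneration
with `run_bias_sd = 0` differ *only* in the bias term, which is what
lets the bias-removal property be asserted at 1e-6 rather than
statistically. A small fraction of transitions (2%) receives an additive
co-eluting interference in the endogenous channel only. One run per
patient by default; `n_replicates` adds technical replicates to exercise
CV computation (the replicate design of the emulated assay is not
documented, so this is a stand-in).

What the generator does **not** emulate: chromatographic peak shapes,
retention-time scheduling, correlated proteins (each protein's residual
is independent), batch structure beyond a scalar run bias, and
non-Gaussian heavy tails of real FFPE data. Passing tests therefore
demonstrate algorithmic correctness under the stated statistical model,
not robustness to every failure mode of real acquisitions.

`generate_discovery_dataset()` produces the three discovery groups
(chemoresistant / chemosensitive / no recurrence, default 7 each) with
optional fully-absent-in-one-group proteins and planted mean shifts, to
exercise the candidate criteria.

## Numerical choices and degenerate inputs

* Ties among the three most intense peptides and among equal-AUC
  candidate features are broken lexicographically — deterministic and
  numerically inert.
* A TFIp of exactly 6 months belongs to neither response group; the
  clinical reader refuses such rows rather than guessing.
* Zero-variance features are dropped from logistic fits with a warning;
  fully missing proteins make `impute_min()` fail loudly.
* `run_pipeline()` writes no timestamps and formats floating-point
  output with 17 significant digits, so a rerun under the same config is
  byte-identical and CSV round trips are exact.
* Every run requires an explicit master seed; there is no silent default.

## Problem sizes in the test suite

The packaged tests run the generators at reduced but structurally
faithful sizes chosen to keep the full suite comfortably reproducible on
one CPU: the selection-recovery experiment uses the study-scale 25/63
cohort with 29 proteins and 500 resampling repeats across 20 master
seeds; the permutation-null consensus uses 100 repeats per permutation
across 50 permutations; coverage calibration uses 2,000 simulated
30/30 cohorts; oracle equivalences use 200–1,000 random instances.

## Known limitations

* The consensus model is refit and evaluated on the whole cohort, as in
  the emulated design. That in-sample evaluation is optimistic for a
  model *selected* on the same data: under label permutation the
  consensus whole-cohort AUC centers near 0.6–0.66, not 0.5, purely from
  winner's-curse selection over 29 candidates plus in-sample optimism
  (the per-repeat validation AUC, by contrast, is unbiased and centers
  at 0.5 under the null). Any external use of the consensus AUC should
  prefer the validation-fold distribution or an untouched cohort.
* With three planted signal proteins at 1.5 residual-SDs each, the third
  protein's true incremental AUC over the best pair is ≈ 0.034 —
  marginal against the 0.02 acceptance gate measured on ~39 training
  samples — so the consensus frequently settles on a two-protein subset
  of the planted trio (it essentially never admits a noise protein).
  Exact trio recovery at these settings is the exception, not the rule;
  stronger or more numerous training data, a smaller gate, or a larger
  training fraction change that balance.
* Protein inference from shared peptides, spectral identification and
  survival analysis are out of scope.
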