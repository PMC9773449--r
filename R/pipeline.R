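# End-to-end driver: simulate (or read) -> quantify -> rollup -> impute ->
# select -> consensus -> evaluate, with every artifact and a run manifest
# written to the output directory. All outputs are plain text and contain
# no timestamps, so a rerun under the same config is bit-identical.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' A master seed is required; there is no implicit default seed.
#'
#' @param seed Master integer seed (required).
#' @param clinical_csv,transitions_csv Optional input paths; when NULL the
#'   cohort and PRM data are simulated from `cohort` and `prm`.
#' @param cohort List of [cohort_spec()] arguments (without seed).
#' @param prm List of [prm_sim_spec()] arguments (without seed).
#' @param qc List of [qc_transitions()] thresholds.
#' @param lod_background,lod_quantile Background for
#'   [replace_below_lod()]: fixed floor(s) or the estimation quantile.
#' @param norm_target Target for [normalize_by_standards()].
#' @param max_missing_peptide,max_missing_sample [drop_failed()]
#'   thresholds.
#' @param selection List of [selection_config()] arguments (without seed).
#' @param partial_window Months window for
#'   [partial_sensitivity_subset()].
#' @param log_ca125 Log-transform CA125 in the clinical design.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            clinical_csv = NULL, transitions_csv = NULL,
                            cohort = list(), prm = list(),
                            qc = list(), lod_background = NULL,
                            lod_quantile = 0.05, norm_target = 0,
                            max_missing_peptide = 0.5,
                            max_missing_sample = 0.5,
                            selection = list(), partial_window = c(6, 12),
                            log_ca125 = TRUE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("pipeline_config: 'seed' is required; runs are never implicitly",
         " seeded", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), clinical_csv = clinical_csv,
                 transitions_csv = transitions_csv, cohort = cohort,
                 prm = prm, qc = qc, lod_background = lod_background,
                 lod_quantile = lod_quantile, norm_target = norm_target,
                 max_missing_peptide = max_missing_peptide,
                 max_missing_sample = max_missing_sample,
                 selection = selection, partial_window = partial_window,
                 log_ca125 = log_ca125),
            class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(id = rownames(m),
                   apply(m, 2L, sprintf, fmt = "%.17g"),
                   check.names = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, path)
}

.roc_json <- function(rs) {
  list(auc = rs$auc, ci_low = rs$ci_low, ci_high = rs$ci_high,
       ci_method = rs$ci_method, level = rs$level,
       youden_threshold = rs$youden_threshold,
       sensitivity = rs$sensitivity_at_youden,
       specificity = rs$specificity_at_youden,
       n_positive = rs$n_positive, n_negative = rs$n_negative)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> transition QC -> peptide summation ->
#' below-LOD replacement -> internal-standard normalization -> peptide /
#' sample attrition -> best-peptide rollup -> minimum imputation ->
#' repeated resampled forward selection -> frequency consensus ->
#' clinical-covariate and partial-chemosensitivity evaluation, writing
#' every artifact plus a machine-readable manifest (input checksums,
#' config echo, seed, package version, output checksums) under `out_dir`.
#' Any stage failure aborts with the stage name after writing a partial
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `transitions`, `qc`, `peptide_quant`, `protein_matrix`, `repeats`,
#'   `consensus`, `evaluation`, `files`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(p) files[[length(files) + 1L]] <<- p
  stage <- "init"
  manifest <- list(seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("chemosig")),
                   config = unclass(config), inputs = list(),
                   stages = character(0))
  fail <- function(e) {
    manifest$status <- paste0("failed at stage '", stage, "'")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(name, expr) {
    stage <<- name
    r <- tryCatch(expr, error = fail)
    manifest$stages <<- c(manifest$stages, name)
    r
  }

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  add("config.yaml")

  # --- inputs -------------------------------------------------------------
  dat <- run_stage("simulate", {
    if (is.null(config$clinical_csv)) {
      cs <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
      cohort <- generate_cohort(cs)
    } else {
      manifest$inputs$clinical_csv <<-
        unname(tools::md5sum(config$clinical_csv))
      cohort <- read_clinical(config$clinical_csv)
    }
    if (is.null(config$transitions_csv)) {
      ps <- do.call(prm_sim_spec,
                    c(config$prm, list(seed = config$seed + 1L)))
      tt <- generate_prm_dataset(cohort, ps)
    } else {
      manifest$inputs$transitions_csv <<-
        unname(tools::md5sum(config$transitions_csv))
      tt <- read_transitions(config$transitions_csv)
    }
    write_clinical(cohort, file.path(out_dir, "cohort.csv"))
    add("cohort.csv")
    write_transitions(tt, file.path(out_dir, "transitions.csv"))
    add("transitions.csv")
    list(cohort = cohort, tt = tt)
  })

  # --- quantify -----------------------------------------------------------
  quant <- run_stage("quantify", {
    verdict <- do.call(qc_transitions, c(list(dat$tt), config$qc))
    areas <- sum_peptide_area(dat$tt, verdict)
    std <- areas[areas$channel == "standard", , drop = FALSE]
    run_ref <- tapply(log2(std$area), std$run_id, stats::median)
    areas <- replace_below_lod(areas, background = config$lod_background,
                               probs = config$lod_quantile,
                               run_reference = run_ref)
    pq <- normalize_by_standards(areas, target = config$norm_target)
    pq <- drop_failed(pq, config$max_missing_peptide,
                      config$max_missing_sample)
    qc_report <- list(
      peptides_failing_any_run =
        sum(tapply(!verdict$peptides$pass, verdict$peptides$peptide, any)),
      dropped_peptides = attr(pq, "dropped_peptides"),
      dropped_runs = attr(pq, "dropped_runs"),
      n_peptides_in = length(unique(dat$tt$peptide)),
      n_peptides_out = nrow(pq$log2_endogenous),
      n_runs_in = length(unique(dat$tt$run_id)),
      n_runs_out = ncol(pq$log2_endogenous),
      rejection_reasons = as.list(table(
        verdict$transitions$reason[!is.na(verdict$transitions$reason)]))
    )
    jsonlite::write_json(qc_report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    add("qc_report.json")
    .write_matrix_tsv(pq$log2_endogenous,
                      file.path(out_dir, "peptide_matrix.tsv"), "peptide")
    add("peptide_matrix.tsv")
    list(verdict = verdict, pq = pq)
  })

  pm <- run_stage("rollup", {
    groups <- stats::setNames(dat$cohort$group, dat$cohort$patient_id)
    pm <- best_peptide_rollup(quant$pq, groups = groups)
    pm <- impute_min(pm)
    .write_matrix_tsv(pm, file.path(out_dir, "protein_matrix.tsv"),
                      "protein")
    add("protein_matrix.tsv")
    pm
  })

  # --- select -------------------------------------------------------------
  sel <- run_stage("select", {
    x <- t(unclass(pm))
    y <- attr(pm, "groups")
    cfg <- do.call(selection_config,
                   c(config$selection, list(seed = config$seed + 2L)))
    reps <- run_repeats(x, y, cfg)
    cons <- consensus(reps, x, y)
    .write_tsv(as.data.frame(reps), file.path(out_dir, "repeats.tsv"))
    add("repeats.tsv")
    .write_tsv(cons$frequency_table, file.path(out_dir, "frequency.tsv"))
    add("frequency.tsv")
    jsonlite::write_json(
      c(list(proteins = cons$proteins, frequency = cons$frequency,
             n_repeats = cons$n_repeats,
             coefficients = as.list(cons$model$coefficients),
             ridged = cons$model$ridged),
        .roc_json(cons$roc)),
      file.path(out_dir, "consensus.json"), auto_unbox = TRUE,
      pretty = TRUE, digits = NA)
    add("consensus.json")
    .write_tsv(cons$roc$curve, file.path(out_dir, "roc_points.tsv"))
    add("roc_points.tsv")
    list(x = x, y = y, reps = reps, cons = cons)
  })

  # --- evaluate -----------------------------------------------------------
  evaluation <- run_stage("evaluate", {
    run_pat <- attr(pm, "run_patient")[colnames(pm)]
    cohort_runs <- dat$cohort[match(run_pat, dat$cohort$patient_id), ,
                              drop = FALSE]
    clin <- encode_clinical(cohort_runs, log_ca125 = config$log_ca125)
    ev <- evaluate_with_clinical(sel$x, sel$cons$proteins, clin, sel$y)
    part <- partial_sensitivity_subset(cohort_runs, config$partial_window)
    pidx <- match(part$patient_id, run_pat)
    pclin <- encode_clinical(part, log_ca125 = config$log_ca125)
    pev <- evaluate_with_clinical(sel$x[pidx, , drop = FALSE],
                                  sel$cons$proteins, pclin,
                                  part$group)
    out <- list(
      whole_cohort = list(proteins = .roc_json(ev$proteins),
                          clinical = .roc_json(ev$clinical),
                          combined = .roc_json(ev$combined),
                          p_proteins_vs_combined = ev$p_value,
                          n_used = ev$n_used, n_excluded = ev$n_excluded),
      partial_sensitivity = list(
        proteins = .roc_json(pev$proteins),
        clinical = .roc_json(pev$clinical),
        combined = .roc_json(pev$combined),
        p_proteins_vs_combined = pev$p_value,
        n_partial = attr(part, "n_partial"))
    )
    jsonlite::write_json(out, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    add("evaluation.json")
    out
  })

  stage <- "manifest"
  manifest$status <- "ok"
  manifest$outputs <- as.list(
    stats::setNames(unname(tools::md5sum(file.path(out_dir,
                                                   unlist(files)))),
                    unlist(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(cohort = dat$cohort, transitions = dat$tt,
                 qc = quant$verdict, peptide_quant = quant$pq,
                 protein_matrix = pm, repeats = sel$reps,
                 consensus = sel$cons, evaluation = evaluation,
                 files = c(unlist(files), "manifest.json")))
}
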