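# Synthetic PRM (parallel reaction monitoring) transition tables: per run,
# peptide and fragment ion, an endogenous and a heavy internal-standard
# area. Log2 areas are normal around a per-protein baseline; per-run
# multiplicative biases hit both channels; missingness is intensity-
# dependent; a small fraction of transitions carries an additive
# co-eluting interference in the endogenous channel only.

#' Specification of a synthetic PRM dataset
#'
#' @param n_proteins Panel size (default 29). Protein ids are
#'   `PROT01..PROTnn`; peptides `PROTnn_pep1..`; fragments `y3, y4, ...`.
#' @param peptides_per_protein 1 or 2 (default 1).
#' @param fragments_per_peptide Product ions per peptide, >= 3 (default 5;
#'   at least 4 are needed for the leave-one-out interference check to be
#'   informative).
#' @param signal_proteins Protein ids carrying the planted group effect.
#' @param effect_size Log2 shift added to signal proteins in the
#'   chemoresistant group (default 0).
#' @param residual_sd Biological log2 SD per (patient, protein) (default 1).
#' @param run_bias_sd SD of the per-run log2 bias applied to both channels
#'   (default 0.5).
#' @param missing_rate Mean fraction of endogenous fragment areas dropped;
#'   the drop probability decreases with the (bias-free) abundance, i.e.
#'   censoring is preferentially low-abundance (default 0.05).
#' @param lod Linear-area floor regarded as the detection limit; recorded
#'   for downstream background replacement (default `2^15`).
#' @param interference_rate Fraction of transitions (peptide x fragment)
#'   given an additive interfering endogenous area (default 0.02).
#' @param n_replicates Technical replicate runs per patient (default 1).
#' @param baseline_range Log2 range protein baselines are drawn from.
#' @param fragment_sd,standard_sd Log2 measurement noise per endogenous /
#'   standard fragment area.
#' @param seed Integer seed (required).
#' @return Validated list of class `prm_sim_spec`.
#' @export
prm_sim_spec <- function(n_proteins = 29, peptides_per_protein = 1,
                         fragments_per_peptide = 5,
                         signal_proteins = character(),
                         effect_size = 0, residual_sd = 1,
                         run_bias_sd = 0.5, missing_rate = 0.05,
                         lod = 2^15, interference_rate = 0.02,
                         n_replicates = 1, baseline_range = c(16, 23),
                         fragment_sd = 0.15, standard_sd = 0.1, seed) {
  if (missing(seed)) stop("prm_sim_spec: 'seed' is required", call. = FALSE)
  ids <- sprintf("PROT%02d", seq_len(n_proteins))
  if (!all(signal_proteins %in% ids)) {
    stop("prm_sim_spec: 'signal_proteins' not in the panel: ",
         paste(setdiff(signal_proteins, ids), collapse = ", "),
         call. = FALSE)
  }
  if (fragments_per_peptide < 3) {
    stop("prm_sim_spec: 'fragments_per_peptide' must be >= 3",
         call. = FALSE)
  }
  if (residual_sd <= 0) {
    stop("prm_sim_spec: 'residual_sd' must be > 0", call. = FALSE)
  }
  for (r in c("missing_rate", "interference_rate")) {
    v <- get(r)
    if (v < 0 || v > 1) {
      stop("prm_sim_spec: '", r, "' must be in [0, 1]", call. = FALSE)
    }
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 fragments_per_peptide = as.integer(fragments_per_peptide),
                 proteins = ids, signal_proteins = signal_proteins,
                 effect_size = effect_size, residual_sd = residual_sd,
                 run_bias_sd = run_bias_sd, missing_rate = missing_rate,
                 lod = lod, interference_rate = interference_rate,
                 n_replicates = as.integer(n_replicates),
                 baseline_range = baseline_range,
                 fragment_sd = fragment_sd, standard_sd = standard_sd,
                 seed = as.integer(seed)),
            class = "prm_sim_spec")
}

#' Generate a synthetic PRM transition table
#'
#' For every run x peptide x fragment an endogenous and an internal-
#' standard area is produced. Standard areas share the run bias but carry
#' no biological effect; signal proteins are shifted by `effect_size`
#' (log2) in the chemoresistant group. All random components are drawn in
#' a fixed order and biases are drawn as `run_bias_sd * N(0,1)`, so
#' regenerating the same spec with `run_bias_sd = 0` changes only the bias
#' term and nothing else.
#'
#' @param cohort Clinical cohort data.frame (see [generate_cohort()]).
#' @param spec A [prm_sim_spec()].
#' @return `data.frame` with columns `run_id`, `patient_id`, `protein`,
#'   `peptide`, `fragment`, `channel` (endogenous/standard), `area`, `rt`.
#'   Attributes: `run_bias` (named log2 biases), `interfered`
#'   (data.frame of transitions carrying interference), `spec`.
#' @export
generate_prm_dataset <- function(cohort, spec) {
  stopifnot(inherits(spec, "prm_sim_spec"))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  set.seed(spec$seed)

  prot <- spec$proteins
  pep <- as.vector(t(outer(prot, seq_len(spec$peptides_per_protein),
                           function(p, k) paste0(p, "_pep", k))))
  pep_prot <- rep(prot, each = spec$peptides_per_protein)
  frag <- paste0("y", 2L + seq_len(spec$fragments_per_peptide))
  n_pep <- length(pep)
  n_frag <- spec$fragments_per_peptide

  pat <- cohort$patient_id
  resistant <- cohort$group == "chemoresistant"
  runs <- as.vector(t(outer(pat, seq_len(spec$n_replicates),
                            function(p, k) paste0("run_", p, "_", k))))
  run_pat <- rep(pat, each = spec$n_replicates)
  n_run <- length(runs)

  # fixed per-panel structure
  prot_base <- stats::runif(length(prot), spec$baseline_range[1],
                            spec$baseline_range[2])
  names(prot_base) <- prot
  pep_off <- stats::rnorm(n_pep, 0, 0.5)
  frag_off <- stats::rnorm(n_pep * n_frag, 0, 1)
  pep_rt <- stats::runif(n_pep, 10, 100)

  # biological residual per (patient, protein), shared by its peptides and
  # by technical replicates
  bio <- matrix(stats::rnorm(length(pat) * length(prot), 0,
                             spec$residual_sd),
                nrow = length(pat), dimnames = list(pat, prot))

  # row grid: run x peptide x fragment
  grid <- expand.grid(fragment = frag, peptide = pep, run_id = runs,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("run_id", "peptide", "fragment")]
  pi <- match(grid$peptide, pep)
  ri <- match(grid$run_id, runs)
  fi <- match(grid$fragment, frag)
  grid$patient_id <- run_pat[ri]
  grid$protein <- pep_prot[pi]
  n_rows <- nrow(grid)

  is_sig <- grid$protein %in% spec$signal_proteins
  is_res <- resistant[match(grid$patient_id, pat)]

  base_log2 <- prot_base[grid$protein] + pep_off[pi] +
    frag_off[(pi - 1L) * n_frag + fi]
  endo_log2 <- base_log2 +
    ifelse(is_sig & is_res, spec$effect_size, 0) +
    bio[cbind(match(grid$patient_id, pat), match(grid$protein, prot))] +
    stats::rnorm(n_rows) * spec$fragment_sd
  std_log2 <- base_log2 + stats::rnorm(n_rows) * spec$standard_sd

  run_bias <- spec$run_bias_sd * stats::rnorm(n_run)
  names(run_bias) <- runs

  rt_endo <- pep_rt[pi] + stats::rnorm(n_rows) * 0.02
  rt_std <- pep_rt[pi] + stats::rnorm(n_rows) * 0.02

  # interference: per transition (peptide x fragment), additive area in the
  # endogenous channel only, constant in log2 offset across runs
  n_trans <- n_pep * n_frag
  int_flag <- stats::runif(n_trans) < spec$interference_rate
  int_mag <- stats::runif(n_trans, 1, 3)
  ti <- (pi - 1L) * n_frag + fi
  endo_lin <- 2^endo_log2
  add <- int_flag[ti] *
    2^(prot_base[pep_prot[pi]] + frag_off[ti] + int_mag[ti])
  endo_lin <- endo_lin + add

  # intensity-dependent missingness, decided on bias-free abundances
  u_miss <- stats::runif(n_rows)
  pr_miss <- spec$missing_rate * 2 *
    (1 - (rank(endo_lin) - 0.5) / n_rows)
  drop_endo <- u_miss < pmin(pr_miss, 1)

  # per-run bias hits both channels multiplicatively
  endo_lin <- endo_lin * 2^run_bias[ri]
  std_lin <- 2^(std_log2 + run_bias[ri])

  keep <- !drop_endo
  out <- rbind(
    data.frame(grid[keep, c("run_id", "patient_id", "protein", "peptide",
                            "fragment")],
               channel = "endogenous", area = endo_lin[keep],
               rt = rt_endo[keep]),
    data.frame(grid[, c("run_id", "patient_id", "protein", "peptide",
                        "fragment")],
               channel = "standard", area = std_lin, rt = rt_std)
  )
  rownames(out) <- NULL
  tp <- rep(pep, each = n_frag)
  tf <- rep(frag, times = n_pep)
  structure(out,
            run_bias = run_bias,
            interfered = data.frame(peptide = tp[int_flag],
                                    fragment = tf[int_flag]),
            spec = spec)
}
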