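# Synthetic discovery-phase peptide tables: three response groups
# (chemoresistant, chemosensitive, chemosensitive without recurrence),
# log-normal peptide areas, optional presence/absence proteins (fully
# absent in one designated group) and proteins with planted mean shifts.

.discovery_groups <- c("chemoresistant", "chemosensitive",
                       "chemosensitive_no_recurrence")

#' Specification of a synthetic discovery dataset
#'
#' @param n_per_group Samples per group, >= 4 (default 7).
#' @param n_proteins Panel size (default 100); ids `DPROT001...`
#' @param peptides_per_protein Peptides per protein (default 3).
#' @param presence_absence Named character vector: names are protein ids
#'   whose values are fully absent in the named group and present in the
#'   other two groups.
#' @param effect_proteins Named numeric vector: log2 shift added to the
#'   chemoresistant group for each named protein. Must be disjoint from
#'   `presence_absence`.
#' @param residual_sd Log2 residual SD (default 1).
#' @param baseline_range Log2 range of protein baselines.
#' @param seed Integer seed (required).
#' @return Validated list of class `discovery_sim_spec`.
#' @export
discovery_sim_spec <- function(n_per_group = 7, n_proteins = 100,
                               peptides_per_protein = 3,
                               presence_absence = character(),
                               effect_proteins = numeric(),
                               residual_sd = 1, baseline_range = c(16, 23),
                               seed) {
  if (missing(seed)) {
    stop("discovery_sim_spec: 'seed' is required", call. = FALSE)
  }
  if (n_per_group < 4) {
    stop("discovery_sim_spec: 'n_per_group' must be >= 4", call. = FALSE)
  }
  ids <- sprintf("DPROT%03d", seq_len(n_proteins))
  if (length(presence_absence)) {
    if (is.null(names(presence_absence)) ||
        !all(names(presence_absence) %in% ids) ||
        !all(presence_absence %in% .discovery_groups)) {
      stop("discovery_sim_spec: 'presence_absence' must map panel protein",
           " ids to a group", call. = FALSE)
    }
  }
  if (length(effect_proteins) && (is.null(names(effect_proteins)) ||
                                  !all(names(effect_proteins) %in% ids))) {
    stop("discovery_sim_spec: 'effect_proteins' must be named by panel",
         " protein ids", call. = FALSE)
  }
  if (length(intersect(names(presence_absence), names(effect_proteins)))) {
    stop("discovery_sim_spec: 'presence_absence' and 'effect_proteins'",
         " must be disjoint", call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 proteins = ids, presence_absence = presence_absence,
                 effect_proteins = effect_proteins,
                 residual_sd = residual_sd,
                 baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "discovery_sim_spec")
}

#' Generate a synthetic discovery peptide table
#'
#' Three groups of `n_per_group` samples; linear-scale peptide areas with
#' log2-normal noise; presence/absence proteins have every value removed in
#' their designated group; effect proteins carry the stated mean shift in
#' the chemoresistant group.
#'
#' @param spec A [discovery_sim_spec()].
#' @return Long `data.frame` with columns `protein`, `peptide`, `sample`,
#'   `group`, `area` (linear scale).
#' @export
generate_discovery_dataset <- function(spec) {
  stopifnot(inherits(spec, "discovery_sim_spec"))
  set.seed(spec$seed)
  prot <- spec$proteins
  n_pep <- spec$peptides_per_protein
  pep <- as.vector(t(outer(prot, seq_len(n_pep),
                           function(p, k) paste0(p, "_pep", k))))
  pep_prot <- rep(prot, each = n_pep)
  groups <- rep(.discovery_groups, each = spec$n_per_group)
  samples <- paste0("S", sprintf("%02d", seq_along(groups)))

  prot_base <- stats::runif(length(prot), spec$baseline_range[1],
                            spec$baseline_range[2])
  names(prot_base) <- prot
  pep_off <- stats::rnorm(length(pep), 0, 0.5)

  grid <- expand.grid(peptide = pep, sample = samples,
                      stringsAsFactors = FALSE)
  pi <- match(grid$peptide, pep)
  si <- match(grid$sample, samples)
  grid$protein <- pep_prot[pi]
  grid$group <- groups[si]

  shift <- numeric(nrow(grid))
  if (length(spec$effect_proteins)) {
    hit <- grid$protein %in% names(spec$effect_proteins) &
      grid$group == "chemoresistant"
    shift[hit] <- spec$effect_proteins[grid$protein[hit]]
  }
  log2area <- prot_base[grid$protein] + pep_off[pi] + shift +
    stats::rnorm(nrow(grid), 0, spec$residual_sd)
  grid$area <- 2^log2area

  if (length(spec$presence_absence)) {
    absent <- grid$group == spec$presence_absence[grid$protein]
    absent[is.na(absent)] <- FALSE
    grid <- grid[!absent, , drop = FALSE]
  }
  rownames(grid) <- NULL
  grid[, c("protein", "peptide", "sample", "group", "area")]
}
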