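# Verification-phase PRM quantification: transition QC against the
# internal-standard pattern, fragment summation, below-LOD background
# replacement, internal-standard median normalization, technical CV,
# peptide/sample attrition, best-peptide protein rollup and
# minimum-abundance imputation.

.check_transition_table <- function(tt) {
  req <- c("run_id", "patient_id", "protein", "peptide", "fragment",
           "channel", "area", "rt")
  if (!all(req %in% names(tt))) {
    stop("transition table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tt$channel %in% c("endogenous", "standard"))) {
    stop("channel must be 'endogenous' or 'standard'", call. = FALSE)
  }
  if (any(tt$area < 0, na.rm = TRUE)) {
    stop("negative transition areas", call. = FALSE)
  }
  invisible(tt)
}

#' Transition-level quality control
#'
#' Numeric surrogate for the manual trace review of PRM data. Per (run,
#' peptide): fragments whose endogenous/standard retention-time difference
#' exceeds `rt_window` are rejected (`rt_outlier`); then, while at least 4
#' fragments remain, the fragment whose removal improves the Pearson
#' correlation between the endogenous and standard fragment-intensity
#' patterns by more than `interference_margin` is rejected
#' (`interference`). A peptide fails in a run when fewer than
#' `min_fragments` fragments survive (`too_few_traces`) or when the final
#' endogenous/standard pattern correlation stays below `min_correlation`
#' (`poor_correlation`).
#'
#' @param tt Transition table (see [generate_prm_dataset()] /
#'   [read_transitions()]).
#' @param min_fragments Minimal surviving fragments per (run, peptide)
#'   (default 3).
#' @param interference_margin Correlation improvement that flags a
#'   fragment as interfered (default 0.1).
#' @param rt_window Maximal |rt endogenous - rt standard| in minutes
#'   (default 1).
#' @param min_correlation Minimal final pattern correlation (default 0.5).
#' @return Object of class `qc_verdict`: list with `transitions`
#'   (`run_id`, `peptide`, `fragment`, `accepted`, `reason`) and
#'   `peptides` (`run_id`, `peptide`, `n_accepted`, `pass`,
#'   `fail_reason`).
#' @export
qc_transitions <- function(tt, min_fragments = 3,
                           interference_margin = 0.1, rt_window = 1,
                           min_correlation = 0.5) {
  .check_transition_table(tt)
  has_std <- tapply(tt$channel == "standard", tt$peptide, any)
  if (any(!has_std)) {
    stop("peptide(s) with no internal-standard rows: ",
         paste(names(has_std)[!has_std], collapse = ", "), call. = FALSE)
  }
  e <- tt[tt$channel == "endogenous", , drop = FALSE]
  s <- tt[tt$channel == "standard", , drop = FALSE]
  skey <- paste(s$run_id, s$peptide, s$fragment, sep = "\r")
  ekey <- paste(e$run_id, e$peptide, e$fragment, sep = "\r")
  sidx <- match(ekey, skey)

  grp <- paste(e$run_id, e$peptide, sep = "\r")
  idx_list <- split(seq_len(nrow(e)), grp)

  trans <- vector("list", length(idx_list))
  peps <- vector("list", length(idx_list))
  for (gi in seq_along(idx_list)) {
    ii <- idx_list[[gi]]
    ea <- e$area[ii]
    sa <- s$area[sidx[ii]]
    drt <- abs(e$rt[ii] - s$rt[sidx[ii]])
    ok <- !is.na(sa)
    reason <- rep(NA_character_, length(ii))

    rt_bad <- ok & drt > rt_window
    reason[rt_bad] <- "rt_outlier"
    ok <- ok & !rt_bad

    # iterative leave-one-out interference screen
    repeat {
      live <- which(ok)
      if (length(live) < 4L) break
      safe_cor <- function(x, y) {
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
        stats::cor(x, y)
      }
      r_all <- safe_cor(ea[live], sa[live])
      r_loo <- vapply(seq_along(live), function(j) {
        safe_cor(ea[live[-j]], sa[live[-j]])
      }, numeric(1))
      gain <- r_loo - r_all
      j <- which.max(gain)
      if (gain[j] > interference_margin) {
        reason[live[j]] <- "interference"
        ok[live[j]] <- FALSE
      } else break
    }

    live <- which(ok)
    fail_reason <- NA_character_
    if (length(live) < min_fragments) {
      fail_reason <- "too_few_traces"
    } else if (length(live) >= 3L) {
      r_fin <- if (stats::sd(ea[live]) == 0 ||
                   stats::sd(sa[live]) == 0) 0
               else stats::cor(ea[live], sa[live])
      if (r_fin < min_correlation) fail_reason <- "poor_correlation"
    }
    pass <- is.na(fail_reason)
    if (!pass) {
      reason[ok] <- fail_reason
      ok[] <- FALSE
    }
    trans[[gi]] <- data.frame(run_id = e$run_id[ii],
                              peptide = e$peptide[ii],
                              fragment = e$fragment[ii],
                              accepted = ok, reason = reason)
    peps[[gi]] <- data.frame(run_id = e$run_id[ii][1],
                             peptide = e$peptide[ii][1],
                             n_accepted = sum(ok), pass = pass,
                             fail_reason = fail_reason)
  }
  structure(list(transitions = do.call(rbind, trans),
                 peptides = do.call(rbind, peps)),
            class = "qc_verdict")
}

#' Sum accepted fragment areas per peptide
#'
#' Per (run, peptide, channel), the peptide area is the sum of the
#' QC-accepted fragments' areas. Peptides failing QC in a run yield no
#' value for that run.
#'
#' @param tt Transition table.
#' @param verdict A [qc_transitions()] result.
#' @return `data.frame` with columns `run_id`, `patient_id`, `protein`,
#'   `peptide`, `channel`, `area`.
#' @export
sum_peptide_area <- function(tt, verdict) {
  .check_transition_table(tt)
  stopifnot(inherits(verdict, "qc_verdict"))
  acc <- verdict$transitions[verdict$transitions$accepted, , drop = FALSE]
  akey <- paste(acc$run_id, acc$peptide, acc$fragment, sep = "\r")
  tkey <- paste(tt$run_id, tt$peptide, tt$fragment, sep = "\r")
  keep <- tt[tkey %in% akey, , drop = FALSE]
  if (nrow(keep) == 0L) {
    return(data.frame(run_id = character(0), patient_id = character(0),
                      protein = character(0), peptide = character(0),
                      channel = character(0), area = numeric(0)))
  }
  agg <- stats::aggregate(area ~ run_id + patient_id + protein + peptide +
                            channel, data = keep, FUN = sum)
  agg <- agg[order(agg$peptide, agg$run_id, agg$channel), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Replace below-LOD endogenous areas with a background estimate
#'
#' Endogenous peptide areas below the peptide's background estimate are
#' set to that estimate and flagged `below_lod`. The background is either
#' supplied per peptide (named vector or single floor) or estimated as a
#' low quantile of the peptide's observed endogenous areas.
#'
#' When `run_reference` (a named per-run log2 level, typically the run's
#' internal-standard median) is supplied, areas are first brought onto the
#' run-adjusted scale `area / 2^reference` for background estimation and
#' comparison, and the replacement value is mapped back to the run's own
#' scale. This keeps per-run intensity biases from masquerading as
#' detection-limit censoring.
#'
#' @param areas Summed peptide areas (see [sum_peptide_area()]).
#' @param background NULL (estimate from the data), a single positive
#'   floor, or a named per-peptide vector of positive floors. Interpreted
#'   on the run-adjusted scale when `run_reference` is given.
#' @param probs Quantile used when estimating the background (default
#'   0.05).
#' @param run_reference Optional named per-run log2 reference level.
#' @return `areas` with endogenous values floored and a logical
#'   `below_lod` column (FALSE for standard rows).
#' @export
replace_below_lod <- function(areas, background = NULL, probs = 0.05,
                              run_reference = NULL) {
  endo <- areas$channel == "endogenous"
  peps <- unique(areas$peptide[endo])
  adj <- if (is.null(run_reference)) {
    rep(0, nrow(areas))
  } else {
    unname(run_reference[areas$run_id])
  }
  adj_area <- areas$area / 2^adj
  if (is.null(background)) {
    background <- vapply(split(adj_area[endo], areas$peptide[endo]),
                         stats::quantile, numeric(1), probs = probs,
                         names = FALSE)
  } else if (is.null(names(background))) {
    background <- stats::setNames(rep(background[1], length(peps)), peps)
  }
  if (any(background <= 0)) {
    stop("background estimates must be positive", call. = FALSE)
  }
  bg <- background[areas$peptide]
  low <- endo & !is.na(bg) & adj_area < bg
  areas$below_lod <- low
  areas$area[low] <- bg[low] * 2^adj[low]
  areas
}

#' Internal-standard median normalization
#'
#' Log2-transforms peptide areas and applies one shift per run: `shift =
#' target - median(log2 standard areas of the run)`, added to every
#' endogenous and standard value of that run. After normalization all
#' runs' standard medians equal `target`. The default target is the fixed
#' constant 0, i.e. values are expressed relative to the run's internal-
#' standard median — a scale that is exactly invariant to per-run biases.
#' `target = "median"` instead uses the median of the run-level standard
#' medians, preserving the absolute log2-area scale.
#'
#' @param areas Summed peptide areas (after [replace_below_lod()], if
#'   used).
#' @param target Numeric constant, or `"median"`.
#' @return Object of class `peptide_quant`: list with `log2_endogenous`
#'   (peptides x runs matrix), `log2_standard`, `below_lod` (logical
#'   matrix), `shifts` (per run), `run_patient` (named run -> patient
#'   map).
#' @export
normalize_by_standards <- function(areas, target = 0) {
  runs <- sort(unique(areas$run_id))
  peps <- sort(unique(areas$peptide))
  std <- areas[areas$channel == "standard", , drop = FALSE]
  endo <- areas[areas$channel == "endogenous", , drop = FALSE]
  std_runs <- unique(std$run_id)
  if (!all(runs %in% std_runs)) {
    stop("run(s) with no internal-standard values: ",
         paste(setdiff(runs, std_runs), collapse = ", "), call. = FALSE)
  }
  run_med <- tapply(log2(std$area), factor(std$run_id, runs),
                    stats::median)
  run_med <- stats::setNames(as.numeric(run_med), runs)
  tgt <- if (identical(target, "median")) stats::median(run_med)
         else as.numeric(target)
  shifts <- tgt - run_med

  mk <- function(df) {
    m <- matrix(NA_real_, length(peps), length(runs),
                dimnames = list(peps, runs))
    m[cbind(match(df$peptide, peps), match(df$run_id, runs))] <-
      log2(df$area) + shifts[match(df$run_id, runs)]
    m
  }
  lod <- matrix(FALSE, length(peps), length(runs),
                dimnames = list(peps, runs))
  if (!is.null(endo$below_lod)) {
    lod[cbind(match(endo$peptide, peps), match(endo$run_id, runs))] <-
      endo$below_lod
  }
  rp <- unique(areas[, c("run_id", "patient_id")])
  structure(list(log2_endogenous = mk(endo), log2_standard = mk(std),
                 below_lod = lod, shifts = shifts,
                 run_patient = stats::setNames(rp$patient_id, rp$run_id)),
            class = "peptide_quant")
}

#' Technical coefficient of variation per peptide
#'
#' CV = sample SD / mean x 100, computed on linear-scale endogenous areas
#' across technical replicate runs of the same patient; a peptide's CV is
#' the median over patients with at least `min_replicates` replicates.
#' Peptides with zero mean report NA.
#'
#' @param areas Summed peptide areas with replicate runs (columns
#'   `peptide`, `patient_id`, `run_id`, `channel`, `area`).
#' @param min_replicates Minimal replicates per patient (default 2).
#' @return Named numeric vector of percent CVs per peptide.
#' @export
compute_cv <- function(areas, min_replicates = 2) {
  endo <- areas[areas$channel == "endogenous", , drop = FALSE]
  per_pat <- function(df) {
    cvs <- tapply(df$area, df$patient_id, function(a) {
      if (length(a) < min_replicates) return(NA_real_)
      m <- mean(a)
      if (m == 0) return(NA_real_)
      stats::sd(a) / m * 100
    })
    cvs <- cvs[!is.na(cvs)]
    if (!length(cvs)) return(NA_real_)
    stats::median(cvs)
  }
  out <- vapply(split(endo, endo$peptide), per_pat, numeric(1))
  if (all(is.na(out))) {
    stop("no patient has >= ", min_replicates, " replicate runs",
         call. = FALSE)
  }
  out
}

#' Remove failing peptides and low-quality samples
#'
#' A peptide is dropped when its fraction of missing values across runs
#' exceeds `max_missing_peptide`; afterwards a run (sample) is dropped
#' when its fraction of missing values across the surviving peptides
#' exceeds `max_missing_sample`.
#'
#' @param pq A [normalize_by_standards()] result.
#' @param max_missing_peptide Fraction threshold (default 0.5).
#' @param max_missing_sample Fraction threshold (default 0.5).
#' @return The filtered `peptide_quant`; removed ids in attributes
#'   `"dropped_peptides"` and `"dropped_runs"`.
#' @export
drop_failed <- function(pq, max_missing_peptide = 0.5,
                        max_missing_sample = 0.5) {
  stopifnot(inherits(pq, "peptide_quant"))
  m <- pq$log2_endogenous
  pep_bad <- rowMeans(is.na(m)) > max_missing_peptide
  m2 <- m[!pep_bad, , drop = FALSE]
  run_bad <- colMeans(is.na(m2)) > max_missing_sample
  if (all(run_bad)) stop("all samples removed", call. = FALSE)
  keep_p <- !pep_bad
  keep_r <- !run_bad
  out <- pq
  out$log2_endogenous <- m[keep_p, keep_r, drop = FALSE]
  out$log2_standard <- pq$log2_standard[keep_p, keep_r, drop = FALSE]
  out$below_lod <- pq$below_lod[keep_p, keep_r, drop = FALSE]
  out$shifts <- pq$shifts[keep_r]
  out$run_patient <- pq$run_patient[colnames(out$log2_endogenous)]
  attr(out, "dropped_peptides") <- rownames(m)[pep_bad]
  attr(out, "dropped_runs") <- colnames(m)[run_bad]
  out
}

#' Best-peptide protein rollup
#'
#' One surrogate peptide is chosen per protein and its log2 values become
#' the protein's values. The default criterion is the lowest technical CV
#' (when `cv` is supplied), tie-broken by higher mean abundance, then by
#' peptide id; without CVs the peptide with the highest mean abundance is
#' chosen.
#'
#' @param pq A `peptide_quant` (after [drop_failed()], typically).
#' @param peptide_map Named character vector peptide -> protein; defaults
#'   to stripping a `"_pepK"` suffix from the peptide id.
#' @param cv Optional named per-peptide percent CVs (see [compute_cv()]).
#' @param groups Optional named group labels per patient, attached to the
#'   output matrix columns via the run -> patient map.
#' @return A [protein_matrix()] (proteins x runs); the chosen peptide per
#'   protein in attribute `"chosen_peptides"`. Proteins with no surviving
#'   peptide are absent (with a warning).
#' @export
best_peptide_rollup <- function(pq, peptide_map = NULL, cv = NULL,
                                groups = NULL) {
  stopifnot(inherits(pq, "peptide_quant"))
  m <- pq$log2_endogenous
  peps <- rownames(m)
  if (is.null(peptide_map)) {
    peptide_map <- stats::setNames(sub("_pep[0-9]+$", "", peps), peps)
  }
  if (!all(peps %in% names(peptide_map))) {
    stop("peptide_map does not cover all peptides", call. = FALSE)
  }
  prots <- unique(unname(peptide_map))
  missing_prot <- setdiff(prots, unique(peptide_map[peps]))
  if (length(missing_prot)) {
    warning("protein(s) with no surviving peptide excluded: ",
            paste(missing_prot, collapse = ", "), call. = FALSE)
  }
  chosen <- vapply(split(peps, peptide_map[peps]), function(pp) {
    means <- rowMeans(m[pp, , drop = FALSE], na.rm = TRUE)
    if (!is.null(cv)) {
      cvs <- cv[pp]
      cvs[is.na(cvs)] <- Inf
      ord <- order(cvs, -means, pp)
    } else {
      ord <- order(-means, pp)
    }
    pp[ord[1L]]
  }, character(1))
  vals <- m[chosen, , drop = FALSE]
  rownames(vals) <- names(chosen)
  glab <- NULL
  if (!is.null(groups)) glab <- unname(groups[pq$run_patient[colnames(vals)]])
  out <- protein_matrix(vals, groups = glab)
  attr(out, "chosen_peptides") <- chosen
  attr(out, "below_lod") <- {
    bl <- pq$below_lod[chosen, , drop = FALSE]
    rownames(bl) <- names(chosen)
    bl
  }
  attr(out, "run_patient") <- pq$run_patient
  out
}

#' Minimum-abundance imputation
#'
#' Every missing value is replaced by the minimum observed log2 value of
#' that protein across runs. Proteins with no observed value at all raise
#' an error; the output contains no missing values.
#'
#' @param pm A [protein_matrix()].
#' @return The imputed [protein_matrix()]; logical `"imputed"` attribute
#'   marks replaced cells.
#' @export
impute_min <- function(pm) {
  fully <- rowSums(!is.na(pm)) == 0L
  if (any(fully)) {
    stop("protein(s) with no observed value: ",
         paste(rownames(pm)[fully], collapse = ", "), call. = FALSE)
  }
  imp <- is.na(pm)
  mins <- apply(pm, 1L, min, na.rm = TRUE)
  out <- pm
  for (k in which(rowSums(imp) > 0L)) {
    out[k, imp[k, ]] <- mins[k]
  }
  attr(out, "imputed") <- imp
  out
}
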