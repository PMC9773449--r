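# Discovery-phase quantification: top-3 peptide summarization to protein
# level, equalized-median normalization, presence filtering, differential
# testing with multiple-testing correction, and candidate selection.

#' Construct a proteins x samples log2 abundance matrix
#'
#' Thin S3 container: a numeric matrix (NA = missing) plus per-sample group
#' labels.
#'
#' @param values Numeric matrix, proteins in rows, samples in columns.
#' @param groups Character vector of group labels, one per column (or NULL
#'   when labels are attached later).
#' @return Object of class `protein_matrix`.
#' @export
protein_matrix <- function(values, groups = NULL) {
  values <- as.matrix(values)
  if (!is.null(groups)) {
    if (length(groups) != ncol(values)) {
      stop("one group label per sample column is required", call. = FALSE)
    }
    groups <- as.character(groups)
    names(groups) <- colnames(values)
  }
  structure(values, groups = groups, class = c("protein_matrix", "matrix"))
}

#' @export
print.protein_matrix <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("protein_matrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  if (!is.null(g)) print(table(group = g))
  invisible(x)
}

.pm_groups <- function(pm) {
  g <- attr(pm, "groups")
  if (is.null(g)) stop("protein_matrix has no group labels", call. = FALSE)
  g
}

#' Top-3 peptide summarization
#'
#' Protein abundance per sample is the mean of the three most intense
#' peptide areas (linear scale); with fewer than three observed peptides,
#' the mean of those observed. Proteins with no observed peptide in a
#' sample are missing there. The summarized matrix is log2-transformed.
#'
#' @param peptide_table Long `data.frame` with columns `protein`,
#'   `peptide`, `sample`, `area` (linear scale, >= 0) and optionally
#'   `group`.
#' @param groups Optional named character vector sample -> group; taken
#'   from the `group` column when present.
#' @return A [protein_matrix()] of log2 abundances.
#' @export
top3_summarize <- function(peptide_table, groups = NULL) {
  req <- c("protein", "peptide", "sample", "area")
  if (!all(req %in% names(peptide_table))) {
    stop("peptide table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(peptide_table$area < 0, na.rm = TRUE)) {
    stop("negative peptide areas", call. = FALSE)
  }
  if (is.null(groups) && "group" %in% names(peptide_table)) {
    g <- unique(peptide_table[, c("sample", "group")])
    groups <- stats::setNames(g$group, g$sample)
  }
  tab <- peptide_table[!is.na(peptide_table$area), , drop = FALSE]
  proteins <- sort(unique(peptide_table$protein))
  samples <- sort(unique(peptide_table$sample))
  m <- matrix(NA_real_, length(proteins), length(samples),
              dimnames = list(proteins, samples))
  key <- split(tab$area, list(factor(tab$protein, proteins),
                              factor(tab$sample, samples)), drop = FALSE)
  top3 <- vapply(key, function(a) {
    if (!length(a)) return(NA_real_)
    mean(sort(a, decreasing = TRUE)[seq_len(min(3L, length(a)))])
  }, numeric(1))
  m[] <- top3  # split() order is protein-major within sample ✱ column-major
  protein_matrix(log2(m), groups = if (is.null(groups)) NULL
                 else groups[samples])
}

#' Equalized-median normalization
#'
#' Shifts every sample column by a constant so that all per-sample medians
#' (over present values) equal the global median of the pre-normalization
#' column medians. Missingness is unchanged; the operation is idempotent.
#'
#' @param pm A [protein_matrix()] on log2 scale.
#' @return The normalized [protein_matrix()]; per-sample shifts in
#'   attribute `"shifts"`.
#' @export
equalize_median_normalize <- function(pm) {
  med <- apply(pm, 2L, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop("sample(s) with no present values: ",
         paste(colnames(pm)[is.na(med)], collapse = ", "), call. = FALSE)
  }
  target <- stats::median(med)
  shifts <- target - med
  out <- pm + rep(shifts, each = nrow(pm))
  attr(out, "shifts") <- shifts
  out
}

#' Presence filter
#'
#' Retains proteins with at least `min_present` present values in every
#' group under comparison.
#'
#' @param pm A [protein_matrix()] with group labels.
#' @param min_present Minimal number of present values per group (default
#'   4).
#' @param groups Groups to enforce the rule in (default: all groups in the
#'   matrix).
#' @return The filtered [protein_matrix()]; removed protein ids in
#'   attribute `"removed_proteins"`.
#' @export
presence_filter <- function(pm, min_present = 4, groups = NULL) {
  g <- .pm_groups(pm)
  if (is.null(groups)) groups <- unique(g)
  sizes <- table(g)[groups]
  if (any(min_present > sizes)) {
    stop("min_present exceeds the size of group(s): ",
         paste(groups[min_present > sizes], collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pm) == 0L) {
    attr(pm, "removed_proteins") <- character(0)
    return(pm)
  }
  ok <- rep(TRUE, nrow(pm))
  for (grp in groups) {
    cnt <- rowSums(!is.na(pm[, g == grp, drop = FALSE]))
    ok <- ok & cnt >= min_present
  }
  out <- pm[ok, , drop = FALSE]
  out <- protein_matrix(out, groups = g)
  attr(out, "removed_proteins") <- rownames(pm)[!ok]
  out
}

#' Differential abundance testing between two groups
#'
#' Two-sided two-sample t test per protein on present values (Welch by
#' default), with multiple-testing adjustment across all tested proteins
#' of the comparison (Benjamini-Hochberg by default, reported as a
#' q-value). Proteins with fewer than two present values in either group
#' are skipped and recorded.
#'
#' @param pm A [protein_matrix()] with group labels, log2 scale.
#' @param comparison Character vector of the two group labels; the log2
#'   fold change is `mean(comparison[1]) - mean(comparison[2])`.
#' @param var_equal Pooled-variance t test instead of Welch (default
#'   FALSE).
#' @param adjust_method Multiple-testing method for [stats::p.adjust()]
#'   (default "BH").
#' @param q_cutoff Significance threshold on the adjusted value (default
#'   0.05).
#' @return `data.frame` with columns `protein`, `log2fc`, `t`, `p`, `q`,
#'   `significant`; skipped proteins (id + reason) in attribute
#'   `"skipped"`.
#' @export
differential_test <- function(pm, comparison, var_equal = FALSE,
                              adjust_method = "BH", q_cutoff = 0.05) {
  g <- .pm_groups(pm)
  if (length(comparison) != 2L || !all(comparison %in% g)) {
    stop("comparison must name two groups present in the matrix",
         call. = FALSE)
  }
  i1 <- g == comparison[1]
  i2 <- g == comparison[2]
  res <- vector("list", nrow(pm))
  skipped <- character(0)
  for (k in seq_len(nrow(pm))) {
    a <- pm[k, i1][!is.na(pm[k, i1])]
    b <- pm[k, i2][!is.na(pm[k, i2])]
    if (length(a) < 2L || length(b) < 2L) {
      skipped <- c(skipped, rownames(pm)[k])
      next
    }
    tt <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {  # zero variance in both groups
      res[[k]] <- c(mean(a) - mean(b), 0, 1)
    } else {
      res[[k]] <- c(mean(a) - mean(b), unname(tt$statistic), tt$p.value)
    }
  }
  keep <- !vapply(res, is.null, logical(1))
  m <- do.call(rbind, res[keep])
  out <- data.frame(protein = rownames(pm)[keep],
                    log2fc = m[, 1], t = m[, 2], p = m[, 3])
  out$q <- stats::p.adjust(out$p, method = adjust_method)
  out$significant <- out$q < q_cutoff
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) {
    data.frame(protein = skipped, reason = "fewer than 2 present values")
  } else {
    data.frame(protein = character(0), reason = character(0))
  }
  out
}

#' Select biomarker candidates
#'
#' Union of (i) significantly differential proteins (q below the cutoff),
#' (ii) criterion A: present in at least `min_present` samples of one group
#' and completely absent in another, (iii) criterion B: completely present
#' or completely absent in the chemoresistant group, and (iv) an explicit
#' literature list. A protein satisfying several criteria keeps all tags;
#' literature ids absent from the quantified panel are kept with a warning
#' flag.
#'
#' @param diff Result of [differential_test()] on the same matrix.
#' @param pm The [protein_matrix()] the test was computed on.
#' @param literature Character vector of externally nominated protein ids.
#' @param resistant_group Label of the chemoresistant group.
#' @param min_present Presence count for criterion A (default 4).
#' @param q_cutoff Significance threshold (default 0.05).
#' @return `data.frame` with columns `protein`, logical `differential`,
#'   `criterion_a`, `criterion_b`, `literature`, `unquantified` (literature
#'   id not in the panel) and `reasons` (comma-joined tags).
#' @export
select_candidates <- function(diff, pm, literature = character(),
                              resistant_group = "chemoresistant",
                              min_present = 4, q_cutoff = 0.05) {
  g <- .pm_groups(pm)
  grps <- unique(g)
  sig <- diff$protein[diff$q < q_cutoff]

  crit_a <- character(0)
  crit_b <- character(0)
  if (nrow(pm)) {
    cnt <- sapply(grps, function(grp) {
      rowSums(!is.na(pm[, g == grp, drop = FALSE]))
    })
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1,
                                         dimnames = list(rownames(pm),
                                                         grps))
    size <- table(g)[grps]
    a_hit <- apply(cnt, 1L, function(r) {
      any(outer(r >= min_present, r == 0, "&") & !diag(length(r)))
    })
    crit_a <- rownames(pm)[a_hit]
    if (resistant_group %in% grps) {
      rc <- cnt[, resistant_group]
      other <- rowSums(cnt) - rc
      crit_b <- rownames(pm)[(rc == size[resistant_group] | rc == 0) &
                               other > 0]
    }
  }
  unq <- setdiff(literature, rownames(pm))
  if (length(unq)) {
    warning("literature protein(s) not in the quantified panel: ",
            paste(unq, collapse = ", "), call. = FALSE)
  }
  ids <- sort(unique(c(sig, crit_a, crit_b, literature)))
  out <- data.frame(protein = ids,
                    differential = ids %in% sig,
                    criterion_a = ids %in% crit_a,
                    criterion_b = ids %in% crit_b,
                    literature = ids %in% literature,
                    unquantified = ids %in% unq)
  out$reasons <- apply(out[, c("differential", "criterion_a",
                               "criterion_b", "literature")], 1L,
                       function(r) paste(c("differential", "criterion_a",
                                           "criterion_b",
                                           "literature")[r],
                                         collapse = ","))
  out
}
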