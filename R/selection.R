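# Predictive analysis: repeated 8:10 train/validation splits, AUC-gain
# forward logistic selection, frequency consensus over repeats, and
# clinical-covariate combination.

#' Configuration for the resampled signature selection
#'
#' @param n_repeats Number of independent train/validation resamples
#'   (default 500).
#' @param delta_auc Minimal training-AUC gain required to accept one more
#'   protein into the classifier (default 0.02; a candidate is accepted only
#'   when the gain is strictly greater).
#' @param split_ratio Training:validation ratio as a length-2 vector,
#'   default `c(8, 10)` (training is the smaller part).
#' @param seed Master seed; every repeat derives its own sub-seed from it.
#'   Required — there is no implicit default.
#' @param stratified Preserve class proportions in both parts (default
#'   TRUE).
#' @param max_features Optional cap on the signature size.
#' @param positive Positive class label.
#' @return Validated list of class `selection_config`.
#' @export
selection_config <- function(n_repeats = 500, delta_auc = 0.02,
                             split_ratio = c(8, 10), seed,
                             stratified = TRUE, max_features = NULL,
                             positive = "chemoresistant") {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("selection_config: 'seed' is required", call. = FALSE)
  }
  if (!(delta_auc > 0 && delta_auc < 1)) {
    stop("selection_config: 'delta_auc' must be in (0, 1)", call. = FALSE)
  }
  if (length(split_ratio) != 2L || any(split_ratio <= 0)) {
    stop("selection_config: 'split_ratio' parts must be positive",
         call. = FALSE)
  }
  if (n_repeats < 1L) {
    stop("selection_config: 'n_repeats' must be >= 1", call. = FALSE)
  }
  structure(list(n_repeats = as.integer(n_repeats), delta_auc = delta_auc,
                 split_ratio = split_ratio, seed = as.integer(seed),
                 stratified = isTRUE(stratified),
                 max_features = max_features, positive = positive),
            class = "selection_config")
}

#' Split a cohort into training and validation parts
#'
#' Training size is `round(n * r)` with `r = split_ratio[1] /
#' sum(split_ratio)` (8:10 by default, so the training part is the smaller
#' one); the remainder goes to validation. Stratified splits apply the same
#' rounding per class, clamped so both classes appear in both parts. Uses
#' the current RNG state — seed before calling for reproducibility.
#'
#' @param labels Class labels for all samples.
#' @param split_ratio Length-2 training:validation ratio.
#' @param stratified Preserve class proportions (default TRUE).
#' @param positive Positive class label.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_cohort <- function(labels, split_ratio = c(8, 10), stratified = TRUE,
                         positive = "chemoresistant") {
  y <- .binary_labels(labels, positive)
  n <- length(y)
  frac <- split_ratio[1] / sum(split_ratio)
  if (stratified) {
    train <- integer(0)
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      if (length(idx) < 2L) {
        stop("need at least 2 samples per class to split", call. = FALSE)
      }
      k <- round(length(idx) * frac)
      k <- min(max(k, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, k))
    }
    train <- sort(train)
  } else {
    k <- round(n * frac)
    k <- min(max(k, 1L), n - 1L)
    train <- sort(sample.int(n, k))
    if (length(unique(y[train])) < 2L ||
        length(unique(y[-train])) < 2L) {
      stop("unstratified split produced a single-class part", call. = FALSE)
    }
  }
  list(train = train, validation = setdiff(seq_len(n), train))
}

# In-sample AUC of the fitted multivariate logistic model on feature
# columns `cols`. For a single feature the fitted probability is a strictly
# monotone transform of the feature whenever the MLE slope is nonzero, and
# the slope's sign equals the sign of the profile score at zero,
# sum((y - ybar) * x); so the AUC is auc(x) oriented by sign(cov(x, y))
# with no fit needed. Multi-feature models are fitted by IRLS.
.train_auc <- function(x, y, cols) {
  if (length(cols) == 1L) {
    xi <- x[, cols]
    s <- sum((y - mean(y)) * xi)
    if (s == 0) return(0.5)
    a <- .auc01(xi, y)
    return(if (s > 0) a else 1 - a)
  }
  X <- cbind(1, x[, cols, drop = FALSE])
  fit <- .logit_irls(X, y)
  if (is.null(fit) || !fit$converged || max(abs(fit$coef)) > 15) {
    fit2 <- .logit_irls(X, y, lambda = 1e-4)
    if (!is.null(fit2)) fit <- fit2
  }
  if (is.null(fit)) return(NA_real_)
  .auc01(fit$fitted, y)
}

# rank AUC on pre-validated 0/1 labels
.auc01 <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1L)
  n0 <- length(y) - n1
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC-gain forward selection of a protein signature
#'
#' Step 0 selects the single protein with the highest training AUC from a
#' univariate logistic fit. Each later step refits the logistic model with
#' every remaining protein added, and accepts the best addition only if its
#' in-sample training AUC exceeds the incumbent AUC by more than
#' `delta_auc`; otherwise selection stops. Ties between equally scoring
#' candidates are broken by protein name (lexicographic) for determinism.
#'
#' @param x Feature matrix (samples x proteins) with column names.
#' @param y Class labels.
#' @param delta_auc Minimal AUC gain to accept an addition (default 0.02,
#'   strictly greater-than).
#' @param max_features Optional cap on the number of selected proteins.
#' @param positive Positive class label.
#' @return List with `features` (ordered by addition) and `auc_path`
#'   (training AUC after each accepted step).
#' @export
forward_select <- function(x, y, delta_auc = 0.02, max_features = NULL,
                           positive = "chemoresistant") {
  yy <- .binary_labels(y, positive)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  feats <- colnames(x)
  if (length(feats) < 1L) stop("no candidate features", call. = FALSE)
  if (is.null(max_features)) max_features <- length(feats)

  auc1 <- vapply(feats, function(f) .train_auc(x, yy, f), numeric(1))
  ord <- order(-auc1, feats)   # ties: lexicographic
  selected <- feats[ord[1L]]
  path <- auc1[ord[1L]]
  remaining <- setdiff(feats, selected)

  while (length(remaining) > 0L && length(selected) < max_features) {
    cand <- vapply(remaining, function(f) {
      .train_auc(x, yy, c(selected, f))
    }, numeric(1))
    cand[is.na(cand)] <- -Inf
    o <- order(-cand, remaining)
    best <- remaining[o[1L]]
    gain <- cand[o[1L]] - path[length(path)]
    if (!(gain > delta_auc)) break
    selected <- c(selected, best)
    path <- c(path, cand[o[1L]])
    remaining <- setdiff(remaining, best)
  }
  list(features = selected, auc_path = unname(path))
}

#' Repeated resampled signature selection
#'
#' Runs `n_repeats` independent train/validation splits. In each repeat the
#' signature is selected on the training part by [forward_select()], the
#' selected combination is refitted on the training part, and its
#' validation-set AUC is recorded. Per-repeat sub-seeds are derived
#' deterministically from the master seed, so the whole procedure is
#' bit-reproducible.
#'
#' @param x Feature matrix (samples x proteins).
#' @param y Class labels.
#' @param config A [selection_config()].
#' @return Object of class `chemosig_repeats`: data.frame with one row per
#'   repeat (`repeat_id`, `combination` — "+"-joined in order of addition,
#'   `n_features`, `train_auc`, `validation_auc`, `failed`), plus the
#'   per-repeat selections as the `"selections"` attribute.
#' @export
run_repeats <- function(x, y, config) {
  stopifnot(inherits(config, "selection_config"))
  yy <- .binary_labels(y, config$positive)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_repeats)

  selections <- vector("list", config$n_repeats)
  out <- data.frame(repeat_id = seq_len(config$n_repeats),
                    combination = NA_character_, n_features = NA_integer_,
                    train_auc = NA_real_, validation_auc = NA_real_,
                    failed = FALSE)
  for (i in seq_len(config$n_repeats)) {
    set.seed(sub_seeds[i])
    res <- tryCatch({
      sp <- split_cohort(yy, config$split_ratio, config$stratified)
      fs <- forward_select(x[sp$train, , drop = FALSE], yy[sp$train],
                           delta_auc = config$delta_auc,
                           max_features = config$max_features)
      Xtr <- cbind(1, x[sp$train, fs$features, drop = FALSE])
      fit <- .logit_irls(Xtr, yy[sp$train])
      if (is.null(fit) || !fit$converged || max(abs(fit$coef)) > 15) {
        f2 <- .logit_irls(Xtr, yy[sp$train], lambda = 1e-4)
        if (!is.null(f2)) fit <- f2
      }
      if (is.null(fit)) stop("logistic refit failed")
      sc <- stats::plogis(drop(
        cbind(1, x[sp$validation, fs$features, drop = FALSE]) %*% fit$coef))
      list(fs = fs, vauc = .auc01(sc, yy[sp$validation]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$failed[i] <- TRUE
    } else {
      selections[[i]] <- res$fs$features
      out$combination[i] <- paste(res$fs$features, collapse = "+")
      out$n_features[i] <- length(res$fs$features)
      out$train_auc[i] <- res$fs$auc_path[length(res$fs$auc_path)]
      out$validation_auc[i] <- res$vauc
    }
  }
  structure(out, selections = selections, class = c("chemosig_repeats",
                                                    "data.frame"))
}

#' Frequency-consensus signature over resampling repeats
#'
#' Combinations are tallied as unordered protein sets; the most frequently
#' selected set is the consensus signature. Ties are broken toward the
#' smaller set, then lexicographically. The winning set is refitted by
#' [fit_logistic()] on the whole cohort and its whole-cohort ROC summary is
#' computed.
#'
#' @param repeats Result of [run_repeats()].
#' @param x Whole-cohort feature matrix used for the refit.
#' @param y Whole-cohort labels.
#' @param positive Positive class label.
#' @return Object of class `chemosig_consensus`: list with `proteins`,
#'   `frequency`, `n_repeats`, `frequency_table` (all sets tallied),
#'   `model` ([fit_logistic()] result), `roc` ([roc_summary()]) and
#'   `scores` (whole-cohort fitted probabilities).
#' @export
consensus <- function(repeats, x, y, positive = "chemoresistant") {
  stopifnot(inherits(repeats, "chemosig_repeats"))
  sel <- attr(repeats, "selections")
  sel <- sel[!vapply(sel, is.null, logical(1))]
  if (length(sel) == 0L) stop("no successful repeats", call. = FALSE)
  keys <- vapply(sel, function(s) paste(sort(s), collapse = "+"),
                 character(1))
  tab <- table(keys)
  freq <- as.integer(tab)
  key <- names(tab)
  size <- lengths(strsplit(key, "+", fixed = TRUE))
  ord <- order(-freq, size, key)   # most frequent, then smaller, then lex
  winner <- strsplit(key[ord[1L]], "+", fixed = TRUE)[[1L]]

  model <- fit_logistic(as.matrix(x)[, winner, drop = FALSE], y,
                        positive = positive)
  scores <- model$fitted
  structure(list(
    proteins = winner,
    frequency = freq[ord[1L]],
    n_repeats = nrow(repeats),
    frequency_table = data.frame(combination = key[ord],
                                 n_proteins = size[ord],
                                 frequency = freq[ord]),
    model = model,
    roc = roc_summary(scores, y, positive = positive),
    scores = scores
  ), class = "chemosig_consensus")
}

#' @export
print.chemosig_consensus <- function(x, ...) {
  cat("Consensus signature:", paste(x$proteins, collapse = " + "), "\n")
  cat(sprintf("  selected in %d of %d repeats\n", x$frequency, x$n_repeats))
  print(x$roc)
  invisible(x)
}

#' Encode clinical covariates for modelling
#'
#' Builds the numeric design used alongside the protein signature: age in
#' years, menopausal status (postmenopausal = 1), log CA125 (natural log;
#' serum CA125 spans orders of magnitude) and primary treatment
#' (neoadjuvant chemotherapy = 1). Rows with a missing covariate are
#' excluded with a warning; the kept row indices are returned as the
#' `"kept"` attribute.
#'
#' @param cohort Clinical cohort data.frame (see [generate_cohort()] /
#'   [read_clinical()]).
#' @param log_ca125 Log-transform CA125 (default TRUE).
#' @return Numeric matrix with columns `age`, `postmenopausal`,
#'   `log_ca125` (or `ca125`), `neoadjuvant`.
#' @export
encode_clinical <- function(cohort, log_ca125 = TRUE) {
  ca <- if (log_ca125) log(cohort$ca125) else cohort$ca125
  m <- cbind(age = cohort$age,
             postmenopausal = as.numeric(cohort$menopausal_status == "post"),
             ca = ca,
             neoadjuvant = as.numeric(cohort$treatment == "neoadjuvant"))
  colnames(m)[3] <- if (log_ca125) "log_ca125" else "ca125"
  keep <- stats::complete.cases(m)
  if (any(!keep)) {
    warning(sum(!keep), " sample(s) excluded for missing clinical",
            " covariates", call. = FALSE)
  }
  structure(m[keep, , drop = FALSE], kept = which(keep))
}

#' Evaluate the protein signature with and without clinical covariates
#'
#' Fits three whole-cohort logistic models — proteins alone, clinical
#' covariates alone, and proteins plus covariates — and returns their ROC
#' summaries together with the paired DeLong p-value comparing the
#' proteins-only and combined curves. Samples lacking a clinical covariate
#' are excluded from all three models so the comparison stays paired.
#'
#' @param x Protein feature matrix (samples x proteins).
#' @param proteins Protein signature (column names of `x`) to evaluate.
#' @param clinical Encoded covariate matrix from [encode_clinical()], or a
#'   cohort data.frame (encoded internally).
#' @param y Class labels (aligned with rows of `x`).
#' @param positive Positive class label.
#' @return List with `proteins`, `clinical`, `combined` (each a
#'   [roc_summary()]), `p_value` (proteins vs combined), `n_used`,
#'   `n_excluded`.
#' @export
evaluate_with_clinical <- function(x, proteins, clinical, y,
                                   positive = "chemoresistant") {
  x <- as.matrix(x)
  if (is.data.frame(clinical) && !is.null(clinical$ca125)) {
    clinical <- encode_clinical(clinical)
  }
  kept <- attr(clinical, "kept")
  if (is.null(kept)) kept <- seq_len(nrow(clinical))
  yy <- .binary_labels(y, positive)[kept]
  xp <- x[kept, proteins, drop = FALSE]

  fit_p <- fit_logistic(xp, yy)
  fit_c <- fit_logistic(clinical, yy)
  fit_b <- fit_logistic(cbind(xp, clinical), yy)
  cmp <- roc_compare(fit_p$fitted, fit_b$fitted, yy)
  list(proteins = roc_summary(fit_p$fitted, yy),
       clinical = roc_summary(fit_c$fitted, yy),
       combined = roc_summary(fit_b$fitted, yy),
       p_value = cmp$p_value,
       n_used = length(yy),
       n_excluded = nrow(x) - length(yy))
}

#' Restrict a cohort to chemoresistant vs partially chemosensitive patients
#'
#' Keeps every chemoresistant patient and only those chemosensitive
#' patients whose treatment-free interval to platinum falls in the window
#' (default 6 < TFIp <= 12 months — the partially chemosensitive subgroup).
#' Patients without recurrence are excluded.
#'
#' @param cohort Clinical cohort data.frame with `group` and `tfip_months`.
#' @param window Length-2 numeric, months; the half-open interval
#'   `(window[1], window[2]]`.
#' @return The subset cohort; number of partially chemosensitive patients
#'   in attribute `"n_partial"`.
#' @export
partial_sensitivity_subset <- function(cohort, window = c(6, 12)) {
  res <- cohort$group == "chemoresistant"
  part <- cohort$group == "chemosensitive" &
    !is.na(cohort$tfip_months) &
    cohort$tfip_months > window[1] & cohort$tfip_months <= window[2]
  if (!any(part)) {
    stop("no chemosensitive patients with TFIp in (", window[1], ", ",
         window[2], "] months", call. = FALSE)
  }
  structure(cohort[res | part, , drop = FALSE], n_partial = sum(part))
}
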