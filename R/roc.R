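#' @keywords internal
#' Coerce labels to 0/1 with 1 = positive (chemoresistant) class.
#'
#' Accepts logical, 0/1 numeric, or character/factor vectors. For
#' character/factor input the positive class defaults to "chemoresistant".
.binary_labels <- function(labels, positive = "chemoresistant") {
  if (is.logical(labels)) {
    y <- as.integer(labels)
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    y <- as.integer(labels)
  } else {
    labels <- as.character(labels)
    if (!positive %in% labels) {
      stop("positive class '", positive, "' not present in labels",
           call. = FALSE)
    }
    y <- as.integer(labels == positive)
  }
  if (anyNA(y)) stop("labels contain missing values", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in labels", call. = FALSE)
  }
  y
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Computes the empirical AUC as the Mann-Whitney pair statistic: the
#' fraction of (positive, negative) pairs in which the positive sample
#' scores higher, with ties counted one half. Higher scores indicate the
#' positive (chemoresistant) class; the orientation is fixed, never
#' auto-flipped.
#'
#' @param scores Numeric classification scores, higher = more likely
#'   positive.
#' @param labels Class labels: logical, 0/1, or character/factor (see
#'   `positive`).
#' @param positive Positive class for character/factor labels. Default
#'   `"chemoresistant"`.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)) # 1: perfect separation
#' @export
roc_auc <- function(scores, labels, positive = "chemoresistant") {
  y <- .binary_labels(labels, positive)
  if (length(scores) != length(y)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (anyNA(scores)) stop("scores contain missing values", call. = FALSE)
  r <- rank(scores)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10[i] = Pr-hat(score_i > random negative),
# V01[j] = Pr-hat(random positive > score_j), ties one half. Midrank trick
# avoids the O(n1*n0) double loop.
.delong_placements <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  n1 <- length(pos)
  n0 <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos)
  r_neg <- rank(neg)
  v10 <- (r_all[seq_len(n1)] - r_pos) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_neg) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Confidence interval for the AUC
#'
#' Asymptotic interval from the DeLong variance of placement values, the
#' standard choice for comparing and bounding empirical AUCs. The default
#' interval is built on the logit scale (delta method) and back-
#' transformed, which keeps the nominal coverage at moderate sample sizes
#' where the plain Wald interval on the AUC scale undercovers;
#' `method = "delong_wald"` gives the AUC-scale Wald interval. When the
#' placement variance degenerates (e.g. AUC = 1 on a small sample) the
#' function falls back to a stratified bootstrap percentile interval and
#' flags the fallback in the `"method"` attribute.
#'
#' @inheritParams roc_auc
#' @param level Confidence level, default 0.95.
#' @param method `"delong"` (logit scale, default), `"delong_wald"` (AUC
#'   scale) or `"bootstrap"`.
#' @param boot_n Bootstrap replicates when bootstrapping.
#' @return Numeric vector `c(low, high)` truncated to \[0, 1\], with
#'   attributes `auc` and `method`.
#' @export
roc_auc_ci <- function(scores, labels, level = 0.95,
                       method = c("delong", "delong_wald", "bootstrap"),
                       boot_n = 2000, positive = "chemoresistant") {
  method <- match.arg(method)
  y <- .binary_labels(labels, positive)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("need at least 2 samples per class for a confidence interval",
         call. = FALSE)
  }
  pl <- .delong_placements(scores, y)
  v <- stats::var(pl$v10) / length(pl$v10) +
    stats::var(pl$v01) / length(pl$v01)
  z <- stats::qnorm(1 - (1 - level) / 2)
  degenerate <- v <= 0 || pl$auc <= 0 || pl$auc >= 1
  if (method == "delong" && !degenerate) {
    se_logit <- sqrt(v) / (pl$auc * (1 - pl$auc))
    ci <- stats::plogis(stats::qlogis(pl$auc) + c(-1, 1) * z * se_logit)
    used <- "delong"
  } else if (method == "delong_wald" && v > 0) {
    ci <- pl$auc + c(-1, 1) * z * sqrt(v)
    used <- "delong_wald"
  } else {
    # degenerate variance or explicit request: stratified bootstrap
    ci <- .boot_auc_ci(scores, y, level, boot_n)
    used <- if (method == "bootstrap") "bootstrap" else
      "bootstrap_fallback"
  }
  ci <- pmin(pmax(ci, 0), 1)
  structure(ci, auc = pl$auc, method = used, names = c("low", "high"))
}

.boot_auc_ci <- function(scores, y, level, boot_n) {
  ip <- which(y == 1L)
  io <- which(y == 0L)
  aucs <- vapply(seq_len(boot_n), function(b) {
    bp <- sample(ip, length(ip), replace = TRUE)
    bo <- sample(io, length(io), replace = TRUE)
    s <- c(scores[bp], scores[bo])
    yy <- c(rep(1L, length(bp)), rep(0L, length(bo)))
    r <- rank(s)
    n1 <- length(bp)
    (sum(r[yy == 1L]) - n1 * (n1 + 1) / 2) / (n1 * length(bo))
  }, numeric(1))
  a <- (1 - level) / 2
  stats::quantile(aucs, c(a, 1 - a), names = FALSE, type = 7)
}

#' Paired comparison of two ROC curves
#'
#' Two-sided test of equal AUCs for two score vectors computed on the same
#' samples, using the covariance of DeLong placement values (the paired
#' DeLong test). Identical score vectors give p = 1.
#'
#' @param scores_a,scores_b Paired score vectors on identical samples.
#' @inheritParams roc_auc
#' @return List with `auc_a`, `auc_b`, `statistic` (z) and `p_value`.
#' @export
roc_compare <- function(scores_a, scores_b, labels,
                        positive = "chemoresistant") {
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors must have equal length", call. = FALSE)
  }
  y <- .binary_labels(labels, positive)
  if (length(scores_a) != length(y)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  pa <- .delong_placements(scores_a, y)
  pb <- .delong_placements(scores_b, y)
  n1 <- length(pa$v10)
  n0 <- length(pa$v01)
  v <- stats::var(pa$v10 - pb$v10) / n1 + stats::var(pa$v01 - pb$v01) / n0
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

# Threshold set: midpoints between consecutive distinct scores plus -Inf/+Inf
# sentinels, so the step curve and the pair statistic agree exactly.
.roc_thresholds <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    c(-Inf, Inf)
  } else {
    c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  }
}

#' Empirical ROC curve points
#'
#' Sensitivity and specificity at every cutpoint (midpoints between
#' consecutive distinct scores, with infinite sentinels). A sample is
#' called positive when its score exceeds the threshold.
#'
#' @inheritParams roc_auc
#' @return `data.frame` with columns `threshold`, `sensitivity`,
#'   `specificity`, ordered by increasing threshold.
#' @export
roc_curve <- function(scores, labels, positive = "chemoresistant") {
  y <- .binary_labels(labels, positive)
  th <- .roc_thresholds(scores)
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  sens <- vapply(th, function(t) mean(pos > t), numeric(1))
  spec <- vapply(th, function(t) mean(neg <= t), numeric(1))
  data.frame(threshold = th, sensitivity = sens, specificity = spec)
}

#' Youden-optimal cutoff
#'
#' Threshold maximizing Youden's J = sensitivity + specificity - 1 over all
#' cutpoints; ties are resolved toward higher specificity (the larger
#' threshold).
#'
#' @inheritParams roc_auc
#' @return List with `threshold`, `sensitivity`, `specificity`, `j`.
#' @export
roc_youden <- function(scores, labels, positive = "chemoresistant") {
  crv <- roc_curve(scores, labels, positive)
  j <- crv$sensitivity + crv$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[length(best)]  # larger threshold -> higher specificity
  list(threshold = crv$threshold[pick],
       sensitivity = crv$sensitivity[pick],
       specificity = crv$specificity[pick],
       j = j[pick])
}

#' Full ROC summary
#'
#' Bundles the ROC curve, AUC, confidence interval and Youden-optimal
#' operating point for one score vector.
#'
#' @inheritParams roc_auc_ci
#' @return Object of class `roc_summary`: list with `curve`, `auc`,
#'   `ci_low`, `ci_high`, `ci_method`, `level`, `youden_threshold`,
#'   `sensitivity_at_youden`, `specificity_at_youden`, `n_positive`,
#'   `n_negative`.
#' @export
roc_summary <- function(scores, labels, level = 0.95,
                        method = c("delong", "bootstrap"),
                        positive = "chemoresistant") {
  method <- match.arg(method)
  ci <- roc_auc_ci(scores, labels, level = level, method = method,
                   positive = positive)
  yo <- roc_youden(scores, labels, positive)
  y <- .binary_labels(labels, positive)
  structure(list(
    curve = roc_curve(scores, labels, positive),
    auc = as.numeric(attr(ci, "auc")),
    ci_low = unname(ci[1]),
    ci_high = unname(ci[2]),
    ci_method = attr(ci, "method"),
    level = level,
    youden_threshold = yo$threshold,
    sensitivity_at_youden = yo$sensitivity,
    specificity_at_youden = yo$specificity,
    n_positive = sum(y == 1L),
    n_negative = sum(y == 0L)
  ), class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("ROC summary: AUC %.3f (%d%% CI %.3f-%.3f, %s)\n",
              x$auc, round(100 * x$level), x$ci_low, x$ci_high,
              x$ci_method))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.3f, specificity %.3f\n",
              x$youden_threshold, x$sensitivity_at_youden,
              x$specificity_at_youden))
  cat(sprintf("  n = %d positive / %d negative\n",
              x$n_positive, x$n_negative))
  invisible(x)
}
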