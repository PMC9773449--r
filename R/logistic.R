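# Maximum-likelihood logistic regression by Newton/IRLS, with an optional
# small ridge penalty (intercept unpenalized) used as a fallback under
# quasi-separation. Written lean because forward selection refits it
# hundreds of thousands of times on small cohorts.

.logit_irls <- function(X, y, lambda = 0, maxit = 50, tol = 1e-9) {
  p <- ncol(X)
  pen <- c(0, rep(lambda, p - 1L))  # never penalize the intercept
  pen_mat <- if (lambda > 0) diag(pen, p) else NULL
  b <- numeric(p)
  converged <- FALSE
  failed <- FALSE
  tryCatch(
    for (it in seq_len(maxit)) {
      eta <- drop(X %*% b)
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      w[w < 1e-10] <- 1e-10
      g <- drop(crossprod(X, y - mu))
      H <- crossprod(X, w * X)
      if (lambda > 0) {
        g <- g - pen * b
        H <- H + pen_mat
      }
      step <- solve(H, g)
      b <- b + step
      if (max(abs(step)) < tol * max(1, max(abs(b)))) {
        converged <- TRUE
        break
      }
      # unpenalized likelihood diverges under separation; stop early, the
      # caller falls back to the ridge fit
      if (lambda == 0 && max(abs(b)) > 100) break
    },
    error = function(e) failed <<- TRUE
  )
  if (failed || any(!is.finite(b))) return(NULL)
  list(coef = b, fitted = stats::plogis(drop(X %*% b)),
       converged = converged)
}

#' Fit a logistic regression classifier
#'
#' Unpenalized maximum-likelihood fit of class membership (chemoresistant =
#' 1) on one or more features; the per-sample predicted probability is the
#' classification score. On quasi-separated data, where the unpenalized
#' likelihood diverges, the fit falls back to a small ridge penalty
#' (`ridge_fallback`, intercept unpenalized) and flags the fallback.
#' Constant features are dropped with a warning.
#'
#' @param x Numeric matrix (samples x features), or a vector for a single
#'   feature. Column names are kept as coefficient names.
#' @param y Class labels (logical, 0/1, or character/factor; see
#'   [roc_auc()]).
#' @param ridge_fallback Ridge penalty used when the unpenalized fit fails
#'   to converge or separates. Default 1e-4.
#' @param positive Positive class for character/factor labels.
#' @return Object of class `chemosig_logit`: list with `coefficients`
#'   (intercept first), `fitted` (probabilities), `converged`, `ridged`,
#'   `features`, `dropped` (constant features removed).
#' @export
fit_logistic <- function(x, y, ridge_fallback = 1e-4,
                         positive = "chemoresistant") {
  yy <- .binary_labels(y, positive)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  if (nrow(x) != length(yy)) {
    stop("x and y differ in number of samples", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  if (sum(yy == 1L) < 2L || sum(yy == 0L) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  keep <- apply(x, 2L, function(col) diff(range(col)) > 0)
  dropped <- colnames(x)[!keep]
  if (length(dropped)) {
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  x <- x[, keep, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, x)

  fit <- .logit_irls(X, yy)
  ridged <- FALSE
  # quasi-separation: diverging coefficients or no convergence
  if (is.null(fit) || !fit$converged || max(abs(fit$coef)) > 15) {
    fit <- .logit_irls(X, yy, lambda = ridge_fallback)
    ridged <- TRUE
  }
  if (is.null(fit)) stop("logistic fit failed", call. = FALSE)
  names(fit$coef) <- colnames(X)
  structure(list(coefficients = fit$coef, fitted = fit$fitted,
                 converged = fit$converged, ridged = ridged,
                 features = colnames(x), dropped = dropped),
            class = "chemosig_logit")
}

#' @export
predict.chemosig_logit <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1L)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && length(object$features)) {
    newdata <- newdata[, object$features, drop = FALSE]
  }
  X <- cbind(1, newdata)
  stats::plogis(drop(X %*% object$coefficients))
}

#' @export
print.chemosig_logit <- function(x, ...) {
  cat("Logistic classifier (", length(x$features), " feature(s)",
      if (x$ridged) ", ridge fallback" else "", ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
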