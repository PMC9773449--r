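# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force pair counting for the AUC, a
# hand-rolled IRLS for logistic coefficients, and exhaustive scans for
# cutoffs and greedy selection steps.

# AUC by explicit enumeration of all (positive, negative) pairs
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# textbook IRLS for unpenalized logistic regression (weighted least
# squares form, no shortcuts shared with the package implementation)
oracle_logit <- function(X, y, maxit = 100) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-X %*% beta))
    W <- diag(as.vector(p * (1 - p)) + 1e-12)
    z <- X %*% beta + solve(W) %*% (y - p)
    beta_new <- solve(t(X) %*% W %*% X, t(X) %*% W %*% z)
    if (max(abs(beta_new - beta)) < 1e-12) break
    beta <- beta_new
  }
  as.vector(beta)
}

# exhaustive Youden scan over every threshold between sorted scores
oracle_youden_j <- function(scores, y) {
  cand <- c(-Inf, sort(unique(scores)), Inf)
  best <- -Inf
  for (t in cand) {
    sens <- mean(scores[y == 1] > t)
    spec <- mean(scores[y == 0] <= t)
    best <- max(best, sens + spec - 1)
  }
  best
}

# small labelled feature matrix with a planted shift on given columns
make_features <- function(n1, n0, p, shift_cols = integer(0), shift = 0,
                          seed = 1) {
  set.seed(seed)
  y <- rep(c("chemoresistant", "chemosensitive"), c(n1, n0))
  x <- matrix(rnorm((n1 + n0) * p), n1 + n0, p,
              dimnames = list(NULL, sprintf("PROT%02d", seq_len(p))))
  if (length(shift_cols)) {
    x[y == "chemoresistant", shift_cols] <-
      x[y == "chemoresistant", shift_cols] + shift
  }
  list(x = x, y = y)
}

# minimal hand-built transition table: one run, one peptide, given
# endogenous and standard fragment areas
make_transitions <- function(e_areas, s_areas = e_areas,
                             run = "run_P001_1", patient = "P001",
                             protein = "PROT01", peptide = "PROT01_pep1",
                             rt_e = 50, rt_s = 50) {
  frags <- paste0("y", seq_along(e_areas) + 2L)
  rbind(
    data.frame(run_id = run, patient_id = patient, protein = protein,
               peptide = peptide, fragment = frags, channel = "endogenous",
               area = e_areas, rt = rt_e),
    data.frame(run_id = run, patient_id = patient, protein = protein,
               peptide = peptide, fragment = frags, channel = "standard",
               area = s_areas, rt = rt_s)
  )
}
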