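# PRM quantification: QC, summation, LOD handling, internal-standard
# normalization, CV, attrition, rollup and imputation.

test_that("fragments matching the standard pattern are accepted", {
  tt <- make_transitions(e_areas = c(100, 80, 60, 40, 20))
  v <- qc_transitions(tt)
  expect_true(all(v$transitions$accepted))
  expect_true(v$peptides$pass)
})

test_that("an inflated fragment is rejected as interference", {
  e <- c(100, 80, 60, 40, 20)
  e[2] <- e[2] * 10
  tt <- make_transitions(e_areas = e, s_areas = c(100, 80, 60, 40, 20))
  v <- qc_transitions(tt)
  bad <- v$transitions[v$transitions$fragment == "y4", ]
  expect_false(bad$accepted)
  expect_identical(bad$reason, "interference")
  expect_true(v$peptides$pass)  # 4 clean fragments remain
  expect_equal(v$peptides$n_accepted, 4)
})

test_that("too few detected traces fail the peptide", {
  tt <- make_transitions(e_areas = c(100, 80))
  v <- qc_transitions(tt, min_fragments = 3)
  expect_false(v$peptides$pass)
  expect_identical(v$peptides$fail_reason, "too_few_traces")
  expect_true(all(!v$transitions$accepted))
})

test_that("retention-time outliers and missing standards are handled", {
  tt <- make_transitions(e_areas = c(100, 80, 60, 40, 20))
  tt$rt[tt$channel == "endogenous" & tt$fragment == "y3"] <- 55
  v <- qc_transitions(tt, rt_window = 1)
  r <- v$transitions[v$transitions$fragment == "y3", ]
  expect_identical(r$reason, "rt_outlier")
  no_std <- tt[tt$channel == "endogenous", ]
  expect_error(qc_transitions(no_std), "no internal-standard")
})

test_that("qc decisions equal a brute-force filter on random tables", {
  set.seed(61)
  for (i in 1:10) {
    e <- 2^runif(6, 10, 16)
    tt <- make_transitions(e_areas = e, s_areas = 2^runif(6, 10, 16))
    v <- qc_transitions(tt, interference_margin = 0.05)
    # accepted + rejected partition the fragments
    expect_setequal(v$transitions$fragment, paste0("y", 3:8))
    expect_equal(sum(v$transitions$accepted) +
                   sum(!v$transitions$accepted), 6)
    if (v$peptides$pass) {
      live <- v$transitions$accepted
      expect_gte(sum(live), 3)
    }
  }
})

test_that("peptide areas are sums over accepted fragments only", {
  tt <- make_transitions(e_areas = c(5, 5, 10, 40, 20))
  v <- qc_transitions(tt)
  a <- sum_peptide_area(tt, v)
  acc <- v$transitions$fragment[v$transitions$accepted]
  e <- tt[tt$channel == "endogenous" & tt$fragment %in% acc, ]
  expect_equal(a$area[a$channel == "endogenous"], sum(e$area))
  # failing peptide yields no value
  tt2 <- make_transitions(e_areas = c(7, 9))
  v2 <- qc_transitions(tt2)
  a2 <- sum_peptide_area(tt2, v2)
  expect_equal(nrow(a2), 0)
})

test_that("below-LOD areas are replaced by the background and flagged", {
  a <- data.frame(run_id = c("r1", "r2"), patient_id = c("p1", "p2"),
                  protein = "P1", peptide = "P1_pep1",
                  channel = "endogenous", area = c(3, 12))
  out <- replace_below_lod(a, background = 10)
  expect_equal(out$area, c(10, 12))
  expect_identical(out$below_lod, c(TRUE, FALSE))
  expect_error(replace_below_lod(a, background = -1), "positive")
  # all above background: identity
  out2 <- replace_below_lod(a, background = 1)
  expect_equal(out2$area, a$area)
  expect_false(any(out2$below_lod))
})

make_norm_input <- function(bias = c(r1 = 0, r2 = 0), n_pep = 4,
                            seed = 63) {
  set.seed(seed)
  peps <- paste0("P", seq_len(n_pep), "_pep1")
  grid <- expand.grid(run_id = names(bias), peptide = peps,
                      stringsAsFactors = FALSE)
  grid$patient_id <- grid$run_id
  grid$protein <- sub("_pep1", "", grid$peptide)
  base <- runif(n_pep, 14, 18)[match(grid$peptide, peps)]
  rbind(
    data.frame(grid, channel = "endogenous",
               area = 2^(base + rnorm(nrow(grid)) + bias[grid$run_id])),
    data.frame(grid, channel = "standard",
               area = 2^(base + bias[grid$run_id]))
  )
}

test_that("standard medians are exactly equalized across runs", {
  a <- make_norm_input(bias = c(r1 = 1.3, r2 = -0.4, r3 = 0.7))
  pq <- normalize_by_standards(a)
  med <- apply(pq$log2_standard, 2, median, na.rm = TRUE)
  expect_lt(diff(range(med)), 1e-9)
  expect_equal(unname(med[1]), 0)  # default target
  pq2 <- normalize_by_standards(a, target = "median")
  med2 <- apply(pq2$log2_standard, 2, median, na.rm = TRUE)
  expect_lt(diff(range(med2)), 1e-9)
})

test_that("injected run biases are recovered as relative shifts", {
  a <- make_norm_input(bias = c(r1 = 1, r2 = -1))
  pq <- normalize_by_standards(a, target = "median")
  # biases +1/-1 -> shifts -1/+1 around their mean
  expect_equal(unname(pq$shifts - mean(pq$shifts)), c(-1, 1),
               tolerance = 1e-9)
  # already equal-median runs: zero shifts
  a0 <- make_norm_input(bias = c(r1 = 0, r2 = 0))
  pq0 <- normalize_by_standards(a0, target = "median")
  expect_equal(unname(pq0$shifts), c(0, 0), tolerance = 1e-9)
})

test_that("normalization removes run bias and keeps channel ratios", {
  a0 <- make_norm_input(bias = c(r1 = 0, r2 = 0, r3 = 0), seed = 67)
  ab <- a0
  bias <- c(r1 = 2, r2 = -1, r3 = 0.5)
  ab$area <- ab$area * 2^bias[ab$run_id]
  n0 <- normalize_by_standards(a0)
  nb <- normalize_by_standards(ab)
  expect_equal(nb$log2_endogenous, n0$log2_endogenous, tolerance = 1e-9)
  # endogenous - standard ratio unchanged by normalization
  raw_ratio <- with(ab, tapply(log2(area), list(peptide, run_id), sum))
  e <- ab[ab$channel == "endogenous", ]
  s <- ab[ab$channel == "standard", ]
  ratio_raw <- log2(e$area) - log2(s$area)
  ratio_norm <- nb$log2_endogenous - nb$log2_standard
  expect_equal(unname(ratio_norm[cbind(match(e$peptide, rownames(ratio_norm)),
                                       match(e$run_id, colnames(ratio_norm)))]),
               unname(ratio_raw), tolerance = 1e-9)
  expect_error(normalize_by_standards(
    a0[a0$channel == "endogenous" | a0$run_id != "r1", ]),
    "no internal-standard")
})

test_that("CV follows the sd/mean formula and is scale invariant", {
  a <- data.frame(run_id = c("r1", "r2"), patient_id = "p1",
                  protein = "P1", peptide = "P1_pep1",
                  channel = "endogenous", area = c(90, 110))
  expect_equal(unname(compute_cv(a)), sd(c(90, 110)) / 100 * 100)
  expect_equal(unname(compute_cv(a)), 14.14, tolerance = 0.01)
  a3 <- data.frame(run_id = paste0("r", 1:3), patient_id = "p1",
                   protein = "P1", peptide = "P1_pep1",
                   channel = "endogenous", area = c(100, 100, 100))
  expect_equal(unname(compute_cv(a3)), 0)
  a_scaled <- transform(a, area = area * 7)
  expect_equal(compute_cv(a_scaled), compute_cv(a))
})

test_that("failing peptides and poor samples are dropped by rule", {
  m <- matrix(rnorm(20, 15), 4, 5,
              dimnames = list(paste0("P", 1:4, "_pep1"),
                              paste0("r", 1:5)))
  m[1, 1:4] <- NA           # peptide missing in 80% of runs
  pq <- structure(list(log2_endogenous = m, log2_standard = m,
                       below_lod = is.na(m) & FALSE,
                       shifts = setNames(numeric(5), colnames(m)),
                       run_patient = setNames(paste0("p", 1:5),
                                              colnames(m))),
                  class = "peptide_quant")
  out <- drop_failed(pq, max_missing_peptide = 0.5)
  expect_identical(attr(out, "dropped_peptides"), "P1_pep1")
  # a sample missing most surviving peptides is dropped
  m2 <- m
  m2[2:4, 5] <- NA
  pq2 <- pq
  pq2$log2_endogenous <- m2
  out2 <- drop_failed(pq2, max_missing_sample = 0.5)
  expect_identical(attr(out2, "dropped_runs"), "r5")
  # no failures: unchanged
  pq$log2_endogenous[1, ] <- rnorm(5, 15)
  out3 <- drop_failed(pq)
  expect_equal(dim(out3$log2_endogenous), dim(m))
})

test_that("best-peptide rollup picks by CV then abundance and passes through", {
  m <- rbind(P1_pep1 = rnorm(4, 14), P1_pep2 = rnorm(4, 18),
             P2_pep1 = rnorm(4, 16))
  colnames(m) <- paste0("r", 1:4)
  pq <- structure(list(log2_endogenous = m, log2_standard = m,
                       below_lod = matrix(FALSE, 3, 4,
                                          dimnames = dimnames(m)),
                       shifts = setNames(numeric(4), colnames(m)),
                       run_patient = setNames(paste0("p", 1:4),
                                              colnames(m))),
                  class = "peptide_quant")
  cv <- c(P1_pep1 = 3, P1_pep2 = 8, P2_pep1 = 5)
  pm <- best_peptide_rollup(pq, cv = cv)
  expect_identical(unname(attr(pm, "chosen_peptides")["P1"]), "P1_pep1")
  expect_equal(unname(pm["P1", ]), unname(m["P1_pep1", ]))
  # single-peptide protein is forced
  expect_identical(unname(attr(pm, "chosen_peptides")["P2"]), "P2_pep1")
  # without CVs the higher-abundance peptide wins
  pm2 <- best_peptide_rollup(pq)
  expect_identical(unname(attr(pm2, "chosen_peptides")["P1"]), "P1_pep2")
})

test_that("minimum imputation fills every gap at the protein minimum", {
  v <- rbind(P1 = c(8, 10, NA), P2 = c(NA, 5, 7))
  colnames(v) <- paste0("r", 1:3)
  pm <- protein_matrix(v)
  out <- impute_min(pm)
  expect_equal(unname(out["P1", ]), c(8, 10, 8))
  expect_equal(unname(out["P2", ]), c(5, 5, 7))
  expect_false(anyNA(out))
  expect_identical(unname(attr(out, "imputed")["P1", ]),
                   c(FALSE, FALSE, TRUE))
  # no missing values: identity
  full <- protein_matrix(rbind(P1 = 1:3))
  expect_equal(unclass(impute_min(full)), unclass(full),
               ignore_attr = TRUE)
  # imputation never lowers the per-protein minimum
  expect_equal(apply(out, 1, min), apply(v, 1, min, na.rm = TRUE))
  all_na <- protein_matrix(rbind(P1 = c(NA_real_, NA_real_)))
  expect_error(impute_min(all_na), "no observed value")
})
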