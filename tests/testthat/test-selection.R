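# Resampled forward selection, consensus, clinical combination and the
# partial-chemosensitivity subset.

test_that("splits follow the 8:10 ratio with the documented rounding", {
  set.seed(71)
  y18 <- rep(c("chemoresistant", "chemosensitive"), 9)
  sp <- split_cohort(y18, stratified = FALSE)
  expect_length(sp$train, 8)
  expect_length(sp$validation, 10)
  y80 <- rep(c("chemoresistant", "chemosensitive"), c(30, 50))
  sp80 <- split_cohort(y80, stratified = FALSE)
  expect_length(sp80$train, 36)
  expect_length(sp80$validation, 44)
  expect_length(intersect(sp80$train, sp80$validation), 0)
})

test_that("stratified splits keep both classes in both parts", {
  y <- rep(c("chemoresistant", "chemosensitive"), c(25, 63))
  for (s in 1:50) {
    set.seed(s)
    sp <- split_cohort(y)
    expect_length(sp$train, 39)  # 11 + 28 per-class rounding
    expect_equal(sum(y[sp$train] == "chemoresistant"), 11)
    expect_setequal(unique(y[sp$validation]),
                    c("chemoresistant", "chemosensitive"))
  }
})

test_that("forward selection applies the strict AUC-gain stopping rule", {
  # construct features with known training AUC structure: A strong, B
  # adds nothing beyond noise
  d <- make_features(20, 30, 3, shift_cols = 1, shift = 3, seed = 73)
  fs <- forward_select(d$x, d$y, delta_auc = 0.2)
  expect_identical(fs$features, "PROT01")  # no pair gains > 0.2
  expect_length(fs$auc_path, 1)
  # with a tiny threshold more features enter, path strictly increases
  fs2 <- forward_select(d$x, d$y, delta_auc = 1e-4)
  expect_true(all(diff(fs2$auc_path) > 1e-4))
  # max_features caps the signature size
  fs3 <- forward_select(d$x, d$y, delta_auc = 1e-4, max_features = 2)
  expect_lte(length(fs3$features), 2)
})

test_that("greedy path matches an exhaustive per-step oracle", {
  set.seed(79)
  for (i in 1:30) {
    n <- sample(24:40, 1)
    p <- sample(2:5, 1)
    y01 <- integer(n)
    while (sum(y01) < 3 || sum(1 - y01) < 3) y01 <- rbinom(n, 1, 0.4)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("F%02d", 1:p)))
    x[y01 == 1, 1] <- x[y01 == 1, 1] + runif(1, 0, 2)
    fs <- forward_select(x, y01, delta_auc = 0.02)
    # replay every step exhaustively with the package's scoring
    chosen <- character(0)
    repeat {
      rem <- setdiff(colnames(x), chosen)
      if (!length(rem) ||
          length(chosen) >= length(fs$features)) break
      aucs <- vapply(rem, function(f) {
        chemosig:::.train_auc(x, y01, c(chosen, f))
      }, numeric(1))
      best <- rem[order(-aucs, rem)][1]
      gain <- if (length(chosen)) {
        max(aucs) - fs$auc_path[length(chosen)]
      } else {
        Inf
      }
      if (length(chosen) && !(gain > 0.02)) break
      chosen <- c(chosen, best)
      expect_identical(fs$features[length(chosen)], best)
      expect_equal(fs$auc_path[length(chosen)], max(aucs))
    }
    expect_identical(fs$features, chosen)
  }
})

test_that("single-feature scoring equals the refitted logistic AUC", {
  # the cov-sign shortcut must agree with an explicit univariate fit
  set.seed(83)
  for (i in 1:20) {
    n <- sample(20:50, 1)
    y01 <- integer(n)
    while (length(unique(y01)) < 2) y01 <- rbinom(n, 1, 0.5)
    x <- cbind(f = rnorm(n) - y01 * runif(1, -2, 2))
    short <- chemosig:::.train_auc(x, y01, "f")
    fit <- glm.fit(cbind(1, x), y01, family = binomial())
    expect_equal(short, roc_auc(fit$fitted.values, y01),
                 tolerance = 1e-9)
  }
})

test_that("repeated selection is reproducible and records valid repeats", {
  d <- make_features(12, 20, 6, shift_cols = 1:2, shift = 1.5, seed = 89)
  cfg <- selection_config(n_repeats = 25, seed = 101)
  r1 <- run_repeats(d$x, d$y, cfg)
  r2 <- run_repeats(d$x, d$y, cfg)
  expect_identical(r1, r2)
  expect_false(any(r1$failed))
  expect_true(all(r1$n_features >= 1))
  expect_true(all(r1$validation_auc >= 0 & r1$validation_auc <= 1))
  # training/validation AUC paths respect the acceptance rule
  sel <- attr(r1, "selections")
  expect_true(all(lengths(sel) == r1$n_features))
})

test_that("selection_config validates its fields", {
  expect_error(selection_config(n_repeats = 10), "seed")
  expect_error(selection_config(delta_auc = 0, seed = 1), "delta_auc")
  expect_error(selection_config(split_ratio = c(8, -1), seed = 1),
               "split_ratio")
})

test_that("consensus tallies unordered sets with documented tie-breaks", {
  d <- make_features(10, 14, 4, seed = 91)
  fake <- structure(
    data.frame(repeat_id = 1:5,
               combination = c("A+B+C", "B+A+C", "A+B+C", "A+B", "A+D"),
               n_features = c(3, 3, 3, 2, 2),
               train_auc = 0.9, validation_auc = 0.8, failed = FALSE),
    selections = list(c("PROT01", "PROT02", "PROT03"),
                      c("PROT02", "PROT01", "PROT03"),
                      c("PROT01", "PROT02", "PROT03"),
                      c("PROT01", "PROT02"),
                      c("PROT01", "PROT04")),
    class = c("chemosig_repeats", "data.frame"))
  cons <- consensus(fake, d$x, d$y)
  # order inside a combination does not matter: the trio counted 3 times
  expect_setequal(cons$proteins, c("PROT01", "PROT02", "PROT03"))
  expect_equal(cons$frequency, 3)
  # tie: the smaller set wins, then lexicographic
  fake2 <- fake
  attr(fake2, "selections") <- list(c("PROT01", "PROT02"),
                                    c("PROT01", "PROT02"),
                                    c("PROT01", "PROT03"),
                                    c("PROT01", "PROT03"),
                                    c("PROT01", "PROT02", "PROT03"))
  cons2 <- consensus(fake2, d$x, d$y)
  expect_setequal(cons2$proteins, c("PROT01", "PROT02"))
})

test_that("planted proteins dominate the consensus without false positives", {
  d <- make_features(25, 63, 10, shift_cols = 1:3, shift = 2.5,
                     seed = 93)
  reps <- run_repeats(d$x, d$y, selection_config(n_repeats = 60,
                                                 seed = 103))
  cons <- consensus(reps, d$x, d$y)
  # the consensus set is drawn entirely from the planted proteins: no
  # noise feature survives the frequency tally
  expect_gte(length(cons$proteins), 1)
  expect_true(all(cons$proteins %in% sprintf("PROT%02d", 1:3)))
  expect_gt(cons$roc$auc, 0.9)
  expect_gt(mean(reps$validation_auc), 0.85)
})

test_that("clinical encoding and combined evaluation behave sensibly", {
  co <- generate_cohort(cohort_spec(seed = 107))
  clin <- encode_clinical(co)
  expect_identical(colnames(clin),
                   c("age", "postmenopausal", "log_ca125", "neoadjuvant"))
  expect_equal(nrow(clin), 88)
  d <- make_features(25, 63, 8, shift_cols = 1:2, shift = 1.5, seed = 109)
  ev <- evaluate_with_clinical(d$x, c("PROT01", "PROT02"), clin, d$y)
  expect_true(ev$combined$auc > 0.5)
  expect_true(ev$p_value >= 0 && ev$p_value <= 1)
  expect_equal(ev$n_excluded, 0)
  # missing covariate excludes the sample with a warning
  co2 <- co
  co2$ca125[1] <- NA
  expect_warning(clin2 <- encode_clinical(co2), "excluded")
  expect_equal(nrow(clin2), 87)
  ev2 <- evaluate_with_clinical(d$x, c("PROT01", "PROT02"), clin2, d$y)
  expect_equal(ev2$n_excluded, 1)
})

test_that("pure-noise covariates barely move a strong protein signature", {
  d <- make_features(150, 250, 4, shift_cols = 1:2, shift = 1.5,
                     seed = 113)
  noise <- matrix(rnorm(400 * 4), 400, 4,
                  dimnames = list(NULL, c("age", "postmenopausal",
                                          "log_ca125", "neoadjuvant")))
  ev <- evaluate_with_clinical(d$x, c("PROT01", "PROT02"), noise, d$y)
  expect_lt(abs(ev$combined$auc - ev$proteins$auc), 0.02)
})

test_that("partial-chemosensitivity subset applies the (6, 12] window", {
  co <- data.frame(
    patient_id = paste0("P", 1:5),
    tfip_months = c(3, 5, 8, 11, 20),
    group = c("chemoresistant", "chemoresistant", "chemosensitive",
              "chemosensitive", "chemosensitive"))
  sub <- partial_sensitivity_subset(co)
  expect_setequal(sub$patient_id, c("P1", "P2", "P3", "P4"))
  expect_equal(attr(sub, "n_partial"), 2)
  # boundary: TFIp = 12 is retained
  co$tfip_months[3] <- 12
  expect_true("P3" %in% partial_sensitivity_subset(co)$patient_id)
  # no partially sensitive patients: error
  co$tfip_months[3:5] <- c(20, 30, 40)
  expect_error(partial_sensitivity_subset(co), "TFIp")
})
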