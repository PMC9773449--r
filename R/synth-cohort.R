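# Synthetic clinical cohorts. Group structure follows the verification
# design: chemoresistant = recurrence with TFIp < 6 months, chemosensitive
# = TFIp > 6 months. Covariate defaults give a mildly older, mostly
# postmenopausal, higher-CA125, more often neoadjuvant-treated resistant
# group, in line with the cohort tables the design emulates.

#' Specification of a synthetic clinical cohort
#'
#' @param n_resistant,n_sensitive Group sizes (default 25 / 63).
#' @param tfip_resistant_range Months, within (0, 6). Default `c(1, 5)`.
#' @param tfip_sensitive_range Months, within (6, Inf). Default
#'   `c(6.5, 63)`; draws are log-uniform to mimic the long right tail of
#'   recurrence times.
#' @param clinical_effects List of per-covariate group effects:
#'   `age_shift` (years added to the resistant group), `p_postmenopausal`
#'   (length-2 `c(resistant, sensitive)` probabilities), `log_ca125_shift`
#'   (added to the resistant group's log CA125), `p_neoadjuvant` (length-2
#'   probabilities), `p_dead` (length-2 probabilities).
#' @param age_mean,age_sd Baseline (sensitive-group) age distribution,
#'   truncated to \[35, 85\].
#' @param ca125_meanlog,ca125_sdlog Baseline log-normal CA125 (U/mL).
#' @param seed Integer seed (required).
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_resistant = 25, n_sensitive = 63,
                        tfip_resistant_range = c(1, 5),
                        tfip_sensitive_range = c(6.5, 63),
                        clinical_effects = list(),
                        age_mean = 59, age_sd = 9,
                        ca125_meanlog = 6.4, ca125_sdlog = 1.2,
                        seed) {
  if (missing(seed)) stop("cohort_spec: 'seed' is required", call. = FALSE)
  eff <- utils::modifyList(list(
    age_shift = 4,
    p_postmenopausal = c(0.96, 0.71),
    log_ca125_shift = 0.5,
    p_neoadjuvant = c(0.72, 0.30),
    p_dead = c(1.0, 0.51)
  ), clinical_effects)
  if (n_resistant < 2 || n_sensitive < 2) {
    stop("cohort_spec: counts must be >= 2 per group ('n_resistant'/",
         "'n_sensitive')", call. = FALSE)
  }
  if (tfip_resistant_range[1] <= 0 || tfip_resistant_range[2] >= 6) {
    stop("cohort_spec: 'tfip_resistant_range' must lie within (0, 6)",
         call. = FALSE)
  }
  if (tfip_sensitive_range[1] <= 6) {
    stop("cohort_spec: 'tfip_sensitive_range' must lie within (6, Inf)",
         call. = FALSE)
  }
  for (p in c("p_postmenopausal", "p_neoadjuvant", "p_dead")) {
    if (any(eff[[p]] < 0 | eff[[p]] > 1)) {
      stop("cohort_spec: '", p, "' probabilities must be in [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(n_resistant = as.integer(n_resistant),
                 n_sensitive = as.integer(n_sensitive),
                 tfip_resistant_range = tfip_resistant_range,
                 tfip_sensitive_range = tfip_sensitive_range,
                 effects = eff, age_mean = age_mean, age_sd = age_sd,
                 ca125_meanlog = ca125_meanlog, ca125_sdlog = ca125_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# inverse-CDF truncated normal: deterministic given the RNG stream
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# FIGO stage frequencies per group (resistant; sensitive)
.stage_levels <- c("IIIA", "IIIB", "IIIC", "IVA", "IVB")
.stage_probs <- list(resistant = c(0, 0.04, 0.64, 0.12, 0.20),
                     sensitive = c(0.03, 0.10, 0.71, 0.06, 0.10))

#' Generate a synthetic clinical cohort
#'
#' Draws one record per patient: TFIp inside the per-group range (uniform
#' for the resistant group, log-uniform for the sensitive group), age from
#' a truncated normal, menopausal status / treatment / vital status from
#' per-group Bernoulli probabilities, CA125 log-normal, FIGO stage from
#' per-group frequencies. The response group is derived from TFIp.
#' Deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @return `data.frame` with columns `patient_id`, `age`,
#'   `menopausal_status` (pre/post), `stage`, `ca125`, `treatment`
#'   (surgery/neoadjuvant), `tfip_months`, `status` (alive/dead), `group`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 1))
#' table(cohort$group)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  eff <- spec$effects
  one_group <- function(n, resistant) {
    i <- if (resistant) 1L else 2L
    tfip <- if (resistant) {
      stats::runif(n, spec$tfip_resistant_range[1],
                   spec$tfip_resistant_range[2])
    } else {
      exp(stats::runif(n, log(spec$tfip_sensitive_range[1]),
                       log(spec$tfip_sensitive_range[2])))
    }
    data.frame(
      age = round(.rtruncnorm(n, spec$age_mean +
                                if (resistant) eff$age_shift else 0,
                              spec$age_sd, 35, 85), 1),
      menopausal_status = ifelse(
        stats::rbinom(n, 1, eff$p_postmenopausal[i]) == 1, "post", "pre"),
      stage = sample(.stage_levels, n, replace = TRUE,
                     prob = .stage_probs[[if (resistant) "resistant"
                                          else "sensitive"]]),
      ca125 = round(stats::rlnorm(n, spec$ca125_meanlog +
                                    if (resistant) eff$log_ca125_shift
                                    else 0,
                                  spec$ca125_sdlog), 1),
      treatment = ifelse(stats::rbinom(n, 1, eff$p_neoadjuvant[i]) == 1,
                         "neoadjuvant", "surgery"),
      tfip_months = round(tfip, 2),
      status = ifelse(stats::rbinom(n, 1, eff$p_dead[i]) == 1,
                      "dead", "alive")
    )
  }
  out <- rbind(one_group(spec$n_resistant, TRUE),
               one_group(spec$n_sensitive, FALSE))
  out <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(out))), out)
  out$group <- ifelse(out$tfip_months < 6, "chemoresistant",
                      "chemosensitive")
  rownames(out) <- NULL
  out
}
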