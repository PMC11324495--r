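#' Configuration for the synthetic screening-cohort generator
#'
#' Bundles and validates every parameter of the synthetic PLCO-like cohort:
#' the SNP panel (allele frequencies and per-allele effects), the
#' proportional-hazards incidence model, censoring, the baseline PSA model,
#' high-grade (Gleason >= 7) assignment among cases, and post-diagnosis
#' prostate-cancer mortality.
#'
#' Defaults are calibrated so that a cohort of 30,000 men aged 55-74
#' reproduces the broad strokes of a PLCO-like screening population:
#' roughly 12% cumulative prostate-cancer incidence over ~12 years of
#' follow-up (an overall event rate near 11 per 1,000 person-years), a PRS
#' whose case/control AUC is about 0.63, a baseline PSA whose 10-year
#' time-dependent AUC is about 0.8, and Gleason >= 7 disease in roughly 39%
#' of cases detected by a PSA > 4 ng/mL screen.
#'
#' @param n_participants Number of men in the cohort.
#' @param n_snps Number of risk SNPs on the panel.
#' @param maf_range Length-2 vector in (0, 0.5]; minor-allele frequencies are
#'   drawn uniformly from this interval.
#' @param logor_mean,logor_sd Mean and SD of the per-allele log odds ratio
#'   drawn for each SNP; the risk allele is defined as the allele with a
#'   positive effect.
#' @param baseline_hazard Baseline diagnosis hazard, events per person-year,
#'   for a man at the centred linear predictor.
#' @param age_loghr Log hazard ratio per year of age (centred at 65) on
#'   diagnosis.
#' @param followup_admin_years Length-2 vector (min, max) of administrative
#'   censoring times for incidence follow-up, drawn uniformly.
#' @param dropout_rate Exponential dropout (loss to follow-up) rate per
#'   person-year.
#' @param mortality_extra_years Additional years of mortality follow-up past
#'   the administrative incidence cut (death ascertainment continues after
#'   cancer ascertainment closes).
#' @param psa_log_intercept Intercept of log baseline PSA (log ng/mL) at age
#'   55 for an average-risk, never-diagnosed man.
#' @param psa_age_slope Increase in log PSA per year of age.
#' @param psa_risk_coef Log-PSA increase per unit of centred genetic score.
#' @param psa_case_shift Maximal pre-clinical log-PSA elevation for a case on
#'   the eve of diagnosis; the elevation decays linearly to zero ten years
#'   before diagnosis (`w(dt) = max(0, 1 - dt/10)`).
#' @param psa_sigma Residual SD of log PSA.
#' @param gleason_high_prob_coef Named vector `c(intercept, log_psa, risk)`:
#'   logistic model for P(Gleason >= 7) among cases, on centred log PSA and
#'   the genetic score.
#' @param death_given_case_rate Post-diagnosis prostate-cancer death hazard
#'   per person-year, applied to cases only.
#' @param covariate_freqs Named list of prevalence specifications for the
#'   baseline covariates (see defaults).
#' @param covariate_loghr Named vector of log hazard ratios applied to
#'   family history, enlarged prostate, diabetes, current smoking and black
#'   race in the diagnosis model.
#' @param screening_arm_prob Probability a participant is randomised to the
#'   screening arm.
#' @param missing_rate Fraction of genotype entries set missing (completely
#'   at random) in the returned dosage matrix.
#' @param seed Integer seed; the panel stream uses `seed`, the cohort stream
#'   `seed + 1`, so all randomness flows from one base seed per run.
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_participants = 500, seed = 1)
#' cfg$n_snps
#' @export
sim_config <- function(n_participants = 30000,
                       n_snps = 80,
                       maf_range = c(0.1, 0.5),
                       logor_mean = 0.064,
                       logor_sd = 0.04,
                       baseline_hazard = 0.0103,
                       age_loghr = 0.04,
                       followup_admin_years = c(10, 13),
                       dropout_rate = 0.01,
                       mortality_extra_years = 6,
                       psa_log_intercept = -0.05,
                       psa_age_slope = 0.025,
                       psa_risk_coef = 0.15,
                       psa_case_shift = 1.7,
                       psa_sigma = 0.7,
                       gleason_high_prob_coef = c(
                         intercept = -1.17,
                         log_psa = 0.35,
                         risk = 0.25
                       ),
                       death_given_case_rate = 0.0075,
                       covariate_freqs = list(
                         family_history_pca = 0.07,
                         enlarged_prostate = 0.22,
                         diabetes = 0.07,
                         smoking = c(never = 0.42, former = 0.48, current = 0.10),
                         race = c(white = 0.88, black = 0.04, other = 0.08),
                         bmi_class = c(`0-25` = 0.26, `25-30` = 0.49, `>30` = 0.25),
                         prior_psa_tests = c(`0` = 0.45, `1` = 0.20, `>=2` = 0.35)
                       ),
                       covariate_loghr = c(
                         family_history_pca = 0.40,
                         enlarged_prostate = 0.15,
                         diabetes = 0.10,
                         smoking_current = 0.10,
                         race_black = 0.30
                       ),
                       screening_arm_prob = 0.586,
                       missing_rate = 0.02,
                       seed = 20240801) {
  cfg <- as.list(environment())

  stopifnot(
    n_participants >= 1, n_snps >= 1,
    length(maf_range) == 2, length(followup_admin_years) == 2
  )
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must lie within (0, 0.5] with min <= max.")
  }
  if (baseline_hazard <= 0 || dropout_rate <= 0 || death_given_case_rate <= 0) {
    abort("Hazard and dropout rates must be strictly positive.")
  }
  if (followup_admin_years[1] <= 0 ||
    followup_admin_years[1] > followup_admin_years[2]) {
    abort("`followup_admin_years` must be positive and ordered (min, max).")
  }
  if (psa_sigma <= 0 || logor_sd < 0) abort("Scale parameters must be >= 0.")
  scalar_freqs <- unlist(covariate_freqs[c(
    "family_history_pca", "enlarged_prostate", "diabetes"
  )])
  multi <- covariate_freqs[c("smoking", "race", "bmi_class", "prior_psa_tests")]
  if (any(scalar_freqs <= 0) || any(scalar_freqs >= 1)) {
    abort("Scalar covariate prevalences must lie in (0, 1).")
  }
  ok <- vapply(multi, function(p) {
    all(p > 0) && abs(sum(p) - 1) < 1e-8
  }, logical(1))
  if (!all(ok)) {
    abort("Multinomial covariate frequency vectors must be positive and sum to 1.")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  if (screening_arm_prob <= 0 || screening_arm_prob > 1) {
    abort("`screening_arm_prob` must lie in (0, 1].")
  }
  cfg$seed <- as.integer(seed)

  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d participants, %d SNPs, seed %d\n",
    x$n_participants, x$n_snps, x$seed
  ))
  cat(sprintf(
    "  baseline hazard %.4f /py, admin follow-up %.0f-%.0f y, dropout %.3f /py\n",
    x$baseline_hazard, x$followup_admin_years[1], x$followup_admin_years[2],
    x$dropout_rate
  ))
  invisible(x)
}
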