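#' Simulate a SNP risk panel
#'
#' Draws a panel of independent risk SNPs: minor-allele frequencies uniform
#' over `config$maf_range` and per-allele log odds ratios from
#' `N(logor_mean, logor_sd)`. The risk allele is, by definition, the allele
#' with the positive effect; when a drawn effect is negative the coding is
#' flipped, so `risk_allele_freq` may exceed 0.5 while `maf` always stays in
#' the configured range. `published_beta`/`published_p` mimic the external
#' GWAS summary statistics a real panel would carry and equal the generating
#' truth here.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per SNP: `rsid`, `risk_allele`,
#'   `other_allele`, `maf`, `risk_allele_freq`, `beta_true`,
#'   `published_beta`, `published_p`.
#' @examples
#' panel <- simulate_panel(sim_config(n_snps = 5, seed = 1))
#' panel
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$n_snps

  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  beta <- rnorm(p, config$logor_mean, config$logor_sd)

  flip <- beta < 0
  risk_freq <- ifelse(flip, 1 - maf, maf)
  beta_risk <- abs(beta)

  alleles <- c("A", "C", "G", "T")
  a1 <- sample(alleles, p, replace = TRUE)
  a2 <- vapply(a1, function(a) sample(setdiff(alleles, a), 1L), character(1))

  tibble(
    rsid = sprintf("rs%06d", seq_len(p)),
    risk_allele = unname(a1),
    other_allele = unname(a2),
    maf = maf,
    risk_allele_freq = risk_freq,
    beta_true = beta_risk,
    published_beta = beta_risk,
    published_p = 5e-8 * runif(p)
  )
}

sample_levels <- function(n, freqs) {
  factor(
    sample(names(freqs), n, replace = TRUE, prob = freqs),
    levels = names(freqs)
  )
}

#' Simulate a censored screening cohort with genotypes
#'
#' Generates genotypes under Hardy-Weinberg equilibrium
#' (`dosage ~ Binomial(2, risk_allele_freq)` per SNP), a latent genetic risk
#' score `g = sum(beta * dosage)` (centred), diagnosis times from an
#' exponential proportional-hazards model on `g`, age and the baseline
#' covariates, censoring as the minimum of uniform administrative follow-up
#' and exponential dropout, baseline PSA from a log-normal model that rises
#' with age, with genetic risk, and with proximity to a forthcoming
#' diagnosis (`psa_case_shift * max(0, 1 - t_dx/10)` for observed cases),
#' Gleason >= 7 status among cases from a logistic model on log PSA and `g`,
#' and prostate-cancer death among cases from an exponential post-diagnosis
#' hazard censored at `mortality_extra_years` past the administrative
#' incidence cut.
#'
#' A `missing_rate` fraction of genotype entries is blanked completely at
#' random in the returned matrix; the latent risk uses the complete
#' genotypes, so imputation error is a property of downstream analysis, not
#' of the truth.
#'
#' @param config A [sim_config()].
#' @param panel A panel from [simulate_panel()] (or any tibble with `rsid`,
#'   `risk_allele_freq`, `beta_true`).
#' @return A list of class `sim_cohort` with elements `cohort` (tibble, one
#'   row per participant) and `genotypes` (integer matrix, participants x
#'   SNPs, risk-allele dosages 0/1/2 with `NA` for missing).
#' @examples
#' cfg <- sim_config(n_participants = 200, seed = 1)
#' sim <- simulate_cohort(cfg, simulate_panel(cfg))
#' head(sim$cohort)
#' @export
simulate_cohort <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"))
  req <- c("rsid", "risk_allele_freq", "beta_true")
  if (!all(req %in% names(panel))) {
    abort("`panel` must carry rsid, risk_allele_freq and beta_true columns.")
  }
  set.seed(config$seed + 1L)

  n <- config$n_participants
  p <- nrow(panel)
  f <- panel$risk_allele_freq
  beta <- panel$beta_true

  id <- sprintf("P%06d", seq_len(n))
  arm <- ifelse(runif(n) < config$screening_arm_prob, "screening", "control")

  # entry ages 55-74, mildly front-loaded as in trial accrual
  age <- sample(55:74, n, replace = TRUE, prob = seq(1, 0.5, length.out = 20)) +
    runif(n)

  cv <- config$covariate_freqs
  family_history <- rbinom(n, 1, cv$family_history_pca)
  enlarged <- rbinom(n, 1, cv$enlarged_prostate)
  diabetes <- rbinom(n, 1, cv$diabetes)
  smoking <- sample_levels(n, cv$smoking)
  race <- sample_levels(n, cv$race)
  bmi_class <- sample_levels(n, cv$bmi_class)
  prior_psa <- sample_levels(n, cv$prior_psa_tests)

  G <- matrix(
    rbinom(n * p, 2L, rep(f, each = n)),
    nrow = n, ncol = p, dimnames = list(id, panel$rsid)
  )
  g <- drop(G %*% beta) - sum(2 * f * beta)

  hr <- config$covariate_loghr
  cov_lp <- hr[["family_history_pca"]] * family_history +
    hr[["enlarged_prostate"]] * enlarged +
    hr[["diabetes"]] * diabetes +
    hr[["smoking_current"]] * (smoking == "current") +
    hr[["race_black"]] * (race == "black")
  cov_lp <- cov_lp - (hr[["family_history_pca"]] * cv$family_history_pca +
    hr[["enlarged_prostate"]] * cv$enlarged_prostate +
    hr[["diabetes"]] * cv$diabetes +
    hr[["smoking_current"]] * cv$smoking[["current"]] +
    hr[["race_black"]] * cv$race[["black"]])
  lp <- g + cov_lp + config$age_loghr * (age - 65)

  t_event <- rexp(n, rate = config$baseline_hazard * exp(lp))
  c_admin <- runif(n, config$followup_admin_years[1], config$followup_admin_years[2])
  c_drop <- rexp(n, rate = config$dropout_rate)
  censor <- pmin(c_admin, c_drop)
  dx_event <- as.integer(t_event <= censor)
  t_dx <- pmin(t_event, censor)

  # pre-clinical PSA elevation, linear over the 10 years before diagnosis
  w <- ifelse(dx_event == 1L, pmax(0, 1 - t_dx / 10), 0)
  log_psa <- config$psa_log_intercept +
    config$psa_age_slope * (age - 55) +
    config$psa_risk_coef * g +
    config$psa_case_shift * w +
    rnorm(n, 0, config$psa_sigma)
  psa <- exp(log_psa)

  gleason <- rep(NA_integer_, n)
  case <- which(dx_event == 1L)
  if (length(case)) {
    gc <- config$gleason_high_prob_coef
    eta <- gc[["intercept"]] +
      gc[["log_psa"]] * (log_psa[case] - mean(log_psa)) +
      gc[["risk"]] * g[case]
    gleason[case] <- rbinom(length(case), 1, plogis(eta))
  }

  mort_censor <- c_admin + config$mortality_extra_years
  t_death <- mort_censor
  pca_death <- integer(n)
  if (length(case)) {
    t_d_event <- t_dx[case] + rexp(length(case), config$death_given_case_rate)
    pca_death[case] <- as.integer(t_d_event <= mort_censor[case])
    t_death[case] <- pmin(t_d_event, mort_censor[case])
  }

  if (config$missing_rate > 0) {
    miss <- runif(n * p) < config$missing_rate
    G[miss] <- NA_integer_
  }

  cohort <- tibble(
    id = id,
    arm = arm,
    age_entry_years = age,
    age_group = assign_age_group(age),
    race = race,
    bmi_class = bmi_class,
    smoking = smoking,
    family_history_pca = family_history,
    prior_psa_tests = prior_psa,
    enlarged_prostate = enlarged,
    diabetes = diabetes,
    psa_baseline_ng_ml = psa,
    t_dx_years = t_dx,
    dx_event = dx_event,
    t_death_years = t_death,
    pca_death_event = pca_death,
    gleason_ge7 = gleason
  )

  structure(list(cohort = cohort, genotypes = G), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d participants x %d SNPs; %d diagnoses, %d PCa deaths\n",
    nrow(x$cohort), ncol(x$genotypes),
    sum(x$cohort$dx_event), sum(x$cohort$pca_death_event)
  ))
  invisible(x)
}

# fixture writers -------------------------------------------------------------

#' Write simulated data as plain-text fixtures
#'
#' `write_cohort()` writes the participant table as CSV, `write_panel()` the
#' SNP panel as CSV, and `write_genotypes()` the dosage matrix as TSV (first
#' column `id`, one column per rsid, `NA` for missing).
#'
#' @param cohort,panel Tibbles as produced by the simulator.
#' @param genotypes Dosage matrix with participant rownames and rsid
#'   colnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_genotypes <- function(genotypes, path) {
  df <- as_tibble(genotypes, rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV file path.
#' @return A cohort tibble with the factor columns restored.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cohort file not found: %s", path))
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  if ("age_group" %in% names(cohort)) {
    cohort$age_group <- factor(cohort$age_group, levels = age_group_levels())
  }
  cohort
}
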