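outcome_cols <- function(outcome) {
  switch(match.arg(outcome, c("incidence", "mortality")),
    incidence = c(time = "t_dx_years", event = "dx_event"),
    mortality = c(time = "t_death_years", event = "pca_death_event")
  )
}

#' Default adjustment covariates
#'
#' The baseline covariates adjusted for in the multivariable models: age
#' group, race, BMI class, smoking status, family history of prostate
#' cancer, prior PSA testing, history of enlarged prostate and diabetes.
#'
#' @return Character vector of column names.
#' @export
std_adjustment <- function() {
  c(
    "age_group", "race", "bmi_class", "smoking", "family_history_pca",
    "prior_psa_tests", "enlarged_prostate", "diabetes"
  )
}

#' Person-year event rates by group
#'
#' Sums follow-up person-years from entry to event or censoring within each
#' group and reports events per 1,000 person-years, with the group shares of
#' participants and of events.
#'
#' @param cohort Cohort tibble.
#' @param by Character vector of grouping columns (empty for the overall
#'   rate).
#' @param outcome `"incidence"` (diagnosis follow-up) or `"mortality"`
#'   (death follow-up).
#' @return A tibble with, per group: `n`, `pct_participants`, `n_events`,
#'   `pct_events`, `person_years_thousands`, `rate_per_1000_py`.
#' @examples
#' cohort <- tibble::tibble(
#'   g = c("a", "a", "b"), t_dx_years = c(5, 10, 8), dx_event = c(1, 0, 1)
#' )
#' person_year_rates(cohort, by = "g")
#' @export
person_year_rates <- function(cohort, by = character(), outcome = "incidence") {
  cols <- outcome_cols(outcome)
  time <- cohort[[cols[["time"]]]]
  event <- check_binary(cohort[[cols[["event"]]]], cols[["event"]])
  if (any(time < 0) || anyNA(time)) abort("Follow-up times must be non-negative.")

  df <- cohort |>
    mutate(.time = time, .event = event) |>
    group_by(across(all_of(by))) |>
    summarise(
      n = dplyr::n(),
      n_events = sum(.data$.event),
      person_years_thousands = sum(.data$.time) / 1000,
      .groups = "drop"
    ) |>
    mutate(
      pct_participants = 100 * .data$n / sum(.data$n),
      pct_events = 100 * .data$n_events / sum(.data$n_events),
      rate_per_1000_py = .data$n_events / .data$person_years_thousands
    ) |>
    select(
      all_of(by), "n", "pct_participants", "n_events", "pct_events",
      "person_years_thousands", "rate_per_1000_py"
    )
  df
}

prep_model_data <- function(cohort, vars) {
  out <- cohort |> select(all_of(vars))
  for (v in vars) {
    x <- out[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      f <- forcats::fct_na_value_to_level(factor(x), level = "missing")
      out[[v]] <- droplevels(f)
    }
  }
  out
}

#' Multivariable Cox proportional-hazards fit
#'
#' Fits the partial likelihood with Efron tie handling for an exposure of
#' interest plus an adjustment set. Categorical covariates (and categorical
#' exposures) get an explicit `"missing"` level rather than dropping rows,
#' so the analysed n equals the cohort n.
#'
#' @param cohort Cohort tibble.
#' @param exposure Name of the exposure column.
#' @param outcome `"incidence"` or `"mortality"`.
#' @param adjust Character vector of adjustment columns (default
#'   [std_adjustment()], less the exposure itself).
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @return A list of class `cox_fit`: the underlying `coxph` `fit`, a tidy
#'   `terms` table (term, level, log HR, HR, CI, p), `exposure`, `outcome`,
#'   `n`, `n_events`. `tidy()` returns the term table, `glance()` the
#'   exposure row(s).
#' @examples
#' cfg <- sim_config(n_participants = 2000, seed = 5)
#' sim <- simulate_cohort(cfg, simulate_panel(cfg))
#' fit <- cox_fit(sim$cohort, exposure = "family_history_pca")
#' glance(fit)
#' @export
cox_fit <- function(cohort, exposure, outcome = "incidence",
                    adjust = setdiff(std_adjustment(), exposure),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cols <- outcome_cols(outcome)
  stopifnot(exposure %in% names(cohort))
  adjust <- setdiff(adjust, exposure)
  missing_adj <- setdiff(adjust, names(cohort))
  if (length(missing_adj)) {
    abort(sprintf(
      "Adjustment column(s) not in cohort: %s",
      paste(missing_adj, collapse = ", ")
    ))
  }

  event <- check_binary(cohort[[cols[["event"]]]], cols[["event"]])
  if (sum(event) < 1) abort("At least one event is required.")
  if (length(unique(cohort[[exposure]])) < 2L) {
    abort(sprintf("Exposure `%s` does not vary.", exposure))
  }

  md <- prep_model_data(cohort, c(exposure, adjust))
  md$.time <- cohort[[cols[["time"]]]]
  md$.event <- event

  fml <- as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", c(exposure, adjust)), collapse = " + ")
  ))
  fit <- tryCatch(
    coxph(fml, data = md, ties = ties),
    error = function(e) abort(sprintf("Cox model failed to converge: %s", conditionMessage(e)))
  )
  monotone <- any(abs(coef(fit)) > 10, na.rm = TRUE)
  if (monotone) {
    warn("Possible monotone likelihood: some |log HR| > 10; interpret with care.")
  }

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  terms <- tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    hr = exp(unname(est)),
    conf_low = exp(unname(est) - qnorm(0.975) * unname(se)),
    conf_high = exp(unname(est) + qnorm(0.975) * unname(se)),
    p = 2 * pnorm(-abs(unname(est) / unname(se)))
  )

  structure(
    list(
      fit = fit, terms = terms, exposure = exposure, outcome = outcome,
      adjust = adjust, ties = ties,
      n = nrow(md), n_events = sum(event), monotone = monotone
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> %s ~ %s (+%d covariates), %d subjects / %d events\n",
    x$outcome, x$exposure, length(x$adjust), x$n, x$n_events
  ))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) x$terms

#' @export
glance.cox_fit <- function(x, ...) {
  x$terms |>
    filter(startsWith(.data$term, x$exposure) |
      startsWith(.data$term, sprintf("`%s`", x$exposure))) |>
    mutate(n = x$n, n_events = x$n_events)
}

combo_levels <- c("low/PSA-", "low/PSA+", "high/PSA-", "high/PSA+")

psa_prs_combo <- function(prs_group, psa_positive) {
  factor(
    paste0(
      as.character(prs_group),
      ifelse(psa_positive, "/PSA+", "/PSA-")
    ),
    levels = combo_levels
  )
}

#' Joint PRS x PSA interaction analysis
#'
#' Implements the two interaction codings for the joint association of PRS
#' group and PSA positivity with prostate-cancer incidence or mortality:
#'
#' * `"age_stratified_4level"` — within each age group, a 4-level factor
#'   \{low/PSA-, low/PSA+, high/PSA-, high/PSA+\} with low/PSA- as the
#'   within-stratum reference; one adjusted Cox model per age group.
#' * `"cross_age_16level"` — one model with a single 16-level factor (the 4
#'   combinations crossed with the 4 age groups, age-major ordering) whose
#'   uniform reference is low/PSA- at age <60.
#'
#' The cohort must already carry `prs_group` and a logical `psa_positive`
#' column (typically from [classify_screening()] with the age- and
#' PRS-specific cut-offs). Empty levels are dropped with a warning.
#'
#' @param cohort Cohort tibble with `prs_group`, `psa_positive`, `age_group`.
#' @param scheme Interaction coding (see above).
#' @param outcome `"incidence"` or `"mortality"`.
#' @param adjust Adjustment columns; `age_group` is handled by the scheme
#'   and removed from the covariates automatically.
#' @return A tibble with one row per factor level (reference rows included
#'   with HR 1): `age_group`, `level`, `hr`, `conf_low`, `conf_high`, `p`,
#'   `reference`, `n`, `n_events`.
#' @export
interaction_analysis <- function(cohort,
                                 scheme = c("age_stratified_4level", "cross_age_16level"),
                                 outcome = "incidence",
                                 adjust = std_adjustment()) {
  scheme <- match.arg(scheme)
  need <- c("prs_group", "psa_positive", "age_group")
  if (!all(need %in% names(cohort))) {
    abort("Cohort needs prs_group, psa_positive and age_group columns.")
  }
  adjust <- setdiff(adjust, c("age_group", "prs_group", "psa_positive"))

  cohort <- cohort |>
    mutate(.combo = psa_prs_combo(.data$prs_group, .data$psa_positive))

  extract <- function(fit, lev_all, lev_ref, age_of_level) {
    terms <- tidy(fit)
    got <- sub("^`?\\.term`?", "", terms$term)
    purrr::map(lev_all, function(lv) {
      if (lv == lev_ref) {
        tibble(
          level = lv, hr = 1, conf_low = NA_real_, conf_high = NA_real_,
          p = NA_real_, reference = TRUE
        )
      } else if (lv %in% got) {
        i <- match(lv, got)
        tibble(
          level = lv, hr = terms$hr[i], conf_low = terms$conf_low[i],
          conf_high = terms$conf_high[i], p = terms$p[i], reference = FALSE
        )
      } else {
        tibble(
          level = lv, hr = NA_real_, conf_low = NA_real_,
          conf_high = NA_real_, p = NA_real_, reference = FALSE
        )
      }
    }) |>
      list_rbind() |>
      mutate(
        age_group = age_of_level(.data$level),
        n = fit$n, n_events = fit$n_events
      )
  }

  if (scheme == "age_stratified_4level") {
    out <- purrr::map(age_group_levels(), function(ag) {
      sub <- cohort |> filter(.data$age_group == ag)
      sub$.term <- droplevels(sub$.combo)
      if (nlevels(sub$.term) < nlevels(sub$.combo)) {
        warn(sprintf("Empty PRS/PSA level(s) dropped in age group %s.", ag))
      }
      fit <- cox_fit(sub, exposure = ".term", outcome = outcome, adjust = adjust)
      extract(fit, combo_levels, combo_levels[1], function(...) ag)
    }) |> list_rbind()
  } else {
    lev16 <- as.vector(outer(combo_levels, age_group_levels(),
      function(cb, ag) paste(ag, cb, sep = " | ")
    ))
    cohort$.term <- factor(
      paste(as.character(cohort$age_group), as.character(cohort$.combo), sep = " | "),
      levels = lev16
    )
    drop_n <- sum(table(cohort$.term) == 0)
    if (drop_n > 0) {
      warn(sprintf("%d empty level(s) dropped from the 16-level coding.", drop_n))
    }
    cohort$.term <- droplevels(cohort$.term)
    fit <- cox_fit(cohort, exposure = ".term", outcome = outcome, adjust = adjust)
    out <- extract(
      fit, lev16, lev16[1],
      function(lv) sub(" \\|.*$", "", lv)
    )
  }
  out |>
    select(
      "age_group", "level", "hr", "conf_low", "conf_high", "p",
      "reference", "n", "n_events"
    )
}

#' Log-rank test
#'
#' Standard log-rank comparison of survival between groups.
#'
#' @param cohort Cohort tibble.
#' @param by Name of the grouping column (>= 2 groups with events).
#' @param outcome `"incidence"` or `"mortality"`.
#' @return One-row tibble: `chisq`, `df`, `p`.
#' @export
logrank <- function(cohort, by, outcome = "incidence") {
  cols <- outcome_cols(outcome)
  g <- cohort[[by]]
  if (length(unique(g)) < 2L) abort("Log-rank needs at least two groups.")
  sd <- survdiff(
    Surv(cohort[[cols[["time"]]]], cohort[[cols[["event"]]]]) ~ g
  )
  df <- length(sd$n) - 1
  tibble(chisq = sd$chisq, df = df, p = pchisq(sd$chisq, df, lower.tail = FALSE))
}
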