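#' Derive PRS-specific and age-specific PSA cut-offs
#'
#' Runs the time-dependent ROC ([td_roc()]) of baseline PSA within every
#' requested (PRS stratum x age group) cell and assembles the cut-off table
#' used by the screening strategies. The stratum value `"all"` denotes no
#' restriction on that axis; the overall (all, all) cell is always included.
#' Cells with fewer than `min_cases` events by the horizon are flagged
#' `unreliable` (their cut-off is still reported); cells where the tdROC is
#' undefined (no cases or no controls) get an `NA` cut-off and the flag.
#'
#' @param cohort Cohort tibble; needs `psa_baseline_ng_ml`, `t_dx_years`,
#'   `dx_event`, `age_group`, and `prs_group` when `by` includes `"prs"`.
#' @param by Stratification axes: any of `"age"`, `"prs"`; empty for the
#'   overall cell only.
#' @param horizon Horizon in years (default 10).
#' @param min_cases Minimum events by horizon for a cell to be considered
#'   reliable (default 20).
#' @return A tibble of class `cutoff_table`: `prs_stratum`, `age_group`,
#'   `cutoff_ng_ml`, `td_auc`, `n`, `n_cases`, `unreliable`, `source`
#'   (`"derived"`).
#' @examples
#' cfg <- sim_config(n_participants = 4000, seed = 4)
#' sim <- simulate_cohort(cfg, simulate_panel(cfg))
#' stratified_cutoffs(sim$cohort, by = "age")
#' @export
stratified_cutoffs <- function(cohort, by = c("age", "prs"), horizon = 10,
                               min_cases = 20) {
  if (length(by)) by <- match.arg(by, c("age", "prs"), several.ok = TRUE)
  age_vals <- if ("age" %in% by) c("all", age_group_levels()) else "all"
  prs_vals <- if ("prs" %in% by) c("all", "low", "high") else "all"
  if ("prs" %in% by && !"prs_group" %in% names(cohort)) {
    abort("Stratifying by PRS needs a `prs_group` column (see select_prs()).")
  }

  cells <- tidyr::expand_grid(prs_stratum = prs_vals, age_group = age_vals)
  rows <- purrr::pmap(cells, function(prs_stratum, age_group) {
    sub <- cohort
    if (prs_stratum != "all") {
      sub <- filter(sub, .data$prs_group == .env$prs_stratum)
    }
    if (age_group != "all") {
      sub <- filter(sub, as.character(.data$age_group) == .env$age_group)
    }
    base <- tibble(
      prs_stratum = prs_stratum, age_group = age_group,
      cutoff_ng_ml = NA_real_, td_auc = NA_real_,
      n = nrow(sub), n_cases = NA_integer_, unreliable = TRUE
    )
    if (nrow(sub) == 0) return(base)
    td <- tryCatch(
      td_roc(sub, horizon = horizon),
      error = function(e) NULL
    )
    if (is.null(td)) return(base)
    base$cutoff_ng_ml <- td$cutoff
    base$td_auc <- td$td_auc
    base$n_cases <- td$n_cases
    base$unreliable <- td$n_cases < min_cases
    base
  })
  out <- list_rbind(rows) |> mutate(source = "derived")
  class(out) <- c("cutoff_table", class(out))
  out
}

#' Published PLCO-derived PSA cut-off table
#'
#' The fixed PSA cut-off values (ng/mL) reported from the PLCO screening
#' cohort for the 10-year prostate-cancer risk: age-specific cut-offs for
#' the whole cohort (1.41, 1.46, 1.59, 2.12 for ages <60, 60-64, 65-69,
#' >=70), for the low-PRS group (1.42, 1.65, 1.60, 2.24), and for the
#' high-PRS group (1.48, 1.47, 1.89, 2.72), together with the PRS-specific
#' overall cut-offs (1.42 and 1.62) and the reported per-cell tdAUCs.
#' Useful for evaluating the screening strategies without re-deriving
#' cut-offs, and as the `"fixed"` cut-off source of [run_pipeline()].
#'
#' @return A `cutoff_table` tibble with `source = "fixed"`.
#' @examples
#' reference_cutoffs()
#' @export
reference_cutoffs <- function() {
  ages <- age_group_levels()
  out <- bind_rows(
    tibble(
      prs_stratum = "all", age_group = ages,
      cutoff_ng_ml = c(1.41, 1.46, 1.59, 2.12),
      td_auc = c(0.832, 0.808, 0.806, 0.809)
    ),
    tibble(
      prs_stratum = "low", age_group = "all",
      cutoff_ng_ml = 1.42, td_auc = 0.818
    ),
    tibble(
      prs_stratum = "low", age_group = ages,
      cutoff_ng_ml = c(1.42, 1.65, 1.60, 2.24),
      td_auc = c(0.816, 0.796, 0.793, 0.788)
    ),
    tibble(
      prs_stratum = "high", age_group = "all",
      cutoff_ng_ml = 1.62, td_auc = 0.816
    ),
    tibble(
      prs_stratum = "high", age_group = ages,
      cutoff_ng_ml = c(1.48, 1.47, 1.89, 2.72),
      td_auc = c(0.840, 0.809, 0.804, 0.824)
    )
  ) |>
    mutate(
      n = NA_integer_, n_cases = NA_integer_,
      unreliable = FALSE, source = "fixed"
    )
  class(out) <- c("cutoff_table", class(out))
  out
}

#' Bootstrap stability of derived cut-offs
#'
#' Resamples participants with replacement `B` times, re-derives the
#' stratified cut-off table on each resample, and reports the 2.5th and
#' 97.5th percentiles of each cell's cut-off. `B = 2000` mirrors the usual
#' internal-stability analysis; smaller `B` is adequate for smoke tests.
#'
#' @inheritParams stratified_cutoffs
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Optional integer seed for the resampling stream.
#' @return The point-estimate `cutoff_table` with `ci_lo`, `ci_hi` and
#'   `n_boot` (resamples where the cell's cut-off was defined) appended.
#' @export
bootstrap_cutoff_stability <- function(cohort, by = c("age", "prs"),
                                       horizon = 10, min_cases = 20,
                                       B = 2000, seed = NULL) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  point <- stratified_cutoffs(cohort, by = by, horizon = horizon,
                              min_cases = min_cases)
  draws <- purrr::map(seq_len(B), function(b) {
    res <- cohort[sample.int(nrow(cohort), replace = TRUE), , drop = FALSE]
    stratified_cutoffs(res, by = by, horizon = horizon,
                       min_cases = min_cases)$cutoff_ng_ml
  })
  M <- do.call(cbind, draws)
  point$ci_lo <- apply(M, 1, quantile, probs = 0.025, na.rm = TRUE)
  point$ci_hi <- apply(M, 1, quantile, probs = 0.975, na.rm = TRUE)
  point$n_boot <- rowSums(!is.na(M))
  point
}

#' Plot a cut-off table
#'
#' Age-specific PSA cut-offs by PRS stratum.
#'
#' @param cutoffs A `cutoff_table`.
#' @return A ggplot object.
#' @export
plot_cutoffs <- function(cutoffs) {
  df <- cutoffs |>
    filter(.data$age_group != "all", !is.na(.data$cutoff_ng_ml)) |>
    mutate(age_group = factor(.data$age_group, levels = age_group_levels()))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$age_group, y = .data$cutoff_ng_ml,
    colour = .data$prs_stratum, group = .data$prs_stratum
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Age group (years)", y = "PSA cut-off (ng/mL)",
      colour = "PRS stratum"
    )
}
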