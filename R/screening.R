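screening_strategies <- c("traditional", "improved1", "improved2", "improved3")

lookup_cutoff <- function(cutoffs, prs, age) {
  hit <- cutoffs |>
    filter(.data$prs_stratum == prs, .data$age_group == age)
  if (nrow(hit) != 1 || is.na(hit$cutoff_ng_ml)) {
    abort(sprintf("No usable cut-off for cell (%s, %s).", prs, age))
  }
  hit$cutoff_ng_ml
}

cutoff_vector <- function(cutoffs, prs_strata, ages) {
  map2(prs_strata, ages, lookup_cutoff, cutoffs = cutoffs) |> unlist()
}

#' Classify participants under a screening positivity strategy
#'
#' The four positivity rules, all using the strict inequality
#' `PSA > cut-off`:
#'
#' * `traditional` — PSA > 4 ng/mL, one threshold for everyone;
#' * `improved1` — PSA above the age-specific cut-off (stratum `all`);
#' * `improved2` — PSA above the age- and PRS-specific cut-off;
#' * `improved3` — high-PRS participants positive when PSA exceeds the
#'   age-specific high-PRS cut-off; low-PRS participants are always
#'   negative, whatever their PSA.
#'
#' @param cohort Cohort tibble; needs `psa_baseline_ng_ml` and `age_group`,
#'   plus `prs_group` for the PRS-aware strategies.
#' @param strategy One of `"traditional"`, `"improved1"`, `"improved2"`,
#'   `"improved3"`.
#' @param cutoffs A `cutoff_table` (from [stratified_cutoffs()] or
#'   [reference_cutoffs()]); unused by `traditional`. A missing cell raises
#'   an error naming the cell.
#' @return The cohort with a logical `screen_positive` column appended.
#' @examples
#' cohort <- tibble::tibble(
#'   psa_baseline_ng_ml = c(2.8, 50), age_group = c(">=70", "<60"),
#'   prs_group = c("high", "low")
#' )
#' classify_screening(cohort, "improved3", reference_cutoffs())$screen_positive
#' @export
classify_screening <- function(cohort, strategy = screening_strategies,
                               cutoffs = NULL) {
  strategy <- match.arg(strategy, screening_strategies)
  psa <- cohort$psa_baseline_ng_ml
  if (is.null(psa) || anyNA(psa)) abort("`psa_baseline_ng_ml` must be present, non-missing.")
  if (strategy != "traditional") {
    if (is.null(cutoffs)) abort("This strategy needs a cut-off table.")
    age <- as.character(cohort$age_group)
    if (anyNA(age)) abort("`age_group` must be present, non-missing.")
  }
  if (strategy %in% c("improved2", "improved3")) {
    prs <- as.character(cohort$prs_group)
    if (is.null(cohort$prs_group) || anyNA(prs)) {
      abort("`prs_group` must be present, non-missing.")
    }
  }

  positive <- switch(strategy,
    traditional = psa > 4,
    improved1 = psa > cutoff_vector(cutoffs, rep("all", nrow(cohort)), age),
    improved2 = psa > cutoff_vector(cutoffs, prs, age),
    improved3 = {
      out <- rep(FALSE, nrow(cohort))
      hi <- prs == "high"
      if (any(hi)) {
        out[hi] <- psa[hi] > cutoff_vector(cutoffs, prs[hi], age[hi])
      }
      out
    }
  )
  cohort |> mutate(screen_positive = positive)
}

clopper_pearson <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  100 * as.numeric(binom.test(x, n)$conf.int)
}

#' Evaluate a screening classification against observed cancer status
#'
#' Cross-tabulates screen positivity against case status and derives the
#' full metric panel: sensitivity, specificity, PPV and NPV (percent, with
#' exact Clopper-Pearson 95% CIs), the proportion of high-grade disease
#' (Gleason >= 7) among true positives, and the false-positive proportion
#' on both reported denominators — among screen positives (`1 - PPV`) and
#' among all participants. Zero-denominator metrics are returned as `NA`.
#'
#' @param data Data frame with one row per participant.
#' @param positive,case Bare column names of screen positivity (logical)
#'   and observed case status (0/1).
#' @param gleason Bare column name of the Gleason >= 7 flag among cases
#'   (`NA` for non-cases), or `NULL` to skip the high-grade proportion.
#' @return A list of class `screen_eval`: `confusion` (tp/fp/fn/tn tibble)
#'   and `metrics` (tibble of metric, percent, CI bounds, numerator,
#'   denominator).
#' @examples
#' df <- tibble::tibble(pos = c(TRUE, TRUE, FALSE), case = c(1, 0, 1))
#' evaluate_screening(df, pos, case)
#' @export
evaluate_screening <- function(data, positive = screen_positive,
                               case = dx_event, gleason = gleason_ge7) {
  pos <- as.logical(dplyr::pull(data, {{ positive }}))
  y <- check_binary(dplyr::pull(data, {{ case }}), "case")
  stopifnot(length(pos) == length(y), !anyNA(pos))
  gl <- tryCatch(dplyr::pull(data, {{ gleason }}), error = function(e) NULL)

  tp <- sum(pos & y == 1L)
  fp <- sum(pos & y == 0L)
  fn <- sum(!pos & y == 1L)
  tn <- sum(!pos & y == 0L)
  n <- length(y)

  hg <- if (!is.null(gl)) sum(gl[pos & y == 1L] == 1L, na.rm = TRUE) else NA_integer_

  row <- function(metric, x, d) {
    ci <- clopper_pearson(x, d)
    tibble(
      metric = metric,
      pct = if (d > 0) 100 * x / d else NA_real_,
      conf_low = ci[1], conf_high = ci[2],
      numerator = x, denominator = d
    )
  }
  metrics <- bind_rows(
    row("sensitivity", tp, tp + fn),
    row("specificity", tn, tn + fp),
    row("ppv", tp, tp + fp),
    row("npv", tn, tn + fn),
    if (!is.null(gl)) row("high_grade_among_tp", hg, tp),
    row("fp_among_positives", fp, tp + fp),
    row("fp_among_all", fp, n)
  )

  structure(
    list(
      confusion = tibble(tp = tp, fp = fp, fn = fn, tn = tn, n_total = n),
      metrics = metrics
    ),
    class = "screen_eval"
  )
}

#' Build a screening evaluation directly from confusion counts
#'
#' Convenience constructor for evaluating printed or external 2x2 tables
#' with the same metric panel as [evaluate_screening()].
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @param hg_tp Optional count of high-grade (Gleason >= 7) cancers among
#'   the true positives.
#' @return A `screen_eval` object.
#' @examples
#' screen_eval_from_counts(tp = 1040, fp = 1139, fn = 2536, tn = 24530)
#' @export
screen_eval_from_counts <- function(tp, fp, fn, tn, hg_tp = NULL) {
  df <- tibble(
    pos = rep(c(TRUE, TRUE, FALSE, FALSE), times = c(tp, fp, fn, tn)),
    case = rep(c(1L, 0L, 1L, 0L), times = c(tp, fp, fn, tn))
  )
  if (!is.null(hg_tp)) {
    stopifnot(hg_tp <= tp)
    df$gl <- NA_integer_
    idx <- which(df$pos & df$case == 1L)
    df$gl[idx] <- rep(c(1L, 0L), times = c(hg_tp, tp - hg_tp))
    evaluate_screening(df, pos, case, gl)
  } else {
    evaluate_screening(df, pos, case, gleason = NULL)
  }
}

#' @export
print.screen_eval <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf(
    "<screen_eval> tp %d / fp %d / fn %d / tn %d (n %d)\n",
    cm$tp, cm$fp, cm$fn, cm$tn, cm$n_total
  ))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.screen_eval <- function(x, ...) x$metrics

#' @export
glance.screen_eval <- function(x, ...) {
  wide <- setNames(x$metrics$pct, x$metrics$metric)
  bind_cols(x$confusion, as_tibble(as.list(wide)))
}

#' Reduction in missed cancers relative to a reference strategy
#'
#' The percentage-point share of all cases that a new strategy detects but
#' the reference misses: `(fn_ref - fn_new) / total cases * 100`. Both
#' evaluations must come from the same cohort (equal case totals).
#'
#' @param eval_ref,eval_new `screen_eval` objects (reference and new).
#' @return Percent of all cases, a single number.
#' @examples
#' ref <- screen_eval_from_counts(1040, 1139, 2536, 24530)
#' new <- screen_eval_from_counts(1498, 2484, 2078, 23185)
#' missed_reduction(ref, new)
#' @export
missed_reduction <- function(eval_ref, eval_new) {
  cm_r <- eval_ref$confusion
  cm_n <- eval_new$confusion
  cases_r <- cm_r$tp + cm_r$fn
  cases_n <- cm_n$tp + cm_n$fn
  if (cases_r != cases_n) {
    abort("Case totals differ; both evaluations must use the same cohort.")
  }
  100 * (cm_r$fn - cm_n$fn) / cases_r
}

#' McNemar comparison of two screening strategies
#'
#' Paired comparison of sensitivity (restricted to cases) or specificity
#' (restricted to non-cases) between two classifications of the same
#' participants. The chi-square statistic is the uncorrected
#' `(b - c)^2 / (b + c)` on the discordant counts; with `exact = TRUE` an
#' exact binomial test on the discordant pairs is used instead. With no
#' discordant pairs the p-value is 1.
#'
#' @param data Data frame with one row per participant.
#' @param positive_a,positive_b Bare column names of the two logical
#'   classifications.
#' @param case Bare column name of case status (0/1).
#' @param metric `"sensitivity"` or `"specificity"`.
#' @param exact Use the exact binomial form (default `FALSE`).
#' @return One-row tibble: `metric`, `b`, `c`, `statistic`, `p`.
#' @export
compare_strategies <- function(data, positive_a, positive_b, case = dx_event,
                               metric = c("sensitivity", "specificity"),
                               exact = FALSE) {
  metric <- match.arg(metric)
  pa <- as.logical(dplyr::pull(data, {{ positive_a }}))
  pb <- as.logical(dplyr::pull(data, {{ positive_b }}))
  y <- check_binary(dplyr::pull(data, {{ case }}), "case")
  keep <- if (metric == "sensitivity") y == 1L else y == 0L

  pa <- pa[keep]
  pb <- pb[keep]
  b <- sum(pa & !pb)
  cc <- sum(!pa & pb)
  if (b + cc == 0) {
    return(tibble(metric = metric, b = b, c = cc, statistic = 0, p = 1))
  }
  if (exact) {
    p <- binom.test(b, b + cc)$p.value
    stat <- NA_real_
  } else {
    stat <- (b - cc)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  tibble(metric = metric, b = b, c = cc, statistic = stat, p = p)
}

#' Full multi-strategy screening report
#'
#' Classifies the cohort under each requested strategy, evaluates every
#' classification, and assembles one row per strategy with the confusion
#' counts, the metric panel, the high-grade and false-positive proportions
#' and the McNemar comparisons of sensitivity and specificity against the
#' traditional strategy (which is always evaluated as the reference).
#'
#' @param cohort Cohort tibble (see [classify_screening()] for required
#'   columns).
#' @param cutoffs A `cutoff_table`.
#' @param strategies Strategies to report (default all four).
#' @return A tibble of class `strategy_report` with columns `strategy`,
#'   `tp`, `fp`, `fn`, `tn`, `sens`, `spec`, `ppv`, `npv`, `hg_prop`,
#'   `fp_among_pos`, `fp_among_all`, `p_vs_traditional_sens`,
#'   `p_vs_traditional_spec`, `missed_reduction_pct`.
#' @export
strategy_report <- function(cohort, cutoffs, strategies = screening_strategies) {
  strategies <- match.arg(strategies, screening_strategies, several.ok = TRUE)
  have_gleason <- "gleason_ge7" %in% names(cohort)

  classifications <- purrr::map(
    union("traditional", strategies),
    function(s) classify_screening(cohort, s, cutoffs)$screen_positive
  )
  names(classifications) <- union("traditional", strategies)
  ref <- classifications[["traditional"]]

  eval_one <- function(s) {
    df <- cohort |> mutate(.pos = classifications[[s]], .ref = ref)
    ev <- if (have_gleason) {
      evaluate_screening(df, .data$.pos, .data$dx_event, .data$gleason_ge7)
    } else {
      evaluate_screening(df, .data$.pos, .data$dx_event, gleason = NULL)
    }
    g <- glance(ev)
    cmp_sens <- compare_strategies(df, .data$.pos, .data$.ref, .data$dx_event, "sensitivity")
    cmp_spec <- compare_strategies(df, .data$.pos, .data$.ref, .data$dx_event, "specificity")
    ref_ev <- evaluate_screening(df, .data$.ref, .data$dx_event, gleason = NULL)
    tibble(
      strategy = s,
      tp = g$tp, fp = g$fp, fn = g$fn, tn = g$tn,
      sens = g$sensitivity, spec = g$specificity, ppv = g$ppv, npv = g$npv,
      hg_prop = if (have_gleason) g$high_grade_among_tp else NA_real_,
      fp_among_pos = g$fp_among_positives, fp_among_all = g$fp_among_all,
      p_vs_traditional_sens = if (s == "traditional") NA_real_ else cmp_sens$p,
      p_vs_traditional_spec = if (s == "traditional") NA_real_ else cmp_spec$p,
      missed_reduction_pct = if (s == "traditional") NA_real_ else {
        missed_reduction(ref_ev, ev)
      }
    )
  }

  out <- purrr::map(strategies, eval_one) |> list_rbind()
  class(out) <- c("strategy_report", class(out))
  out
}

#' Plot a strategy report
#'
#' Bar panel of sensitivity, specificity, PPV and NPV by strategy.
#'
#' @param object A `strategy_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.strategy_report <- function(object, ...) {
  df <- object |>
    select("strategy", "sens", "spec", "ppv", "npv") |>
    tidyr::pivot_longer(-"strategy", names_to = "metric", values_to = "pct")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$strategy, y = .data$pct, fill = .data$strategy
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "Percent") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
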