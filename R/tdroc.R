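#' Kaplan-Meier inverse-probability-of-censoring weights at a horizon
#'
#' Estimates the censoring survival function G(t) by Kaplan-Meier (treating
#' censorings as the events) and assigns each subject the weight used by
#' the cumulative/dynamic time-dependent ROC estimator at `horizon`:
#'
#' * event by the horizon (cases; events at exactly the horizon count):
#'   weight `1 / G(T-)`, the left limit at the event time;
#' * still under observation at the horizon (controls): weight
#'   `1 / G(horizon-)` (the left limit, so censorings at exactly the
#'   horizon do not deflate their own weight);
#' * censored before the horizon: weight 0 (such subjects carry no
#'   information about status at the horizon).
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param horizon Evaluation horizon in the time unit of `time`.
#' @return A tibble with one row per subject: `time`, `event`, `class`
#'   (`"case"`, `"control"`, `"censored"`) and `weight`.
#' @examples
#' censoring_km_weights(c(2, 5, 12, 12), c(1, 0, 0, 0), horizon = 10)
#' @export
censoring_km_weights <- function(time, event, horizon) {
  event <- check_binary(event, "event")
  stopifnot(length(time) == length(event), horizon > 0)
  if (any(time <= 0) || anyNA(time)) abort("`time` must be positive, non-missing.")

  km <- survfit(Surv(time, 1 - event) ~ 1)
  # right-continuous G and its left limit, as step functions of time
  steps <- c(1, km$surv)
  g_at <- function(t) steps[findInterval(t, km$time) + 1L]
  g_left <- function(t) {
    steps[findInterval(t, km$time, left.open = TRUE) + 1L]
  }

  cls <- dplyr::case_when(
    event == 1L & time <= horizon ~ "case",
    time >= horizon ~ "control",
    .default = "censored"
  )
  w <- numeric(length(time))
  w[cls == "case"] <- 1 / g_left(time[cls == "case"])
  w[cls == "control"] <- 1 / g_left(horizon)
  if (any(!is.finite(w))) {
    abort(paste(
      "Censoring survival reaches 0 before a needed time;",
      "consider a shorter horizon."
    ))
  }
  tibble(time = time, event = event, class = cls, weight = w)
}

#' Time-dependent ROC at a fixed horizon with IPCW
#'
#' Cumulative/dynamic time-dependent ROC of a baseline marker for event
#' status by `horizon`: cases are subjects with an event by the horizon,
#' dynamic controls are subjects event-free and still under observation at
#' the horizon, and subjects censored earlier are removed via
#' inverse-probability-of-censoring weights ([censoring_km_weights()]).
#' For each threshold c on the grid of sorted unique marker values,
#' `sensitivity(c)` is the weighted fraction of cases with marker > c and
#' `specificity(c)` the weighted fraction of controls with marker <= c.
#' The tdAUC is the trapezoidal area under the resulting curve and the
#' optimal cut-off maximises the Youden index, ties broken toward the
#' smaller threshold.
#'
#' @param data Data frame with one row per subject.
#' @param marker,time,event Bare column names of the baseline marker, the
#'   follow-up time and the event indicator.
#' @param horizon Horizon in years (default 10).
#' @return A list of class `td_roc`: `horizon`, `td_auc`, `cutoff`, `curve`
#'   (tibble of `threshold`, `sensitivity`, `specificity`, `youden`),
#'   `n_cases`, `n_controls`, `n_censored`, `sum_case_weight`,
#'   `sum_control_weight`.
#' @examples
#' cfg <- sim_config(n_participants = 2000, seed = 3)
#' sim <- simulate_cohort(cfg, simulate_panel(cfg))
#' td <- td_roc(sim$cohort, psa_baseline_ng_ml, t_dx_years, dx_event)
#' glance(td)
#' @export
td_roc <- function(data, marker = psa_baseline_ng_ml, time = t_dx_years,
                   event = dx_event, horizon = 10) {
  m <- dplyr::pull(data, {{ marker }})
  tt <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  if (anyNA(m)) abort("Marker values must be non-missing.")

  wt <- censoring_km_weights(tt, ev, horizon)
  is_case <- wt$class == "case"
  is_ctrl <- wt$class == "control"
  if (!any(is_case)) abort("No events by the horizon.")
  if (!any(is_ctrl)) abort("No controls under observation at the horizon.")

  thr <- sort(unique(m))
  wc <- wt$weight[is_case]
  sum_wc <- sum(wc)
  # weighted counts of cases, and counts of controls, per threshold bin
  case_bin <- numeric(length(thr))
  agg <- rowsum(wc, match(m[is_case], thr))
  case_bin[as.integer(rownames(agg))] <- agg
  ctrl_bin <- tabulate(match(m[is_ctrl], thr), nbins = length(thr))
  n_ctrl <- sum(is_ctrl)

  sens <- (sum_wc - cumsum(case_bin)) / sum_wc
  spec <- cumsum(ctrl_bin) / n_ctrl

  curve <- tibble(
    threshold = thr,
    sensitivity = sens,
    specificity = spec,
    youden = sens + spec - 1
  )

  # trapezoid over the full curve, anchored at (FPR, TPR) = (1, 1) and (0, 0)
  fpr <- c(1, 1 - curve$specificity)
  tpr <- c(1, curve$sensitivity)
  o <- order(fpr, tpr)
  fpr <- c(0, fpr[o])
  tpr <- c(0, tpr[o])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)

  best <- which(curve$youden == max(curve$youden))[1L]

  structure(
    list(
      horizon = horizon,
      td_auc = auc,
      cutoff = curve$threshold[best],
      curve = curve,
      n_cases = sum(is_case),
      n_controls = n_ctrl,
      n_censored = sum(wt$class == "censored"),
      sum_case_weight = sum_wc,
      sum_control_weight = sum(wt$weight[is_ctrl])
    ),
    class = "td_roc"
  )
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf(
    "<td_roc> horizon %g y: tdAUC %.4f, Youden cut-off %.4g (%d cases, %d controls, %d censored)\n",
    x$horizon, x$td_auc, x$cutoff, x$n_cases, x$n_controls, x$n_censored
  ))
  invisible(x)
}

#' @export
tidy.td_roc <- function(x, ...) x$curve

#' @export
glance.td_roc <- function(x, ...) {
  tibble(
    horizon = x$horizon, td_auc = x$td_auc, cutoff = x$cutoff,
    n_cases = x$n_cases, n_controls = x$n_controls, n_censored = x$n_censored
  )
}

#' @rdname td_roc
#' @param object A `td_roc` object.
#' @param ... Ignored.
#' @export
autoplot.td_roc <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(
    x = 1 - .data$specificity, y = .data$sensitivity
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf(
        "Time-dependent ROC at %g years (tdAUC %.3f)",
        object$horizon, object$td_auc
      )
    )
}
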