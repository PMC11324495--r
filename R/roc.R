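#' Empirical ROC curve, AUC and Youden-optimal cut-off
#'
#' Computes the empirical ROC of a score against a binary outcome with the
#' positivity rule `score > threshold` evaluated over the sorted unique
#' score values. The AUC is the Mann-Whitney statistic (ties counted 1/2),
#' which equals the trapezoidal area under this curve. The optimal cut-off
#' maximises the Youden index (sensitivity + specificity - 1); ties are
#' broken toward the smaller threshold, favouring sensitivity.
#'
#' @param score Numeric marker values.
#' @param y Binary outcome (1 = case).
#' @return A list of class `roc_result`: `auc`, `cutoff`, `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `youden`), `n_cases`,
#'   `n_controls`.
#' @examples
#' r <- roc_auc(c(1, 2, 3, 4, 5, 5), c(0, 0, 1, 0, 1, 1))
#' r$auc
#' r$cutoff
#' @export
roc_auc <- function(score, y) {
  y <- check_binary(y, "y")
  stopifnot(length(score) == length(y), !anyNA(score))
  check_both_classes(y)

  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  r <- rank(score, ties.method = "average")
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(score))
  n1_le <- cumsum(tabulate(
    match(score[y == 1L], thr),
    nbins = length(thr)
  ))
  n0_le <- cumsum(tabulate(
    match(score[y == 0L], thr),
    nbins = length(thr)
  ))
  curve <- tibble(
    threshold = thr,
    sensitivity = (n1 - n1_le) / n1,
    specificity = n0_le / n0
  )
  curve$youden <- curve$sensitivity + curve$specificity - 1
  best <- which(curve$youden == max(curve$youden))[1L]

  structure(
    list(
      auc = auc,
      cutoff = curve$threshold[best],
      curve = curve,
      n_cases = n1,
      n_controls = n0
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.4f, Youden cut-off %.4g (%d cases / %d controls)\n",
    x$auc, x$cutoff, x$n_cases, x$n_controls
  ))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble(
    auc = x$auc, cutoff = x$cutoff,
    n_cases = x$n_cases, n_controls = x$n_controls
  )
}

# structural components of the Mann-Whitney AUC (midrank form)
delong_components <- function(score, y) {
  case <- score[y == 1L]
  ctrl <- score[y == 0L]
  m <- length(case)
  n <- length(ctrl)
  all_r <- rank(c(case, ctrl), ties.method = "average")
  case_r <- rank(case, ties.method = "average")
  ctrl_r <- rank(ctrl, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - case_r) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - ctrl_r) / m
  list(auc = sum(all_r[seq_len(m)] - case_r) / (m * n), v10 = v10, v01 = v01)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same participants using
#' the structural-components estimator of the covariance of correlated
#' Mann-Whitney AUCs; the p-value uses a normal reference. Identical scores
#' return a difference of 0 with p exactly 1.
#'
#' @param score_a,score_b Paired numeric scores.
#' @param y Binary outcome (1 = case).
#' @return One-row tibble: `auc_a`, `auc_b`, `diff`, `se`, `z`, `p`.
#' @examples
#' set.seed(1)
#' y <- rbinom(100, 1, 0.4)
#' delong_compare(rnorm(100) + y, rnorm(100), y)
#' @export
delong_compare <- function(score_a, score_b, y) {
  if (length(score_a) != length(score_b)) {
    abort("`score_a` and `score_b` must have the same length.")
  }
  y <- check_binary(y, "y")
  stopifnot(length(score_a) == length(y))
  check_both_classes(y)

  a <- delong_components(score_a, y)
  b <- delong_components(score_b, y)
  m <- length(a$v10)
  n <- length(a$v01)

  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n

  d <- a$auc - b$auc
  se <- sqrt(max(var_diff, 0))
  if (d == 0) {
    z <- 0
    p <- 1
  } else if (se == 0) {
    z <- sign(d) * Inf
    p <- 0
  } else {
    z <- d / se
    p <- 2 * pnorm(-abs(z))
  }
  tibble(auc_a = a$auc, auc_b = b$auc, diff = d, se = se, z = z, p = p)
}

#' Variance of a single AUC by DeLong structural components
#'
#' @param score Numeric marker values.
#' @param y Binary outcome (1 = case).
#' @return The estimated variance of the Mann-Whitney AUC.
#' @export
delong_auc_variance <- function(score, y) {
  y <- check_binary(y, "y")
  check_both_classes(y)
  cmp <- delong_components(score, y)
  stats::var(cmp$v10) / length(cmp$v10) + stats::var(cmp$v01) / length(cmp$v01)
}
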