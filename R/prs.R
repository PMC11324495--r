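#' Per-SNP univariate logistic association
#'
#' Fits, for each SNP, the univariate logistic regression of case status on
#' the risk-allele dosage (additive 0/1/2 coding) and reports the per-allele
#' log odds ratio with its Wald test. SNPs with constant dosage, or whose
#' fit fails to converge or shows separation (|beta| > 10), are flagged and
#' their estimates set to `NA`.
#'
#' @param G Fully observed dosage matrix (participants x SNPs).
#' @param y Binary case indicator, one per participant.
#' @return A tibble with one row per SNP: `rsid`, `beta`, `se`, `or`, `p`,
#'   `flag` (`"ok"`, `"constant"`, or `"unstable"`).
#' @examples
#' cfg <- sim_config(n_participants = 500, n_snps = 4, missing_rate = 0, seed = 2)
#' sim <- simulate_cohort(cfg, simulate_panel(cfg))
#' per_snp_association(sim$genotypes, sim$cohort$dx_event)
#' @export
per_snp_association <- function(G, y) {
  y <- check_binary(y, "y")
  stopifnot(nrow(G) == length(y))
  check_both_classes(y)
  if (anyNA(G)) abort("`G` must be fully imputed (no missing dosages).")

  fit_one <- function(dose) {
    if (length(unique(dose)) < 2L) {
      return(c(NA_real_, NA_real_, NA_real_, 1))
    }
    fit <- suppressWarnings(glm(y ~ dose, family = binomial()))
    b <- coef(fit)[["dose"]]
    se <- sqrt(vcov(fit)["dose", "dose"])
    p <- 2 * pnorm(-abs(b / se))
    unstable <- !fit$converged || abs(b) > 10
    c(b, se, p, if (unstable) 2 else 0)
  }

  res <- unname(t(apply(G, 2, fit_one)))
  tibble(
    rsid = colnames(G) %||% sprintf("snp%d", seq_len(ncol(G))),
    beta = res[, 1],
    se = res[, 2],
    or = exp(res[, 1]),
    p = res[, 3],
    flag = c("ok", "constant", "unstable")[res[, 4] + 1]
  )
}

#' Flag panel SNPs validated in-cohort
#'
#' A SNP is validated when its in-cohort univariate association is
#' significant at `alpha` (two-sided Wald) *and* direction-consistent with
#' the published risk allele, i.e. the fitted per-risk-allele log odds ratio
#' is positive. Validation drives which SNPs enter the restricted score
#' variants (PRS2/PRS4). No multiplicity correction is applied; `alpha` is
#' exposed so stricter policies can be configured.
#'
#' @param panel SNP panel tibble (`rsid`, ...).
#' @param assoc Result of [per_snp_association()].
#' @param alpha Two-sided significance level (default 0.05).
#' @return The panel with `fitted_beta`, `fitted_p` and logical `validated`
#'   columns appended.
#' @export
validate_snps <- function(panel, assoc, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  missing_assoc <- setdiff(panel$rsid, assoc$rsid)
  if (length(missing_assoc)) {
    abort(sprintf(
      "No association results for panel SNP(s): %s",
      paste(head(missing_assoc, 5), collapse = ", ")
    ))
  }
  panel |>
    select(-any_of(c("fitted_beta", "fitted_p", "validated"))) |>
    left_join(
      assoc |> select("rsid", fitted_beta = "beta", fitted_p = "p"),
      by = "rsid"
    ) |>
    mutate(
      validated = !is.na(.data$fitted_beta) &
        .data$fitted_p < alpha & .data$fitted_beta > 0
    )
}

prs_variants <- c("PRS1", "PRS2", "PRS3", "PRS4")

#' Compute polygenic risk scores
#'
#' Four score variants over the risk-allele dosage matrix:
#'
#' * `PRS1` — unweighted count of risk alleles over all panel SNPs;
#' * `PRS2` — unweighted count over the validated SNPs only;
#' * `PRS3` — dosages weighted by the in-cohort univariate log odds ratios
#'   (`fitted_beta`), all SNPs;
#' * `PRS4` — weighted as PRS3, validated SNPs only.
#'
#' @param G Fully imputed dosage matrix (participants x SNPs).
#' @param panel Panel tibble; must carry `validated` for PRS2/PRS4 and
#'   `fitted_beta` for PRS3/PRS4 (see [validate_snps()]).
#' @param variants Which variants to compute (default all four).
#' @return A tibble with `id` plus one column per requested variant, and an
#'   `n_snps` attribute giving the number of SNPs behind each variant.
#' @export
compute_prs <- function(G, panel, variants = prs_variants) {
  variants <- match.arg(variants, prs_variants, several.ok = TRUE)
  if (anyNA(G)) abort("`G` must be fully imputed (no missing dosages).")
  idx <- match(panel$rsid, colnames(G))
  if (anyNA(idx)) abort("Every panel SNP must be a column of `G`.")
  G <- G[, idx, drop = FALSE]

  needs_valid <- any(variants %in% c("PRS2", "PRS4"))
  needs_beta <- any(variants %in% c("PRS3", "PRS4"))
  if (needs_valid && !"validated" %in% names(panel)) {
    abort("PRS2/PRS4 need a `validated` flag; run validate_snps() first.")
  }
  if (needs_beta && !"fitted_beta" %in% names(panel)) {
    abort("PRS3/PRS4 need `fitted_beta`; run validate_snps() first.")
  }
  if (needs_beta && anyNA(panel$fitted_beta)) {
    abort("`fitted_beta` contains NA; weighted variants are undefined.")
  }

  v <- if (needs_valid) panel$validated else NULL
  b <- if (needs_beta) panel$fitted_beta else NULL
  score <- function(variant) {
    switch(variant,
      PRS1 = rowSums(G),
      PRS2 = rowSums(G[, v, drop = FALSE]),
      PRS3 = drop(G %*% b),
      PRS4 = drop(G[, v, drop = FALSE] %*% b[v])
    )
  }
  out <- tibble(id = rownames(G) %||% as.character(seq_len(nrow(G))))
  for (variant in variants) out[[variant]] <- unname(score(variant))

  n_snps <- vapply(variants, function(x) {
    if (x %in% c("PRS2", "PRS4")) sum(v) else nrow(panel)
  }, integer(1))
  attr(out, "n_snps") <- n_snps
  out
}

#' Select the optimal PRS variant and dichotomise the cohort
#'
#' Computes the case/control ROC of every supplied score variant, selects
#' the variant with the largest AUC (ties broken toward the variant built
#' from fewest SNPs, then toward the unweighted variant), and splits
#' participants at the selected variant's Youden-optimal cut-off:
#' `high` if score > cut-off, else `low`.
#'
#' @param scores Tibble from [compute_prs()] (`id` + variant columns).
#' @param y Binary case indicator aligned with `scores` rows.
#' @return A list of class `prs_selection`: `variant`, `cutoff`, `auc`
#'   (tibble of per-variant AUC and DeLong comparisons against the chosen
#'   variant), `roc` (the chosen variant's [roc_auc()] result) and
#'   `assignments` (tibble `id`, `score`, `prs_group`).
#' @export
select_prs <- function(scores, y) {
  y <- check_binary(y, "y")
  variants <- intersect(prs_variants, names(scores))
  if (!length(variants)) abort("`scores` carries no PRS variant columns.")
  stopifnot(nrow(scores) == length(y))

  n_snps <- attr(scores, "n_snps")
  if (is.null(n_snps)) {
    n_snps <- setNames(rep(NA_integer_, length(variants)), variants)
  }
  weighted <- variants %in% c("PRS3", "PRS4")
  auc <- vapply(variants, function(v) roc_auc(scores[[v]], y)$auc, numeric(1))

  ord <- order(-auc, n_snps[variants], weighted)
  chosen <- variants[ord[1L]]
  roc <- roc_auc(scores[[chosen]], y)

  cmp <- purrr::map(variants, function(v) {
    if (v == chosen) {
      tibble(delong_p = NA_real_)
    } else {
      tibble(delong_p = delong_compare(
        scores[[chosen]], scores[[v]], y
      )$p)
    }
  }) |> list_rbind()
  auc_tbl <- tibble(
    variant = variants,
    n_snps = unname(n_snps[variants]),
    weighted = weighted,
    auc = unname(auc),
    selected = variants == chosen
  ) |> bind_cols(cmp)

  assignments <- tibble(
    id = scores$id,
    score = scores[[chosen]],
    prs_group = factor(
      ifelse(scores[[chosen]] > roc$cutoff, "high", "low"),
      levels = c("low", "high")
    )
  )

  structure(
    list(
      variant = chosen, cutoff = roc$cutoff,
      auc = auc_tbl, roc = roc, assignments = assignments
    ),
    class = "prs_selection"
  )
}

#' @export
print.prs_selection <- function(x, ...) {
  split <- mean(x$assignments$prs_group == "low")
  cat(sprintf(
    "<prs_selection> %s (AUC %.3f), cut-off %.4g; %.1f%% low / %.1f%% high\n",
    x$variant, x$auc$auc[x$auc$selected], x$cutoff,
    100 * split, 100 * (1 - split)
  ))
  invisible(x)
}

#' @export
tidy.prs_selection <- function(x, ...) x$auc

#' @export
glance.prs_selection <- function(x, ...) {
  tibble(
    variant = x$variant,
    auc = x$auc$auc[x$auc$selected],
    cutoff = x$cutoff,
    pct_low = 100 * mean(x$assignments$prs_group == "low"),
    pct_high = 100 * mean(x$assignments$prs_group == "high")
  )
}
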