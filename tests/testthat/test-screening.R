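test_that("positivity rules follow their definitions at the boundaries", {
  cuts <- reference_cutoffs()

  # strict inequality: PSA exactly 4 is negative under traditional screening
  ch <- toy_screen_cohort(4.0, factor("<60", age_group_levels()), "low")
  expect_false(classify_screening(ch, "traditional")$screen_positive)

  # a low-PRS participant is never positive under improved3, whatever the PSA
  ch2 <- toy_screen_cohort(50, factor("<60", age_group_levels()), "low")
  expect_false(classify_screening(ch2, "improved3", cuts)$screen_positive)

  # high-PRS, age >= 70: 2.80 exceeds the published 2.72 ng/mL cut-off
  ch3 <- toy_screen_cohort(2.80, factor(">=70", age_group_levels()), "high")
  expect_true(classify_screening(ch3, "improved3", cuts)$screen_positive)
  expect_true(classify_screening(ch3, "improved2", cuts)$screen_positive)

  # improved1 uses the all-participants age cut-off (2.12 at >= 70)
  expect_true(classify_screening(ch3, "improved1", cuts)$screen_positive)
  ch4 <- toy_screen_cohort(2.10, factor(">=70", age_group_levels()), "high")
  expect_false(classify_screening(ch4, "improved1", cuts)$screen_positive)

  # a missing cut-off cell is an error naming the cell
  cuts_missing <- dplyr::filter(cuts, !(.data$prs_stratum == "high" &
    .data$age_group == ">=70"))
  expect_error(
    classify_screening(ch3, "improved2", cuts_missing),
    "high, >=70"
  )
})

test_that("classification is deterministic and order-independent", {
  set.seed(163)
  n <- 500
  ch <- toy_screen_cohort(
    exp(rnorm(n)),
    factor(sample(age_group_levels(), n, TRUE), age_group_levels()),
    sample(c("low", "high"), n, TRUE)
  )
  cuts <- reference_cutoffs()
  pos <- classify_screening(ch, "improved2", cuts)$screen_positive
  perm <- sample.int(n)
  pos_perm <- classify_screening(ch[perm, ], "improved2", cuts)$screen_positive
  expect_identical(pos_perm, pos[perm])
  expect_identical(pos, classify_screening(ch, "improved2", cuts)$screen_positive)
})

test_that("strategy implication properties hold", {
  set.seed(167)
  n <- 2000
  ch <- toy_screen_cohort(
    exp(rnorm(n, 0.3, 0.9)),
    factor(sample(age_group_levels(), n, TRUE), age_group_levels()),
    sample(c("low", "high"), n, TRUE)
  )
  cuts <- reference_cutoffs()
  trad <- classify_screening(ch, "traditional", cuts)$screen_positive
  imp1 <- classify_screening(ch, "improved1", cuts)$screen_positive
  imp2 <- classify_screening(ch, "improved2", cuts)$screen_positive
  imp3 <- classify_screening(ch, "improved3", cuts)$screen_positive

  # all published age cut-offs are below 4 ng/mL, so traditional positives
  # are a subset of improved1 positives
  expect_true(all(imp1[trad]))
  # improved3 positives are a subset of improved2 positives (same high cells)
  expect_true(all(imp2[imp3]))

  # lowering a cut-off cell can only add positives in that stratum
  lower <- cuts
  i <- which(lower$prs_stratum == "high" & lower$age_group == ">=70")
  lower$cutoff_ng_ml[i] <- lower$cutoff_ng_ml[i] - 1
  imp2_low <- classify_screening(ch, "improved2", lower)$screen_positive
  expect_true(all(imp2_low[imp2]))
})

test_that("metric identities hold to machine precision on random confusions", {
  set.seed(173)
  for (rep in 1:10) {
    cm <- as.list(rpois(4, c(50, 80, 120, 400)) + 1)
    names(cm) <- c("tp", "fp", "fn", "tn")
    ev <- screen_eval_from_counts(cm$tp, cm$fp, cm$fn, cm$tn)
    g <- glance(ev)
    expect_equal(g$ppv, 100 * cm$tp / (cm$tp + cm$fp))
    expect_equal(g$fp_among_positives, 100 - g$ppv, tolerance = 1e-12)
    expect_equal(g$sensitivity + 100 * cm$fn / (cm$tp + cm$fn), 100,
      tolerance = 1e-12
    )
    expect_equal(g$specificity + 100 * cm$fp / (cm$fp + cm$tn), 100,
      tolerance = 1e-12
    )
    expect_equal(g$fp_among_all, 100 * cm$fp / sum(unlist(cm)))
    ci <- ev$metrics[ev$metrics$metric == "sensitivity", ]
    expect_true(ci$conf_low <= ci$pct && ci$pct <= ci$conf_high)
  }
  # degenerate: no errors at all
  perf <- glance(screen_eval_from_counts(10, 0, 0, 20))
  expect_equal(perf$sensitivity, 100)
  expect_equal(perf$specificity, 100)
})

test_that("missed-cancer reduction follows its definition", {
  ref <- screen_eval_from_counts(1040, 1139, 2536, 24530)
  new <- screen_eval_from_counts(1498, 2484, 2078, 23185)
  expect_equal(missed_reduction(ref, new), 100 * (2536 - 2078) / 3576)
  expect_equal(missed_reduction(ref, ref), 0)
  all_found <- screen_eval_from_counts(3576, 2484, 0, 23185)
  expect_equal(missed_reduction(ref, all_found), 100 * 2536 / 3576)
  other <- screen_eval_from_counts(10, 5, 5, 100)
  expect_error(missed_reduction(ref, other), "Case totals differ")
})

test_that("McNemar comparisons match the closed form and hold their level", {
  # discordant counts b = 100, c = 10
  df <- tibble::tibble(
    a = rep(c(TRUE, FALSE, TRUE), times = c(100, 10, 50)),
    b = rep(c(FALSE, TRUE, TRUE), times = c(100, 10, 50)),
    case = 1L
  )
  out <- compare_strategies(df, a, b, case, "sensitivity")
  expect_equal(out$statistic, (100 - 10)^2 / (100 + 10))
  expect_equal(out$p, pchisq(out$statistic, 1, lower.tail = FALSE))

  same <- compare_strategies(dplyr::mutate(df, b = a), a, b, case, "sensitivity")
  expect_equal(same$p, 1)

  # null flip noise: nominal 5% level
  set.seed(179)
  rej <- vapply(1:1000, function(i) {
    pa <- rbinom(300, 1, 0.5) == 1
    flip <- runif(300) < 0.1
    pb <- xor(pa, flip) # discordance symmetric in both directions
    d <- tibble::tibble(a = pa, b = pb, case = 1L)
    compare_strategies(d, a, b, case, "sensitivity")$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.08)
})

test_that("the strategy report assembles all metrics and comparisons", {
  fx <- small_sim(n = 6000, seed = 181)
  ch <- fx$sim$cohort
  G <- impute_missing(fx$sim$genotypes, ch$dx_event == 0L)
  sel <- select_prs(
    compute_prs(G, validate_snps(fx$panel, per_snp_association(G, ch$dx_event))),
    ch$dx_event
  )
  ch$prs_group <- sel$assignments$prs_group

  cuts <- reference_cutoffs()
  rep_tbl <- strategy_report(ch, cuts)
  expect_equal(rep_tbl$strategy, screening_strategies)
  expect_true(all(rep_tbl$tp + rep_tbl$fp + rep_tbl$fn + rep_tbl$tn == nrow(ch)))

  # lower age-specific thresholds cannot reduce sensitivity vs PSA > 4
  t_row <- rep_tbl[rep_tbl$strategy == "traditional", ]
  i1_row <- rep_tbl[rep_tbl$strategy == "improved1", ]
  expect_gt(i1_row$sens, t_row$sens)
  expect_true(is.na(t_row$p_vs_traditional_sens))
  expect_false(is.na(i1_row$p_vs_traditional_sens))
  expect_true(all(rep_tbl$fp_among_pos >= 0 & rep_tbl$fp_among_pos <= 100))
})
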