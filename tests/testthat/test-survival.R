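test_that("person-year rates reproduce printed-table arithmetic", {
  # 1,306 events over 71.25 thousand person-years -> 18.33 per 1,000 PYs
  n <- 6721
  cohort <- tibble::tibble(
    t_dx_years = rep(71250 / n, n),
    dx_event = rep(c(1L, 0L), times = c(1306, n - 1306))
  )
  r <- person_year_rates(cohort)
  expect_equal(round(r$rate_per_1000_py, 2), 18.33)
  expect_equal(round(r$person_years_thousands, 2), 71.25)

  # 385 events over 71.90 thousand person-years -> 5.35 per 1,000 PYs
  n2 <- 6345
  cohort2 <- tibble::tibble(
    t_dx_years = rep(71900 / n2, n2),
    dx_event = rep(c(1L, 0L), times = c(385, n2 - 385))
  )
  expect_equal(round(person_year_rates(cohort2)$rate_per_1000_py, 2), 5.35)

  # zero events -> zero rate
  cohort3 <- tibble::tibble(t_dx_years = c(1, 2), dx_event = c(0L, 0L))
  expect_equal(person_year_rates(cohort3)$rate_per_1000_py, 0)
  expect_error(
    person_year_rates(tibble::tibble(t_dx_years = -1, dx_event = 1L)),
    "non-negative"
  )
})

test_that("the pooled rate is the person-year-weighted mean of stratum rates", {
  fx <- small_sim(n = 4000, seed = 113)
  ch <- fx$sim$cohort
  overall <- person_year_rates(ch)
  by_age <- person_year_rates(ch, by = "age_group")
  pooled <- sum(by_age$rate_per_1000_py * by_age$person_years_thousands) /
    sum(by_age$person_years_thousands)
  expect_equal(overall$rate_per_1000_py, pooled, tolerance = 1e-9)
  expect_equal(sum(by_age$pct_events), 100, tolerance = 1e-9)
})

test_that("Cox log-HR matches brute-force partial-likelihood maximisation", {
  # 4-subject, tie-free fixture
  cohort <- tibble::tibble(
    t_dx_years = c(1, 2, 3, 4),
    dx_event = c(1L, 1L, 0L, 1L),
    x = c(1, 0, 1, 0)
  )
  fit <- cox_fit(cohort, "x", adjust = character())
  oracle <- cox_oracle_loghr(cohort$t_dx_years, cohort$dx_event, cohort$x)
  expect_equal(fit$terms$estimate, oracle, tolerance = 1e-6)

  # larger tie-free fixtures
  set.seed(131)
  for (rep in 1:4) {
    n <- 18
    t <- sort(rexp(n, 0.2)) + seq(0, 1e-3, length.out = n) # break ties
    e <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)
    if (sum(e) == 0 || length(unique(x)) < 2) next
    co <- tibble::tibble(t_dx_years = t, dx_event = as.integer(e), x = x)
    fit <- cox_fit(co, "x", adjust = character())
    expect_equal(
      fit$terms$estimate,
      cox_oracle_loghr(t, e, x),
      tolerance = 1e-6
    )
    # Efron and Breslow agree exactly without ties
    fitb <- cox_fit(co, "x", adjust = character(), ties = "breslow")
    expect_equal(fit$terms$estimate, fitb$terms$estimate, tolerance = 1e-10)
  }

  expect_error(
    cox_fit(dplyr::mutate(cohort, x = 1), "x", adjust = character()),
    "does not vary"
  )
})

test_that("missing covariate values become an explicit category", {
  fx <- small_sim(n = 1500, seed = 137)
  ch <- fx$sim$cohort
  ch$race[1:100] <- NA
  fit <- cox_fit(ch, "family_history_pca", adjust = c("age_group", "race"))
  expect_equal(fit$n, nrow(ch)) # no rows dropped
  expect_true(any(grepl("racemissing", fit$terms$term)))
})

test_that("interaction codings reproduce the required level structure", {
  fx <- small_sim(n = 8000, seed = 139)
  ch <- fx$sim$cohort
  set.seed(1)
  ch$prs_group <- factor(sample(c("low", "high"), nrow(ch), TRUE),
    levels = c("low", "high")
  )
  ch$psa_positive <- ch$psa_baseline_ng_ml > 1.5

  t16 <- interaction_analysis(ch, "cross_age_16level", adjust = "race")
  expect_equal(nrow(t16), 16L)
  expect_equal(as.integer(table(t16$age_group)), rep(4L, 4))
  ref <- t16[t16$reference, ]
  expect_equal(nrow(ref), 1L)
  expect_equal(ref$age_group, "<60")
  expect_equal(ref$level, "<60 | low/PSA-")
  expect_equal(ref$hr, 1)

  t4 <- interaction_analysis(ch, "age_stratified_4level", adjust = "race")
  expect_equal(nrow(t4), 16L) # 4 levels in each of 4 age strata
  expect_equal(sum(t4$reference), 4L)
  expect_true(all(t4$hr[t4$reference] == 1))
})

test_that("the 16-level coding recovers multiplicative PRS and PSA effects", {
  # generate times with hazard ratio 2 for PSA+, 1.5 for high PRS, no age
  # modification; the joint level should estimate ~3 against the reference
  set.seed(149)
  ratios <- vapply(1:8, function(i) {
    n <- 6000
    age <- runif(n, 55, 75)
    prs <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
    psa_pos <- runif(n) < 0.4
    lp <- log(2) * psa_pos + log(1.5) * (prs == "high")
    t <- rexp(n, 0.02 * exp(lp))
    cens <- runif(n, 8, 15)
    ch <- tibble::tibble(
      t_dx_years = pmin(t, cens),
      dx_event = as.integer(t <= cens),
      age_group = assign_age_group(age),
      prs_group = prs,
      psa_positive = psa_pos
    )
    t16 <- interaction_analysis(ch, "cross_age_16level", adjust = character())
    joint <- t16$hr[t16$age_group == "<60" & t16$level == "<60 | high/PSA+"]
    joint
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.45)
})

test_that("the log-rank test behaves at the null and under strong separation", {
  # literally identical groups: statistic 0
  t <- rexp(100, 0.1)
  e <- rbinom(100, 1, 0.8)
  ch <- tibble::tibble(
    t_dx_years = rep(t, 2), dx_event = as.integer(rep(e, 2)),
    g = rep(c("a", "b"), each = 100)
  )
  lr <- logrank(ch, "g")
  expect_lt(lr$chisq, 1e-10)
  expect_error(logrank(dplyr::mutate(ch, g = "a"), "g"), "two groups")

  # strongly separated exponentials
  set.seed(151)
  n <- 500
  g <- rep(c(0, 1), each = n / 2)
  t2 <- rexp(n, 0.05 * 5^g)
  ch2 <- tibble::tibble(
    t_dx_years = pmin(t2, 20),
    dx_event = as.integer(t2 <= 20),
    g = factor(g)
  )
  expect_lt(logrank(ch2, "g")$p, 0.001)

  # null calibration
  set.seed(157)
  rej <- vapply(1:1000, function(i) {
    tt <- rexp(500, 0.1)
    ee <- as.integer(tt <= 12)
    tibble::tibble(
      t_dx_years = pmin(tt, 12), dx_event = ee,
      g = factor(rbinom(500, 1, 0.5))
    ) |>
      logrank("g") |>
      (\(x) x$p < 0.05)()
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})
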