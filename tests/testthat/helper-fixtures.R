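# shared fixtures and independent oracles for the suite

.fixture_cache <- new.env(parent = emptyenv())

# one calibrated default-scale simulation, shared across files
default_sim <- function() {
  if (is.null(.fixture_cache$default)) {
    cfg <- sim_config(seed = 7)
    panel <- simulate_panel(cfg)
    .fixture_cache$default <- list(
      config = cfg, panel = panel, sim = simulate_cohort(cfg, panel)
    )
  }
  .fixture_cache$default
}

small_sim <- function(n = 2000, seed = 11, ...) {
  cfg <- sim_config(n_participants = n, seed = seed, ...)
  panel <- simulate_panel(cfg)
  list(config = cfg, panel = panel, sim = simulate_cohort(cfg, panel))
}

# O(n^2) pair-counting AUC oracle (ties count 1/2)
auc_pairs <- function(score, y) {
  s1 <- score[y == 1]
  s0 <- score[y == 0]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# brute-force univariate logistic log-likelihood, maximised by optim
logistic_oracle_or <- function(dose, y) {
  nll <- function(par) {
    eta <- par[1] + par[2] * dose
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- optim(c(0, 0), nll, method = "BFGS")
  exp(fit$par[2])
}

# brute-force Cox partial likelihood for one binary covariate, no ties
cox_oracle_loghr <- function(time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  pl <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + x[i] * b - log(sum(exp(b * x[risk])))
    }
    -s
  }
  optimize(pl, c(-10, 10), tol = 1e-9)$minimum
}

# cohort skeleton for screening tests
toy_screen_cohort <- function(psa, age_group, prs_group, case = NULL, gleason = NULL) {
  tibble::tibble(
    psa_baseline_ng_ml = psa,
    age_group = age_group,
    prs_group = prs_group,
    dx_event = case %||% rep(0L, length(psa)),
    gleason_ge7 = gleason %||% rep(NA_integer_, length(psa))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
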