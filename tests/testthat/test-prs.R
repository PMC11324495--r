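test_that("per-SNP logistic association matches a brute-force likelihood oracle", {
  # genotype table: cases (10, 20, 30), controls (30, 20, 10) across 0/1/2
  dose <- c(rep(0:2, times = c(10, 20, 30)), rep(0:2, times = c(30, 20, 10)))
  y <- rep(c(1L, 0L), each = 60)
  G <- cbind(rs1 = dose)
  res <- per_snp_association(G, y)
  expect_equal(res$or, logistic_oracle_or(dose, y), tolerance = 1e-4)
  expect_equal(res$flag, "ok")

  # perfectly balanced table: OR 1 by construction
  dose0 <- rep(rep(0:2, each = 10), 2)
  y0 <- rep(c(1L, 0L), each = 30)
  res0 <- per_snp_association(cbind(rs1 = dose0), y0)
  expect_equal(res0$beta, 0, tolerance = 1e-10)

  # constant dosage is flagged, not estimated
  resc <- per_snp_association(cbind(rs1 = rep(1L, 120)), y)
  expect_equal(resc$flag, "constant")
  expect_true(is.na(resc$beta))

  expect_error(per_snp_association(cbind(rs1 = c(NA, 1L)), c(0L, 1L)), "imputed")
})

test_that("SNP validation requires significance and direction consistency", {
  panel <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"))
  assoc <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    beta = c(0.1, -0.1, 0.1),
    p = c(0.03, 0.03, 0.2)
  )
  out <- validate_snps(panel, assoc, alpha = 0.05)
  expect_identical(out$validated, c(TRUE, FALSE, FALSE))
  expect_error(validate_snps(tibble::tibble(rsid = "rs9"), assoc), "rs9")
})

test_that("validation on a null panel behaves like a one-sided nominal test", {
  # under the null, p < alpha and positive direction jointly hold with
  # probability alpha/2; a handful of 100-SNP panels should average ~2.5
  set.seed(31)
  rates <- replicate(4, {
    n <- 800
    y <- rbinom(n, 1, 0.3)
    G <- matrix(rbinom(n * 100, 2, 0.3), n, 100,
      dimnames = list(NULL, sprintf("rs%03d", 1:100))
    )
    assoc <- per_snp_association(G, y)
    panel <- tibble::tibble(rsid = colnames(G))
    c(
      validated = sum(validate_snps(panel, assoc)$validated),
      significant = sum(assoc$p < 0.05)
    )
  })
  expect_gt(mean(rates["validated", ]), 0.5)
  expect_lt(mean(rates["validated", ]), 5)
  expect_gt(mean(rates["significant", ]), 2)
  expect_lt(mean(rates["significant", ]), 9)
})

test_that("the four PRS variants follow their definitions", {
  panel <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    validated = c(TRUE, FALSE, TRUE),
    fitted_beta = c(0.1, 0.2, 0.3)
  )
  G <- rbind(
    P1 = c(0L, 0L, 0L),
    P2 = c(1L, 2L, 0L),
    P3 = c(2L, 1L, 1L)
  )
  colnames(G) <- panel$rsid
  s <- compute_prs(G, panel)
  expect_equal(s$PRS1, c(0, 3, 4))
  expect_equal(s$PRS2, c(0, 1, 3)) # validated SNPs only
  expect_equal(s$PRS3, c(0, 0.1 * 1 + 0.2 * 2, 0.1 * 2 + 0.2 * 1 + 0.3 * 1))
  expect_equal(s$PRS4, c(0, 0.1, 0.1 * 2 + 0.3))
  expect_identical(attr(s, "n_snps"), c(PRS1 = 3L, PRS2 = 2L, PRS3 = 3L, PRS4 = 2L))

  expect_error(
    compute_prs(G, dplyr::select(panel, "rsid"), "PRS3"),
    "fitted_beta"
  )
  expect_error(
    compute_prs(G, dplyr::select(panel, "rsid"), "PRS2"),
    "validated"
  )
})

test_that("PRS1 dominates PRS2 and their difference is the non-validated dosage sum", {
  set.seed(41)
  for (rep in 1:5) {
    p <- 12
    n <- 30
    panel <- tibble::tibble(
      rsid = sprintf("rs%02d", 1:p),
      validated = rbinom(p, 1, 0.6) == 1,
      fitted_beta = rnorm(p, 0.1, 0.05)
    )
    G <- matrix(rbinom(n * p, 2, 0.35), n, p, dimnames = list(NULL, panel$rsid))
    s <- compute_prs(G, panel)
    expect_true(all(s$PRS1 >= s$PRS2))
    expect_equal(
      s$PRS1 - s$PRS2,
      rowSums(G[, !panel$validated, drop = FALSE])
    )
    expect_true(all(s$PRS1 >= 0 & s$PRS1 <= 2 * p & s$PRS1 == round(s$PRS1)))
  }
})

test_that("variant selection picks the largest AUC and splits at the Youden cut-off", {
  set.seed(51)
  n <- 3000
  y <- rbinom(n, 1, 0.3)
  # four scores with strictly increasing signal, PRS4 strongest
  base <- rnorm(n)
  mk <- function(strength) base + strength * y + rnorm(n, 0, 0.5)
  scores <- tibble::tibble(
    id = as.character(1:n),
    PRS1 = mk(0.2), PRS2 = mk(0.35), PRS3 = mk(0.55), PRS4 = mk(0.8)
  )
  attr(scores, "n_snps") <- c(PRS1 = 102L, PRS2 = 80L, PRS3 = 102L, PRS4 = 80L)
  sel <- select_prs(scores, y)
  aucs <- sel$auc$auc
  expect_identical(sel$variant, sel$auc$variant[which.max(aucs)])
  expect_identical(sel$variant, "PRS4")
  expect_true(all(diff(aucs) > 0))

  # the split is exactly score > cut-off
  expect_identical(
    sel$assignments$prs_group == "high",
    scores$PRS4 > sel$cutoff
  )

  # all-equal AUCs: fewest SNPs then unweighted preference -> PRS2
  same <- scores
  for (v in c("PRS1", "PRS2", "PRS3", "PRS4")) same[[v]] <- scores$PRS1
  attr(same, "n_snps") <- attr(scores, "n_snps")
  expect_identical(select_prs(same, y)$variant, "PRS2")
})

test_that("weighted selection is no worse than unweighted under heterogeneous effects", {
  # effect-size heterogeneity is what the beta-weighting exploits
  diffs <- vapply(1:20, function(s) {
    fx <- small_sim(n = 3000, seed = 300 + s, logor_sd = 0.05)
    ch <- fx$sim$cohort
    G <- impute_missing(fx$sim$genotypes, ch$dx_event == 0L)
    panel <- validate_snps(fx$panel, per_snp_association(G, ch$dx_event))
    if (sum(panel$validated) < 2) {
      return(0)
    }
    s <- compute_prs(G, panel, c("PRS2", "PRS4"))
    roc_auc(s$PRS4, ch$dx_event)$auc - roc_auc(s$PRS2, ch$dx_event)$auc
  }, numeric(1))
  expect_gt(mean(diffs), -0.005)
})
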