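#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir Directory where every stage writes its CSV artifacts and
#'   the manifest.
#' @param seed Master seed; each stage derives its own stream from it
#'   (simulation uses `seed`/`seed + 1`, bootstrap `seed + 2`), so stages
#'   can be re-run in isolation reproducibly.
#' @param simulate If `TRUE` (default) the cohort is simulated with
#'   `sim`; otherwise `cohort_path`, `genotypes_path` and `panel_path` must
#'   name existing files.
#' @param sim A [sim_config()] used when `simulate = TRUE`; its seed is
#'   overridden by `seed`.
#' @param cohort_path,genotypes_path,panel_path Input files (cohort CSV,
#'   genotype TSV, panel CSV) used when `simulate = FALSE`.
#' @param horizon_years tdROC horizon (default 10).
#' @param validation_alpha Two-sided alpha for SNP validation.
#' @param cutoff_source `"derived"` (tdROC on the data) or `"fixed"` (the
#'   published table from [reference_cutoffs()], skipping derivation).
#' @param bootstrap_B Bootstrap resamples for cut-off stability (0 = skip).
#' @param strategies Screening strategies for the final report.
#' @param adjust Adjustment covariates for the Cox models.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 20240801,
                       simulate = TRUE,
                       sim = sim_config(),
                       cohort_path = NULL,
                       genotypes_path = NULL,
                       panel_path = NULL,
                       horizon_years = 10,
                       validation_alpha = 0.05,
                       cutoff_source = c("derived", "fixed"),
                       bootstrap_B = 0,
                       strategies = screening_strategies,
                       adjust = std_adjustment()) {
  cutoff_source <- match.arg(cutoff_source)
  stopifnot(horizon_years > 0, bootstrap_B >= 0)
  strategies <- match.arg(strategies, screening_strategies, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

write_stage <- function(x, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(as_tibble(x), path)
  path
}

#' Run the full risk-adapted screening pipeline
#'
#' Orchestrates simulate (or load) -> genotype imputation -> per-SNP
#' association and validation -> PRS construction, selection and
#' dichotomisation -> PRS-/age-specific PSA cut-offs -> person-year rates,
#' Cox association and interaction codings -> screening-strategy report.
#' Every stage writes a CSV under `config$out_dir` and a `manifest.json`
#' records the configuration hash, per-stage row counts and package
#' version, so two runs with the same config and seed produce identical
#' artifacts.
#'
#' PRS construction and selection use the full cohort; cut-off derivation,
#' the rate/Cox/interaction analyses and the strategy report use the
#' screening arm, whose baseline PSA is the screened marker.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `panel`, `selection`, `cutoffs`, `rates`, `cox`, `interactions`,
#'   `report`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  log_msg <- function(...) message(sprintf("[%s] ", stage), sprintf(...))

  on_failure <- function(e) {
    abort(sprintf("Pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
  }
  withCallingHandlers(
    {
      if (config$simulate) {
        sim_cfg <- config$sim
        sim_cfg$seed <- as.integer(config$seed)
        panel <- simulate_panel(sim_cfg)
        sim <- simulate_cohort(sim_cfg, panel)
        cohort <- sim$cohort
        G <- sim$genotypes
        log_msg("simulated %d participants x %d SNPs", nrow(cohort), ncol(G))
      } else {
        for (p in c(config$cohort_path, config$genotypes_path, config$panel_path)) {
          if (is.null(p) || !file.exists(p)) {
            abort(sprintf("Input file not found: %s", p %||% "<unset>"))
          }
        }
        panel <- readr::read_csv(config$panel_path, show_col_types = FALSE)
        cohort <- read_cohort(config$cohort_path)
        G <- read_genotypes(config$genotypes_path, panel, format = "tsv")
        log_msg("loaded %d participants x %d SNPs", nrow(cohort), ncol(G))
      }
      write_stage(panel, config$out_dir, "panel.csv")
      write_stage(cohort, config$out_dir, "cohort.csv")

      stage <- "prs"
      G <- impute_missing(G, is_control = cohort$dx_event == 0L)
      assoc <- per_snp_association(G, cohort$dx_event)
      panel <- validate_snps(panel, assoc, alpha = config$validation_alpha)
      scores <- compute_prs(G, panel)
      selection <- select_prs(scores, cohort$dx_event)
      cohort <- cohort |>
        left_join(
          selection$assignments |> select("id", "prs_group"),
          by = "id"
        )
      write_stage(assoc, config$out_dir, "snp_association.csv")
      write_stage(scores, config$out_dir, "prs_scores.csv")
      write_stage(selection$auc, config$out_dir, "prs_auc.csv")
      log_msg(
        "selected %s (AUC %.3f), %d/%d SNPs validated",
        selection$variant, selection$auc$auc[selection$auc$selected],
        sum(panel$validated), nrow(panel)
      )

      screening_arm <- cohort |> filter(.data$arm == "screening")

      stage <- "cutoffs"
      if (config$cutoff_source == "fixed") {
        cutoffs <- reference_cutoffs()
        log_msg("using the fixed published cut-off table")
      } else if (config$bootstrap_B > 0) {
        cutoffs <- bootstrap_cutoff_stability(
          screening_arm,
          horizon = config$horizon_years,
          B = config$bootstrap_B, seed = config$seed + 2L
        )
        log_msg("derived cut-offs with %d bootstrap resamples", config$bootstrap_B)
      } else {
        cutoffs <- stratified_cutoffs(screening_arm, horizon = config$horizon_years)
        log_msg("derived %d cut-off cells", nrow(cutoffs))
      }
      write_stage(cutoffs, config$out_dir, "cutoffs.csv")

      stage <- "survival"
      screening_arm <- classify_screening(screening_arm, "improved2", cutoffs) |>
        rename(psa_positive = "screen_positive")
      rates <- bind_rows(
        person_year_rates(screening_arm, by = character(), outcome = "incidence") |>
          mutate(group = "overall", .before = 1),
        person_year_rates(screening_arm,
          by = c("prs_group", "psa_positive"), outcome = "incidence"
        ) |>
          mutate(group = "prs_x_psa", .before = 1)
      )
      cox <- cox_fit(screening_arm, exposure = "prs_group", adjust = config$adjust)
      interactions <- interaction_analysis(
        screening_arm,
        scheme = "cross_age_16level", adjust = config$adjust
      )
      write_stage(rates, config$out_dir, "person_year_rates.csv")
      write_stage(tidy(cox), config$out_dir, "cox_prs_incidence.csv")
      write_stage(interactions, config$out_dir, "interaction_16level.csv")
      log_msg("rates, Cox and 16-level interaction written")

      stage <- "screen"
      report <- strategy_report(screening_arm, cutoffs, config$strategies)
      write_stage(report, config$out_dir, "strategy_report.csv")
      log_msg("evaluated %d strategies", nrow(report))

      stage <- "manifest"
      cfg_for_hash <- config
      cfg_for_hash$out_dir <- NULL
      cfg_json <- jsonlite::toJSON(
        cfg_for_hash[order(names(cfg_for_hash))],
        auto_unbox = TRUE, digits = NA, force = TRUE
      )
      tmp <- tempfile()
      writeLines(as.character(cfg_json), tmp)
      manifest <- list(
        config_hash = unname(tools::md5sum(tmp)),
        seed = config$seed,
        package_version = as.character(utils::packageVersion("prscreen")),
        rows = list(
          cohort = nrow(cohort),
          screening_arm = nrow(screening_arm),
          panel = nrow(panel),
          validated_snps = sum(panel$validated),
          cutoff_cells = nrow(cutoffs),
          strategies = nrow(report)
        ),
        prs_variant = selection$variant
      )
      unlink(tmp)
      jsonlite::write_json(
        manifest, file.path(config$out_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA
      )
    },
    error = on_failure
  )

  invisible(list(
    cohort = cohort, panel = panel, selection = selection, cutoffs = cutoffs,
    rates = rates, cox = cox, interactions = interactions, report = report,
    manifest = manifest
  ))
}
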