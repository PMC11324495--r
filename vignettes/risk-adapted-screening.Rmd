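---
title: "Methods: PRS-specific and age-specific PSA screening cut-offs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS-specific and age-specific PSA screening cut-offs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery of `prscreen`: the models,
the estimator conventions, the synthetic-data generator and its calibration,
and the design decisions taken where several defensible choices existed. It
states no empirical result beyond what the package's tests and the
acceptance script themselves compute.

## The analysis in one paragraph

A screening cohort of men aged 55–74 carries, per participant, a baseline
PSA (ng/mL), risk-allele dosages for a panel of SNPs, baseline covariates,
and censored times to prostate-cancer diagnosis and to prostate-cancer
death. The pipeline (i) builds four polygenic risk score (PRS) variants and
selects the one with the largest case/control AUC, dichotomising the cohort
at the Youden point of its ROC; (ii) derives PSA positivity thresholds from
the time-dependent ROC of baseline PSA for 10-year incident cancer, overall
and within age × PRS strata; (iii) quantifies incidence and mortality
associations with person-year rates and proportional-hazards models,
including two joint PRS × PSA interaction codings; and (iv) compares four
screening positivity rules on the usual confusion-matrix metric panel.

## PRS construction and selection

With dosage $g_{ij} \in \{0,1,2\}$ of the risk allele of SNP $j$ in man $i$
and in-cohort univariate logistic log odds ratios $\hat\beta_j$ (additive
coding), the variants are

$$\mathrm{PRS1}_i = \sum_{j} g_{ij}, \quad
  \mathrm{PRS2}_i = \sum_{j \in V} g_{ij}, \quad
  \mathrm{PRS3}_i = \sum_{j} \hat\beta_j g_{ij}, \quad
  \mathrm{PRS4}_i = \sum_{j \in V} \hat\beta_j g_{ij},$$

where $V$ is the validated subset: SNPs with two-sided Wald $p < \alpha$
*and* $\hat\beta_j > 0$ under risk-allele coding (direction consistent with
the published risk allele). Decisions:

* **Validation $\alpha = 0.05$, no multiplicity correction.** Validation is
  a replication filter, not a discovery scan; a nominal test matched to the
  published direction is the intended behaviour. $\alpha$ is an argument.
  Note the joint null probability of validation is $\alpha/2$ (significance
  *and* positive direction), which the suite verifies by simulation.
* **In-cohort weights, not published weights.** The weighted variants use
  $\hat\beta_j$ refitted in the cohort; published betas are kept only for
  the direction check. Refitted weights adapt to the cohort's LD and
  ancestry profile, at the price of in-sample optimism — which is why a
  null-effect test in the suite uses the unweighted variant to check that
  genotypes carry no signal when all true effects are zero.
* **Missing dosages** are imputed as the homozygous dosage of the major
  allele among controls (2 if the risk-allele frequency among controls
  exceeds 0.5, else 0); ties at exactly 0.5 resolve to 0. Non-missing
  entries are never modified.
* **Selection** takes the maximal AUC; ties break toward the variant with
  fewest SNPs, then toward the unweighted variant (cheaper and more
  transferable at equal discrimination). Pairwise DeLong tests (structural
  components, normal reference) are reported but do not gate the selection.
* **Strand/allele mismatches** in VCF input are an error, never
  auto-corrected: a silently flipped allele changes the sign of a SNP's
  contribution.

The ROC machinery uses the empirical curve over the sorted unique score
values with positivity `score > c`; the AUC is the Mann–Whitney statistic
(ties 1/2); the Youden point maximises sensitivity + specificity − 1 with
ties broken toward the *smaller* threshold, favouring sensitivity — the
appropriate direction for a screening instrument.

## Time-dependent ROC with censoring weights

For horizon $t$ (10 years), cumulative cases are subjects with an event by
$t$ (events at exactly $t$ count as cases) and dynamic controls are
subjects event-free and still under observation at $t$. Censoring is
handled by inverse-probability-of-censoring weighting with the Kaplan–Meier
censoring survival function $\hat G$: cases weigh $1/\hat G(T_i-)$,
controls $1/\hat G(t-)$, and subjects censored before $t$ weigh 0.
Weighted sensitivity and specificity are computed at every observed marker
value; the tdAUC is the trapezoidal area; the optimal cut-off is the Youden
point with the same tie rule as above. Conventions worth stating because
they fix the numbers bit-for-bit:

* threshold grid = sorted unique observed marker values (exact empirical
  curve), rounding to 0.01 ng/mL only for display;
* left limits $\hat G(T-)$ and $\hat G(t-)$, so a subject's own censoring
  (or a censoring tied at the horizon) never deflates its weight;
* if $\hat G$ hits 0 before a needed time the estimator aborts and suggests
  a shorter horizon rather than returning unstable weights;
* with no censoring all weights are 1 and the estimator reduces *exactly*,
  at every threshold, to the binary ROC of the indicator $T \le t$ — the
  suite enforces this and a fully hand-enumerated 6-subject example.

These are the standard cumulative/dynamic IPCW conventions; other published
implementations differ in tie and limit conventions, so agreement with them
is expected only up to those choices.

Stratified cut-offs run this estimator within each PRS stratum × age group
cell; cells with fewer than 20 cases by the horizon are flagged
`unreliable` rather than dropped. Bootstrap stability resamples
participants with replacement (default B = 2000) and reports 2.5/97.5
percentile intervals per cell. A fixed table of published PLCO cut-offs
(`reference_cutoffs()`) can stand in for derivation when the goal is
strategy evaluation alone.

## Survival analyses

Person-year rates divide event counts by follow-up summed from entry to
event or censoring, reported per 1,000 person-years; incidence and
mortality use separate follow-up scales (cancer ascertainment closes
earlier than death ascertainment). Cox models use Efron tie handling
(with heavy ties Breslow biases toward the null; Efron and Breslow agree
exactly on tie-free data, which the suite checks). Categorical covariates
receive an explicit `missing` level instead of row deletion, so the
analysed n is the cohort n. Confidence intervals are Wald on the log scale.

The two interaction codings answer different questions: the 4-level coding
(low/PSA−, low/PSA+, high/PSA−, high/PSA+ within each age stratum,
within-stratum reference) gives age-conditional joint effects; the 16-level
coding (the same four combinations crossed with the four age groups, one
model, uniform reference low/PSA− at age <60) makes all 16 cells
commensurable on one scale. Empty levels are dropped with a warning rather
than silently re-referenced.

## Screening strategies and metrics

All four rules are evaluated on **baseline** PSA with strict inequality
(PSA > cut-off), including the traditional rule, so comparisons are
like-for-like on the marker the cut-offs were derived from (a trial's
operational "any round > 4" definition is a different estimand). Case
status is cancer diagnosed during available incidence follow-up; a
horizon-restricted case definition would be a one-line change in the
evaluation call but is not the default, matching how screening tables are
usually tabulated. Two false-positive proportions are both computed and
labelled explicitly — FP among screen positives (the complement of PPV) and
FP among all participants — because both denominators appear in practice
and conflating them changes the number by an order of magnitude. The
high-grade proportion takes true positives as its denominator. Exact
Clopper–Pearson intervals accompany every proportion. Paired strategy
comparisons use McNemar's test restricted to cases (sensitivity) or
non-cases (specificity), uncorrected $(b-c)^2/(b+c)$ by default with an
exact binomial option; no discordant pairs yields p = 1.

## The synthetic-cohort generator

`simulate_cohort()` generates, in order: genotypes
$g_{ij} \sim \mathrm{Bin}(2, f_j)$ under Hardy–Weinberg; a centred latent
genetic score $g_i = \sum_j \beta_j g_{ij} - \sum_j 2 f_j \beta_j$;
diagnosis times from an exponential proportional-hazards model
$h_i = h_0 \exp(g_i + x_i^\top\gamma + \delta\,(\mathrm{age}_i - 65))$;
censoring as the minimum of uniform administrative follow-up (10–13 years)
and exponential dropout; baseline PSA
$\log \mathrm{PSA}_i = \mu + a(\mathrm{age}_i - 55) + b\,g_i +
s\,w(T_i)\,1\{\text{case}\} + \varepsilon_i$ with
$w(T) = \max(0, 1 - T/10)$; Gleason ≥7 among cases from a logistic model on
centred log PSA and $g_i$; and prostate-cancer death among cases from an
exponential post-diagnosis hazard censored six years after the
administrative incidence cut. A configurable 2% of genotype entries is then
blanked completely at random — enough to exercise the imputation rule
without influencing results. The latent risk uses the complete genotypes,
so imputation error is purely analytic.

Key generator decisions:

* **Exponential baseline hazard, not Weibull.** The downstream analysis
  consumes times and censoring indicators, not hazard shapes; a rate scale
  is the only thing calibration needs.
* **Linear pre-clinical PSA window $w(T) = \max(0, 1 - T/10)$.** The
  10-year ramp makes baseline PSA informative at exactly the evaluation
  horizon and decays to nothing for diagnoses more than a decade out.
* **An age→hazard path (`age_loghr`, default 0.04/year) is included** in
  addition to the age→PSA path, since incidence genuinely rises with age;
  tests of a marker-independent null switch both paths off.
* **Calibration.** Defaults were set, once, so that a 30,000-man cohort
  lands near the anchor values of the population being emulated: overall
  incidence ≈ 11 per 1,000 person-years (~12% cumulative over ~12 years),
  selected-PRS AUC ≈ 0.63, 10-year tdAUC of baseline PSA ≈ 0.8, high-grade
  disease in ~39% of cases detected at PSA > 4, and case fatality from
  prostate cancer near 8–9%. Covariate prevalences and log hazard ratios
  (0.1–0.4) are configuration values, not code.
* **Seeding.** One base seed per run: the panel stream uses `seed`, the
  cohort stream `seed + 1`, the pipeline's bootstrap `seed + 2`; identical
  configurations are byte-identical.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, ancestry structure, multi-round PSA trajectories, digital rectal
examination, non-cancer mortality as a competing risk (censoring subsumes
it), and diagnostic work-up behaviour. Consequently, passing tests show the
estimators are correct and the pipeline coherent under the stated
generative model — not that the derived cut-offs transfer to any real
population.

A wording note on the emulated covariate list: published descriptions of
the source cohort print the entry-age groups once as "<60, 60–74, 65–69,
≥70", an evident typo for 60–64; the generator uses the four-group
partition <60 / 60–64 / 65–69 / ≥70 throughout.

## Numerical and testing choices

Problem sizes in the test-suite were chosen to keep the full run in a few
minutes on one core while leaving comfortable Monte-Carlo margins: one
shared 30,000-man calibrated cohort for distributional checks; 20,000 for
null tdAUC and cumulative-incidence agreement; 20 seeds × 20,000 for the
age-monotonicity of derived cut-offs; 50 replicates × 5,000 for Cox
parameter recovery; 1,000 null fits for the logistic type-I error; 2,000
bootstrap replicates against the DeLong variance. Independent oracles are
kept deliberately naive: $O(n^2)$ pair counting for AUC, a hand-enumerated
six-subject tdROC fixture, brute-force likelihood maximisation for
logistic and Cox estimates, and the pROC implementation as an external
cross-check for AUC and DeLong p-values.

Degenerate inputs fail loudly by design: single-class outcomes, constant
exposures, missing cut-off cells, all-missing control genotypes and
exhausted censoring support are errors naming the offending SNP, cell or
path, because every one of these silently corrupts a downstream number if
allowed through.

## Known limitations

Youden cut-points are argmax estimators and converge slowly; per-cell
bootstrap intervals are the honest way to report them, and thin cells
(fewer than 20 horizon cases) are flagged. The in-cohort beta weighting of
PRS3/PRS4 is optimistic in-sample; out-of-sample validation would need an
external cohort, which is exactly what the synthetic generator cannot
substitute for. The 16-level interaction coding estimates cell contrasts,
not formal interaction tests. McNemar p-values for strategies that are
near-supersets of each other (for example, traditional vs the age-specific
rule when every age cut-off is below 4 ng/mL) are driven almost entirely by
one discordant direction; that is a property of the design, not a flaw of
the test.
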