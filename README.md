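# mvtlogit

Bayesian multivariate latent Student-*t* regression for several correlated
binary outcomes observed on the same subjects, built for epidemiological
questions of the form *"how does a categorical exposure relate to a family
of co-occurring conditions — marginally, jointly, and cumulatively?"*.  The
motivating setting is cancer-survivorship late effects: relating a
three-level corticosteroid-dose / cranial-radiotherapy exposure to obesity,
insulin resistance, (pre-)hypertension and dyslipidemia in survivors of
childhood acute lymphoblastic leukemia, adjusting for sex, age at
diagnosis, white-blood-cell count at diagnosis, and time since diagnosis.

## The model

The four binary outcomes of subject *i* are the sign pattern of a latent
Student-*t* vector:

```
Z_i ~ St_4(mu_i, delta^2 R, nu),    Y_i^j = 1(Z_i^j > 0)
mu_i^j = beta_0^j + beta_1^j T1_i + beta_2^j T2_i + beta_C^j' C_i
```

with `nu = 7.3` and `delta^2 = pi^2 (nu - 2) / (3 nu)`.  That calibration
makes each latent margin track the standard logistic CDF to within 0.002,
so every non-intercept coefficient is a conditional log odds ratio — the
familiar currency of logistic regression — while the unstructured
correlation matrix `R` captures residual dependence between outcomes.
Priors are `N(0, 1000)` on intercepts, `N(0, 4)` on other coefficients, and
uniform over the space of correlation matrices.

The package provides:

* a data-augmented MCMC sampler (gamma mixing variables, truncated-normal
  latents, conjugate coefficient updates, Metropolis correlation step with
  burn-in adaptation toward 25% acceptance), written in C++;
* a Genz-type randomized quasi-Monte-Carlo orthant integrator for the
  multivariate *t* at non-integer degrees of freedom, used for joint
  outcome-configuration probabilities;
* post-hoc association measures per posterior draw: conditional odds
  ratios, g-computation population risk differences (PRDs),
  joint-configuration contrasts, and cumulative contrasts
  `P(N >= k)` for carrying at least *k* outcomes;
* Geweke / effective-sample-size / sequential-boxplot diagnostics;
* a synthetic-cohort generator with known ground truth (confounded
  three-level exposure, heavy-tailed WBC count, latent-*t* outcomes) so the
  whole pipeline is testable without access to patient-level data;
* a `run_full_analysis()` driver fitting the crude, fully adjusted, and
  adjusted-without-WBC model variants and emitting report tables, plus a
  small CLI in `inst/scripts/mvtlogit-analysis.R`.

## Worked example

```r
library(mvtlogit)

gen    <- generator_spec(n = 241, seed = 20)   # synthetic survivor cohort
cohort <- generate_cohort(gen)
table(cohort$exposure)
#> LD/NoCRT   LD/CRT   HD/CRT
#>      106       77       58

draws <- run_chain(cohort, config = mcmc_config(reduced = TRUE, seed = 20))
draws
#> mvtlogit posterior draws: 1800 retained draws, 28 coefficients + 6 correlations
#>   schedule 20000 / 2000 / thin 10; Metropolis acceptance 0.289

odds_ratios(draws, "t1")        # LD/CRT vs LD/NoCRT, one OR per outcome
#>   measure     label      contrast  mean median lower upper
#> 1      OR beta_O_t1 per 1 unit(s) 1.830  1.750 0.910  3.22
#> 2      OR beta_I_t1 per 1 unit(s) 0.819  0.762 0.348  1.67
#> 3      OR beta_H_t1 per 1 unit(s) 1.062  0.924 0.305  2.70
#> 4      OR beta_D_t1 per 1 unit(s) 3.163  2.970 1.616  5.60

marginal_risk_difference(draws, cohort, "D")
#>   measure label           contrast  mean median lower upper
#> 1     PRD     D LD/CRT vs LD/NoCRT 0.239  0.238 0.107 0.367

residual_correlation_summary(draws, c("O", "I"))
#>   measure   label contrast  mean median lower upper
#> 1     rho rho_O_I     <NA> 0.732   0.74 0.578 0.849

cumulative_risk_difference(draws, cohort, 1,
                           draw_idx = round(seq(1, 1800, length.out = 50)))
#>          measure label           contrast  mean median  lower upper
#> 1 cumulative-PRD  N>=1 LD/CRT vs LD/NoCRT 0.155  0.157 0.0513 0.245
```

Reading the output: the posterior median odds ratio of dyslipidemia under
LD/CRT versus the baseline exposure is 2.97 (95% CrI 1.62–5.60) in this
synthetic cohort — the generator's true value is log(1.98) plus sampling
noise at n = 241 — and the same exposure contrast carries a 0.24 excess
dyslipidemia risk and a 0.16 excess risk of presenting at least one
complication.  The obesity–insulin-resistance residual correlation posterior
(median 0.74) brackets the generating value 0.69.  Equal-tailed 95% credible
intervals come from the 2.5th/97.5th empirical percentiles of the retained
draws; posterior medians are the headline for odds ratios because their
posteriors are right-skewed.

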