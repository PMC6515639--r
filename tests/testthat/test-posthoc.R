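spec4 <- model_spec()
full_terms <- c("(Intercept)", "t1", "t2", "sex", "age_dx", "wbc_dx",
                "time_dx")
delta <- sqrt(scale_constant(7.3))

test_that("posterior summaries use equal-tailed empirical percentiles", {
  s <- summarize_posterior(1:5)
  expect_equal(s$median, 3)
  expect_equal(s$mean, 3)
  expect_error(summarize_posterior(1), "at least 2")
  # symmetric draws: mean ~= median
  set.seed(1)
  x <- rnorm(5000)
  s2 <- summarize_posterior(x)
  expect_equal(s2$mean, s2$median, tolerance = 0.05)
  # closed-form normal quantile oracle
  set.seed(2)
  y <- rnorm(10000, 0.15, 0.07)
  s3 <- summarize_posterior(y)
  expect_lt(abs(s3$lower - (0.15 + qnorm(0.025) * 0.07)), 0.01)
  expect_lt(abs(s3$upper - (0.15 + qnorm(0.975) * 0.07)), 0.01)
})

test_that("odds ratios transform draws per-draw before summarizing", {
  # three draws of a single chain: log 1, log 2, log 4 -> median OR 2
  beta <- matrix(0, 3, 28)
  cols <- mvtlogit:::beta_colnames(spec4, full_terms)
  beta[, which(cols == "beta_D_t1")] <- log(c(1, 2, 4))
  d <- make_draws(beta, matrix(0, 3, 6), full_terms)
  or <- odds_ratios(d, "beta_D_t1")
  expect_equal(or$median, 2)
  # null draws
  or0 <- odds_ratios(d, "beta_O_t1")
  expect_equal(or0$mean, 1)
  expect_equal(or0$lower, 1)
  expect_equal(or0$upper, 1)
  # term matching expands across outcomes
  expect_equal(nrow(odds_ratios(d, "t1")), 4)
  expect_error(odds_ratios(d, "nope"), "unknown term")
  # the WBC convention: exponentiate at a 10-unit increment
  beta[, which(cols == "beta_I_wbc_dx")] <- log(1.08) / 10
  d2 <- make_draws(beta, matrix(0, 3, 6), full_terms)
  or10 <- odds_ratios(d2, "beta_I_wbc_dx", increment = 10)
  expect_equal(or10$median, 1.08, tolerance = 1e-10)
})

# single fixed draw with a known treatment effect on dyslipidemia
one_draw <- function(effect = 1, R = diag(4)) {
  beta <- matrix(0, 1, 28)
  cols <- mvtlogit:::beta_colnames(spec4, full_terms)
  beta[, which(cols == "beta_D_t1")] <- effect
  make_draws(rbind(beta, beta), rbind(mvtlogit:::corr_to_free(R),
                                      mvtlogit:::corr_to_free(R)),
             full_terms)
}

test_that("population risk difference matches the univariate t oracle", {
  # single survivor with all-zero covariates: mu(T1) = 1, mu(T0) = 0
  cohort <- toy_cohort(1)
  cohort$sex <- 0; cohort$age_dx <- 0; cohort$wbc_dx <- 1e-12
  cohort$time_dx <- 0
  d <- one_draw(effect = 1)
  prd <- marginal_risk_difference(d, cohort, "D")
  oracle <- integrate(function(z) dt(z / delta, 7.3) / delta,
                      lower = -1, upper = 0, rel.tol = 1e-10)$value
  expect_equal(prd$mean, oracle, tolerance = 1e-6)
  expect_equal(prd$mean, pt(1 / delta, 7.3) - 0.5, tolerance = 1e-9)
  # null contrast: identical arms give exactly zero per draw
  prd0 <- marginal_risk_difference(d, cohort, "D",
                                   contrast = c("LD/CRT", "LD/CRT"))
  expect_identical(unique(attr(prd0, "per_draw")), 0)
  expect_error(marginal_risk_difference(d, cohort, "Q"), "unknown outcome")
  expect_error(marginal_risk_difference(d, cohort, "D",
                                        contrast = c("LD/CRT", "bogus")),
               "unknown exposure")
})

test_that("configuration differences vanish in the symmetric/null cases", {
  cohort <- toy_cohort(3)
  d0 <- one_draw(effect = 0)
  cd <- configuration_probability_difference(d0, cohort, c(1, 0, 0, 1))
  expect_lt(abs(cd$mean), 2e-3)  # beta = 0 draw: both arms 1/16
  d <- one_draw(effect = 1.2)
  cd0 <- configuration_probability_difference(d, cohort, "1001",
                                              contrast = c("HD/CRT",
                                                           "HD/CRT"))
  expect_equal(cd0$mean, 0)
})

test_that("configuration difference matches a latent-simulation oracle", {
  set.seed(3)
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.69; R[1, 4] <- R[4, 1] <- 0.36
  cohort <- toy_cohort(1)
  d <- one_draw(effect = 1, R = R)
  pat <- c(1, 0, 0, 1)
  cd <- configuration_probability_difference(d, cohort, pat,
                                             draw_idx = 1:2)
  # brute-force latent draws under each arm
  sim_arm <- function(level) {
    X <- build_design(cohort, "full", "identity")
    lv <- exposure_levels()
    X[, "t1"] <- as.numeric(level == lv[2])
    X[, "t2"] <- as.numeric(level == lv[3])
    B <- matrix(d$beta[1, ], 4, 7)
    mu <- as.numeric(X %*% t(B))
    z <- mvtnorm::rmvt(4e5, sigma = scale_constant(7.3) * R, df = 7.3,
                       delta = mu, type = "shifted")
    hit <- rep(TRUE, nrow(z))
    for (j in 1:4) hit <- hit & ((z[, j] > 0) == (pat[j] == 1))
    mean(hit)
  }
  mc <- sim_arm("LD/CRT") - sim_arm("LD/NoCRT")
  se <- sqrt(2 * 0.12 * 0.88 / 4e5)
  expect_lt(abs(cd$mean - mc), 3 * se + 1e-3)
})

test_that("cumulative contrasts sum the right configurations", {
  cohort <- toy_cohort(2)
  d <- one_draw(effect = 1)
  cfg <- outcome_configurations(4)
  expect_error(cumulative_risk_difference(d, cohort, 5), "between 1 and")
  # complement identity: the k = 1 cumulative equals minus the all-zero
  # configuration difference
  c1 <- cumulative_risk_difference(d, cohort, 1, draw_idx = 1:2)
  c0 <- configuration_probability_difference(d, cohort, "0000",
                                             draw_idx = 1:2)
  expect_equal(c1$mean, -c0$mean, tolerance = 2e-3)
  # all 16 configuration differences cancel (both arms integrate to one)
  tab <- mvtlogit:::configuration_difference_table(d, cohort,
                                                   c("LD/CRT", "LD/NoCRT"),
                                                   draw_idx = 1:2)
  expect_lt(abs(sum(tab[1, ])), 1e-3)
  # null contrast is zero at every k
  for (k in 1:4) {
    ck <- cumulative_risk_difference(d, cohort, k,
                                     contrast = c("LD/CRT", "LD/CRT"),
                                     draw_idx = 1:2)
    expect_equal(ck$mean, 0)
  }
})

test_that("marginal PRD decomposes into its eight joint configurations", {
  cohort <- toy_cohort(2)
  d <- one_draw(effect = 0.8)
  prd <- marginal_risk_difference(d, cohort, "D")
  cfg <- outcome_configurations(4)
  tab <- mvtlogit:::configuration_difference_table(d, cohort,
                                                   c("LD/CRT", "LD/NoCRT"),
                                                   draw_idx = 1:2)
  joint_sum <- sum(tab[1, cfg[, 4] == 1])
  expect_equal(prd$mean, joint_sum, tolerance = 2e-3)
})

test_that("residual correlation summaries resolve outcome pairs", {
  d <- make_draws(matrix(0, 4, 28), matrix(rep(c(0.5, 0, 0, 0, 0, -0.1),
                                               each = 4), 4, 6), full_terms)
  s <- residual_correlation_summary(d, c("O", "I"))
  expect_equal(s$mean, 0.5)
  expect_equal(s$lower, 0.5)
  expect_equal(s$upper, 0.5)
  expect_equal(s$label, "rho_O_I")
  s2 <- residual_correlation_summary(d, c(3, 4))
  expect_equal(s2$median, -0.1)
  # order of the pair does not matter
  expect_equal(residual_correlation_summary(d, c("I", "O"))$mean, 0.5)
  expect_error(residual_correlation_summary(d, c("O", "O")), "diagonal")
  expect_error(residual_correlation_summary(d, c("O", "Z")), "two outcomes")
})
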