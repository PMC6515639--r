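delta_sq <- scale_constant(7.3)
delta <- sqrt(delta_sq)

test_that("schedule arithmetic gives the documented retained-draw counts", {
  expect_equal(mcmc_config()$n_retained, 10000L)
  expect_equal(mcmc_config(n_iter = 1100, n_burn = 100, thin = 10)$n_retained,
               100L)
  expect_equal(mcmc_config(reduced = TRUE)$n_retained, 1800L)
  expect_error(mcmc_config(n_iter = 100, n_burn = 100), "n_burn")
})

test_that("burn-and-thin keeps the right draws", {
  cfg <- mcmc_config(n_iter = 1100, n_burn = 100, thin = 10)
  raw <- matrix(seq_len(1100), ncol = 1)
  kept <- burn_and_thin(raw, cfg)
  expect_equal(nrow(kept), 100)
  expect_equal(kept[1, 1], 101)  # first post-burn-in draw
  expect_equal(kept[2, 1], 111)
  # identity schedule
  cfg2 <- mcmc_config(n_iter = 50, n_burn = 0, thin = 1)
  expect_equal(burn_and_thin(matrix(1:50), cfg2), matrix(1:50))
  # degenerate schedules
  expect_error(burn_and_thin(matrix(1:10), cfg), "n_iter")
  cfg$n_burn <- cfg$n_iter <- 100L
  expect_error(burn_and_thin(matrix(1:100), cfg), "no post-burn-in")
  # non-divisible schedule logs the floor
  expect_message(cfg3 <- mcmc_config(n_iter = 105, n_burn = 0, thin = 10),
                 "not divisible")
  expect_equal(cfg3$n_retained, 11L)  # draws 1, 11, ..., 101
})

test_that("chain state initialization satisfies its invariants", {
  set.seed(1)
  Y <- matrix(rbinom(40, 1, 0.5), 10, 4)
  Y[, 1] <- c(0, 1, rep(0:1, 4))  # ensure both classes
  X <- cbind(1, rnorm(10))
  st <- init_state(Y, X)
  expect_true(all(sign(st$Z) == ifelse(Y == 1, 1, -1)))
  expect_true(all(st$phi > 0))
  expect_equal(st$R, diag(4))
  expect_equal(st$beta, matrix(0, 4, 2))
  expect_error(init_state(Y[0, ], X[0, , drop = FALSE]), "no records")
  Yc <- Y; Yc[, 2] <- 1
  expect_warning(init_state(Yc, X), "constant")
})

test_that("mixing-variable conditional has the closed-form gamma moments", {
  # z = mu: quadratic form zero, so phi ~ Gamma((nu+4)/2, nu/2),
  # mean (nu+4)/nu = 11.3/7.3
  n <- 4000
  st <- list(Z = matrix(0, n, 4), Mu = matrix(0, n, 4), R = diag(4))
  set.seed(2)
  st2 <- sample_mixing(st)
  m <- mean(st2$phi)
  se <- sd(st2$phi) / sqrt(n)
  expect_lt(abs(m - 11.3 / 7.3), 3 * se)
  # enormous quadratic form drives the conditional toward zero
  stq <- list(Z = matrix(100, 2, 4), Mu = matrix(0, 2, 4), R = diag(4))
  set.seed(3)
  expect_lt(max(sample_mixing(stq)$phi), 0.05)
})

test_that("latent updates respect truncation and half-normal moments", {
  n <- 10000
  Y <- matrix(1L, n, 4)
  st <- list(Z = matrix(0.1, n, 4), Mu = matrix(0, n, 4), R = diag(4),
             phi = rep(1, n))
  set.seed(4)
  st2 <- sample_latents(st, Y)
  expect_true(all(st2$Z > 0))
  # R = I, phi = 1, mu = 0, y = 1: half-normal with scale delta
  m <- mean(st2$Z)
  tse <- delta * sqrt(1 - 2 / pi) / sqrt(length(st2$Z))
  expect_lt(abs(m - delta * sqrt(2 / pi)), 3 * tse)
  # y = 0 side stays nonpositive
  Y0 <- matrix(0L, 50, 4)
  st0 <- list(Z = matrix(-0.1, 50, 4), Mu = matrix(0.5, 50, 4), R = diag(4),
              phi = rep(1, 50))
  set.seed(5)
  expect_true(all(sample_latents(st0, Y0)$Z <= 0))
})

test_that("latent conditional mean moves with a correlated partner", {
  # strong positive correlation and partner fixed high: conditional mean
  # above the unconditional one
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.9
  n <- 4000
  Z <- matrix(0, n, 4); Z[, 2] <- 2
  Y <- matrix(1L, n, 4)
  st <- list(Z = Z, Mu = matrix(0, n, 4), R = R, phi = rep(1, n))
  set.seed(6)
  st_cor <- sample_latents(st, Y)
  st$R <- diag(4)
  set.seed(6)
  st_ind <- sample_latents(st, Y)
  expect_gt(mean(st_cor$Z[, 1]), mean(st_ind$Z[, 1]))
})

test_that("coefficient conditional collapses to weighted least squares", {
  # diffuse prior, R = I, phi = 1: posterior mean is the per-outcome
  # ordinary least-squares fit of Z on X
  set.seed(7)
  n <- 400
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  Z <- matrix(rnorm(n * 4, mean = 1), n, 4)
  spec <- model_spec(prior_var_intercept = 1e8, prior_var_slope = 1e8)
  st <- list(Z = Z, phi = rep(1, n), R = diag(4))
  draws <- replicate(300, {
    sample_beta(st, X, spec)$beta
  })
  post_mean <- apply(draws, c(1, 2), mean)
  ols <- t(solve(crossprod(X), crossprod(X, Z)))  # p x d
  expect_lt(max(abs(post_mean - ols)), 0.03)
  # with no information (prior variance tiny) the draw hugs the prior mean 0
  spec0 <- model_spec(prior_var_intercept = 1e-6, prior_var_slope = 1e-6)
  set.seed(8)
  b0 <- sample_beta(st, X, spec0)$beta
  expect_lt(max(abs(b0)), 0.05)
  # determinism
  set.seed(9); b1 <- sample_beta(st, X, spec)$beta
  set.seed(9); b2 <- sample_beta(st, X, spec)$beta
  expect_identical(b1, b2)
})

test_that("correlation Metropolis behaves at the degenerate step and null", {
  n <- 300
  set.seed(10)
  st <- list(Z = matrix(rnorm(n * 4, sd = delta), n, 4),
             Mu = matrix(0, n, 4), R = diag(4), phi = rep(1, n))
  st0 <- update_correlation(st, proposal_scale = 0)
  expect_true(st0$accepted)
  expect_equal(st0$R, diag(4))
  # independent data: retained correlation draws center on zero
  acc <- 0; rs <- numeric(300)
  cur <- st
  set.seed(11)
  for (i in seq_len(300)) {
    cur <- update_correlation(cur, proposal_scale = 0.15)
    rs[i] <- cur$R[1, 2]
    acc <- acc + cur$accepted
  }
  expect_lt(abs(mean(rs[101:300])), 3 * sd(rs[101:300]) / sqrt(20) + 0.1)
  expect_gt(acc, 0)
})

test_that("full chains are reproducible and respect the schedule", {
  gen <- generator_spec(n = 60, seed = 21)
  cohort <- generate_cohort(gen)
  cfg <- mcmc_config(n_iter = 600, n_burn = 100, thin = 5, seed = 77)
  d1 <- run_chain(cohort, config = cfg)
  d2 <- run_chain(cohort, config = cfg)
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$R, d2$R)
  expect_equal(nrow(d1$beta), 100)
  expect_equal(ncol(d1$beta), 28)
  expect_equal(ncol(d1$R), 6)
  expect_true(all(is.finite(d1$beta)))
  # every stored correlation draw is a valid correlation matrix
  for (i in c(1, 50, 100)) {
    expect_silent(check_correlation(mvtlogit:::free_to_corr(d1$R[i, ], 4)))
  }
})

test_that("retained draws persist as a labelled table with a metadata sidecar", {
  gen <- generator_spec(n = 40, seed = 51)
  cohort <- generate_cohort(gen)
  d <- run_chain(cohort, config = mcmc_config(n_iter = 400, n_burn = 100,
                                              thin = 10, seed = 2),
                 covariate_set = "crude")
  f <- tempfile(fileext = ".csv")
  write_draws(d, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 30)
  expect_true(all(c("beta_O_t1", "rho_O_I") %in% names(back)))
  expect_equal(back$rho_H_D, unname(d$R[, "rho_H_D"]))
  meta <- readLines(paste0(f, ".meta"))
  expect_true(any(grepl("seed: 2", meta)))
  expect_true(any(grepl("acceptance_rate", meta)))
})

test_that("adaptation lands the acceptance rate near its target", {
  gen <- generator_spec(n = 150, seed = 31)
  cohort <- generate_cohort(gen)
  d <- run_chain(cohort, config = mcmc_config(n_iter = 6000, n_burn = 1500,
                                              thin = 5, seed = 5))
  expect_gt(d$meta$acceptance_rate, 0.10)
  expect_lt(d$meta$acceptance_rate, 0.45)
})

test_that("a single-outcome fit approximates univariate logistic regression", {
  set.seed(12)
  n <- 1500
  x <- rnorm(n)
  eta <- -0.4 + 0.9 * x
  y <- rbinom(n, 1, plogis(eta))
  labs <- c(Y = "y")
  spec1 <- model_spec(outcome_labels = labs)
  d <- latent_t_mcmc(matrix(y, ncol = 1), cbind(`(Intercept)` = 1, x = x),
                     spec1, mcmc_config(n_iter = 4000, n_burn = 1000,
                                        thin = 3, seed = 13))
  post <- colMeans(d$beta)
  ref <- coef(glm(y ~ x, family = binomial()))
  expect_equal(unname(post[1]), unname(ref[1]), tolerance = 0.15)
  expect_equal(unname(post[2]), unname(ref[2]), tolerance = 0.15)
})
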