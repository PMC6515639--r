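#' MCMC configuration
#'
#' The default schedule is the full production schedule: 1,050,000 draws,
#' 50,000 burn-in, thinning factor 100, leaving 10,000 retained draws.
#' `reduced = TRUE` switches to a desk schedule (20,000 / 2,000 / 10) that
#' preserves 1,800 retained draws for quick exploratory fits.
#'
#' @param n_iter total number of MCMC iterations.
#' @param n_burn burn-in iterations discarded.
#' @param thin thinning factor applied after burn-in.
#' @param proposal_scale initial SD of the random-walk proposal on the free
#'   correlations.
#' @param seed integer RNG seed for the chain.
#' @param adapt adapt the proposal scale toward `target_accept` during
#'   burn-in (Robbins-Monro), then freeze.
#' @param target_accept Metropolis acceptance rate targeted by adaptation.
#' @param reduced use the reduced desk schedule.
#' @return An object of class `mvtlogit_mcmc_config` with the derived field
#'   `n_retained`.
#' @export
#' @examples
#' mcmc_config()$n_retained           # 10000
#' mcmc_config(reduced = TRUE)$n_retained
mcmc_config <- function(n_iter = 1050000L, n_burn = 50000L, thin = 100L,
                        proposal_scale = 0.1, seed = 1L, adapt = TRUE,
                        target_accept = 0.25, reduced = FALSE) {
  if (reduced) {
    n_iter <- 20000L; n_burn <- 2000L; thin <- 10L
  }
  stopifnot(n_burn >= 0, n_burn < n_iter, thin >= 1, proposal_scale >= 0,
            target_accept > 0, target_accept < 1)
  n_ret <- (n_iter - n_burn - 1) %/% thin + 1
  if ((n_iter - n_burn) %% thin != 0) {
    message(sprintf("schedule not divisible: retaining %d draws", n_ret))
  }
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), proposal_scale = proposal_scale,
                 seed = as.integer(seed), adapt = adapt,
                 target_accept = target_accept,
                 n_retained = as.integer(n_ret)),
            class = "mvtlogit_mcmc_config")
}

# prior precisions for the stacked coefficient vector vec(B), B = p x d with
# the outcome index fastest; intercept column gets the large prior variance
prior_precisions <- function(spec, d) {
  v <- c(rep(1 / spec$prior_var_intercept, spec$p),
         rep(1 / spec$prior_var_slope, spec$p * (d - 1)))
  v
}

beta_colnames <- function(spec, terms) {
  codes <- names(spec$outcome_labels)
  as.vector(vapply(terms, function(tm) paste0("beta_", codes, "_", tm),
                   character(spec$p)))
}

rho_colnames <- function(spec) {
  codes <- names(spec$outcome_labels)
  pr <- corr_pairs(spec$p)
  paste0("rho_", codes[pr[, 1]], "_", codes[pr[, 2]])
}

#' Initialize the chain state
#'
#' Deterministic starting point: \eqn{\beta = 0}, \eqn{R = I}, \eqn{\phi = 1}
#' and latents at \eqn{\pm\delta/2} with sign matching the observed outcome.
#'
#' @param Y n x p 0/1 outcome matrix.
#' @param X n x d design matrix.
#' @param spec a [model_spec()].
#' @return List with components `Z`, `phi`, `beta` (p x d matrix), `R`,
#'   `Mu`, satisfying the sign-consistency invariant.
#' @export
init_state <- function(Y, X, spec = model_spec()) {
  Y <- as.matrix(Y)
  if (nrow(Y) == 0L) stop("no records", call. = FALSE)
  stopifnot(all(Y %in% c(0, 1)), nrow(Y) == nrow(X), ncol(Y) == spec$p)
  if (any(apply(Y, 2, function(col) length(unique(col)) == 1L))) {
    warning("an outcome column is constant: its intercept is weakly identified",
            call. = FALSE)
  }
  delta <- sqrt(scale_constant(spec$nu))
  list(Z = ifelse(Y == 1, delta / 2, -delta / 2),
       phi = rep(1, nrow(Y)),
       beta = matrix(0, spec$p, ncol(X)),
       R = diag(spec$p),
       Mu = matrix(0, nrow(Y), spec$p))
}

#' Sample the mixing variables
#'
#' Full conditional of the per-subject gamma mixing variable in the
#' scale-mixture representation \eqn{Z_i|\phi_i \sim N(\mu_i,
#' (\delta^2/\phi_i)R)}, \eqn{\phi_i \sim Gamma(\nu/2, \nu/2)}:
#' \eqn{\phi_i | \cdot \sim Gamma((\nu+p)/2, (\nu+q_i)/2)} with
#' \eqn{q_i = (z_i-\mu_i)'(\delta^2 R)^{-1}(z_i-\mu_i)}.
#'
#' @param state chain state as from [init_state()].
#' @param spec a [model_spec()].
#' @return Updated state with fresh `phi`.
#' @export
sample_mixing <- function(state, spec = model_spec()) {
  state$phi <- cpp_update_phi(state$Z, state$Mu, state$R,
                              scale_constant(spec$nu), spec$nu)
  state
}

#' Sample the latent outcome propensities
#'
#' Coordinate-wise truncated-normal Gibbs update of the latent matrix: each
#' \eqn{Z_i^j} is drawn from its univariate normal full conditional given
#' the other coordinates, truncated to \eqn{(0,\infty)} when \eqn{y_i^j = 1}
#' and \eqn{(-\infty, 0]} otherwise, so sign consistency holds by
#' construction.
#'
#' @inheritParams sample_mixing
#' @param Y the n x p 0/1 outcome matrix.
#' @return Updated state with fresh `Z`.
#' @export
sample_latents <- function(state, Y, spec = model_spec()) {
  Ym <- matrix(as.integer(as.matrix(Y)), nrow(state$Z), ncol(state$Z))
  state$Z <- cpp_update_Z(state$Z, Ym, state$Mu, state$R, state$phi,
                          scale_constant(spec$nu))
  state
}

#' Sample the regression coefficients
#'
#' Exact multivariate-normal full conditional of the stacked coefficient
#' vector for the heteroscedastic linear model \eqn{Z_i \sim N(Bx_i,
#' (\delta^2/\phi_i)R)} under the independent normal prior.  Stacking is
#' vec(B) with B the p x d coefficient matrix (outcome index fastest);
#' posterior precision is prior precision plus
#' \eqn{\sum_i \phi_i/\delta^2 (x_i x_i') \otimes R^{-1}}.
#'
#' @inheritParams sample_mixing
#' @param X the n x d design matrix.
#' @return Updated state with fresh `beta` and recomputed `Mu`.
#' @export
sample_beta <- function(state, X, spec = model_spec()) {
  b <- cpp_update_beta(state$Z, X, state$phi, state$R,
                       scale_constant(spec$nu),
                       prior_precisions(spec, ncol(X)))
  state$beta <- matrix(b, spec$p, ncol(X))
  state$Mu <- X %*% t(state$beta)
  state
}

#' Metropolis update of the latent correlation matrix
#'
#' Random-walk multivariate-normal proposal on the free off-diagonals with
#' covariance `proposal_scale^2 I`; proposals outside the correlation-matrix
#' space are rejected outright, otherwise acceptance uses the ratio of
#' \eqn{\prod_i N(z_i | \mu_i, (\delta^2/\phi_i)R)} at proposed and current
#' R (the flat prior over the correlation space cancels).
#'
#' @inheritParams sample_mixing
#' @param proposal_scale proposal SD.
#' @return Updated state; element `accepted` reports the outcome.
#' @export
update_correlation <- function(state, spec = model_spec(),
                               proposal_scale = 0.1) {
  r <- corr_to_free(state$R)
  if (proposal_scale == 0) {
    state$accepted <- TRUE  # degenerate step: chain never moves
    return(state)
  }
  up <- cpp_update_R(state$Z, state$Mu, state$phi, r,
                     scale_constant(spec$nu), proposal_scale)
  state$R <- free_to_corr(as.numeric(up$r), spec$p)
  state$accepted <- up$accepted
  state
}

#' Run the data-augmented MCMC sampler on outcome/design matrices
#'
#' Low-level engine behind [run_chain()].  Sweep order per iteration is
#' mixing variables, latents, coefficients, correlation; burn-in and
#' thinning are applied to all parameters.  Fully reproducible from
#' `config$seed`.
#'
#' @param Y n x p 0/1 outcome matrix.
#' @param X n x d design matrix with column names.
#' @param spec a [model_spec()] with `p = ncol(Y)`.
#' @param config an [mcmc_config()].
#' @return An object of class `mvtlogit_draws`: list with `beta` (retained
#'   draws x stacked coefficients, labelled `beta_<outcome>_<term>`), `R`
#'   (retained draws x free correlations, labelled `rho_<j>_<k>`), and
#'   `meta` (config echo, acceptance rate, final proposal scale, design
#'   info).
#' @export
latent_t_mcmc <- function(Y, X, spec = model_spec(), config = mcmc_config()) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  st <- init_state(Y, X, spec)  # validates; value unused beyond checks
  set.seed(config$seed)
  res <- cpp_run_chain(matrix(as.integer(Y), nrow(Y), ncol(Y)), X, spec$nu,
                       scale_constant(spec$nu),
                       prior_precisions(spec, ncol(X)),
                       config$n_iter, config$n_burn, config$thin,
                       config$proposal_scale, config$adapt,
                       config$target_accept)
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(ncol(X)))
  beta <- res$beta
  colnames(beta) <- beta_colnames(spec, terms)
  Rd <- res$r
  if (spec$p > 1) colnames(Rd) <- rho_colnames(spec)
  structure(list(beta = beta, R = Rd,
                 meta = list(config = config,
                             acceptance_rate = res$acceptance_rate,
                             proposal_scale_final = res$proposal_scale_final,
                             terms = terms, spec = spec, n = nrow(Y))),
            class = "mvtlogit_draws")
}

#' Fit the latent-t regression to a cohort
#'
#' Builds the outcome and design matrices for the requested model variant
#' and runs the sampler.
#'
#' @param cohort an `mvtlogit_cohort`.
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @inheritParams build_design
#' @return An `mvtlogit_draws` object (see [latent_t_mcmc()]); `meta` also
#'   records the covariate set and WBC form.
#' @export
run_chain <- function(cohort, spec = model_spec(), config = mcmc_config(),
                      covariate_set = "full", wbc_form = "identity") {
  Y <- as.matrix(as.data.frame(cohort)[, unname(spec$outcome_labels)])
  X <- build_design(cohort, covariate_set, wbc_form)
  draws <- latent_t_mcmc(Y, X, spec, config)
  draws$meta$covariate_set <- covariate_set
  draws$meta$wbc_form <- wbc_form
  draws
}

#' @export
print.mvtlogit_draws <- function(x, ...) {
  cat(sprintf("mvtlogit posterior draws: %d retained draws, %d coefficients",
              nrow(x$beta), ncol(x$beta)),
      sprintf("+ %d correlations\n", ncol(x$R)))
  cat(sprintf("  schedule %d / %d / thin %d; Metropolis acceptance %.3f\n",
              x$meta$config$n_iter, x$meta$config$n_burn, x$meta$config$thin,
              x$meta$acceptance_rate))
  invisible(x)
}

#' Apply burn-in and thinning to raw draws
#'
#' Drops the first `n_burn` rows, then keeps every `thin`-th row starting
#' with the first post-burn-in draw.  Non-divisible schedules keep
#' `floor((n_iter - n_burn)/thin)` draws (plus the leading one) with a
#' message.
#'
#' @param raw matrix (or vector) of draws, one row per iteration; the row
#'   count must equal `config$n_iter`.
#' @param config an [mcmc_config()].
#' @return Matrix of retained draws.
#' @export
burn_and_thin <- function(raw, config) {
  raw <- as.matrix(raw)
  if (nrow(raw) != config$n_iter) {
    stop("raw draw count must equal config$n_iter", call. = FALSE)
  }
  if (config$n_iter == config$n_burn) stop("no post-burn-in draws",
                                           call. = FALSE)
  idx <- seq.int(config$n_burn + 1L, config$n_iter, by = config$thin)
  raw[idx, , drop = FALSE]
}

#' Write retained draws to a delimited table with a metadata sidecar
#'
#' @param draws an `mvtlogit_draws`.
#' @param path CSV path for the draws (one row per retained draw); a
#'   `<path>.meta.json`-style sidecar would normally follow, here a plain
#'   `.meta` text file with the config echo, seed and acceptance rate.
#' @return `path` invisibly.
#' @export
write_draws <- function(draws, path) {
  utils::write.csv(cbind(as.data.frame(draws$beta), as.data.frame(draws$R)),
                   path, row.names = FALSE)
  meta <- draws$meta
  lines <- c(sprintf("n_iter: %d", meta$config$n_iter),
             sprintf("n_burn: %d", meta$config$n_burn),
             sprintf("thin: %d", meta$config$thin),
             sprintf("seed: %d", meta$config$seed),
             sprintf("acceptance_rate: %.6f", meta$acceptance_rate),
             sprintf("proposal_scale_final: %.6f", meta$proposal_scale_final))
  writeLines(lines, paste0(path, ".meta"))
  invisible(path)
}

#' Successive-conditional validity check of the sampler
#'
#' Alternates forward simulation of data from the model at the current
#' parameters with one application of every posterior update.  If the
#' kernels are correct the marginal law of \eqn{(\beta, R)} along this chain
#' is exactly the prior, so chain means of the monitored statistics are
#' compared to the analytic prior moments (\eqn{E\beta = 0},
#' \eqn{E\rho = 0}, \eqn{E\rho^2 = 1/3} for two outcomes) via z-scores using
#' autocorrelation-adjusted standard errors.
#'
#' @param n subjects in the toy data set.
#' @param p outcomes (2 keeps the flat correlation prior analytic).
#' @param n_sweeps chain length.
#' @param spec a [model_spec()] with `p` outcome labels.
#' @param proposal_scale Metropolis proposal SD.
#' @param seed RNG seed.
#' @return Data frame with one row per monitored statistic: chain mean,
#'   prior mean, effective sample size and z-score.
#' @export
successive_conditional_check <- function(n = 5, p = 2, n_sweeps = 1e5,
                                         spec = NULL, proposal_scale = 0.5,
                                         seed = 1L) {
  if (is.null(spec)) {
    labs <- paste0("y", seq_len(p))
    names(labs) <- LETTERS[seq_len(p)]
    spec <- model_spec(outcome_labels = labs)
  }
  stopifnot(spec$p == p, p == 2)
  set.seed(seed)
  X <- cbind(1, stats::rbinom(n, 1, 0.5))
  res <- cpp_sc_chain(X, spec$nu, scale_constant(spec$nu),
                      prior_precisions(spec, ncol(X)), as.integer(n_sweeps),
                      proposal_scale)
  d <- ncol(X)
  draws <- res$draws
  stats_list <- list()
  for (k in seq_len(p * d)) {
    stats_list[[paste0("beta", k)]] <- list(chain = draws[, k], prior_mean = 0)
  }
  rho <- draws[, p * d + 1]
  stats_list$rho <- list(chain = rho, prior_mean = 0)
  stats_list$rho_sq <- list(chain = rho^2, prior_mean = 1 / 3)
  out <- do.call(rbind, lapply(names(stats_list), function(nm) {
    ch <- stats_list[[nm]]$chain
    ess <- effective_sample_size(ch)
    se <- stats::sd(ch) / sqrt(ess)
    data.frame(statistic = nm, chain_mean = mean(ch),
               prior_mean = stats_list[[nm]]$prior_mean, ess = ess,
               z = (mean(ch) - stats_list[[nm]]$prior_mean) / se)
  }))
  rownames(out) <- NULL
  out
}
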