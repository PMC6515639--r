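#' Summarize per-draw values of an association measure
#'
#' Empirical posterior mean, median and equal-tailed 95% credible interval
#' (2.5th and 97.5th empirical percentiles, linear-interpolation quantile
#' convention, `stats::quantile` type 7).
#'
#' @param x numeric vector of per-draw values (length at least 2).
#' @param measure,label,contrast optional annotation columns.
#' @return One-row data frame: measure, label, contrast, mean, median,
#'   lower, upper.
#' @export
#' @examples
#' summarize_posterior(1:5)$median  # 3
summarize_posterior <- function(x, measure = NA_character_,
                                label = NA_character_,
                                contrast = NA_character_) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 draws", call. = FALSE)
  q <- stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  data.frame(measure = measure, label = label, contrast = contrast,
             mean = mean(x), median = stats::median(x),
             lower = q[1], upper = q[2])
}

contrast_label <- function(contrast) {
  paste(contrast[1], "vs", contrast[2])
}

# per-draw coefficient matrix B (p x d) from one row of the draws
draw_beta <- function(draws, i) {
  spec <- draws$meta$spec
  matrix(draws$beta[i, ], spec$p, length(draws$meta$terms))
}

#' Conditional odds ratios for a model term
#'
#' Per draw, \eqn{OR = \exp(increment \cdot \beta)}; the posterior median is
#' the headline estimate (OR posteriors are right-skewed), with the mean and
#' equal-tailed 95% CrI alongside.  The WBC count is conventionally reported
#' per 10-unit increment.
#'
#' @param draws an `mvtlogit_draws`.
#' @param term design term label (e.g. `"t1"`, `"wbc_dx"`), or a full
#'   coefficient column label such as `"beta_D_t1"`.
#' @param increment covariate increment the OR refers to (default 1).
#' @return Data frame with one row per matching coefficient.
#' @export
odds_ratios <- function(draws, term, increment = 1) {
  cols <- if (term %in% colnames(draws$beta)) term else
    colnames(draws$beta)[endsWith(colnames(draws$beta), paste0("_", term))]
  if (length(cols) == 0) stop("unknown term: ", term, call. = FALSE)
  out <- do.call(rbind, lapply(cols, function(cl) {
    or <- exp(increment * draws$beta[, cl])
    summarize_posterior(or, measure = "OR", label = cl,
                        contrast = sprintf("per %g unit(s)", increment))
  }))
  out
}

# linear predictors (n x p) for the whole cohort with the treatment dummies
# forced to one exposure level, all covariates at observed values
predictors_at <- function(B, cohort, level, draws) {
  X <- build_design(cohort,
                    covariate_set = draws$meta$covariate_set %||% "full",
                    wbc_form = draws$meta$wbc_form %||% "identity")
  lv <- exposure_levels()
  X[, "t1"] <- as.numeric(level == lv[2])
  X[, "t2"] <- as.numeric(level == lv[3])
  X %*% t(B)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population risk difference for one outcome
#'
#' g-computation contrast: per draw, each survivor's marginal outcome
#' probability is evaluated with the treatment dummies set to each arm of
#' the contrast (covariates at observed values), the within-survivor
#' differences are averaged over all n survivors, and the resulting per-draw
#' PRDs are summarized over draws.
#'
#' @param draws an `mvtlogit_draws`.
#' @param cohort the cohort the draws were fit to (or any cohort sharing the
#'   design layout).
#' @param outcome outcome code (e.g. `"D"`) or column name.
#' @param contrast character pair `(T_l, T_0)` of exposure levels.
#' @return One-row summary data frame; attribute `per_draw` holds the
#'   per-draw PRD vector.
#' @export
marginal_risk_difference <- function(draws, cohort, outcome,
                                     contrast = c("LD/CRT", "LD/NoCRT")) {
  spec <- draws$meta$spec
  j <- match_outcome(spec, outcome)
  check_contrast(contrast)
  m <- nrow(draws$beta)
  prd <- vapply(seq_len(m), function(i) {
    B <- draw_beta(draws, i)
    mu1 <- predictors_at(B, cohort, contrast[1], draws)[, j]
    mu0 <- predictors_at(B, cohort, contrast[2], draws)[, j]
    mean(marginal_outcome_probability(mu1, spec$nu) -
           marginal_outcome_probability(mu0, spec$nu))
  }, numeric(1))
  out <- summarize_posterior(prd, measure = "PRD",
                             label = names(spec$outcome_labels)[j],
                             contrast = contrast_label(contrast))
  attr(out, "per_draw") <- prd
  out
}

match_outcome <- function(spec, outcome) {
  j <- match(outcome, names(spec$outcome_labels))
  if (is.na(j)) j <- match(outcome, unname(spec$outcome_labels))
  if (is.na(j)) stop("unknown outcome: ", outcome, call. = FALSE)
  j
}

check_contrast <- function(contrast) {
  if (!all(contrast %in% exposure_levels())) {
    stop("unknown exposure level in contrast: ",
         paste(setdiff(contrast, exposure_levels()), collapse = ", "),
         call. = FALSE)
  }
}

# averaged configuration probability differences for all requested patterns:
# returns draws x patterns matrix, each entry the cohort-averaged difference
# P^{T_l}(config) - P^{T_0}(config)
configuration_difference_table <- function(draws, cohort, contrast,
                                           patterns = NULL, draw_idx = NULL,
                                           abseps = 5e-4, qmc_seed = 1L) {
  spec <- draws$meta$spec
  check_contrast(contrast)
  if (is.null(patterns)) patterns <- outcome_configurations(spec$p)
  if (is.null(draw_idx)) draw_idx <- seq_len(nrow(draws$beta))
  out <- matrix(NA_real_, length(draw_idx), nrow(patterns),
                dimnames = list(NULL, rownames(patterns)))
  for (ii in seq_along(draw_idx)) {
    i <- draw_idx[ii]
    B <- draw_beta(draws, i)
    R <- free_to_corr(draws$R[i, ], spec$p)
    mu1 <- predictors_at(B, cohort, contrast[1], draws)
    mu0 <- predictors_at(B, cohort, contrast[2], draws)
    p1 <- joint_configuration_probabilities(mu1, R, spec$nu, patterns,
                                            abseps = abseps,
                                            qmc_seed = qmc_seed)
    p0 <- joint_configuration_probabilities(mu0, R, spec$nu, patterns,
                                            abseps = abseps,
                                            qmc_seed = qmc_seed)
    out[ii, ] <- colMeans(p1 - p0)
  }
  out
}

#' Risk difference for one joint outcome configuration
#'
#' Per draw and survivor, the orthant probability of the given configuration
#' is evaluated under both arms of the contrast and the difference is
#' averaged over survivors (g-computation); the per-draw averages are then
#' summarized.
#'
#' @inheritParams marginal_risk_difference
#' @param pattern 0/1 vector of length p (or its concatenated string form,
#'   e.g. `"1001"`).
#' @param draw_idx optional subset of draw indices (orthant integration per
#'   draw and survivor is the expensive step; a subsample trades CrI
#'   precision for time).
#' @param abseps orthant integration accuracy.
#' @return One-row summary data frame with attribute `per_draw`.
#' @export
configuration_probability_difference <- function(draws, cohort, pattern,
                                                 contrast = c("LD/CRT",
                                                              "LD/NoCRT"),
                                                 draw_idx = NULL,
                                                 abseps = 5e-4) {
  spec <- draws$meta$spec
  if (is.character(pattern) && length(pattern) == 1) {
    pattern <- as.integer(strsplit(pattern, "")[[1]])
  }
  stopifnot(length(pattern) == spec$p, all(pattern %in% c(0, 1)))
  pm <- matrix(as.integer(pattern), 1, spec$p,
               dimnames = list(paste(pattern, collapse = ""), NULL))
  tab <- configuration_difference_table(draws, cohort, contrast, pm, draw_idx,
                                        abseps)
  out <- summarize_posterior(tab[, 1], measure = "config-PRD",
                             label = rownames(pm),
                             contrast = contrast_label(contrast))
  attr(out, "per_draw") <- tab[, 1]
  out
}

#' Cumulative risk difference for co-occurring outcomes
#'
#' Population risk difference for carrying at least `k` of the p outcomes,
#' obtained per draw by summing the averaged configuration differences over
#' all sign patterns with `k` or more positive outcomes (5 patterns for
#' k = 3, 1 for k = 4 when p = 4).
#'
#' @inheritParams configuration_probability_difference
#' @param k threshold count, between 1 and p.
#' @return One-row summary data frame with attribute `per_draw`.
#' @export
cumulative_risk_difference <- function(draws, cohort, k,
                                       contrast = c("LD/CRT", "LD/NoCRT"),
                                       draw_idx = NULL, abseps = 5e-4) {
  spec <- draws$meta$spec
  if (!(k %in% seq_len(spec$p))) {
    stop("`k` must be between 1 and ", spec$p, call. = FALSE)
  }
  cfg <- outcome_configurations(spec$p)
  keep <- attr(cfg, "n_positive") >= k
  tab <- configuration_difference_table(draws, cohort, contrast,
                                        cfg[keep, , drop = FALSE], draw_idx,
                                        abseps)
  per_draw <- rowSums(tab)
  out <- summarize_posterior(per_draw, measure = "cumulative-PRD",
                             label = sprintf("N>=%d", k),
                             contrast = contrast_label(contrast))
  attr(out, "per_draw") <- per_draw
  out
}

#' Posterior summary of a residual correlation
#'
#' Mean, median and equal-tailed 95% CrI of the retained draws of one free
#' element of the latent correlation matrix (a correlation not induced by
#' treatment or covariates).
#'
#' @param draws an `mvtlogit_draws`.
#' @param pair character pair of outcome codes (e.g. `c("O", "I")`) or
#'   integer pair of outcome indices.
#' @return One-row summary data frame.
#' @export
residual_correlation_summary <- function(draws, pair) {
  spec <- draws$meta$spec
  idx <- if (is.character(pair)) {
    match(pair, names(spec$outcome_labels))
  } else as.integer(pair)
  if (any(is.na(idx)) || length(idx) != 2) {
    stop("`pair` must name two outcomes", call. = FALSE)
  }
  if (idx[1] == idx[2]) {
    stop("diagonal elements are fixed at 1", call. = FALSE)
  }
  idx <- sort(idx)
  pr <- corr_pairs(spec$p)
  k <- which(pr[, 1] == idx[1] & pr[, 2] == idx[2])
  summarize_posterior(draws$R[, k], measure = "rho",
                      label = colnames(draws$R)[k])
}
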