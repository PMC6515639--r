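# Deterministic fixtures built in code.

# 241-survivor cohort reproducing the marginal counts of the motivating
# survivor cohort: group sizes 99/82/60, outcome counts per group
# (obesity 27/30/19, insulin resistance 13/15/13, hypertension 8/12/9,
# dyslipidemia 30/37/30), males 41/45/32.  Only the margins matter: within
# each group the first k records carry the condition.
make_margin_cohort <- function() {
  sizes <- c(99L, 82L, 60L)
  counts <- list(obesity = c(27L, 30L, 19L),
                 insulin_resistance = c(13L, 15L, 13L),
                 hypertension = c(8L, 12L, 9L),
                 dyslipidemia = c(30L, 37L, 30L),
                 sex = c(41L, 45L, 32L))
  expo <- rep(exposure_levels(), sizes)
  df <- data.frame(id = sprintf("M%03d", seq_len(sum(sizes))))
  for (v in names(counts)) {
    df[[v]] <- unlist(lapply(1:3, function(g)
      rep(c(1L, 0L), c(counts[[v]][g], sizes[g] - counts[[v]][g]))))
  }
  df$exposure <- factor(expo, levels = exposure_levels())
  df$age_dx <- 6.59
  df$wbc_dx <- 9.6
  df$time_dx <- 15.4
  df$cs_dose <- rep(c(7603, 9747, 19087), sizes)
  df$crt <- rep(c(0L, 1L, 1L), sizes)
  structure(df,
            covariate_names = c("sex", "age_dx", "wbc_dx", "time_dx"),
            class = c("mvtlogit_cohort", "data.frame"))
}

# random valid correlation matrix
random_correlation <- function(p = 4) {
  A <- matrix(rnorm(p * p), p)
  stats::cov2cor(crossprod(A) + diag(p) * 0.5)
}

# hand-assembled posterior-draws object for post-hoc unit tests
make_draws <- function(beta_rows, r_rows, terms,
                       spec = model_spec(), covariate_set = "full",
                       wbc_form = "identity") {
  beta <- matrix(beta_rows, ncol = spec$p * length(terms), byrow = FALSE)
  colnames(beta) <- mvtlogit:::beta_colnames(spec, terms)
  Rd <- matrix(r_rows, ncol = spec$p * (spec$p - 1) / 2)
  colnames(Rd) <- mvtlogit:::rho_colnames(spec)
  structure(list(beta = beta, R = Rd,
                 meta = list(config = mcmc_config(reduced = TRUE),
                             acceptance_rate = 0.25,
                             terms = terms, spec = spec, n = NA,
                             covariate_set = covariate_set,
                             wbc_form = wbc_form)),
            class = "mvtlogit_draws")
}

# tiny cohort for design/posthoc toys
toy_cohort <- function(n = 6) {
  structure(
    data.frame(id = sprintf("T%02d", 1:n),
               obesity = rep_len(c(1L, 0L), n),
               insulin_resistance = rep_len(c(0L, 1L), n),
               hypertension = rep_len(0:1, n),
               dyslipidemia = rep_len(c(1L, 1L, 0L), n),
               sex = rep_len(0:1, n),
               age_dx = seq(2, 12, length.out = n),
               wbc_dx = seq(1, 50, length.out = n),
               time_dx = seq(6, 20, length.out = n),
               exposure = factor(rep_len(exposure_levels(), n),
                                 levels = exposure_levels())),
    covariate_names = c("sex", "age_dx", "wbc_dx", "time_dx"),
    class = c("mvtlogit_cohort", "data.frame"))
}
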