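#' Geweke convergence diagnostic
#'
#' z-score comparing the mean of the first `frac_a` and last `frac_b`
#' portions of a chain, with spectral-density-at-zero variance estimates
#' (delegated to `coda::geweke.diag`, the reference implementation of the
#' test with its classical 0.1/0.5 window fractions).
#'
#' @param chain numeric vector of draws (length at least 100).
#' @param frac_a fraction of the chain in the early window.
#' @param frac_b fraction in the late window.
#' @return The z-score, a single number.
#' @export
geweke_diagnostic <- function(chain, frac_a = 0.1, frac_b = 0.5) {
  chain <- as.numeric(chain)
  if (length(chain) < 100) stop("chain too short (< 100)", call. = FALSE)
  if (stats::var(chain) == 0) {
    stop("zero-variance chain: Geweke diagnostic undefined", call. = FALSE)
  }
  z <- coda::geweke.diag(coda::mcmc(chain), frac1 = frac_a, frac2 = frac_b)$z
  unname(z)
}

#' Effective sample size
#'
#' \eqn{n / (1 + 2\sum_k \rho_k)} with the autocorrelation sum truncated by
#' the initial-monotone-sequence rule (sums of adjacent autocorrelation
#' pairs are kept while positive, then forced nonincreasing) and the result
#' capped at `n` so antithetic chains do not report more information than
#' `n` independent draws.
#'
#' @param chain numeric vector of draws (length at least 100).
#' @return Effective sample size in (0, n].
#' @export
effective_sample_size <- function(chain) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100) stop("chain too short (< 100)", call. = FALSE)
  if (stats::var(chain) == 0) {
    stop("zero-variance chain: ESS undefined", call. = FALSE)
  }
  rho <- as.numeric(stats::acf(chain, lag.max = min(n - 1, 10000),
                               plot = FALSE, demean = TRUE)$acf)
  # Gamma_m = rho_{2m} + rho_{2m+1}; keep while positive, enforce monotone
  m_max <- (length(rho) - 2) %/% 2
  gam <- numeric(0)
  running_min <- Inf
  for (m in 0:m_max) {
    g <- rho[2 * m + 1] + rho[2 * m + 2]
    if (g <= 0) break
    running_min <- min(running_min, g)
    gam <- c(gam, running_min)
  }
  tau <- max(2 * sum(gam) - 1, .Machine$double.eps)
  min(n / tau, n)
}

#' Sequential boxplot summaries of a chain
#'
#' Partitions the chain into `n_segments` equal contiguous segments (any
#' remainder is dropped from the end with a message) and returns the
#' five-number summary of each, the numerical content of the sequential
#' boxplots used for visual convergence assessment.
#'
#' @param chain numeric vector of draws.
#' @param n_segments number of segments (default 10).
#' @return Data frame with one row per segment: min, q1, median, q3, max.
#' @export
sequential_boxplot_summary <- function(chain, n_segments = 10) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n_segments > n) stop("more segments than draws", call. = FALSE)
  seg_len <- n %/% n_segments
  dropped <- n - seg_len * n_segments
  if (dropped > 0) {
    message(sprintf("dropped %d trailing draw(s) to equalize segments",
                    dropped))
  }
  out <- do.call(rbind, lapply(seq_len(n_segments), function(s) {
    x <- chain[((s - 1) * seg_len + 1):(s * seg_len)]
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(segment = s, min = q[1], q1 = q[2], median = q[3],
               q3 = q[4], max = q[5])
  }))
  out
}

#' Convergence report for a set of posterior draws
#'
#' Geweke z-scores, effective sample sizes and sequential five-number
#' summaries for every coefficient and correlation chain, plus the recorded
#' Metropolis acceptance rate.
#'
#' @param draws an `mvtlogit_draws`.
#' @param n_segments segments for the sequential summaries.
#' @return List of class `mvtlogit_diagnostics` with `geweke_z`, `ess`
#'   (named vectors), `segment_summaries` (named list of data frames) and
#'   `acceptance_rate`.
#' @export
diagnose_chains <- function(draws, n_segments = 10) {
  ch <- cbind(draws$beta, draws$R)
  gz <- vapply(colnames(ch), function(j) geweke_diagnostic(ch[, j]),
               numeric(1))
  ess <- vapply(colnames(ch), function(j) effective_sample_size(ch[, j]),
                numeric(1))
  segs <- lapply(stats::setNames(colnames(ch), colnames(ch)), function(j)
    suppressMessages(sequential_boxplot_summary(ch[, j], n_segments)))
  structure(list(geweke_z = gz, ess = ess, segment_summaries = segs,
                 acceptance_rate = draws$meta$acceptance_rate),
            class = "mvtlogit_diagnostics")
}

#' @export
print.mvtlogit_diagnostics <- function(x, ...) {
  cat(sprintf("chains: %d | max |Geweke z| = %.2f | ESS range [%.0f, %.0f]\n",
              length(x$ess), max(abs(x$geweke_z)), min(x$ess), max(x$ess)))
  cat(sprintf("Metropolis acceptance rate: %.3f\n", x$acceptance_rate))
  invisible(x)
}
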