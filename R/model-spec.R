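#' Latent scale constant calibrating the t margin to the logistic
#'
#' Computes \eqn{\delta^2 = \pi^2(\nu - 2) / (3\nu)}.  With \eqn{\nu = 7.3}
#' this choice makes the univariate Student-t margin of the latent vector
#' (scale \eqn{\delta}) nearly indistinguishable from the standard logistic
#' distribution, which is what gives regression coefficients their log
#' odds ratio reading.
#'
#' @param nu degrees of freedom, must exceed 2.
#' @return The positive scalar \eqn{\delta^2}.
#' @export
#' @examples
#' scale_constant(7.3)
scale_constant <- function(nu) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 2) {
    stop("`nu` must be a single finite number greater than 2", call. = FALSE)
  }
  pi^2 * (nu - 2) / (3 * nu)
}

default_outcomes <- function() {
  c(O = "obesity", I = "insulin_resistance", H = "hypertension",
    D = "dyslipidemia")
}

#' Exposure category labels
#'
#' Three-level combined corticosteroid-dose / cranial-radiotherapy exposure:
#' low dose without CRT (baseline), low dose with CRT, high dose with CRT.
#' The high-dose/no-CRT combination does not occur in the study design.
#'
#' @return Character vector of the three category labels, baseline first.
#' @export
exposure_levels <- function() c("LD/NoCRT", "LD/CRT", "HD/CRT")

#' Model specification for the latent-t regression
#'
#' Bundles the fixed distributional constants and prior hyperparameters.
#' \eqn{\delta^2} is always recomputed from `nu` via [scale_constant()],
#' never stored, so the two cannot drift apart.
#'
#' @param nu degrees of freedom of the latent multivariate t (default 7.3,
#'   the logistic-calibrated value).
#' @param outcome_labels named character vector of outcome column names; the
#'   names are single-letter codes used in coefficient labels.
#' @param prior_var_intercept prior variance of each intercept (default 1000,
#'   weakly informative on the baseline log odds).
#' @param prior_var_slope prior variance of each non-intercept coefficient
#'   (default 4: prior SD 2 on the log odds ratio scale).
#' @return An object of class `mvtlogit_spec`.
#' @export
model_spec <- function(nu = 7.3,
                       outcome_labels = default_outcomes(),
                       prior_var_intercept = 1000,
                       prior_var_slope = 4) {
  scale_constant(nu)  # validates nu
  stopifnot(prior_var_intercept > 0, prior_var_slope > 0,
            length(outcome_labels) >= 1)
  if (is.null(names(outcome_labels))) {
    names(outcome_labels) <- toupper(substr(outcome_labels, 1, 1))
  }
  structure(
    list(nu = nu, p = length(outcome_labels), outcome_labels = outcome_labels,
         prior_var_intercept = prior_var_intercept,
         prior_var_slope = prior_var_slope),
    class = "mvtlogit_spec")
}

#' @export
print.mvtlogit_spec <- function(x, ...) {
  cat("Multivariate latent-t model specification\n")
  cat("  outcomes:", paste(x$outcome_labels, collapse = ", "), "\n")
  cat(sprintf("  nu = %.3g, delta^2 = %.4f\n", x$nu, scale_constant(x$nu)))
  cat(sprintf("  prior variances: intercept %g, slopes %g\n",
              x$prior_var_intercept, x$prior_var_slope))
  invisible(x)
}

#' Validate a correlation matrix
#'
#' Checks symmetry, unit diagonal, off-diagonals strictly inside (-1, 1) and
#' strict positive definiteness.
#'
#' @param R square numeric matrix.
#' @return `R` invisibly; errors otherwise.
#' @export
check_correlation <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("`R` must be a square matrix", call. = FALSE)
  }
  if (max(abs(R - t(R))) > 1e-10) stop("`R` must be symmetric", call. = FALSE)
  if (max(abs(diag(R) - 1)) > 1e-10) {
    stop("`R` must have a unit diagonal", call. = FALSE)
  }
  off <- R[upper.tri(R)]
  if (any(abs(off) >= 1)) {
    stop("off-diagonal correlations must lie strictly inside (-1, 1)",
         call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("`R` must be positive definite", call. = FALSE)
  invisible(R)
}

# row-major upper-triangle ordering of the free correlations, matching the
# C++ sampler: (1,2) (1,3) (1,4) (2,3) (2,4) (3,4) for p = 4
corr_pairs <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

corr_to_free <- function(R) {
  pr <- corr_pairs(nrow(R))
  R[pr]
}

free_to_corr <- function(r, p) {
  R <- diag(p)
  pr <- corr_pairs(p)
  R[pr] <- r
  R[pr[, c(2, 1), drop = FALSE]] <- r
  R
}

#' Enumerate the joint outcome configurations
#'
#' All \eqn{2^p} sign patterns of the outcome vector, enumerated
#' lexicographically with the first outcome as the most significant bit, so
#' for four outcomes the order is 0000, 0001, ..., 1111 over (O, I, H, D).
#'
#' @param p number of outcomes (default 4).
#' @return Integer matrix with \eqn{2^p} rows and `p` columns of 0/1 entries;
#'   rownames are the concatenated patterns and the `n_positive` attribute
#'   holds each row's count of affected outcomes.
#' @export
#' @examples
#' outcome_configurations(2)
outcome_configurations <- function(p = 4) {
  stopifnot(p >= 1, p <= 8)
  m <- as.matrix(expand.grid(rev(replicate(p, 0:1, simplify = FALSE)),
                             KEEP.OUT.ATTRS = FALSE))[, p:1, drop = FALSE]
  dimnames(m) <- list(apply(m, 1, paste, collapse = ""), NULL)
  storage.mode(m) <- "integer"
  attr(m, "n_positive") <- as.integer(rowSums(m))
  m
}
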