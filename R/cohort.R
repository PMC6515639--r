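#' Categorize the combined corticosteroid/CRT exposure
#'
#' Splits the cumulative prednisone-equivalent corticosteroid dose at a
#' third-quartile threshold (13,414 mg/m2 in the motivating cohort) and
#' combines it with cranial-radiotherapy status into three categories:
#' `LD/NoCRT` (baseline), `LD/CRT`, `HD/CRT`.  Doses exactly at the
#' threshold count as low dose.  The high-dose/no-CRT combination does not
#' occur in the study design and is rejected.
#'
#' @param cs_dose cumulative corticosteroid dose in mg/m2 (vectorized).
#' @param crt 0/1 cranial radiotherapy indicator.
#' @param threshold dose split point in mg/m2.
#' @return Factor with levels [exposure_levels()].
#' @export
#' @examples
#' categorize_exposure(c(7603, 19087), c(0, 1))
categorize_exposure <- function(cs_dose, crt, threshold = 13414) {
  stopifnot(length(threshold) == 1L, threshold > 0,
            length(cs_dose) == length(crt))
  if (any(cs_dose < 0, na.rm = TRUE)) {
    stop("`cs_dose` must be nonnegative", call. = FALSE)
  }
  if (!all(crt %in% c(0, 1, NA))) {
    stop("`crt` must be 0/1", call. = FALSE)
  }
  bad <- which(cs_dose > threshold & crt == 0)
  if (length(bad)) {
    stop(sprintf(paste0("high corticosteroid dose without CRT (rows %s): ",
                        "this combination is absent from the study design"),
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  lv <- exposure_levels()
  out <- ifelse(crt == 0, lv[1], ifelse(cs_dose <= threshold, lv[2], lv[3]))
  factor(out, levels = lv)
}

#' Load a survivor cohort from a delimited file
#'
#' Reads a CSV (header row, UTF-8) with one row per survivor, maps columns to
#' the canonical names, validates the binary outcomes, and derives the
#' exposure category from `cs_dose`/`crt` when an explicit `exposure` column
#' is absent.  Rows missing any exposure ingredient are dropped with a
#' message; other missing modelled fields also trigger complete-case
#' exclusion (no imputation).
#'
#' @param path file path.
#' @param schema named character vector mapping canonical names (outcomes,
#'   `sex`, `age_dx`, `wbc_dx`, `time_dx`, and either `exposure` or
#'   `cs_dose` + `crt`; optional `id`) to the file's column names.  Defaults
#'   to the identity mapping for the canonical names.
#' @param threshold corticosteroid dose split (mg/m2) used when deriving the
#'   exposure from `cs_dose`/`crt`.
#' @return A `data.frame` of class `mvtlogit_cohort` with canonical columns;
#'   attribute `covariate_names` fixes the adjustment-covariate order and
#'   attribute `n_dropped` records exclusions.
#' @export
load_cohort <- function(path, schema = NULL, threshold = 13414) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    stop("cohort file contains no records", call. = FALSE)
  }
  canon <- c(unname(default_outcomes()), "sex", "age_dx", "wbc_dx", "time_dx",
             "exposure", "cs_dose", "crt", "id")
  map <- stats::setNames(canon, canon)
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    map[names(schema)] <- schema
  }
  need <- c(unname(default_outcomes()), "sex", "age_dx", "wbc_dx", "time_dx")
  have_exposure <- map[["exposure"]] %in% names(raw)
  have_raw <- all(map[c("cs_dose", "crt")] %in% names(raw))
  if (!have_exposure && !have_raw) {
    stop("schema error: need an `exposure` column or both `cs_dose` and `crt`",
         call. = FALSE)
  }
  missing_cols <- need[!map[need] %in% names(raw)]
  if (length(missing_cols)) {
    stop("schema error: mapped column(s) not in file: ",
         paste(map[missing_cols], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(row = seq_len(nrow(raw)))
  for (nm in canon) {
    df[[nm]] <- if (map[[nm]] %in% names(raw)) raw[[map[[nm]]]] else NA
  }
  if (all(is.na(df$id))) df$id <- sprintf("S%04d", df$row)

  # complete-case handling: exposure ingredients first (logged), then the rest
  expo_ok <- if (have_exposure) !is.na(df$exposure) else
    !(is.na(df$cs_dose) | is.na(df$crt))
  n_expo_dropped <- sum(!expo_ok)
  if (n_expo_dropped > 0) {
    message(sprintf("dropped %d record(s) with missing exposure information",
                    n_expo_dropped))
  }
  df <- df[expo_ok, , drop = FALSE]
  cc <- stats::complete.cases(df[, need])
  if (any(!cc)) {
    message(sprintf("dropped %d record(s) with missing covariates or outcomes",
                    sum(!cc)))
  }
  df <- df[cc, , drop = FALSE]
  if (nrow(df) == 0L) stop("no complete records remain", call. = FALSE)

  for (oc in unname(default_outcomes())) {
    v <- df[[oc]]
    if (!all(v %in% c(0, 1))) {
      bad <- df$row[which(!v %in% c(0, 1))[1]]
      stop(sprintf("outcome `%s` is not 0/1 at file row %d", oc, bad),
           call. = FALSE)
    }
    df[[oc]] <- as.integer(v)
  }
  if (have_exposure) {
    if (!all(df$exposure %in% exposure_levels())) {
      stop("`exposure` values must be one of: ",
           paste(exposure_levels(), collapse = ", "), call. = FALSE)
    }
    df$exposure <- factor(df$exposure, levels = exposure_levels())
  } else {
    df$exposure <- categorize_exposure(df$cs_dose, df$crt, threshold)
  }
  stopifnot(all(df$age_dx >= 0), all(df$wbc_dx > 0), all(df$time_dx >= 0))
  df$row <- NULL
  rownames(df) <- NULL
  structure(df,
            covariate_names = c("sex", "age_dx", "wbc_dx", "time_dx"),
            n_dropped = n_expo_dropped + sum(!cc),
            class = c("mvtlogit_cohort", "data.frame"))
}

#' Write a cohort back to CSV
#'
#' Inverse of [load_cohort()] for clean inputs: modelled fields round-trip
#' bit-identically.
#'
#' @param cohort an `mvtlogit_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (nm in names(df)) {  # full precision so numeric fields survive a round trip
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the regression design matrix
#'
#' One row per survivor: intercept, two treatment dummies (`t1` for LD/CRT,
#' `t2` for HD/CRT, baseline LD/NoCRT), then the adjustment covariates in
#' fixed order.  Covariates enter on their natural scale; the white-blood-cell
#' count can be transformed.
#'
#' @param cohort an `mvtlogit_cohort` (or any data frame with the canonical
#'   columns).
#' @param covariate_set `"full"` (sex, age, WBC, time since diagnosis),
#'   `"no_wbc"`, or `"crude"` (intercept and treatment dummies only).
#' @param wbc_form transform applied to the WBC count: `"identity"`, `"log"`
#'   or `"sqrt"`.
#' @return Numeric matrix `n x d` with column names; attributes record the
#'   choices made.
#' @export
build_design <- function(cohort, covariate_set = c("full", "no_wbc", "crude"),
                         wbc_form = c("identity", "log", "sqrt")) {
  covariate_set <- match.arg(covariate_set)
  if (length(wbc_form) == 1 && !wbc_form %in% c("identity", "log", "sqrt")) {
    stop("unknown `wbc_form`: ", wbc_form, call. = FALSE)
  }
  wbc_form <- match.arg(wbc_form)
  expo <- factor(cohort$exposure, levels = exposure_levels())
  X <- cbind(`(Intercept)` = 1,
             t1 = as.numeric(expo == exposure_levels()[2]),
             t2 = as.numeric(expo == exposure_levels()[3]))
  if (covariate_set != "crude") {
    wbc <- switch(wbc_form, identity = cohort$wbc_dx, log = log(cohort$wbc_dx),
                  sqrt = sqrt(cohort$wbc_dx))
    X <- cbind(X, sex = cohort$sex, age_dx = cohort$age_dx)
    if (covariate_set == "full") X <- cbind(X, wbc_dx = wbc)
    X <- cbind(X, time_dx = cohort$time_dx)
  }
  structure(X, covariate_set = covariate_set, wbc_form = wbc_form)
}

#' Descriptive cohort summary
#'
#' Frequencies and percentages for the binary variables and mean/SD for the
#' continuous ones, overall and by exposure group.  Percentages are
#' \eqn{100 \cdot count / group size} rounded to one decimal; SDs are sample
#' SDs and reported as `NA` for groups of size one.
#'
#' @param cohort an `mvtlogit_cohort`.
#' @return List with data frames `binary` (variable, group, count, denom,
#'   pct) and `continuous` (variable, group, mean, sd), plus `group_sizes`.
#' @export
descriptive_summary <- function(cohort) {
  stopifnot(nrow(cohort) >= 1)
  groups <- c("overall", exposure_levels())
  pick <- function(g) if (g == "overall") rep(TRUE, nrow(cohort)) else
    cohort$exposure == g
  bin_vars <- c(unname(default_outcomes()), "sex")
  cont_vars <- intersect(c("cs_dose", "age_dx", "time_dx", "wbc_dx"),
                         names(cohort))
  cont_vars <- cont_vars[vapply(cont_vars,
                                function(v) !all(is.na(cohort[[v]])),
                                logical(1))]
  bin <- do.call(rbind, lapply(bin_vars, function(v) {
    do.call(rbind, lapply(groups, function(g) {
      sel <- pick(g)
      n <- sum(sel)
      cnt <- sum(cohort[[v]][sel] == 1)
      data.frame(variable = v, group = g, count = cnt, denom = n,
                 pct = round(100 * cnt / n, 1))
    }))
  }))
  cont <- do.call(rbind, lapply(cont_vars, function(v) {
    do.call(rbind, lapply(groups, function(g) {
      sel <- pick(g)
      x <- cohort[[v]][sel]
      data.frame(variable = v, group = g, mean = mean(x),
                 sd = if (sum(sel) > 1) stats::sd(x) else NA_real_)
    }))
  }))
  list(binary = bin, continuous = cont,
       group_sizes = c(overall = nrow(cohort),
                       table(cohort$exposure)))
}

#' Select the functional form of the WBC covariate by AIC
#'
#' Fits one univariate maximum-likelihood logistic regression of the chosen
#' outcome on the fully adjusted design per candidate WBC transform and
#' returns the transform with the smallest AIC (\eqn{2k - 2\ell}).  Ties are
#' broken by the fixed candidate order.  Candidates whose fit shows perfect
#' separation are excluded with a warning.
#'
#' @param cohort an `mvtlogit_cohort`.
#' @param outcome outcome column name (default the insulin-resistance
#'   outcome, the one most plausibly driven by disease burden).
#' @param candidate_forms character vector of transforms to compare, in
#'   tie-break order.
#' @return The selected transform tag, with attribute `aic` (named vector).
#' @export
select_covariate_form <- function(cohort, outcome = "insulin_resistance",
                                  candidate_forms = c("identity", "log",
                                                      "sqrt")) {
  stopifnot(outcome %in% names(cohort))
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; cannot compare fits", call. = FALSE)
  }
  if (length(candidate_forms) == 1L) return(candidate_forms)
  aics <- stats::setNames(rep(NA_real_, length(candidate_forms)),
                          candidate_forms)
  for (ci in seq_along(candidate_forms)) {
    form <- candidate_forms[ci]
    X <- build_design(cohort, "full", form)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ X - 1, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep || any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
      warning(sprintf("candidate `%s` excluded: perfect separation", form),
              call. = FALSE)
    } else {
      aics[ci] <- stats::AIC(fit)
    }
  }
  if (all(is.na(aics))) stop("no candidate form could be fit", call. = FALSE)
  sel <- candidate_forms[which.min(aics)]  # which.min: first minimum wins
  structure(sel, aic = aics)
}
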