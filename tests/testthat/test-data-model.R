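test_that("exposure categorization implements the third-quartile split", {
  expect_equal(as.character(categorize_exposure(7603, 0, 13414)), "LD/NoCRT")
  expect_equal(as.character(categorize_exposure(19087, 1, 13414)), "HD/CRT")
  # boundary dose counts as low
  expect_equal(as.character(categorize_exposure(13414, 1, 13414)), "LD/CRT")
  expect_equal(as.character(categorize_exposure(13414, 0, 13414)), "LD/NoCRT")
  expect_error(categorize_exposure(20000, 0, 13414), "absent from the study")
  expect_error(categorize_exposure(-5, 1, 13414), "nonnegative")
})

test_that("categorization partitions the supported dose/CRT grid", {
  doses <- seq(0, 30000, by = 1500)
  grid <- expand.grid(dose = doses, crt = 0:1)
  grid <- grid[!(grid$dose > 13414 & grid$crt == 0), ]
  cats <- categorize_exposure(grid$dose, grid$crt)
  expect_false(any(is.na(cats)))
  expect_setequal(as.character(unique(cats)), exposure_levels())
})

write_temp_cohort <- function(df) {
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

test_that("cohort loading validates, drops incomplete rows, and round-trips", {
  cohort <- toy_cohort(8)
  f <- tempfile(fileext = ".csv")
  write_cohort(cohort, f)
  back <- load_cohort(f)
  expect_s3_class(back, "mvtlogit_cohort")
  expect_equal(nrow(back), 8)
  for (v in c(unname(mvtlogit:::default_outcomes()), "sex")) {
    expect_identical(back[[v]], cohort[[v]], label = v)
  }
  for (v in c("age_dx", "wbc_dx", "time_dx")) {
    # written at full precision; CSV re-typing may integer-ize whole values
    expect_identical(as.numeric(back[[v]]), as.numeric(cohort[[v]]),
                     label = v)
  }
  expect_identical(as.character(back$exposure), as.character(cohort$exposure))

  # a record with missing corticosteroid dose is excluded with a message
  df <- as.data.frame(toy_cohort(6))
  df$exposure <- NULL
  df$cs_dose <- c(5000, NA, 8000, 9000, 20000, 7000)
  df$crt <- c(0, 1, 1, 1, 1, 0)
  f2 <- write_temp_cohort(df)
  expect_message(c2 <- load_cohort(f2), "missing exposure")
  expect_equal(nrow(c2), 5)
  expect_equal(attr(c2, "n_dropped"), 1L)
})

test_that("malformed cohort files raise informative errors", {
  f <- tempfile(fileext = ".csv")
  writeLines("obesity,insulin_resistance", f)
  expect_error(load_cohort(f), "no records")

  df <- as.data.frame(toy_cohort(4))
  df$obesity[2] <- 2
  expect_error(suppressMessages(load_cohort(write_temp_cohort(df))),
               "obesity.*row 2")

  df2 <- as.data.frame(toy_cohort(4))
  df2$sex <- NULL
  expect_error(load_cohort(write_temp_cohort(df2)), "schema error")
  expect_error(load_cohort(tempfile()), "not found")
})

test_that("design matrix uses fixed dummy coding and covariate order", {
  cohort <- toy_cohort(3)  # exposures LD/NoCRT, LD/CRT, HD/CRT in order
  X <- build_design(cohort, "full", "identity")
  expect_equal(colnames(X), c("(Intercept)", "t1", "t2", "sex", "age_dx",
                              "wbc_dx", "time_dx"))
  expect_equal(unname(X[, "t1"]), c(0, 1, 0))
  expect_equal(unname(X[, "t2"]), c(0, 0, 1))
  expect_true(all(X[, "t1"] * X[, "t2"] == 0))
  expect_equal(ncol(build_design(cohort, "crude")), 3)
  expect_equal(ncol(build_design(cohort, "no_wbc")), 6)
  # 4 outcomes x 7 terms = 28 coefficients in the fully adjusted model
  expect_equal(4 * ncol(X), 28)
  expect_equal(unname(build_design(cohort, "full", "log")[, "wbc_dx"]),
               log(cohort$wbc_dx))
  expect_error(build_design(cohort, "full", "cubic"), "wbc_form")
})

test_that("descriptive summary percentages re-derive from printed counts", {
  cohort <- toy_cohort(9)
  ds <- descriptive_summary(cohort)
  expect_equal(sum(ds$group_sizes[-1]), ds$group_sizes[["overall"]])
  for (i in seq_len(nrow(ds$binary))) {
    row <- ds$binary[i, ]
    expect_equal(row$pct, round(100 * row$count / row$denom, 1))
  }
  # single-record group: SD undefined
  one <- toy_cohort(6)[c(1, 2, 2, 3), ]
  one$exposure <- factor(c("LD/NoCRT", "LD/NoCRT", "LD/NoCRT", "HD/CRT"),
                         levels = exposure_levels())
  ds1 <- descriptive_summary(one)
  hd <- ds1$continuous[ds1$continuous$group == "HD/CRT", ]
  expect_true(all(is.na(hd$sd)))
})

test_that("AIC selection recovers the generating WBC form and breaks ties", {
  # data simulated with a linear-in-WBC logit: identity should win in a
  # clear majority of replicates
  wins <- 0L
  for (rep in 1:7) {
    gen <- generator_spec(n = 3000, seed = 100 + rep)
    gen$true_beta["I", "wbc_dx"] <- 0.02  # strengthen the linear signal
    cohort <- generate_cohort(gen)
    sel <- select_covariate_form(cohort, "insulin_resistance")
    wins <- wins + (as.character(sel) == "identity")
  }
  expect_gt(wins, 3)

  # singleton candidate set returns without fitting
  expect_equal(select_covariate_form(toy_cohort(6), "obesity", "log"), "log")
  # tie rule: first of the fixed order wins (duplicate candidates tie exactly)
  cohort <- generate_cohort(generator_spec(n = 300, seed = 3))
  sel <- select_covariate_form(cohort, "obesity", c("log", "log"))
  aic <- attr(sel, "aic")
  expect_equal(unname(aic[1]), unname(aic[2]))
  expect_equal(as.character(sel), "log")
})
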