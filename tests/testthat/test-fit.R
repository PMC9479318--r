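test_that("logistic MLE on a collapsed 2x2 equals the closed-form log OR", {
  # binary DF: cells (df=1,op=1)=30, (1,0)=10, (0,1)=20, (0,0)=25
  op <- c(rep(1L, 30), rep(0L, 10), rep(1L, 20), rep(0L, 25))
  df <- c(rep(1, 40), rep(0, 45))
  rec <- manual_records(op, df)
  fit <- fit_issue_logistic(rec)
  expect_equal(coef_row(fit, "df_std")$estimate,
               log((30 * 25) / (10 * 20)), tolerance = 1e-8)
  expect_false(fit$separation)
  expect_equal(fit$coefficients$ci_hi,
               fit$coefficients$estimate +
                 qnorm(0.975) * fit$coefficients$se, tolerance = 1e-9)
})

test_that("odds factors come from exponentiated log-odds", {
  expect_equal(round(odds_factor(0.12), 2), 1.13)
  op <- rep(c(1L, 0L, 1L, 1L), 30)
  rec <- manual_records(op, rep(c(-1, 0, 1, 2), 30))
  fit <- fit_issue_logistic(rec)
  expect_equal(odds_factor(fit, "df_std"),
               exp(coef_row(fit, "df_std")$estimate))
})

test_that("unit weights reproduce the unweighted fit exactly", {
  set.seed(31)
  op <- rbinom(200, 1, plogis(0.3 * rnorm(200)))
  df <- rnorm(200)
  f1 <- fit_issue_logistic(manual_records(op, df))
  f2 <- fit_issue_logistic(manual_records(op, df, weight = rep(1, 200)))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("weight 2 equals row duplication and weight 0 equals deletion", {
  set.seed(32)
  n <- 150
  df <- rnorm(n)
  op <- rbinom(n, 1, plogis(0.4 * df))
  w <- sample(c(0, 1, 2), n, replace = TRUE)
  weighted <- fit_issue_logistic(manual_records(op, df, weight = w))
  expanded <- manual_records(rep(op, times = w), rep(df, times = w))
  duplicated_fit <- fit_issue_logistic(expanded)
  expect_equal(coef_row(weighted, "df_std")$estimate,
               coef_row(duplicated_fit, "df_std")$estimate,
               tolerance = 1e-8)
  expect_error(fit_issue_logistic(manual_records(op, df,
                                                 weight = rep(-1, n))),
               "non-negative")
})

test_that("single-valued outcomes and monotone trends flag separation", {
  fit <- fit_issue_logistic(manual_records(rep(1L, 50), rnorm(50)))
  expect_true(fit$separation)
  expect_true(all(is.na(fit$coefficients$estimate)))
  rec <- manual_records(rep(c(0L, 1L), each = 40), df = 0,
                        wave = rep(c(1980, 2010), each = 40))
  cr <- fit_change_rate(rec)
  expect_true(cr$separation)
  expect_true(is.na(cr$slope))
})

test_that("change rates recover a synthetic log-odds-per-decade trend", {
  set.seed(77)
  waves <- rep(c(1984, 1994, 2004, 2014), each = 1500)
  dec <- (waves - 1984) / 10
  op <- rbinom(length(waves), 1, plogis(-0.5 + 0.3 * dec))
  cr <- fit_change_rate(manual_records(op, df = 0, wave = waves))
  expect_lt(abs(cr$slope - 0.3), 2 * cr$se)
  flat <- rbinom(4000, 1, 0.5)
  cr0 <- fit_change_rate(manual_records(flat, df = 0,
                                        wave = rep(c(1990, 2000), 2000)))
  expect_lt(abs(cr0$slope), 3 * cr0$se)
  expect_error(fit_change_rate(manual_records(flat, 0, wave = 2000)),
               "2 distinct waves")
})

test_that("pooled M1 equals plain logistic when RE variances are zero", {
  dgp <- survey_dgp(800, 6, waves = c(1990, 2000),
                    beta1_by_group = c(liberal = 0.3, moderate = 0,
                                       conservative = 0), seed = 51)
  s <- gen_survey(dgp)
  lib <- s$records[s$records$ideology3 == "liberal", ]
  lib$df_std <- standardize(lib$df_raw)
  glmm <- suppressWarnings(fit_pooled_m1(lib, nAGQ = 0))
  plain <- fit_pooled_m1(lib, method = "glm_cluster")
  shared <- intersect(glmm$coefficients$term, plain$coefficients$term)
  for (tm in shared) {
    expect_lt(abs(coef_row(glmm, tm)$estimate -
                    coef_row(plain, tm)$estimate), 0.01)
  }
  # fitted RE SDs sit near the zero boundary (small-sample noise allowed)
  expect_true(all(glmm$re_sd < 0.3))
  expect_match(glmm$method, "glmer")
  expect_match(plain$method, "cluster-robust")
})

test_that("M1 estimates are invariant to row order and id relabeling", {
  dgp <- survey_dgp(300, 4, waves = c(1990, 2000),
                    beta1_by_group = c(liberal = 0.2, moderate = 0,
                                       conservative = 0),
                    re_sd_individual = 0.4, seed = 52)
  s <- gen_survey(dgp)
  lib <- s$records[s$records$ideology3 == "liberal", ]
  lib$df_std <- standardize(lib$df_raw)
  f1 <- suppressWarnings(fit_pooled_m1(lib))
  set.seed(1)
  shuf <- lib[sample(nrow(lib)), ]
  shuf$respondent_id <- paste0("zz_", shuf$respondent_id)
  f2 <- suppressWarnings(fit_pooled_m1(shuf))
  expect_equal(coef_row(f1, "df_std")$estimate,
               coef_row(f2, "df_std")$estimate, tolerance = 1e-6)
})

test_that("degenerate grouping levels are dropped with a warning", {
  dgp <- survey_dgp(250, 3, waves = 2000,
                    re_sd_individual = 0.3, seed = 53)
  s <- gen_survey(dgp)
  lib <- s$records[s$records$ideology3 == "liberal", ]
  lib$df_std <- standardize(lib$df_raw)
  expect_warning(fit <- fit_pooled_m1(lib), "issue-wave")
  expect_false("issue_wave" %in% names(fit$re_sd))
  expect_error(fit_pooled_m1(lib[lib$item_id == "item1", ]),
               "at least 2 issues")
})

test_that("M2 recovers an interaction and rejects constant advantage", {
  dgp <- survey_dgp(1500, 12, beta3 = 0.3,
                    beta1_by_group = c(liberal = 0.1, moderate = 0,
                                       conservative = 0), seed = 54)
  s <- gen_survey(dgp)
  lib <- s$records[s$records$ideology3 == "liberal", ]
  lib$df_std <- standardize(lib$df_raw)
  fit <- suppressWarnings(fit_pooled_m2(lib))
  est <- coef_row(fit, "df_std:adv10")
  expect_lt(abs(est$estimate - 0.3), 2.5 * est$se)
  lib$advantage <- 0.2
  expect_error(fit_pooled_m2(lib), "inestimable")
})
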