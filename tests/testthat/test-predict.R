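test_that("alignment counting is antisymmetric and tie-aware", {
  adv <- c(0.2, -0.15, 0.12, 0.3)
  lib <- c(0.6, 0.4, 0.45, 0.5)
  con <- c(0.4, 0.6, 0.5, 0.5)  # last item tied
  # aligned: items 1 and 2; item 3 misaligned; item 4 tied
  p <- suppressMessages(test_prediction1(adv, lib, con))
  expect_equal(p$n_aligned, 2)
  expect_equal(p$n_total, 4)
  expect_equal(p$n_ties, 1)
  flipped <- suppressMessages(test_prediction1(-adv, lib, con))
  expect_equal(flipped$n_aligned, p$n_total - p$n_aligned - p$n_ties)
  single <- suppressMessages(test_prediction1(0.3, 0.5, 0.5))
  expect_equal(single$n_aligned, 0)
  expect_equal(single$n_total, 1)
})

test_that("generated liberal lean aligns with advantage on most items", {
  s <- gen_survey(survey_dgp(
    3000, 100, group_adv_effect = c(liberal = 4, moderate = 2,
                                    conservative = 0), seed = 61))
  rec <- s$records
  prev <- function(g) {
    sub <- rec[rec$ideology3 == g, ]
    tapply(sub$opinion_adv, sub$item_id, mean)[paste0("item", 1:100)]
  }
  p <- suppressMessages(test_prediction1(s$truth$advantage,
                                         prev("liberal"),
                                         prev("conservative")))
  expect_gte(p$n_aligned / p$n_total, 0.85)
})

test_that("perfect proportionality gives r = 1 and noise covers zero", {
  adv <- c(-0.2, -0.05, 0.1, 0.22, 0.3)
  p <- test_prediction2(adv, 2 * adv)
  expect_equal(p$r, 1, tolerance = 1e-12)
  set.seed(62)
  cover <- vapply(1:40, function(i) {
    p0 <- test_prediction2(rnorm(30), rnorm(30))
    p0$ci[1] <= 0 && 0 <= p0$ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.85)
  expect_error(test_prediction2(adv[1:3], adv[1:3]), "at least 4")
  expect_error(test_prediction2(rep(0.1, 5), rnorm(5)), "zero variance")
})

test_that("a noisy linear trend matches the analytic correlation", {
  # rate = 0.3 * adv + noise: r = 0.3 sd(adv) / sqrt(0.3^2 var(adv) + var(e))
  set.seed(63)
  adv <- rnorm(500, 0, 0.16)
  noise <- rnorm(500, 0, 0.04)
  expected_r <- 0.3 * 0.16 / sqrt(0.3^2 * 0.16^2 + 0.04^2)
  p <- test_prediction2(adv, 0.3 * adv + noise)
  expect_equal(p$r, expected_r, tolerance = 0.05)
})

test_that("DF-effect verdicts read the group fits correctly", {
  fits <- list(liberal = stub_fit(0.12, 0.02),
               moderate = stub_fit(0.07, 0.03),
               conservative = stub_fit(0.01, 0.03))
  v <- test_df_effects(fits)
  expect_true(v$p3_positive)
  expect_true(v$p5_covers_zero)
  expect_true(v$ordering_holds)
  flipped <- test_df_effects(list(liberal = stub_fit(-0.12, 0.02),
                                  conservative = stub_fit(0.01, 0.03)))
  expect_false(flipped$p3_positive)
  equal <- test_df_effects(list(liberal = stub_fit(0.05, 0.02),
                                conservative = stub_fit(-0.05, 0.02)))
  expect_true(is.na(equal$ordering_holds))
  expect_error(test_df_effects(list(liberal = stub_fit(0.1, 0.02))),
               "conservative")
})

test_that("identical splits give a zero slope difference", {
  adv <- c(0.1, 0.15, 0.2, 0.25, 0.3)
  rates <- 0.4 * adv + c(0.01, -0.02, 0, 0.02, -0.01)
  f <- fig5_slope_difference(rates, rates, adv)
  expect_equal(f$difference, 0, tolerance = 1e-12)
  expect_equal(f$slope_frequent, f$slope_infrequent, tolerance = 1e-12)
})

test_that("a known slope difference between splits is recovered", {
  set.seed(64)
  hits <- vapply(1:30, function(i) {
    adv <- runif(27, 0.1, 0.3)
    r_inf <- 0.5 * adv + rnorm(27, 0, 0.03)
    r_frq <- (0.5 + 0.36) * adv + rnorm(27, 0, 0.03)
    f <- fig5_slope_difference(r_frq, r_inf, adv)
    abs(f$difference - 0.36) <= 2.5 * f$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # one constant panel yields a zero slope for that panel
  adv <- c(0.1, 0.2, 0.3, 0.4)
  f0 <- suppressWarnings(  # exact-fit inputs by construction
    fig5_slope_difference(0.2 * adv, rep(0.05, 4), adv))
  expect_equal(f0$slope_infrequent, 0, tolerance = 1e-12)
})

test_that("median split labels above-median discussers as frequent", {
  rec <- manual_records(rep(0L, 5), df = c(-2, -1, 0, 1, 2))
  out <- df_median_split(rec)
  expect_identical(out$df_split,
                   c("infrequent", "infrequent", "infrequent",
                     "frequent", "frequent"))
})
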