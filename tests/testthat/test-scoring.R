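test_that("participant advantage reproduces the worked endorsement pattern", {
  expect_identical(participant_advantage(worked_example_row()), 0.25)
  # empty endorsement and the two range endpoints
  expect_identical(participant_advantage(judgment_row()), 0)
  full_yes <- judgment_row(yes_harm = 1L, yes_violence = 1L,
                           yes_fairness = 1L, yes_liberty = 1L)
  full_no <- judgment_row(no_harm = 1L, no_violence = 1L,
                          no_fairness = 1L, no_liberty = 1L)
  expect_identical(participant_advantage(full_yes), 1)
  expect_identical(participant_advantage(full_no), -1)
})

test_that("non-HVFL dummies never enter the score", {
  base <- judgment_row(yes_fairness = 1L)
  extra <- judgment_row(yes_fairness = 1L, yes_purity = 1L,
                        no_authority = 1L, no_loyalty = 1L)
  expect_identical(participant_advantage(base),
                   participant_advantage(extra))
})

test_that("missing or non-binary dummies raise named errors", {
  row <- worked_example_row()
  expect_error(participant_advantage(row[setdiff(names(row), "no_harm")]),
               "no_harm")
  row$yes_liberty <- 2L
  expect_error(participant_advantage(row), "yes_liberty")
})

test_that("score is bounded and antisymmetric under side swap", {
  set.seed(42)
  for (i in 1:200) {
    vals <- setNames(as.list(rbinom(14, 1, runif(1))), dummy_columns())
    row <- do.call(judgment_row, vals)
    s <- participant_advantage(row)
    expect_gte(s, -1)
    expect_lte(s, 1)
    swapped <- row
    names(swapped) <- sub("^yes_", "tmp_", names(swapped))
    names(swapped) <- sub("^no_", "yes_", names(swapped))
    names(swapped) <- sub("^tmp_", "no_", names(swapped))
    expect_equal(participant_advantage(swapped), -s, tolerance = 1e-12)
  }
})

test_that("item advantage matches the two-point formula and flags n = 1", {
  two <- rbind(worked_example_row(),
               judgment_row(no_fairness = 1L, no_harm = 1L,
                            yes_liberty = 1L, participant_id = "p2"))
  est <- item_advantage(two)
  expect_equal(est$mean, 0)
  expect_equal(est$se, 0.25, tolerance = 1e-12)  # sd 0.3536 / sqrt(2)
  expect_identical(est$n_judges, 2L)
  one <- item_advantage(worked_example_row())
  expect_equal(one$mean, 0.25)
  expect_true(is.na(one$se))
  expect_error(item_advantage(data.frame()), "non-empty")
})

test_that("item mean equals the brute-force mean of per-row scores", {
  prof <- profile_with_advantage("itemX", 0.15)
  j <- gen_argument_judgments(list(prof), 60, seed = 7)
  est <- item_advantage(j)
  expect_equal(est$mean, mean(participant_advantage(j)),
               tolerance = 1e-12)
  expect_equal(est$se, sd(participant_advantage(j)) / sqrt(60),
               tolerance = 1e-12)
})

test_that("ideology sub-means exclude judges labelled other", {
  rows <- rbind(
    judgment_row(yes_harm = 1L, ideology = "liberal"),
    judgment_row(yes_harm = 1L, yes_fairness = 1L,
                 ideology = "conservative", participant_id = "p2"),
    judgment_row(no_harm = 1L, ideology = "other", participant_id = "p3"))
  est <- item_advantage(rows)
  expect_equal(est$mean_liberal_based, 0.25)
  expect_equal(est$mean_conservative_based, 0.5)
  # overall mean includes the "other" judge
  expect_equal(est$mean, mean(c(0.25, 0.5, -0.25)))
})

test_that("split reliability is 1 for identical sub-means and errors on < 3 pairs", {
  est <- data.frame(mean_liberal_based = c(0.1, 0.2, -0.1, 0),
                    mean_conservative_based = c(0.1, 0.2, -0.1, 0))
  rel <- ideology_split_reliability(est)
  expect_equal(rel$r, 1)
  expect_error(ideology_split_reliability(est[1:2, ]), "at least 3")
})

test_that("independent sub-means give near-zero correlation", {
  set.seed(99)
  hits <- vapply(1:40, function(i) {
    est <- data.frame(mean_liberal_based = rnorm(100, 0, 0.16),
                      mean_conservative_based = rnorm(100, 0, 0.16))
    abs(ideology_split_reliability(est)$r) < 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("noisy sub-means attenuate the correlation as predicted", {
  # truth SD 0.16, independent measurement noise SD 0.05 on both sides:
  # expected r = 0.16^2 / (0.16^2 + 0.05^2) = 0.911
  set.seed(5)
  n <- 400
  truth <- rnorm(n, 0, 0.16)
  est <- data.frame(mean_liberal_based = truth + rnorm(n, 0, 0.05),
                    mean_conservative_based = truth + rnorm(n, 0, 0.05))
  rel <- ideology_split_reliability(est)
  expect_equal(rel$r, 0.16^2 / (0.16^2 + 0.05^2), tolerance = 0.04)
})

test_that("threshold filter is inclusive at the cutoff and records direction", {
  est <- data.frame(item_id = c("a", "b", "c", "d"),
                    mean = c(0.28, 0.05, -0.24, 0.1))
  filt <- threshold_filter(est, min_abs = 0.1)
  expect_setequal(filt$kept$item_id, c("a", "c", "d"))  # 0.1 kept
  expect_equal(filt$kept$direction[filt$kept$item_id == "c"], -1)
  expect_identical(filt$dropped$item_id, "b")
  expect_warning(threshold_filter(data.frame(item_id = "a", mean = 0)),
                 ">= 0.1")
})
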