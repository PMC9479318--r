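#' Configuration of the end-to-end synthetic pipeline
#'
#' Bundles the sizes and ground-truth effects used by [run_pipeline()]:
#' an endorsement study scoring the HVFL advantage of each issue, a
#' synthetic opinion survey generated so that the five theoretical
#' predictions hold by construction, and the estimation stages that test
#' them.
#'
#' @param n_items Number of moral issues.
#' @param n_judges Endorsement-study judges per item.
#' @param n_respondents Survey respondents.
#' @param waves Survey years.
#' @param beta1_liberal True pooled DF effect among liberals (log-odds
#'   per SD); moderates get half of it and conservatives 0.
#' @param beta3 True DF x advantage interaction per 0.1 advantage.
#' @param group_adv_effect Ideology-advantage alignment strengths.
#' @param trend_adv_coef Opinion trend in log-odds per decade per unit
#'   advantage.
#' @param trend_df_adv_coef DF moderation of the trend.
#' @param re_sds Random-intercept SDs (individual, issue, issue-wave).
#' @param min_abs Advantage threshold for the estimation issue set.
#' @param fit_method `"glmm"` or `"glm_cluster"` for the pooled fits.
#' @param nAGQ Likelihood approximation for glmer fits.
#' @param seed Master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_items = 40, n_judges = 98,
                            n_respondents = 2000,
                            waves = c(1985, 1995, 2005, 2015),
                            beta1_liberal = 0.12, beta3 = 0.10,
                            group_adv_effect = c(liberal = 4,
                                                 moderate = 2,
                                                 conservative = 0),
                            trend_adv_coef = 3,
                            trend_df_adv_coef = 0.25,
                            re_sds = c(individual = 0.5, issue = 0.2,
                                       issuewave = 0.1),
                            min_abs = 0.1,
                            fit_method = c("glmm", "glm_cluster"),
                            nAGQ = 0, seed = 1L) {
  structure(
    list(n_items = .check_count(n_items, "n_items", 2L),
         n_judges = .check_count(n_judges, "n_judges", 2L),
         n_respondents = .check_count(n_respondents, "n_respondents", 2L),
         waves = waves, beta1_liberal = beta1_liberal, beta3 = beta3,
         group_adv_effect = group_adv_effect,
         trend_adv_coef = trend_adv_coef,
         trend_df_adv_coef = trend_df_adv_coef, re_sds = re_sds,
         min_abs = min_abs, fit_method = match.arg(fit_method),
         nAGQ = nAGQ, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full synthetic pipeline
#'
#' Executes score -> prepare -> estimate -> test on synthetic data with
#' known ground truth: (1) generates argument judgments from endorsement
#' profiles and scores each issue's HVFL advantage; (2) keeps issues with
#' |advantage| >= `min_abs`; (3) generates an opinion survey whose
#' generative model aligns advantage with liberal popularity, gives
#' advantaged opinions an advantage-proportional trend, and gives liberals
#' (only) a positive DF effect moderated by advantage; (4) estimates M1
#' per group, M2 for liberals, per-item change rates, and DF-split change
#' rates; (5) assembles the five prediction tests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report is written as
#'   JSON and the intermediate tables as CSV.
#' @return List of class `prediction_report` with elements `p1`, `p2`,
#'   `df_effects` (P3/P5), `m2_interaction` and `fig5` (P4), plus the
#'   intermediate `advantage_estimates`, `fits`, `change_rates`, `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must come from pipeline_config()", call. = FALSE)
  }
  seeds <- .spawn_seeds(config$seed, 4L)

  # -- stage 1: endorsement study and scoring ---------------------------
  set.seed(seeds[1])
  true_adv <- pmin(0.9, pmax(-0.9, rnorm(config$n_items, 0, 0.16)))
  profiles <- lapply(seq_len(config$n_items), function(k) {
    profile_with_advantage(paste0("item", k), true_adv[k])
  })
  judgments <- gen_argument_judgments(profiles, config$n_judges,
                                      seed = seeds[2])
  estimates <- advantage_table(judgments)

  # -- stage 2: threshold filter ----------------------------------------
  filt <- threshold_filter(estimates, min_abs = config$min_abs)
  kept_ids <- as.character(filt$kept$item_id)

  # -- stage 3: synthetic opinion survey --------------------------------
  dgp <- survey_dgp(
    n_respondents = config$n_respondents, n_issues = config$n_items,
    waves = config$waves,
    beta1_by_group = c(liberal = config$beta1_liberal,
                       moderate = config$beta1_liberal / 2,
                       conservative = 0),
    # the theory locates the moderation among liberals: moderates get
    # half, conservatives none
    beta3 = c(liberal = config$beta3, moderate = config$beta3 / 2,
              conservative = 0),
    group_adv_effect = config$group_adv_effect,
    trend_adv_coef = config$trend_adv_coef,
    trend_df_adv_coef = c(liberal = config$trend_df_adv_coef,
                          moderate = config$trend_df_adv_coef / 2,
                          conservative = 0),
    re_sd_individual = config$re_sds[["individual"]],
    re_sd_issue = config$re_sds[["issue"]],
    re_sd_issuewave = config$re_sds[["issuewave"]],
    advantage = true_adv, seed = seeds[3]
  )
  survey <- gen_survey(dgp)
  rec <- survey$records

  # -- stage 4: estimation ----------------------------------------------
  # estimated (not true) advantages drive the analysis, as with real data
  est_adv <- setNames(estimates$mean, as.character(estimates$item_id))
  rec$advantage <- unname(est_adv[as.character(rec$item_id)])
  rec_kept <- rec[rec$item_id %in% kept_ids, , drop = FALSE]
  # code opinions so 1 = estimated-advantaged side
  flip <- rec_kept$advantage < 0
  rec_kept$opinion_adv <- ifelse(flip, 1L - rec_kept$opinion_adv,
                                 rec_kept$opinion_adv)
  rec_kept$advantage <- abs(rec_kept$advantage)

  groups <- c("liberal", "moderate", "conservative")
  fits_m1 <- lapply(setNames(groups, groups), function(g) {
    sub <- rec_kept[rec_kept$ideology3 == g, , drop = FALSE]
    sub$df_std <- standardize(sub$df_raw)
    fit_pooled_m1(sub, method = config$fit_method, nAGQ = config$nAGQ)
  })
  lib <- rec_kept[rec_kept$ideology3 == "liberal", , drop = FALSE]
  lib$df_std <- standardize(lib$df_raw)
  fit_m2 <- fit_pooled_m2(lib, method = config$fit_method,
                          nAGQ = config$nAGQ)

  rates <- change_rate_table(rec)
  lib_split <- df_median_split(lib)
  rate_freq <- change_rate_table(
    lib_split[lib_split$df_split == "frequent", , drop = FALSE])
  rate_infreq <- change_rate_table(
    lib_split[lib_split$df_split == "infrequent", , drop = FALSE])

  # -- stage 5: prediction tests ----------------------------------------
  prev <- function(records, group) {
    sub <- records[records$ideology3 == group, , drop = FALSE]
    p <- tapply(sub$opinion_adv, sub$item_id, mean)
    p[as.character(estimates$item_id)]
  }
  p1 <- test_prediction1(estimates$mean, prev(rec, "liberal"),
                         prev(rec, "conservative"),
                         item_id = as.character(estimates$item_id))
  common <- intersect(as.character(estimates$item_id),
                      as.character(rates$item_id))
  p2 <- test_prediction2(
    est_adv[common],
    setNames(rates$slope, as.character(rates$item_id))[common])
  df_eff <- test_df_effects(fits_m1)
  m2_row <- coef_row(fit_m2, "df_std:adv10")
  fig5_ids <- intersect(as.character(rate_freq$item_id),
                        as.character(rate_infreq$item_id))
  rf <- setNames(rate_freq$slope, as.character(rate_freq$item_id))
  ri <- setNames(rate_infreq$slope, as.character(rate_infreq$item_id))
  adv_kept <- setNames(abs(filt$kept$mean), as.character(filt$kept$item_id))
  fig5 <- fig5_slope_difference(rf[fig5_ids], ri[fig5_ids],
                                adv_kept[fig5_ids])

  report <- structure(
    list(p1 = p1[c("n_aligned", "n_total", "n_ties")],
         p2 = p2[c("r", "ci", "n_items")],
         df_effects = df_eff,
         m2_interaction = m2_row,
         fig5 = fig5,
         advantage_estimates = estimates,
         kept_items = kept_ids,
         fits = c(fits_m1, list(m2_liberal = fit_m2)),
         change_rates = rates,
         truth = survey$truth,
         config = config),
    class = "prediction_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    slim <- list(
      p1 = report$p1,
      p2 = report$p2,
      df_effects = df_eff$effects,
      p3_positive = df_eff$p3_positive,
      p5_covers_zero = df_eff$p5_covers_zero,
      ordering_holds = df_eff$ordering_holds,
      m2_interaction = m2_row,
      fig5 = fig5[c("slope_frequent", "slope_infrequent", "difference",
                    "ci", "n_items")],
      seed = config$seed
    )
    jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(estimates, file.path(out_dir, "advantage_estimates.csv"),
              row.names = FALSE)
    write.csv(rates, file.path(out_dir, "change_rates.csv"),
              row.names = FALSE)
  }
  report
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report>\n")
  cat(sprintf("P1 alignment: %d of %d items\n", x$p1$n_aligned,
              x$p1$n_total))
  cat(sprintf("P2 advantage~change r = %.2f [%.2f, %.2f] (%d items)\n",
              x$p2$r, x$p2$ci[1], x$p2$ci[2], x$p2$n_items))
  eff <- x$df_effects$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("DF effect (%s): %.3f [%.3f, %.3f]\n", eff$group[i],
                eff$estimate[i], eff$ci_lo[i], eff$ci_hi[i]))
  }
  cat(sprintf("P4 interaction (per 0.1 advantage): %.3f [%.3f, %.3f]\n",
              x$m2_interaction$estimate, x$m2_interaction$ci_lo,
              x$m2_interaction$ci_hi))
  cat(sprintf("Trend-moderation slope difference: %.2f [%.2f, %.2f]\n",
              x$fig5$difference, x$fig5$ci[1], x$fig5$ci[2]))
  invisible(x)
}
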