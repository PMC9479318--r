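#' Survey data-generating process
#'
#' Specifies the generative twin of the pooled crossed random-intercept
#' logistic model: for respondent i (ideology group g(i), wave w(i)) and
#' issue k,
#' \deqn{logit P(Opinion_{ik} = 1) = \beta_{0k} + u_i + u_k + u_{kw(i)}
#'   + \beta_{1,g(i)} DF_i + \beta_2 A10_k + \beta_3 DF_i A10_k + \dots}
#' where `DF` is discussion frequency standardized over the generated
#' sample, `A10` is the issue's HVFL advantage centered at the item mean
#' and multiplied by 10 (one unit = 0.1 advantage), and the random
#' intercepts are independent Gaussians on the log-odds scale.
#'
#' Additional optional terms (all defaulting to 0) let the generator
#' express the theory's predictions with known ground truth:
#' `group_adv_effect[g] * A_k` (ideology-advantage alignment),
#' `trend_adv_coef * A_k * decades` (advantage-proportional opinion trend)
#' and `trend_df_adv_coef * DF_i * A_k * decades` (frequency moderation of
#' the trend), with `A_k` the raw advantage and `decades` time since the
#' first wave in decades.
#'
#' @param n_respondents,n_issues Sample dimensions; every respondent
#'   answers every issue.
#' @param waves Numeric survey years; each respondent belongs to one wave.
#' @param group_mix Named proportions of liberal/moderate/conservative.
#' @param df_levels Raw discussion-frequency support (default integers
#'   0-7, "days in the past week"), sampled uniformly and independently of
#'   ideology.
#' @param beta0_issue Per-issue fixed intercept (scalar or length
#'   `n_issues`), log-odds.
#' @param beta1_by_group Named DF slopes (log-odds per SD of DF) for
#'   liberal, moderate, conservative.
#' @param beta2 Advantage main effect per 0.1 advantage (the A10 scale).
#' @param beta3 DF x advantage interaction per 0.1 advantage; either a
#'   scalar (applied to every ideology group) or a named vector over
#'   liberal/moderate/conservative, since the theory locates the
#'   moderation among liberals.
#' @param group_adv_effect,trend_adv_coef,trend_df_adv_coef Optional
#'   alignment and trend terms, see above; `trend_df_adv_coef` may also
#'   be a scalar or a named per-group vector.
#' @param covariate_effects Named log-odds effects of the controls
#'   (education, woman, age, black, other, media); default all 0.
#' @param re_sd_individual,re_sd_issue,re_sd_issuewave Random-intercept
#'   SDs (log-odds), all >= 0.
#' @param advantage Per-issue true advantage in \[-1, 1\]; default drawn
#'   (with the DGP's seed) from N(0, 0.16) truncated to \[-1, 1\],
#'   mirroring the observed spread of item advantages.
#' @param seed Integer master seed; identical configs give byte-identical
#'   output.
#' @return Object of class `survey_dgp`.
#' @export
survey_dgp <- function(n_respondents, n_issues,
                       waves = c(1985, 1995, 2005, 2015),
                       group_mix = c(liberal = 0.27, moderate = 0.33,
                                     conservative = 0.40),
                       df_levels = 0:7,
                       beta0_issue = 0,
                       beta1_by_group = c(liberal = 0, moderate = 0,
                                          conservative = 0),
                       beta2 = 0, beta3 = 0,
                       group_adv_effect = c(liberal = 0, moderate = 0,
                                            conservative = 0),
                       trend_adv_coef = 0, trend_df_adv_coef = 0,
                       covariate_effects = c(education = 0, woman = 0,
                                             age = 0, black = 0, other = 0,
                                             media = 0),
                       re_sd_individual = 0, re_sd_issue = 0,
                       re_sd_issuewave = 0,
                       advantage = NULL, seed = 1L) {
  n_respondents <- .check_count(n_respondents, "n_respondents")
  n_issues <- .check_count(n_issues, "n_issues")
  .check_mix(group_mix, "group_mix")
  if (!setequal(names(group_mix),
                c("liberal", "moderate", "conservative"))) {
    stop("`group_mix` must name liberal, moderate, conservative",
         call. = FALSE)
  }
  for (what in c("re_sd_individual", "re_sd_issue", "re_sd_issuewave")) {
    v <- get(what)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop(sprintf("`%s` must be a single SD >= 0", what), call. = FALSE)
    }
  }
  if (length(beta0_issue) == 1) beta0_issue <- rep(beta0_issue, n_issues)
  if (length(beta0_issue) != n_issues) {
    stop("`beta0_issue` must have length 1 or n_issues", call. = FALSE)
  }
  if (!setequal(names(beta1_by_group),
                c("liberal", "moderate", "conservative"))) {
    stop("`beta1_by_group` must name liberal, moderate, conservative",
         call. = FALSE)
  }
  expand_groups <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) {
      return(c(liberal = x, moderate = x, conservative = x))
    }
    if (!setequal(names(x), c("liberal", "moderate", "conservative"))) {
      stop(sprintf(
        "`%s` must be a scalar or name liberal, moderate, conservative",
        what), call. = FALSE)
    }
    x
  }
  beta3 <- expand_groups(beta3, "beta3")
  trend_df_adv_coef <- expand_groups(trend_df_adv_coef,
                                     "trend_df_adv_coef")
  if (is.null(advantage)) {
    set.seed(seed + 1L)
    advantage <- pmin(1, pmax(-1, rnorm(n_issues, 0, 0.16)))
  }
  if (length(advantage) != n_issues || any(abs(advantage) > 1)) {
    stop("`advantage` must have length n_issues with values in [-1, 1]",
         call. = FALSE)
  }
  structure(
    list(n_respondents = n_respondents, n_issues = n_issues, waves = waves,
         group_mix = group_mix, df_levels = df_levels,
         beta0_issue = beta0_issue, beta1_by_group = beta1_by_group,
         beta2 = beta2, beta3 = beta3,
         group_adv_effect = group_adv_effect,
         trend_adv_coef = trend_adv_coef,
         trend_df_adv_coef = trend_df_adv_coef,
         covariate_effects = covariate_effects,
         re_sd_individual = re_sd_individual, re_sd_issue = re_sd_issue,
         re_sd_issuewave = re_sd_issuewave,
         advantage = advantage, seed = as.integer(seed)),
    class = "survey_dgp"
  )
}

#' Generate a synthetic opinion survey
#'
#' Draws a respondent x issue table from a [survey_dgp()]: respondents get
#' an ideology group (and a consistent 7-point self-placement), a wave, a
#' raw discussion frequency, standard-normal continuous covariates and
#' binary/categorical demographics; opinions are Bernoulli draws from the
#' logistic linear predictor described in [survey_dgp()]. Discussion
#' frequency is standardized over the generated sample before the DF
#' slopes are applied.
#'
#' @param dgp A [survey_dgp()] object.
#' @return List with `records` (one row per respondent x issue, the
#'   analysis-ready survey table) and `truth` (all generator parameters,
#'   the realized advantage vector, and the DF standardization constants),
#'   so recovery tests never re-derive ground truth.
#' @export
gen_survey <- function(dgp) {
  if (!inherits(dgp, "survey_dgp")) {
    stop("`dgp` must be a `survey_dgp` object", call. = FALSE)
  }
  set.seed(dgp$seed)
  n <- dgp$n_respondents
  J <- dgp$n_issues
  waves <- dgp$waves

  group <- sample(names(dgp$group_mix), n, replace = TRUE,
                  prob = dgp$group_mix)
  ideology7 <- ifelse(group == "liberal", sample(1:3, n, replace = TRUE),
                ifelse(group == "moderate", 4L,
                       sample(5:7, n, replace = TRUE)))
  wave <- waves[sample.int(length(waves), n, replace = TRUE)]
  df_raw <- dgp$df_levels[sample.int(length(dgp$df_levels), n,
                                     replace = TRUE)]
  df_std <- if (n > 1 && sd(df_raw) > 0) {
    (df_raw - mean(df_raw)) / sd(df_raw)
  } else rep(0, n)
  education <- rnorm(n)
  age <- rnorm(n)
  media <- rnorm(n)
  woman <- rbinom(n, 1L, 0.5)
  ethnicity <- sample(c("white", "black", "other"), n, replace = TRUE,
                      prob = c(0.7, 0.15, 0.15))
  weight <- rep(1, n)

  u_ind <- rnorm(n, 0, dgp$re_sd_individual)
  u_issue <- rnorm(J, 0, dgp$re_sd_issue)
  u_iw <- matrix(rnorm(J * length(waves), 0, dgp$re_sd_issuewave),
                 nrow = J)

  adv <- dgp$advantage
  adv10 <- (adv - mean(adv)) * 10      # centered, 1 unit = 0.1 advantage
  decades <- (wave - min(waves)) / 10

  i_idx <- rep(seq_len(n), each = J)
  k_idx <- rep(seq_len(J), times = n)
  w_idx <- match(wave, waves)[i_idx]

  b1 <- unname(dgp$beta1_by_group[group])[i_idx]
  b3 <- unname(dgp$beta3[group])[i_idx]
  tdf <- unname(dgp$trend_df_adv_coef[group])[i_idx]
  g_adv <- unname(dgp$group_adv_effect[group])[i_idx]
  ce <- dgp$covariate_effects
  eta <- dgp$beta0_issue[k_idx] +
    u_ind[i_idx] + u_issue[k_idx] + u_iw[cbind(k_idx, w_idx)] +
    b1 * df_std[i_idx] +
    dgp$beta2 * adv10[k_idx] +
    b3 * df_std[i_idx] * adv10[k_idx] +
    g_adv * adv[k_idx] +
    dgp$trend_adv_coef * adv[k_idx] * decades[i_idx] +
    tdf * df_std[i_idx] * adv[k_idx] * decades[i_idx] +
    ce[["education"]] * education[i_idx] + ce[["woman"]] * woman[i_idx] +
    ce[["age"]] * age[i_idx] +
    ce[["black"]] * (ethnicity[i_idx] == "black") +
    ce[["other"]] * (ethnicity[i_idx] == "other") +
    ce[["media"]] * media[i_idx]

  opinion <- rbinom(length(eta), 1L, plogis(eta))

  records <- data.frame(
    respondent_id = paste0("r", i_idx),
    item_id = paste0("item", k_idx),
    wave_year = wave[i_idx],
    opinion_adv = opinion,
    ideology3 = group[i_idx],
    ideology7 = ideology7[i_idx],
    df_raw = df_raw[i_idx],
    df_std = df_std[i_idx],
    education_std = education[i_idx],
    age_std = age[i_idx],
    media_std = media[i_idx],
    woman = woman[i_idx],
    ethnicity = ethnicity[i_idx],
    weight = weight[i_idx],
    advantage = adv[k_idx],
    stringsAsFactors = FALSE
  )
  truth <- c(
    unclass(dgp),
    list(df_mean = mean(df_raw), df_sd = sd(df_raw),
         advantage_centered10 = adv10)
  )
  list(records = records, truth = truth)
}

#' Write a synthetic survey to disk
#'
#' Writes `records` as CSV and `truth` as a JSON sidecar next to it.
#'
#' @param survey A list as returned by [gen_survey()].
#' @param dir Output directory (created if needed).
#' @param stem File stem (default `"survey"`).
#' @return Invisibly, the two file paths.
#' @export
write_survey <- function(survey, dir, stem = "survey") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  js <- file.path(dir, paste0(stem, "_truth.json"))
  write.csv(survey$records, csv, row.names = FALSE)
  jsonlite::write_json(survey$truth, js, auto_unbox = TRUE, digits = NA)
  invisible(c(records = csv, truth = js))
}
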