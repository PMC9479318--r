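# Fit containers and the three regression specifications plus the
# opinion-change-rate estimator. All coefficients are on the log-odds
# scale; CIs are Wald (estimate +/- 1.96 se). Weights enter as
# pseudo-likelihood prior weights, normalized to mean 1.

.fit_result <- function(model_tag, coefficients, re_sd = NULL,
                        n_rows = NA_integer_, n_groups = NULL,
                        method = NA_character_, converged = NA,
                        separation = FALSE, messages = character()) {
  structure(
    list(model_tag = model_tag, coefficients = coefficients,
         re_sd = re_sd, n_rows = n_rows, n_groups = n_groups,
         method = method, converged = converged, separation = separation,
         messages = messages),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model_tag, "|", x$method, "\n")
  cat("rows:", x$n_rows,
      if (x$separation) "| SEPARATION FLAGGED" else "",
      if (isFALSE(x$converged)) "| NOT CONVERGED" else "", "\n")
  print(x$coefficients, digits = 4)
  if (!is.null(x$re_sd)) {
    cat("random-intercept SDs:\n")
    print(x$re_sd, digits = 4)
  }
  invisible(x)
}

#' Extract a coefficient from a fit result
#'
#' @param fit A `fit_result`.
#' @param term Coefficient name (e.g. `"df_std"`).
#' @return One-row data frame with `estimate`, `se`, `ci_lo`, `ci_hi`.
#' @export
coef_row <- function(fit, term) {
  stopifnot(inherits(fit, "fit_result"))
  row <- fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("term `", term, "` not found in fit", call. = FALSE)
  }
  row
}

#' Odds factor of a log-odds coefficient
#'
#' Exponentiates a fitted log-odds coefficient to the factor by which the
#' odds of holding the advantaged opinion change per unit of the
#' predictor. This is the reporting path used for all fits: e.g. a pooled
#' discussion-frequency effect of 0.12 corresponds to an odds factor of
#' exp(0.12) = 1.13 per SD of discussion frequency.
#'
#' @param object A `fit_result` or a numeric log-odds value.
#' @param term Coefficient name when `object` is a fit.
#' @return Numeric odds factor.
#' @export
odds_factor <- function(object, term = NULL) {
  if (is.numeric(object)) return(exp(object))
  exp(coef_row(object, term)$estimate)
}

.coef_table <- function(est, se) {
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_lo = unname(est - qnorm(0.975) * se),
             ci_hi = unname(est + qnorm(0.975) * se),
             stringsAsFactors = FALSE, row.names = NULL)
}

.norm_weights <- function(w, n) {
  if (is.null(w)) return(rep(1, n))
  if (any(is.na(w)) || any(w < 0)) {
    stop("weights must be non-negative and non-missing", call. = FALSE)
  }
  w / mean(w)
}

# model frame shared by all opinion fits; complete cases only
.opinion_frame <- function(records, include_year = FALSE) {
  need <- c("opinion_adv", "df_std", "education_std", "age_std",
            "media_std", "woman", "ethnicity")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(
    opinion_adv = records$opinion_adv,
    df_std = records$df_std,
    education_std = records$education_std,
    woman = records$woman,
    age_std = records$age_std,
    black = as.integer(records$ethnicity == "black"),
    other = as.integer(records$ethnicity == "other"),
    media_std = records$media_std
  )
  if (include_year) {
    if (!"wave_year" %in% names(records)) {
      stop("records missing `wave_year`", call. = FALSE)
    }
    d$year_std <- if (length(unique(records$wave_year)) > 1) {
      standardize(records$wave_year)
    } else 0
  }
  for (extra in c("respondent_id", "item_id", "wave_year", "advantage")) {
    if (extra %in% names(records)) d[[extra]] <- records[[extra]]
  }
  d$.w <- .norm_weights(records$weight, nrow(records))
  keep <- complete.cases(d[setdiff(names(d), c("advantage"))])
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message("dropping ", n_drop, " incomplete row(s) from the fit")
  }
  d[keep, , drop = FALSE]
}

.controls <- function(include_year) {
  c("education_std", "woman", "age_std", "black", "other", "media_std",
    if (include_year) "year_std")
}

# run a glm catching the separation symptom
.glm_binomial <- function(formula, data) {
  sep_warn <- FALSE
  msgs <- character()
  environment(formula) <- environment()
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial(), weights = .w),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep_warn <<- TRUE
      } else if (!grepl("non-integer", conditionMessage(w))) {
        msgs <<- c(msgs, conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  est <- coef(fit)
  # diverging coefficients (|log-odds| > 10) mark (quasi-)separation;
  # the glm warning alone also triggers on benign extreme fitted values
  separation <- any(abs(est) > 10, na.rm = TRUE) ||
    (sep_warn && !fit$converged)
  list(fit = fit, separation = separation, messages = msgs)
}

#' Per-issue logistic regression of opinion on discussion frequency
#'
#' Maximum-likelihood logistic fit of holding the advantaged opinion on
#' standardized discussion frequency and the standard controls (education,
#' woman, age, black/other vs white, media use), for one issue within one
#' ideology group. `df_std` is the discussion-frequency effect in log-odds
#' per SD. Year (standardized) is added as a control when
#' `include_year = TRUE` (the repeated-wave design).
#'
#' @param records Survey records for a single issue and group.
#' @param include_year Control for (standardized) survey year.
#' @return A `fit_result` with `model_tag = "per_issue"`. Perfect
#'   separation (or a one-sided outcome) yields a flagged result with
#'   `NA` estimates.
#' @export
fit_issue_logistic <- function(records, include_year = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  d <- .opinion_frame(records, include_year)
  if (nrow(d) == 0) stop("no complete rows to fit", call. = FALSE)
  rhs <- c("df_std", .controls(include_year))
  rhs <- rhs[vapply(rhs, function(v) length(unique(d[[v]])) > 1, TRUE)]
  f <- as.formula(paste("opinion_adv ~", paste(rhs, collapse = " + ")))
  if (length(unique(d$opinion_adv)) < 2) {
    ct <- .coef_table(setNames(rep(NA_real_, length(rhs) + 1),
                               c("(Intercept)", rhs)),
                     rep(NA_real_, length(rhs) + 1))
    return(.fit_result("per_issue", ct, n_rows = nrow(d),
                       method = "glm (binomial ML)", converged = FALSE,
                       separation = TRUE,
                       messages = "single-valued outcome"))
  }
  res <- .glm_binomial(f, d)
  est <- coef(res$fit)
  se <- sqrt(diag(vcov(res$fit)))
  ct <- .coef_table(est, se)
  if (res$separation) {
    ct$estimate <- NA_real_
    ct$se <- NA_real_
    ct$ci_lo <- NA_real_
    ct$ci_hi <- NA_real_
  }
  .fit_result("per_issue", ct, n_rows = nrow(d),
              method = "glm (binomial ML, pseudo-likelihood weights)",
              converged = res$fit$converged, separation = res$separation,
              messages = res$messages)
}

.glmm_formula <- function(rhs_fixed, re_terms) {
  as.formula(paste("opinion_adv ~",
                   paste(c(rhs_fixed, re_terms), collapse = " + ")))
}

.fit_glmm <- function(d, rhs_fixed, model_tag, nAGQ) {
  d$issue_wave <- interaction(d$item_id, d$wave_year, drop = TRUE)
  re <- c(individual = "respondent_id", issue = "item_id",
          issue_wave = "issue_wave")
  lev <- vapply(re, function(v) length(unique(d[[v]])), integer(1))
  drop_iw <- lev[["issue_wave"]] == lev[["issue"]]
  use <- re
  if (drop_iw) {
    warning("single wave per issue: issue-wave intercept dropped",
            call. = FALSE)
    use <- use[names(use) != "issue_wave"]
  }
  if (lev[["issue"]] == 1) {
    warning("single issue: issue (and issue-wave) intercepts dropped",
            call. = FALSE)
    use <- use[!names(use) %in% c("issue", "issue_wave")]
  }
  re_terms <- sprintf("(1 | %s)", use)
  f <- .glmm_formula(rhs_fixed, re_terms)
  environment(f) <- environment()
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::glmer(f, data = d, family = binomial(), weights = .w,
                nAGQ = nAGQ,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      if (!grepl("non-integer", conditionMessage(w))) {
        msgs <<- c(msgs, conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  vc <- lme4::VarCorr(fit)
  re_sd <- vapply(names(use), function(nm) {
    attr(vc[[use[[nm]]]], "stddev")[[1]]
  }, numeric(1))
  conv_fail <- any(grepl("failed to converge|convergence code",
                         msgs, ignore.case = TRUE))
  .fit_result(
    model_tag, .coef_table(est, se), re_sd = re_sd, n_rows = nrow(d),
    n_groups = vapply(use, function(v) length(unique(d[[v]])), integer(1)),
    method = sprintf(
      "glmer ML (%s), calc.derivs=FALSE, pseudo-likelihood weights",
      if (nAGQ == 0) "nAGQ=0 PIRLS approximation" else "Laplace nAGQ=1"),
    converged = !conv_fail, messages = msgs
  )
}

.fit_glm_cluster <- function(d, rhs_fixed, model_tag) {
  f <- as.formula(paste("opinion_adv ~",
                        paste(rhs_fixed, collapse = " + ")))
  res <- .glm_binomial(f, d)
  vc <- sandwich::vcovCL(res$fit, cluster = d$respondent_id)
  est <- coef(res$fit)
  se <- sqrt(diag(vc))
  .fit_result(
    model_tag, .coef_table(est, se), n_rows = nrow(d),
    n_groups = c(individual = length(unique(d$respondent_id)),
                 issue = length(unique(d$item_id))),
    method = paste("pooled glm fallback, cluster-robust (individual)",
                   "SEs; no random intercepts"),
    converged = res$fit$converged, separation = res$separation,
    messages = res$messages
  )
}

#' Pooled discussion-frequency effect (model M1)
#'
#' Pools one ideology group's data across issues and waves and fits a
#' logistic model with crossed Gaussian random intercepts for individual,
#' issue, and issue-wave, plus the standard controls. `df_std` is the
#' pooled discussion-frequency effect in log-odds per SD.
#'
#' @param records Survey records (across issues and waves).
#' @param group Optional ideology group to subset on (`"liberal"`,
#'   `"moderate"`, `"conservative"`).
#' @param method `"glmm"` (lme4, the default) or `"glm_cluster"`, a
#'   clearly labeled fallback: pooled logistic regression with
#'   cluster-robust (by individual) standard errors and no random
#'   intercepts.
#' @param nAGQ Likelihood approximation for `glmer`: 0 (fast penalized
#'   iteratively reweighted least squares approximation, the default) or
#'   1 (Laplace). Recorded in the result's `method` field.
#' @param include_year Control for standardized survey year (default
#'   `TRUE` when several waves are present).
#' @return A `fit_result` with `model_tag = "M1"`, random-intercept SDs
#'   in `re_sd`, and group counts in `n_groups`.
#' @export
fit_pooled_m1 <- function(records, group = NULL, method = c("glmm",
                                                            "glm_cluster"),
                          nAGQ = 0,
                          include_year = length(unique(
                            records$wave_year)) > 1) {
  method <- match.arg(method)
  if (!is.null(group)) {
    records <- records[records$ideology3 %in% group, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no rows for this group", call. = FALSE)
  if (length(unique(records$item_id)) < 2) {
    stop("pooled M1 needs at least 2 issues", call. = FALSE)
  }
  d <- .opinion_frame(records, include_year)
  rhs <- c("df_std", .controls(include_year))
  rhs <- rhs[vapply(rhs, function(v) length(unique(d[[v]])) > 1, TRUE)]
  if (method == "glmm") .fit_glmm(d, rhs, "M1", nAGQ)
  else .fit_glm_cluster(d, rhs, "M1")
}

#' Pooled model with advantage moderation (model M2)
#'
#' Extends M1 with the item's HVFL argument advantage — centered at the
#' item mean and multiplied by 10, so one unit corresponds to 0.1 on the
#' raw advantage scale — and its interaction with discussion frequency.
#' The interaction `df_std:adv10` measures how the discussion-frequency
#' effect shifts per 0.1 of advantage.
#'
#' @inheritParams fit_pooled_m1
#' @param advantage Optional named vector of per-item advantages keyed by
#'   `item_id`; taken from the records' `advantage` column when absent.
#' @return A `fit_result` with `model_tag = "M2"`.
#' @export
fit_pooled_m2 <- function(records, group = NULL, advantage = NULL,
                          method = c("glmm", "glm_cluster"), nAGQ = 0,
                          include_year = length(unique(
                            records$wave_year)) > 1) {
  method <- match.arg(method)
  if (!is.null(group)) {
    records <- records[records$ideology3 %in% group, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no rows for this group", call. = FALSE)
  if (!is.null(advantage)) {
    idx <- match(as.character(records$item_id), names(advantage))
    if (anyNA(idx)) {
      stop("`advantage` missing for item(s): ",
           paste(unique(records$item_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    records$advantage <- unname(advantage[idx])
  }
  if (!"advantage" %in% names(records) || anyNA(records$advantage)) {
    stop("an advantage value is required for every item", call. = FALSE)
  }
  if (length(unique(records$item_id)) < 2) {
    stop("pooled M2 needs at least 2 issues", call. = FALSE)
  }
  d <- .opinion_frame(records, include_year)
  per_item <- tapply(d$advantage, d$item_id, function(a) a[1])
  if (sd(per_item) == 0) {
    stop("advantage is constant across items: the interaction is ",
         "inestimable", call. = FALSE)
  }
  d$adv10 <- (d$advantage - mean(per_item)) * 10
  rhs_ctrl <- .controls(include_year)
  rhs_ctrl <- rhs_ctrl[vapply(rhs_ctrl,
                              function(v) length(unique(d[[v]])) > 1,
                              TRUE)]
  rhs <- c("df_std", "adv10", "df_std:adv10", rhs_ctrl)
  if (method == "glmm") .fit_glmm(d, rhs, "M2", nAGQ)
  else .fit_glm_cluster(d, rhs, "M2")
}

#' Opinion change rate for one issue
#'
#' Logistic regression of holding the advantaged opinion on time measured
#' in decades, pooling all waves of one issue. The slope is the change
#' rate in log odds per 10 years; its sign says whether the opinion has
#' gained or lost popularity.
#'
#' @param records Survey records for one issue across at least 2 waves.
#' @param reference_year Year mapped to 0 on the decade scale (default:
#'   earliest wave present).
#' @return One-row data frame of class `change_rate`: `item_id`, `slope`,
#'   `se`, `n`, `separation`.
#' @export
fit_change_rate <- function(records, reference_year = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  keep <- !is.na(records$opinion_adv) & !is.na(records$wave_year)
  records <- records[keep, , drop = FALSE]
  waves <- unique(records$wave_year)
  if (length(waves) < 2) {
    stop("change rate needs at least 2 distinct waves", call. = FALSE)
  }
  if (is.null(reference_year)) reference_year <- min(waves)
  d <- data.frame(
    opinion_adv = records$opinion_adv,
    decade = decade_time(records$wave_year, reference_year),
    .w = .norm_weights(records$weight, nrow(records))
  )
  item <- if ("item_id" %in% names(records)) {
    as.character(records$item_id[1])
  } else NA_character_
  if (length(unique(d$opinion_adv)) < 2) {
    return(structure(
      data.frame(item_id = item, slope = NA_real_, se = NA_real_,
                 n = nrow(d), separation = TRUE,
                 stringsAsFactors = FALSE),
      class = c("change_rate", "data.frame")))
  }
  res <- .glm_binomial(opinion_adv ~ decade, d)
  slope <- coef(res$fit)[["decade"]]
  se <- sqrt(diag(vcov(res$fit)))[["decade"]]
  if (res$separation) {
    slope <- NA_real_
    se <- NA_real_
  }
  structure(
    data.frame(item_id = item, slope = slope, se = se, n = nrow(d),
               separation = res$separation, stringsAsFactors = FALSE),
    class = c("change_rate", "data.frame"))
}

#' Change rates for every issue in a record table
#'
#' @param records Survey records across issues; issues with fewer than 2
#'   waves are skipped with a message.
#' @param reference_year Passed to [fit_change_rate()].
#' @return Data frame with one `change_rate` row per estimable item.
#' @export
change_rate_table <- function(records, reference_year = NULL) {
  ids <- unique(records$item_id)
  rows <- lapply(ids, function(id) {
    r <- records[records$item_id == id, , drop = FALSE]
    tryCatch(fit_change_rate(r, reference_year), error = function(e) {
      message("skipping item ", id, ": ", conditionMessage(e))
      NULL
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
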