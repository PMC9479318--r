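# The five prediction tests: alignment of advantage with liberal
# popularity, advantage-proportional opinion change, the positive DF
# effect among liberals, its moderation by advantage, and the near-null
# DF effect among conservatives.

#' Prediction 1: advantage aligns with liberal popularity
#'
#' Counts items for which the sign of the HVFL argument advantage agrees
#' with the sign of (liberal prevalence - conservative prevalence) of the
#' stated opinion. Ties in prevalence (or zero advantage) count as
#' non-aligned and are reported.
#'
#' @param advantage Per-item advantage scores.
#' @param lib_prev,cons_prev Per-item prevalence of the stated opinion
#'   among liberals and conservatives (pooled over waves).
#' @param item_id Optional item identifiers.
#' @return List with `n_aligned`, `n_total`, `n_ties`, and a `detail`
#'   data frame.
#' @export
test_prediction1 <- function(advantage, lib_prev, cons_prev,
                             item_id = NULL) {
  n <- length(advantage)
  if (length(lib_prev) != n || length(cons_prev) != n) {
    stop("`advantage`, `lib_prev`, `cons_prev` must have equal length",
         call. = FALSE)
  }
  if (is.null(item_id)) item_id <- paste0("item", seq_len(n))
  lean <- lib_prev - cons_prev
  tie <- lean == 0 | advantage == 0
  aligned <- !tie & sign(advantage) == sign(lean)
  if (any(tie)) {
    message(sum(tie), " item(s) with tied prevalence or zero advantage ",
            "counted as non-aligned")
  }
  list(n_aligned = sum(aligned), n_total = n, n_ties = sum(tie),
       detail = data.frame(item_id = item_id, advantage = advantage,
                           liberal_lean = lean, aligned = aligned,
                           stringsAsFactors = FALSE))
}

#' Prediction 2: advantage predicts opinion change
#'
#' Pearson correlation between per-item HVFL argument advantage and
#' estimated opinion change rates (log odds per decade), with a Fisher-z
#' confidence interval, plus the scatter table.
#'
#' @param advantage Per-item advantage scores (at least 4 items).
#' @param change_rate Per-item change rates, same length.
#' @param level Confidence level (default 0.95).
#' @return List with `r`, `ci`, `n_items`, and `table`.
#' @export
test_prediction2 <- function(advantage, change_rate, level = 0.95) {
  ok <- !is.na(advantage) & !is.na(change_rate)
  if (sum(ok) < 4) {
    stop("need at least 4 items with advantage and change rate",
         call. = FALSE)
  }
  a <- advantage[ok]
  cr <- change_rate[ok]
  if (sd(a) == 0 || sd(cr) == 0) {
    stop("zero variance in advantage or change rate", call. = FALSE)
  }
  r <- cor(a, cr)
  list(r = r, ci = .fisher_ci(r, sum(ok), level), n_items = sum(ok),
       table = data.frame(advantage = a, change_rate = cr))
}

#' Predictions 3 and 5: discussion-frequency effects by ideology
#'
#' Reads the pooled discussion-frequency coefficient (`df_std`) from M1
#' fits for each ideology group and reports: whether the liberal effect's
#' CI lies above zero (Prediction 3), whether the conservative effect's CI
#' covers zero (Prediction 5), and whether the conservative effect is
#' smaller in magnitude than the liberal one.
#'
#' @param fits Named list of `fit_result` objects, with at least
#'   `liberal` and `conservative` entries.
#' @return List with `effects` (one row per group: estimate, se, ci),
#'   `p3_positive`, `p5_covers_zero`, `ordering_holds` (or `NA` when the
#'   two estimates are exactly equal).
#' @export
test_df_effects <- function(fits) {
  if (!all(c("liberal", "conservative") %in% names(fits))) {
    stop("`fits` must contain liberal and conservative fit results",
         call. = FALSE)
  }
  rows <- lapply(names(fits), function(g) {
    r <- coef_row(fits[[g]], "df_std")
    cbind(data.frame(group = g, stringsAsFactors = FALSE), r)
  })
  eff <- do.call(rbind, rows)
  lib <- eff[eff$group == "liberal", ]
  con <- eff[eff$group == "conservative", ]
  ordering <- if (isTRUE(all.equal(abs(con$estimate), lib$estimate))) {
    NA
  } else {
    abs(con$estimate) < lib$estimate
  }
  list(effects = eff,
       p3_positive = lib$ci_lo > 0,
       p5_covers_zero = con$ci_lo <= 0 && con$ci_hi >= 0,
       ordering_holds = ordering)
}

#' Prediction 4, trend form: slope difference between discussion splits
#'
#' Regresses per-item change rates on per-item advantage separately for
#' frequently and infrequently discussing subsamples and reports both
#' slopes plus their difference (frequent minus infrequent), with a
#' heteroskedasticity-robust CI from the interaction term of the stacked
#' item-level regression.
#'
#' @param rate_frequent,rate_infrequent Per-item change rates estimated on
#'   the frequent- and infrequent-discusser subsamples (same item order).
#' @param advantage Per-item advantage scores.
#' @param level Confidence level (default 0.95).
#' @return List with `slope_frequent`, `slope_infrequent`, `difference`,
#'   `se`, `ci`, `n_items`.
#' @export
fig5_slope_difference <- function(rate_frequent, rate_infrequent,
                                  advantage, level = 0.95) {
  ok <- !is.na(rate_frequent) & !is.na(rate_infrequent) & !is.na(advantage)
  if (sum(ok) < 4) {
    stop("need at least 4 items with change rates in both splits",
         call. = FALSE)
  }
  a <- advantage[ok]
  stacked <- data.frame(
    rate = c(rate_infrequent[ok], rate_frequent[ok]),
    adv = c(a, a),
    frequent = rep(c(0, 1), each = sum(ok))
  )
  fit <- stats::lm(rate ~ adv * frequent, data = stacked)
  vc <- sandwich::vcovHC(fit, type = "HC3")
  est <- coef(fit)
  slope_inf <- est[["adv"]]
  diff <- est[["adv:frequent"]]
  se <- sqrt(vc["adv:frequent", "adv:frequent"])
  q <- qnorm(1 - (1 - level) / 2)
  list(slope_frequent = slope_inf + diff, slope_infrequent = slope_inf,
       difference = diff, se = se, ci = c(diff - q * se, diff + q * se),
       n_items = sum(ok))
}

#' Median split of liberals by discussion frequency
#'
#' Splits one group's records at the within-group median of standardized
#' discussion frequency; values strictly above the median are "frequent".
#'
#' @param records Survey records (already subset to one group, typically
#'   liberals).
#' @return The records with a `df_split` column
#'   (`"frequent"`/`"infrequent"`).
#' @export
df_median_split <- function(records) {
  med <- stats::median(records$df_std, na.rm = TRUE)
  records$df_split <- ifelse(records$df_std > med, "frequent",
                             "infrequent")
  records
}
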