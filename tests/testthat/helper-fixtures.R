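# shared in-code fixtures

# one judgment row with all 14 dummies defaulting to 0
judgment_row <- function(..., ideology = "liberal", item_id = "item1",
                         participant_id = "p1") {
  vals <- setNames(rep(0L, 14L), dummy_columns())
  over <- list(...)
  stopifnot(all(names(over) %in% names(vals)))
  vals[names(over)] <- unlist(over)
  cbind(data.frame(participant_id = participant_id, item_id = item_id,
                   ideology = ideology, answer = "yes",
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(vals)))
}

# the worked endorsement pattern: fairness+harm for yes, liberty for no
worked_example_row <- function() {
  judgment_row(yes_fairness = 1L, yes_harm = 1L, no_liberty = 1L)
}

# minimal analysis-ready survey records built directly (no DGP)
manual_records <- function(opinion, df, weight = NULL, wave = 2000,
                           item = "item1", group = "liberal") {
  n <- length(opinion)
  data.frame(
    respondent_id = paste0("r", seq_len(n)),
    item_id = item,
    wave_year = rep_len(wave, n),
    opinion_adv = opinion,
    ideology3 = rep_len(group, n),
    df_std = df,
    education_std = 0,
    age_std = 0,
    media_std = 0,
    woman = 0L,
    ethnicity = "white",
    weight = if (is.null(weight)) rep(1, n) else weight,
    stringsAsFactors = FALSE
  )
}

# hand-built fit_result carrying a df_std coefficient
stub_fit <- function(estimate, se) {
  ct <- data.frame(term = c("(Intercept)", "df_std"),
                   estimate = c(0, estimate), se = c(0.1, se),
                   ci_lo = c(0, estimate) - qnorm(0.975) * c(0.1, se),
                   ci_hi = c(0, estimate) + qnorm(0.975) * c(0.1, se),
                   stringsAsFactors = FALSE)
  moralargs:::.fit_result("M1", ct, method = "stub", converged = TRUE)
}
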