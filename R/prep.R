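#' Collapse 7-point ideology to a ternary label
#'
#' Steps 1-3 are liberal, step 4 moderate, steps 5-7 conservative; missing
#' values propagate.
#'
#' @param score7 Integer vector with values in 1..7 (or `NA`).
#' @return Character vector of `"liberal"`, `"moderate"`,
#'   `"conservative"`, or `NA`.
#' @export
ternary_ideology <- function(score7) {
  ok <- is.na(score7) | (score7 %in% 1:7)
  if (!all(ok)) {
    stop("`score7` must be integers 1-7 (got ",
         paste(unique(score7[!ok]), collapse = ", "), ")", call. = FALSE)
  }
  lab <- c("liberal", "liberal", "liberal", "moderate",
           "conservative", "conservative", "conservative")
  out <- rep(NA_character_, length(score7))
  out[!is.na(score7)] <- lab[score7[!is.na(score7)]]
  out
}

#' Response-polarity map for one item
#'
#' Records which raw response codes express the HVFL-advantaged opinion,
#' which the disadvantaged one, and which are neutral or missing.
#'
#' @param item_id Item identifier.
#' @param codes Named character vector: names are raw response codes (as
#'   character), values in `advantaged`, `disadvantaged`, `neutral`,
#'   `missing`. At least one code must map to each of
#'   advantaged/disadvantaged.
#' @param advantage Optional advantage score of the item.
#' @return Object of class `polarity_map`.
#' @export
polarity_map <- function(item_id, codes, advantage = NA_real_) {
  allowed <- c("advantaged", "disadvantaged", "neutral", "missing")
  if (is.null(names(codes)) || !all(codes %in% allowed)) {
    stop("`codes` must be a named vector with values in ",
         paste(allowed, collapse = "/"), call. = FALSE)
  }
  if (!any(codes == "advantaged") || !any(codes == "disadvantaged")) {
    stop("`codes` must map at least one code to each side", call. = FALSE)
  }
  structure(list(item_id = item_id, codes = codes, advantage = advantage),
            class = "polarity_map")
}

#' Dichotomize raw opinion responses
#'
#' Graded responses collapse to their side (1 = advantaged opinion,
#' 0 = disadvantaged); neutral and missing-coded responses become `NA`;
#' `NA` input propagates. A raw code absent from the map is an error.
#'
#' @param raw Vector of raw response codes.
#' @param polarity A [polarity_map()] for the item.
#' @return Integer vector of 1/0/`NA`.
#' @export
dichotomize_opinion <- function(raw, polarity) {
  if (!inherits(polarity, "polarity_map")) {
    stop("`polarity` must be a `polarity_map`", call. = FALSE)
  }
  chr <- as.character(raw)
  known <- is.na(chr) | chr %in% names(polarity$codes)
  if (!all(known)) {
    stop("unmapped response code(s) for item ", polarity$item_id, ": ",
         paste(unique(chr[!known]), collapse = ", "), call. = FALSE)
  }
  side <- polarity$codes[chr]
  out <- rep(NA_integer_, length(raw))
  out[!is.na(side) & side == "advantaged"] <- 1L
  out[!is.na(side) & side == "disadvantaged"] <- 0L
  out
}

#' Combine newspaper and TV news exposure into one media-use score
#'
#' Takes the maximum of days-per-week newspaper reading and days-per-week
#' national TV news watching; when one is missing the other is used, and
#' both missing gives `NA`.
#'
#' @param newspaper_days,tv_news_days Numeric vectors in 0-7 (or `NA`).
#' @return Numeric vector of combined media use.
#' @export
media_use_combine <- function(newspaper_days, tv_news_days) {
  for (v in list(newspaper_days, tv_news_days)) {
    if (any(!is.na(v) & (v < 0 | v > 7))) {
      stop("media-use items must lie in 0-7", call. = FALSE)
    }
  }
  pmax(newspaper_days, tv_news_days, na.rm = TRUE)
}

#' Standardize a variable over the analysis sample
#'
#' Centers to mean 0 and scales to SD 1 using the non-missing values of
#' the rows entering the specific fit. Standardizing an already
#' standardized vector leaves it unchanged (idempotence).
#'
#' @param x Numeric vector with at least 2 non-missing values and
#'   positive SD.
#' @return Numeric vector of z-scores (missing values propagate).
#' @export
standardize <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2) {
    stop("need at least 2 non-missing values to standardize",
         call. = FALSE)
  }
  s <- sd(v)
  if (s == 0) {
    stop("cannot standardize a constant column", call. = FALSE)
  }
  (x - mean(v)) / s
}

#' Time in decades relative to a reference year
#'
#' @param year Numeric survey years.
#' @param reference_year Reference year (0 on the decade scale).
#' @return `(year - reference_year) / 10`.
#' @export
decade_time <- function(year, reference_year) {
  (year - reference_year) / 10
}

#' Prepare a raw survey extract for analysis
#'
#' Applies the full recoding chain to a long raw table (one row per
#' respondent x item): dichotomization through per-item polarity maps,
#' ternary ideology, media-use combination, and standardization of the
#' continuous covariates over the prepared sample. The recoding is pure:
#' row order never affects per-row output.
#'
#' @param raw Data frame with columns `respondent_id`, `item_id`,
#'   `wave_year`, `response`, `ideology7`, `df_raw`, `education`, `age`,
#'   `woman`, `ethnicity`, `weight`, and either `media` or the pair
#'   `newspaper_days`/`tv_news_days`.
#' @param polarities Named list of [polarity_map()] objects keyed by
#'   `item_id`.
#' @return Data frame of analysis-ready survey records (columns as in
#'   [gen_survey()]'s `records`), with an `advantage` column when the
#'   polarity maps carry one.
#' @export
prepare_survey <- function(raw, polarities) {
  need <- c("respondent_id", "item_id", "wave_year", "response",
            "ideology7", "df_raw", "education", "age", "woman",
            "ethnicity", "weight")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("`raw` is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(polarities))) {
    names(polarities) <- vapply(polarities, function(p) {
      as.character(p$item_id)
    }, character(1))
  }
  unknown <- setdiff(unique(raw$item_id), names(polarities))
  if (length(unknown) > 0) {
    stop("no polarity map for item(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  opinion <- rep(NA_integer_, nrow(raw))
  adv <- rep(NA_real_, nrow(raw))
  for (id in unique(raw$item_id)) {
    rows <- raw$item_id == id
    opinion[rows] <- dichotomize_opinion(raw$response[rows],
                                         polarities[[as.character(id)]])
    adv[rows] <- polarities[[as.character(id)]]$advantage
  }
  media <- if ("media" %in% names(raw)) {
    raw$media
  } else if (all(c("newspaper_days", "tv_news_days") %in% names(raw))) {
    media_use_combine(raw$newspaper_days, raw$tv_news_days)
  } else {
    stop("`raw` needs a `media` column or newspaper_days/tv_news_days",
         call. = FALSE)
  }
  out <- data.frame(
    respondent_id = raw$respondent_id,
    item_id = raw$item_id,
    wave_year = raw$wave_year,
    opinion_adv = opinion,
    ideology3 = ternary_ideology(raw$ideology7),
    ideology7 = raw$ideology7,
    df_raw = raw$df_raw,
    df_std = standardize(raw$df_raw),
    education_std = standardize(raw$education),
    age_std = standardize(raw$age),
    media_std = standardize(media),
    woman = raw$woman,
    ethnicity = raw$ethnicity,
    weight = raw$weight,
    advantage = adv,
    stringsAsFactors = FALSE
  )
  n_drop <- sum(is.na(out$opinion_adv))
  if (n_drop > 0) {
    message(n_drop, " row(s) have neutral/missing opinions and will drop ",
            "from complete-case fits")
  }
  out
}
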