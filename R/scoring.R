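#' Per-participant HVFL argument advantage
#'
#' For one argument-endorsement record, the advantage of the "yes" opinion
#' is the mean of the four yes-side HVFL dummies minus the mean of the four
#' no-side HVFL dummies:
#' (yes_harm + yes_violence + yes_fairness + yes_liberty)/4 -
#' (no_harm + no_violence + no_fairness + no_liberty)/4.
#' The theoretical range is \[-1, 1\]. A judge who ticked fairness and harm
#' for "yes" and liberty for "no" scores 1/2 - 1/4 = 0.25.
#'
#' Non-HVFL dummies (authority, loyalty, purity) may be present but never
#' enter the score.
#'
#' @param judgments A data frame of judgment rows, or a single named
#'   vector/list, containing the eight HVFL dummy columns
#'   `yes_harm`, `yes_violence`, `yes_fairness`, `yes_liberty`,
#'   `no_harm`, `no_violence`, `no_fairness`, `no_liberty`, each 0/1.
#' @return Numeric vector of per-row advantage scores in \[-1, 1\].
#' @export
#' @examples
#' participant_advantage(c(yes_fairness = 1, yes_harm = 1, yes_violence = 0,
#'                         yes_liberty = 0, no_liberty = 1, no_harm = 0,
#'                         no_violence = 0, no_fairness = 0))
participant_advantage <- function(judgments) {
  if (!is.data.frame(judgments)) {
    judgments <- as.data.frame(as.list(judgments))
  }
  need <- c(paste0("yes_", .hvfl), paste0("no_", .hvfl))
  missing_cols <- setdiff(need, names(judgments))
  if (length(missing_cols) > 0) {
    stop("missing HVFL dummy column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(judgments[need])
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    bad <- need[colSums(is.na(m) | !(m == 0 | m == 1)) > 0]
    stop("HVFL dummies must be 0/1 with no missing values; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rowMeans(m[, paste0("yes_", .hvfl), drop = FALSE]) -
    rowMeans(m[, paste0("no_", .hvfl), drop = FALSE])
}

#' Item-level HVFL argument advantage estimate
#'
#' Averages the per-participant advantage score over all judges of one item
#' and reports the standard error of that mean (sample SD with n-1
#' denominator divided by sqrt(n); `NA` when n < 2). Sub-means based only
#' on liberal and only on conservative judges are reported when those
#' subsets are non-empty (judges with ideology `"other"` enter the overall
#' mean but neither sub-mean).
#'
#' @param judgments Data frame of judgment rows for a single item (columns
#'   as in [participant_advantage()] plus optionally `item_id` and
#'   `ideology`).
#' @param item_id Optional item identifier; taken from the data if absent.
#' @return One-row data frame with columns `item_id`, `mean`, `se`,
#'   `n_judges`, `mean_liberal_based`, `mean_conservative_based`.
#' @export
item_advantage <- function(judgments, item_id = NULL) {
  if (!is.data.frame(judgments) || nrow(judgments) == 0) {
    stop("`judgments` must be a non-empty data frame", call. = FALSE)
  }
  if (is.null(item_id)) {
    item_id <- if ("item_id" %in% names(judgments)) {
      ids <- unique(judgments$item_id)
      if (length(ids) != 1) {
        stop("`judgments` spans several items; filter to one or use ",
             "`advantage_table()`", call. = FALSE)
      }
      ids
    } else NA_character_
  }
  score <- participant_advantage(judgments)
  n <- length(score)
  ideol <- if ("ideology" %in% names(judgments)) {
    as.character(judgments$ideology)
  } else rep(NA_character_, n)
  sub_mean <- function(keep) if (any(keep)) mean(score[keep]) else NA_real_
  data.frame(
    item_id = item_id,
    mean = mean(score),
    se = if (n >= 2) sd(score) / sqrt(n) else NA_real_,
    n_judges = n,
    mean_liberal_based = sub_mean(ideol == "liberal"),
    mean_conservative_based = sub_mean(ideol == "conservative"),
    stringsAsFactors = FALSE
  )
}

#' Advantage estimates for every item in a judgment table
#'
#' @param judgments Data frame of judgment rows with an `item_id` column.
#' @return Data frame with one [item_advantage()] row per item, in order of
#'   first appearance.
#' @export
advantage_table <- function(judgments) {
  if (!is.data.frame(judgments) || nrow(judgments) == 0 ||
      !"item_id" %in% names(judgments)) {
    stop("`judgments` must be a non-empty data frame with `item_id`",
         call. = FALSE)
  }
  ids <- unique(judgments$item_id)
  out <- lapply(ids, function(id) {
    item_advantage(judgments[judgments$item_id == id, , drop = FALSE],
                   item_id = id)
  })
  do.call(rbind, out)
}

#' Ideology-split reliability of advantage measures
#'
#' Pearson correlation between liberal-based and conservative-based item
#' advantage sub-means, with a Fisher-z 95% confidence interval. High
#' values indicate that liberals and conservatives agree on which arguments
#' bear on which opinions.
#'
#' @param estimates Data frame of advantage estimates (from
#'   [advantage_table()]) with `mean_liberal_based` and
#'   `mean_conservative_based` columns.
#' @param level Confidence level for the interval (default 0.95).
#' @return List with `r`, `ci` (length-2), and `n_items` (complete pairs).
#' @export
ideology_split_reliability <- function(estimates, level = 0.95) {
  lib <- estimates$mean_liberal_based
  con <- estimates$mean_conservative_based
  ok <- !is.na(lib) & !is.na(con)
  if (sum(ok) < 3) {
    stop("need at least 3 items with both liberal- and conservative-based ",
         "sub-means", call. = FALSE)
  }
  r <- cor(lib[ok], con[ok])
  list(r = r, ci = .fisher_ci(r, sum(ok), level), n_items = sum(ok))
}

#' Filter items by absolute advantage
#'
#' Keeps items whose estimated advantage is at least `min_abs` in absolute
#' value (inclusive), the regime in which the sign of the advantage — and
#' hence the coding of the advantaged opinion — is considered reliable.
#' Each kept item is annotated with `direction`, the sign of its mean
#' (+1: the stated opinion is advantaged; -1: its opposite is).
#'
#' @param estimates Data frame of advantage estimates with a `mean` column.
#' @param min_abs Inclusive threshold on `|mean|` (default 0.1).
#' @return List with data frames `kept` (with `direction` column) and
#'   `dropped`. Warns when no item passes.
#' @export
threshold_filter <- function(estimates, min_abs = 0.1) {
  if (!is.data.frame(estimates) || nrow(estimates) == 0) {
    stop("`estimates` must be a non-empty data frame", call. = FALSE)
  }
  keep <- abs(estimates$mean) >= min_abs
  kept <- estimates[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    warning("no item reaches |advantage| >= ", min_abs, call. = FALSE)
  } else {
    kept$direction <- sign(kept$mean)
  }
  list(kept = kept, dropped = estimates[!keep, , drop = FALSE])
}
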