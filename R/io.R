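# Delimited-text readers and writers for the pipeline's tables. Survey
# container formats are out of scope: users export to CSV/TSV first.

#' Read an argument-judgment table from CSV
#'
#' Accepts either this package's column layout (`yes_harm`, `no_liberty`,
#' ...) or the colon-separated dialect used by published advantage-measure
#' tables (`yes:harm`), which is renamed on the way in.
#'
#' @param path CSV (or TSV) file path.
#' @param sep Field separator (default `","`).
#' @return Data frame of judgments suitable for [advantage_table()].
#' @export
read_judgments <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep, check.names = FALSE,
                stringsAsFactors = FALSE)
  names(d) <- sub("^(yes|no):", "\\1_", names(d))
  names(d) <- make.names(names(d))
  need <- c(paste0("yes_", .hvfl), paste0("no_", .hvfl))
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("judgment file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d
}

#' Write advantage estimates to CSV
#'
#' @param estimates Data frame from [advantage_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_estimates <- function(estimates, path) {
  write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}

#' Read analysis-ready survey records from CSV
#'
#' @param path CSV file path (layout of [gen_survey()]'s `records` or
#'   [prepare_survey()]'s output).
#' @return Data frame of survey records.
#' @export
read_survey_records <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent_id", "item_id", "wave_year", "opinion_adv",
            "ideology3", "df_std")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("survey file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d
}

#' Read polarity maps from a YAML file
#'
#' Expects a top-level mapping from item id to a `codes` mapping (raw
#' code -> side) and an optional `advantage` scalar. Requires the yaml
#' package.
#'
#' @param path YAML file path.
#' @return Named list of [polarity_map()] objects.
#' @export
read_polarity_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML polarity maps requires the yaml package",
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(id) {
    entry <- raw[[id]]
    polarity_map(id, unlist(entry$codes),
                 advantage = if (is.null(entry$advantage)) NA_real_ else
                   entry$advantage)
  })
  setNames(out, names(raw))
}
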