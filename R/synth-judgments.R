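#' Endorsement profile for one item
#'
#' Describes the population probabilities with which each argument kind is
#' judged to apply to the "yes" side and the "no" side of an item. The true
#' HVFL advantage of the item is the mean over the four HVFL kinds of
#' `p_yes[k] - p_no[k]`.
#'
#' @param item_id Item identifier.
#' @param p_yes,p_no Named numeric vectors of endorsement probabilities in
#'   \[0, 1\] over the seven argument kinds (see [argument_kinds()]).
#' @return Object of class `endorsement_profile` with fields `item_id`,
#'   `p_yes`, `p_no`, `true_advantage`.
#' @export
endorsement_profile <- function(item_id, p_yes, p_no) {
  for (what in c("p_yes", "p_no")) {
    p <- get(what)
    if (length(p) != length(.kinds) || is.null(names(p)) ||
        !setequal(names(p), .kinds)) {
      stop(sprintf("`%s` must be named over the seven argument kinds", what),
           call. = FALSE)
    }
    .check_prob(p, what)
  }
  p_yes <- p_yes[.kinds]
  p_no <- p_no[.kinds]
  structure(
    list(item_id = item_id, p_yes = p_yes, p_no = p_no,
         true_advantage = mean(p_yes[.hvfl] - p_no[.hvfl])),
    class = "endorsement_profile"
  )
}

#' Helper: profile with a prescribed true advantage
#'
#' Builds an [endorsement_profile()] whose HVFL endorsement probabilities
#' are `base + advantage/2` (yes side) and `base - advantage/2` (no side),
#' giving `true_advantage == advantage` exactly; non-HVFL kinds are
#' endorsed with probability `p_other`.
#'
#' @param item_id Item identifier.
#' @param advantage Target true advantage; must satisfy
#'   `base + |advantage|/2 <= 1` and `base - |advantage|/2 >= 0`.
#' @param base Baseline HVFL endorsement probability (default 0.4).
#' @param p_other Endorsement probability for authority/loyalty/purity.
#' @return An `endorsement_profile`.
#' @export
profile_with_advantage <- function(item_id, advantage, base = 0.4,
                                   p_other = 0.2) {
  p_yes <- setNames(rep(p_other, length(.kinds)), .kinds)
  p_no <- p_yes
  p_yes[.hvfl] <- base + advantage / 2
  p_no[.hvfl] <- base - advantage / 2
  endorsement_profile(item_id, p_yes, p_no)
}

#' Generate synthetic argument-judgment data
#'
#' Emulates an endorsement survey: each participant sees every item and,
#' for each (side, kind) pair, independently ticks the argument with the
#' profile's probability. Participant ideology is drawn from
#' `ideology_mix`. The recorded `answer` (yes/no, drawn 50/50) is carried
#' for realism but plays no role in scoring.
#'
#' @param profiles List of [endorsement_profile()] objects, one per item.
#' @param n_participants Number of judges; every judge rates every item.
#' @param ideology_mix Named proportions over ideology labels (subset of
#'   liberal/moderate/conservative/other); must sum to 1.
#' @param seed Integer seed; identical inputs give identical tables.
#' @return Data frame with one row per participant x item: columns
#'   `participant_id`, `item_id`, `ideology`, `answer`, and the fourteen
#'   dummy columns of [dummy_columns()].
#' @export
gen_argument_judgments <- function(profiles, n_participants,
                                   ideology_mix = c(liberal = 0.5,
                                                    conservative = 0.5),
                                   seed = 1L) {
  if (!is.list(profiles) || length(profiles) == 0) {
    stop("`profiles` must be a non-empty list of endorsement profiles",
         call. = FALSE)
  }
  if (!all(vapply(profiles, inherits, TRUE, "endorsement_profile"))) {
    stop("every element of `profiles` must be an `endorsement_profile`",
         call. = FALSE)
  }
  n_participants <- .check_count(n_participants, "n_participants")
  .check_mix(ideology_mix, "ideology_mix")

  set.seed(seed)
  ideology <- sample(names(ideology_mix), n_participants, replace = TRUE,
                     prob = ideology_mix)
  rows <- lapply(profiles, function(pr) {
    yes <- vapply(.kinds, function(k) {
      rbinom(n_participants, 1L, pr$p_yes[[k]])
    }, integer(n_participants))
    no <- vapply(.kinds, function(k) {
      rbinom(n_participants, 1L, pr$p_no[[k]])
    }, integer(n_participants))
    yes <- matrix(yes, nrow = n_participants)
    no <- matrix(no, nrow = n_participants)
    d <- data.frame(
      participant_id = paste0("p", seq_len(n_participants)),
      item_id = pr$item_id,
      ideology = ideology,
      answer = sample(c("yes", "no"), n_participants, replace = TRUE),
      stringsAsFactors = FALSE
    )
    colnames(yes) <- paste0("yes_", .kinds)
    colnames(no) <- paste0("no_", .kinds)
    cbind(d, as.data.frame(yes), as.data.frame(no))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
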