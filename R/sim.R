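#' Configuration of the opinion-dynamics simulator
#'
#' Liberal and conservative agents hold one of two opinions on an issue
#' whose HVFL argument advantage is `advantage` (A > 0 favors opinion 1).
#' Each time step an agent initiates a discussion with probability equal to
#' its frequency-class rate; the partner comes from the agent's own
#' ideological group with probability b (the ingroup bias of the
#' initiator's class), otherwise from the other group. Both parties argue
#' their own opinion; an argument is of an HVFL kind with probability
#' (1+A)/2 when the advocated opinion is advantaged and (1-A)/2 otherwise.
#' A listener holding the opposite opinion switches with probability
#' `persuade_prob` when the argument kind is relevant to it: liberals are
#' moved only by HVFL arguments, conservatives by any kind.
#'
#' @param n_agents Total number of agents.
#' @param prop_liberal Proportion of liberal agents (the rest are
#'   conservative); group sizes are allocated deterministically.
#' @param advantage HVFL argument advantage A of opinion 1, in \[-1, 1\].
#' @param persuade_prob Switch probability s given a relevant argument,
#'   in (0, 1\].
#' @param freq_classes Data frame with columns `class` (label), `rate`
#'   (per-step discussion-initiation probability, in (0, 1\]) and `share`
#'   (within-ideology share, summing to 1). Default: two classes,
#'   infrequent (rate 0.01) and frequent (rate 0.05), 50/50, a time scale
#'   on which the advantaged opinion's rise spans the default horizon.
#' @param bias Ingroup bias per class: `"calibrated"` (the default) uses
#'   [calibrate_ingroup_bias()], a single number applies the same constant
#'   bias to every class, and a numeric vector gives one bias per class.
#' @param init_prevalence Named initial prevalence of opinion 1 for
#'   `liberal` and `conservative` agents (allocated exactly per cell).
#' @param horizon Number of time steps T.
#' @param n_replicates Number of independent replicate runs.
#' @param seed Master seed; per-replicate streams are spawned from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_agents = 2000, prop_liberal = 0.5,
                       advantage = 0.2, persuade_prob = 0.5,
                       freq_classes = data.frame(
                         class = c("infrequent", "frequent"),
                         rate = c(0.01, 0.05),
                         share = c(0.5, 0.5)),
                       bias = "calibrated",
                       init_prevalence = c(liberal = 0.5,
                                           conservative = 0.5),
                       horizon = 500, n_replicates = 200, seed = 1L) {
  n_agents <- .check_count(n_agents, "n_agents", min = 2L)
  .check_prob(prop_liberal, "prop_liberal")
  if (!is.numeric(advantage) || abs(advantage) > 1) {
    stop("`advantage` must lie in [-1, 1]", call. = FALSE)
  }
  .check_prob(persuade_prob, "persuade_prob")
  if (!is.data.frame(freq_classes) ||
      !all(c("class", "rate", "share") %in% names(freq_classes))) {
    stop("`freq_classes` needs columns class, rate, share", call. = FALSE)
  }
  if (any(freq_classes$rate <= 0) || any(freq_classes$rate > 1)) {
    stop("`freq_classes$rate` must lie in (0, 1]", call. = FALSE)
  }
  if (abs(sum(freq_classes$share) - 1) > 1e-9) {
    stop("`freq_classes$share` must sum to 1", call. = FALSE)
  }
  b <- if (identical(bias, "calibrated")) {
    calibrate_ingroup_bias(freq_classes$rate)
  } else if (is.numeric(bias) && length(bias) == 1) {
    rep(bias, nrow(freq_classes))
  } else if (is.numeric(bias) && length(bias) == nrow(freq_classes)) {
    bias
  } else {
    stop("`bias` must be \"calibrated\", a scalar, or one value per class",
         call. = FALSE)
  }
  .check_prob(b, "bias")
  .check_mix(init_prevalence / sum(init_prevalence), "init_prevalence")
  .check_prob(init_prevalence, "init_prevalence")
  if (!setequal(names(init_prevalence), c("liberal", "conservative"))) {
    stop("`init_prevalence` must name liberal and conservative",
         call. = FALSE)
  }
  horizon <- .check_count(horizon, "horizon")
  n_replicates <- .check_count(n_replicates, "n_replicates")
  structure(
    list(n_agents = n_agents, prop_liberal = prop_liberal,
         advantage = advantage, persuade_prob = persuade_prob,
         freq_classes = freq_classes, bias = b,
         init_prevalence = init_prevalence, horizon = horizon,
         n_replicates = n_replicates, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Calibrated ingroup-bias schedule
#'
#' Returns the ingroup bias b(f) = 1 - kappa/f with kappa the smallest
#' class rate, so that the cross-ideology contact rate f (1 - b(f)) = kappa
#' is the same for every frequency class. In this regime discussion
#' frequency has exactly zero expected effect on conservatives' opinions:
#' conservative-conservative discussions carry no net drift, and each
#' conservative's exposure to liberals does not depend on its own rate.
#'
#' @param rates Per-step discussion rates of the frequency classes, all
#'   > 0.
#' @return Numeric vector of biases in \[0, 1\), one per class.
#' @export
calibrate_ingroup_bias <- function(rates) {
  if (!is.numeric(rates) || length(rates) < 1 || any(rates <= 0)) {
    stop("`rates` must be positive", call. = FALSE)
  }
  b <- 1 - min(rates) / rates
  if (any(b < 0) || any(b >= 1)) {
    stop("calibration infeasible: bias outside [0, 1)", call. = FALSE)
  }
  b
}

# deterministic agent roster for a config
.sim_agents <- function(config) {
  n <- config$n_agents
  n_lib <- round(n * config$prop_liberal)
  K <- nrow(config$freq_classes)
  alloc <- function(total, shares) {
    cnt <- floor(total * shares)
    rem <- total - sum(cnt)
    if (rem > 0) cnt[seq_len(rem)] <- cnt[seq_len(rem)] + 1
    cnt
  }
  cnt <- c(alloc(n_lib, config$freq_classes$share),
           alloc(n - n_lib, config$freq_classes$share))
  ideology <- rep(c(0L, 1L), times = c(n_lib, n - n_lib))
  cls <- c(rep(seq_len(K) - 1L, times = cnt[seq_len(K)]),
           rep(seq_len(K) - 1L, times = cnt[K + seq_len(K)]))
  cell <- ideology * K + cls
  op0 <- integer(n)
  for (c_id in unique(cell)) {
    idx <- which(cell == c_id)
    p <- config$init_prevalence[[if (c_id < K) "liberal" else
      "conservative"]]
    n1 <- round(length(idx) * p)
    if (n1 > 0) op0[idx[seq_len(n1)]] <- 1L
  }
  list(ideology = ideology, class_idx = cls, cell = cell, opinion0 = op0,
       rate = config$freq_classes$rate[cls + 1L],
       bias = config$bias[cls + 1L], n_cells = 2L * K)
}

#' Run the agent-based opinion-dynamics model
#'
#' Simulates `n_replicates` independent runs of the model described in
#' [sim_config()] and returns the prevalence of the advantaged opinion
#' (opinion 1) in each ideology x frequency-class cell at every time step.
#'
#' @param config A [sim_config()] object.
#' @return Data frame of class `trajectory_set` in long format: columns
#'   `replicate`, `t` (0..horizon), `ideology`, `freq_class`,
#'   `prevalence`; the config is attached as attribute `config`.
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a `sim_config` object", call. = FALSE)
  }
  ag <- .sim_agents(config)
  K <- nrow(config$freq_classes)
  seeds <- .spawn_seeds(config$seed, config$n_replicates)
  cell_ideol <- rep(c("liberal", "conservative"), each = K)
  cell_class <- rep(as.character(config$freq_classes$class), times = 2)
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(seeds[r])
    prev <- sim_run_cpp(ag$opinion0, ag$ideology, ag$rate, ag$bias,
                        ag$cell, ag$n_cells, config$advantage,
                        config$persuade_prob, config$horizon)
    out[[r]] <- data.frame(
      replicate = r,
      t = rep(0:config$horizon, times = ag$n_cells),
      ideology = rep(cell_ideol, each = config$horizon + 1L),
      freq_class = rep(cell_class, each = config$horizon + 1L),
      prevalence = as.vector(prev),
      stringsAsFactors = FALSE
    )
  }
  traj <- do.call(rbind, out)
  attr(traj, "config") <- config
  class(traj) <- c("trajectory_set", class(traj))
  traj
}

#' Expected one-step drift of the advantaged opinion among liberals
#'
#' Closed form for the expected per-step change of the advantaged-opinion
#' prevalence x in a well-mixed liberal population: each within-group
#' encounter between disagreeing liberals yields a net switch probability
#' of s A toward the advantaged opinion (the listener of the advantaged
#' speaker hears an HVFL argument with probability (1+A)/2, the other
#' listener with probability (1-A)/2), encounters occur at `contact_rate`
#' per agent per step and a random pair disagrees with probability
#' 2 x (1 - x):
#' \deqn{E[\Delta x] = 2\, contact\_rate \cdot s A\, x (1 - x).}
#' Used as an independent oracle for the simulated one-step increments.
#' The formula is exact to first order in `contact_rate` (the dilute
#' limit, which covers the package's default rates): at high rates an
#' agent can be a listener in several encounters of the same step, and
#' coincident switch triggers collapse into a single switch, deflating
#' the realized drift by O(contact_rate^2).
#'
#' @param x Prevalence of the advantaged opinion, in \[0, 1\].
#' @param advantage HVFL argument advantage A.
#' @param persuade Switch probability s.
#' @param contact_rate Within-group discussion initiations per agent per
#'   step (rate times ingroup bias).
#' @return Expected change in prevalence over one step.
#' @export
liberal_drift_oracle <- function(x, advantage, persuade, contact_rate) {
  .check_prob(x, "x")
  2 * contact_rate * persuade * advantage * x * (1 - x)
}

#' Discussion-frequency effect in simulated trajectories
#'
#' For each ideology, the prevalence gap (highest-rate class minus
#' lowest-rate class) at a given time step, averaged over replicates, with
#' a bootstrap percentile confidence interval of the replicate-mean gap.
#'
#' @param traj A `trajectory_set` from [run_simulation()].
#' @param at_time Time step at which to evaluate the gap (0..horizon).
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples of the replicate set (default 2000).
#' @return Data frame with one row per ideology: `gap`, `ci_lo`, `ci_hi`,
#'   `n_replicates`.
#' @export
summarize_df_effect <- function(traj, at_time, level = 0.95,
                                n_boot = 2000) {
  config <- attr(traj, "config")
  if (is.null(config)) {
    stop("`traj` must come from run_simulation()", call. = FALSE)
  }
  if (at_time < 0 || at_time > config$horizon) {
    stop("`at_time` must lie in [0, horizon]", call. = FALSE)
  }
  fc <- config$freq_classes
  if (nrow(fc) < 2) {
    stop("need at least 2 frequency classes for a gap", call. = FALSE)
  }
  hi <- as.character(fc$class[which.max(fc$rate)])
  lo <- as.character(fc$class[which.min(fc$rate)])
  snap <- traj[traj$t == at_time, , drop = FALSE]
  alpha <- (1 - level) / 2
  out <- lapply(unique(snap$ideology), function(g) {
    sg <- snap[snap$ideology == g, , drop = FALSE]
    hi_prev <- sg$prevalence[sg$freq_class == hi][order(
      sg$replicate[sg$freq_class == hi])]
    lo_prev <- sg$prevalence[sg$freq_class == lo][order(
      sg$replicate[sg$freq_class == lo])]
    gaps <- hi_prev - lo_prev
    R <- length(gaps)
    boot <- vapply(seq_len(n_boot), function(b) {
      mean(gaps[sample.int(R, R, replace = TRUE)])
    }, numeric(1))
    data.frame(ideology = g, gap = mean(gaps),
               ci_lo = unname(quantile(boot, alpha)),
               ci_hi = unname(quantile(boot, 1 - alpha)),
               n_replicates = R, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plot replicate-mean trajectories
#'
#' Mean prevalence of the advantaged opinion over time per
#' ideology x frequency-class cell (requires ggplot2).
#'
#' @param traj A `trajectory_set` from [run_simulation()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package", call. = FALSE)
  }
  agg <- stats::aggregate(prevalence ~ t + ideology + freq_class,
                          data = traj, FUN = mean)
  ggplot2::ggplot(agg, ggplot2::aes(
    x = .data[["t"]], y = .data[["prevalence"]],
    colour = .data[["ideology"]], linetype = .data[["freq_class"]])) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time step",
                  y = "prevalence of advantaged opinion",
                  colour = "ideology", linetype = "discussion frequency")
}
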