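small_cfg <- function(...) {
  sim_config(n_agents = 400, horizon = 50, n_replicates = 20, seed = 5, ...)
}

test_that("calibrated ingroup bias equalizes cross-ideology contact", {
  b <- calibrate_ingroup_bias(c(0.2, 1.0))
  expect_equal(b, c(0, 0.8))
  expect_equal(c(0.2, 1.0) * (1 - b), rep(0.2, 2))  # f(1-b) constant
  expect_equal(calibrate_ingroup_bias(0.3), 0)       # single class
  expect_equal(calibrate_ingroup_bias(c(1, 1)), c(0, 0))
  expect_error(calibrate_ingroup_bias(c(0, 1)), "positive")
})

test_that("config validation rejects bad probabilities and shares", {
  expect_error(sim_config(advantage = 1.5), "advantage")
  expect_error(sim_config(freq_classes = data.frame(
    class = "a", rate = 0, share = 1)), "rate")
  expect_error(sim_config(freq_classes = data.frame(
    class = c("a", "b"), rate = c(0.1, 0.2), share = c(0.6, 0.6))),
    "share")
  expect_error(sim_config(bias = c(0.2, 0.5, 0.7)), "bias")
})

test_that("prevalences stay in [0, 1] and include the initial state", {
  traj <- run_simulation(small_cfg())
  expect_true(all(traj$prevalence >= 0 & traj$prevalence <= 1))
  expect_equal(sort(unique(traj$t)), 0:50)
  expect_equal(unique(traj$prevalence[traj$t == 0]), 0.5)
})

test_that("zero persuasion probability freezes the initial state", {
  cfg <- sim_config(n_agents = 300, persuade_prob = 0, horizon = 30,
                    n_replicates = 3, seed = 2)
  traj <- run_simulation(cfg)
  for (d in split(traj, list(traj$replicate, traj$ideology,
                             traj$freq_class))) {
    expect_true(all(d$prevalence == d$prevalence[d$t == 0]))
  }
})

test_that("zero advantage leaves the symmetric state driftless", {
  cfg <- sim_config(n_agents = 1000, advantage = 0, horizon = 100,
                    n_replicates = 60, seed = 8)
  traj <- run_simulation(cfg)
  term <- traj[traj$t == 100, ]
  for (cell in split(term$prevalence,
                     list(term$ideology, term$freq_class))) {
    se <- sd(cell) / sqrt(length(cell))
    expect_lt(abs(mean(cell) - 0.5), 3 * se + 1e-9)
  }
})

test_that("relabeling the opinions mirrors the dynamics of -A", {
  pos <- run_simulation(sim_config(n_agents = 800, advantage = 0.3,
                                   horizon = 80, n_replicates = 40,
                                   seed = 4))
  neg <- run_simulation(sim_config(n_agents = 800, advantage = -0.3,
                                   horizon = 80, n_replicates = 40,
                                   seed = 14))
  m_pos <- mean(pos$prevalence[pos$t == 80])
  m_neg <- mean(neg$prevalence[neg$t == 80])
  se <- sqrt(sd(tapply(pos$prevalence[pos$t == 80],
                       pos$replicate[pos$t == 80], mean))^2 / 40 +
             sd(tapply(neg$prevalence[neg$t == 80],
                       neg$replicate[neg$t == 80], mean))^2 / 40)
  expect_lt(abs(m_pos - (1 - m_neg)), 4 * se)
})

test_that("a bigger advantage speeds up the rise", {
  t_small <- run_simulation(sim_config(n_agents = 1000, advantage = 0.1,
                                       horizon = 300, n_replicates = 30,
                                       seed = 6))
  t_big <- run_simulation(sim_config(n_agents = 1000, advantage = 0.3,
                                     horizon = 300, n_replicates = 30,
                                     seed = 6))
  lib_small <- mean(t_small$prevalence[t_small$t == 300 &
                                         t_small$ideology == "liberal"])
  lib_big <- mean(t_big$prevalence[t_big$t == 300 &
                                     t_big$ideology == "liberal"])
  expect_gt(lib_big, lib_small)
})

test_that("simulated one-step drift matches the closed form at small n", {
  cfg <- sim_config(n_agents = 20000, prop_liberal = 1,
                    freq_classes = data.frame(class = "all", rate = 0.05,
                                              share = 1),
                    bias = 1, advantage = 0.2, persuade_prob = 0.5,
                    horizon = 1, n_replicates = 60, seed = 11)
  traj <- run_simulation(cfg)
  lib <- traj[traj$ideology == "liberal", ]
  inc <- vapply(split(lib, lib$replicate),
                function(d) d$prevalence[d$t == 1] - d$prevalence[d$t == 0],
                numeric(1))
  oracle <- liberal_drift_oracle(0.5, 0.2, 0.5, contact_rate = 0.05)
  se <- sd(inc) / sqrt(length(inc))
  expect_lt(abs(mean(inc) - oracle), 3 * se)
})

test_that("drift oracle vanishes at the boundaries and at zero advantage", {
  expect_equal(liberal_drift_oracle(0, 0.3, 0.5, 1), 0)
  expect_equal(liberal_drift_oracle(1, 0.3, 0.5, 1), 0)
  expect_equal(liberal_drift_oracle(0.7, 0, 0.5, 1), 0)
})

test_that("summarize_df_effect reports gaps with bounds checking", {
  traj <- run_simulation(small_cfg())
  g <- summarize_df_effect(traj, at_time = 25)
  expect_setequal(g$ideology, c("liberal", "conservative"))
  expect_true(all(g$ci_lo <= g$gap & g$gap <= g$ci_hi))
  expect_error(summarize_df_effect(traj, at_time = 51), "horizon")
})

test_that("simulation replicates are reproducible from the master seed", {
  t1 <- run_simulation(small_cfg())
  t2 <- run_simulation(small_cfg())
  expect_identical(t1$prevalence, t2$prevalence)
})
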