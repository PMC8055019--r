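test_that("identical config and seed give bit-identical trajectories", {
  cfg <- small_config("dynamic_ranks", rounds = 150)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$final, b$final)
  expect_identical(a$outcome_counts, b$outcome_counts)
  expect_identical(a$rank_history, b$rank_history)
})

test_that("compiled engine matches the per-agent reference bit for bit", {
  for (variant in c("random_interaction", "partner_choice",
                    "dynamic_ranks")) {
    cfg <- small_config(variant, N = 7, rounds = 150, seed = 17)
    a <- run_simulation(cfg, record_interactions = TRUE,
                        engine = "compiled")
    b <- run_simulation(cfg, record_interactions = TRUE,
                        engine = "reference")
    expect_identical(a$final$strategy, b$final$strategy)
    expect_identical(a$final$network, b$final$network)
    expect_identical(a$final$ranks, b$final$ranks)
    expect_identical(a$final$cumulative_payoff, b$final$cumulative_payoff)
    expect_identical(a$final$rank_accumulator, b$final$rank_accumulator)
    expect_identical(a$interactions, b$interactions)
    expect_equal(unname(a$outcome_counts), unname(b$outcome_counts),
                 ignore_attr = TRUE)
    expect_true(all(a$rank_history == b$rank_history))
    expect_equal(a$centralization, b$centralization)
  }
})

test_that("every agent visits exactly once per round; N = 2 is forced", {
  cfg <- small_config("partner_choice", N = 2, rounds = 25, seed = 5)
  traj <- run_simulation(cfg, record_interactions = TRUE)
  log <- traj$interactions
  for (r in unique(log$round)) {
    rec <- log[log$round == r, ]
    expect_equal(sort(rec$visitor), 1:2)
    expect_equal(sort(rec$host), 1:2)    # each agent also hosts once
    expect_true(all(rec$visitor != rec$host))
  }
  cfg6 <- small_config("partner_choice", N = 6, rounds = 40, seed = 6)
  log6 <- run_simulation(cfg6, record_interactions = TRUE)$interactions
  visits <- table(log6$round)
  expect_true(all(visits == 6))
  expect_true(all(log6$visitor != log6$host))
  hostings <- table(factor(log6$host, levels = 1:6), log6$round)
  expect_true(all(hostings >= 0 & hostings <= 5))
})

test_that("logged payoffs agree with the interaction-resolution rule", {
  cfg <- small_config("dynamic_ranks", N = 6, rounds = 100, seed = 23)
  traj <- run_simulation(cfg, record_interactions = TRUE)
  log <- traj$interactions
  for (k in seq_len(nrow(log))) {
    expected <- resolve_interaction(log$visitor_action[k],
                                    log$host_action[k],
                                    log$rank_relation[k], cfg$payoffs)
    expect_equal(log$visitor_payoff[k], unname(expected["visitor"]))
    expect_equal(log$host_payoff[k], unname(expected["host"]))
  }
  # total accumulated payoff equals the sum over all logged interactions
  expect_equal(sum(traj$final$cumulative_payoff),
               sum(log$visitor_payoff) + sum(log$host_payoff))
})

test_that("random interaction keeps the network frozen at initialization", {
  cfg <- small_config("random_interaction", N = 8, rounds = 200, seed = 9)
  traj <- run_simulation(cfg)
  expect_identical(traj$final$network,
                   initialize_weights(8, cfg$learning$L)$network)
  expect_true(all(traj$centralization < 1e-20))
})

test_that("an all-dove population earns dd per interaction on both sides", {
  cfg <- sim_config("partner_choice", N = 5, rounds = 1,
                    payoffs = payoff_params(f = 0.6),
                    learning = learning_params(epsilon = 0), seed = 77)
  set.seed(77)
  st <- initialize_weights(5, 19)
  st$strategy[, c("w_H", "w_h")] <- 0   # dove weight only, in both roles
  state <- c(st, list(ranks = sample.int(5), rank_accumulator = numeric(5),
                      cumulative_payoff = numeric(5)))
  out <- run_round(state, cfg)
  expect_true(all(out$record$visitor_action == "dove"))
  expect_true(all(out$record$host_action == "dove"))
  hosted <- tabulate(out$record$host, nbins = 5)
  expect_equal(out$state$cumulative_payoff,
               cfg$payoffs$dd + cfg$payoffs$dd * hosted)
})

test_that("ranks stay fixed in static variants and update on schedule", {
  cfg <- small_config("partner_choice", rounds = 100, seed = 3)
  traj <- run_simulation(cfg)
  expect_identical(traj$final$ranks, traj$initial_ranks)
  expect_equal(nrow(traj$rank_history), 1L)
  cfgd <- small_config("dynamic_ranks", rounds = 100, seed = 3)
  trajd <- run_simulation(cfgd)   # interval 30: updates at 30, 60, 90
  expect_equal(trajd$rank_history_rounds, c(0, 30, 60, 90))
  # each stored row is the stable-sort of the accumulator at that time
  expect_setequal(trajd$rank_history[4, ], 1:cfgd$N)
})

test_that("the undiscounted accumulator equals total cumulative payoff", {
  cfg <- small_config("dynamic_ranks", rounds = 80, seed = 13,
                      discount_rank_accumulator = FALSE)
  traj <- run_simulation(cfg)
  expect_equal(traj$final$rank_accumulator, traj$final$cumulative_payoff)
  cfg2 <- small_config("dynamic_ranks", rounds = 80, seed = 13,
                       discount_rank_accumulator = TRUE)
  traj2 <- run_simulation(cfg2)
  expect_true(all(traj2$final$rank_accumulator <
                    traj2$final$cumulative_payoff))
})

test_that("sweeps enumerate the grid-by-seed cells deterministically", {
  base <- small_config("partner_choice", N = 4, rounds = 60)
  grid <- data.frame(f = c(0, 0.4, 0.8))
  res <- run_sweep(base, grid, seeds = c(1, 2))
  expect_equal(nrow(res), 6)
  expect_equal(sort(unique(res$f)), c(0, 0.4, 0.8))
  res2 <- run_sweep(base, grid, seeds = c(1, 2))
  expect_equal(res, res2)
  expect_equal(nrow(run_sweep(base, grid[0, , drop = FALSE], seeds = 1)), 0)
  expect_error(run_sweep(base, grid, seeds = c(1, 1)), "distinct")
  expect_error(run_sweep(base, data.frame(q = 1), seeds = 1), "unsupported")
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config("partner_choice", N = 1), "at least 2")
  expect_error(sim_config("partner_choice", rounds = 0), "at least 1")
  expect_error(sim_config("nonsense"), "arg")
  expect_error(sim_config("dynamic_ranks", rank_update_interval = 0), ">= 1")
})
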