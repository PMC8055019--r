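test_that("choice probabilities follow the tremble-mixed proportional rule", {
  expect_equal(choice_probabilities(c(1, 1), epsilon = 0), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(3, 1), epsilon = 0.1),
               c(0.9 * 0.75 + 0.05, 0.9 * 0.25 + 0.05))
  expect_equal(choice_probabilities(c(5, 0, 0), epsilon = 0), c(1, 0, 0))
  expect_error(choice_probabilities(c(-1, 2), 0), "non-negative")
})

test_that("choice probabilities are a valid distribution with the tremble floor", {
  set.seed(501)
  for (k in 1:30) {
    n <- sample(2:20, 1)
    w <- runif(n, 0, 10) * rbinom(n, 1, 0.8)
    eps <- runif(1)
    p <- choice_probabilities(w, eps)
    expect_equal(sum(p), 1)
    expect_true(all(p >= eps / n - 1e-12))
  }
  # epsilon = 1 is uniform regardless of weights
  expect_equal(choice_probabilities(c(9, 1, 0), 1), rep(1 / 3, 3))
  # all-zero weights fall back to uniform
  expect_equal(choice_probabilities(c(0, 0), 0), c(0.5, 0.5))
})

test_that("strategy updates discount everything and reinforce chosen actions", {
  w <- c(hawk = 2, dove = 1.5)
  out <- update_strategy_weights(w, c(hawk = 0.6), delta = 0.01)
  expect_equal(out, c(hawk = 0.99 * 2 + 0.6, dove = 0.99 * 1.5))
  expect_equal(out[["hawk"]], 2.58)
  # no interaction in the role, delta = 0: identity
  expect_equal(update_strategy_weights(w, delta = 0), w)
  # host playing dove twice in one round: summed payoff reinforces once
  out2 <- update_strategy_weights(c(hawk = 1, dove = 1),
                                  c(dove = 0.4 + 0.6), delta = 0.01)
  expect_equal(out2[["dove"]], 0.99 * 1 + 1.0)
  expect_error(update_strategy_weights(w, c(visit = 1), 0.01), "match")
})

test_that("network updates discount all ties and reinforce the visited one", {
  w <- c(0, 1, 1, 1)
  out <- update_network_weights(w, self = 1, visited = 2, payoff = 0.6,
                                delta = 0.01, v = 1)
  expect_equal(out, c(0, 0.99 + 0.6, 0.99, 0.99))
  expect_equal(out[2], 1.59)
  out10 <- update_network_weights(w, 1, 2, 0.6, delta = 0.01, v = 10)
  expect_equal(out10[2] - 0.99, 6)
  # zero payoff: pure decay
  expect_equal(update_network_weights(w, 1, 3, 0, 0.01, 1), 0.99 * w)
  expect_error(update_network_weights(w, 1, 1, 0.5, 0.01, 1), "itself")
})

test_that("weight initialization is uniform at the prescribed scale", {
  init <- initialize_weights(N = 20, L = 19)
  expect_true(all(init$strategy == 1))
  expect_equal(dim(init$strategy), c(20, 4))
  off_diag <- init$network[row(init$network) != col(init$network)]
  expect_true(all(off_diag == 1))
  expect_true(all(diag(init$network) == 0))
  expect_equal(var(colSums(init$network / rowSums(init$network))), 0)
  expect_equal(initialize_weights(39, 19)$network[1, 2], 0.5)
  expect_error(initialize_weights(1), "at least 2")
})

test_that("repeated updates match the closed-form geometric trajectory", {
  delta <- 0.03; pi <- 0.7; k <- 250
  w <- c(hawk = 1, dove = 1)
  for (t in seq_len(k)) w <- update_strategy_weights(w, c(hawk = pi), delta)
  expect_equal(w[["hawk"]], geometric_weight(1, pi, delta, k))
  expect_equal(w[["dove"]], (1 - delta)^k)
  # zero payoffs: geometric decay to zero
  w0 <- c(hawk = 2, dove = 3)
  for (t in 1:100) w0 <- update_strategy_weights(w0, delta = 0.05)
  expect_equal(unname(w0), 0.95^100 * c(2, 3))
})

test_that("hosting payoffs never leak into visiting weights (role firewall)", {
  # replay a recorded trajectory per role; the replayed weights must equal
  # the engine's, proving host and visitor ledgers are independent
  cfg <- small_config("partner_choice", N = 5, rounds = 80, seed = 31)
  traj <- run_simulation(cfg, record_interactions = TRUE)
  replayed <- replay_strategy_weights(traj$interactions, cfg$N, cfg$rounds,
                                      cfg$learning$delta)
  expect_equal(traj$final$strategy, replayed)
  # fuzz: perturbing any hosting payoff changes only host-role columns
  log2 <- traj$interactions
  log2$host_payoff[7] <- log2$host_payoff[7] + 5
  rep2 <- replay_strategy_weights(log2, cfg$N, cfg$rounds,
                                  cfg$learning$delta)
  expect_equal(rep2[, c("w_h", "w_d")], replayed[, c("w_h", "w_d")])
  expect_false(isTRUE(all.equal(rep2[, c("w_H", "w_D")],
                                replayed[, c("w_H", "w_D")])))
})
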