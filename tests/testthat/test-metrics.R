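test_that("strategy classification implements the 0.8-likelihood rule", {
  expect_equal(classify_agent_strategy(0.95, 0.9), "pure_hawk")
  expect_equal(classify_agent_strategy(0.01, 0.98), "host_guest")
  expect_equal(classify_agent_strategy(0.99, 0.1), "ownership")
  expect_equal(classify_agent_strategy(0.1, 0.15), "pure_dove")
  expect_equal(classify_agent_strategy(0.5, 0.5), "mixed")
  expect_error(classify_agent_strategy(1.2, 0.5), "0, 1")
})

test_that("classification partitions and raising the threshold only grows mixed", {
  set.seed(701)
  ph <- runif(200); pv <- runif(200)
  lo <- classify_agent_strategy(ph, pv, threshold = 0.7)
  hi <- classify_agent_strategy(ph, pv, threshold = 0.9)
  expect_true(all(lo %in% c("pure_hawk", "pure_dove", "ownership",
                            "host_guest", "mixed")))
  # anyone mixed at the lower threshold stays mixed at the higher one
  expect_true(all(hi[lo == "mixed"] == "mixed"))
  # non-mixed classes never flip to a different non-mixed class
  moved <- lo != "mixed" & hi != "mixed"
  expect_true(all(lo[moved] == hi[moved]))
})

test_that("centralization reproduces the uniform and star benchmarks", {
  init <- initialize_weights(20, 19)
  expect_equal(network_centralization(init$network), 0)
  # star: 19 spokes visit the hub with probability 1, hub spreads evenly
  star <- matrix(0, 20, 20)
  star[2:20, 1] <- 5       # any positive weight; rows are normalized
  star[1, 2:20] <- 1
  expect_equal(network_centralization(star), 17.95, tolerance = 1e-4)
  expect_equal(network_centralization(star), 6480 / 361)
  # 3-cycle: every in-weight equals 1
  cyc <- matrix(0, 3, 3); cyc[1, 2] <- 1; cyc[2, 3] <- 1; cyc[3, 1] <- 1
  expect_equal(network_centralization(cyc), 0)
})

test_that("centralization is invariant to agent relabeling", {
  set.seed(702)
  w <- matrix(runif(100), 10, 10); diag(w) <- 0
  perm <- sample.int(10)
  expect_equal(network_centralization(w[perm, perm]),
               network_centralization(w))
})

test_that("interaction fractions count the outcome partition", {
  df <- data.frame(
    visitor_action = c("hawk", "hawk", "hawk", "dove"),
    host_action = c("hawk", "dove", "dove", "dove"))
  fr <- interaction_fractions(df)
  expect_equal(fr, c(hawk_hawk = 0.25, host_guest = 0.5, ownership = 0,
                     dove_dove = 0.25))
  expect_equal(sum(fr), 1)
  all_dove <- data.frame(visitor_action = rep("dove", 5),
                         host_action = rep("dove", 5))
  expect_equal(unname(interaction_fractions(all_dove)[1:3]), c(0, 0, 0))
  expect_error(interaction_fractions(df[0, ]), "empty")
})

test_that("cycle estimator recovers synthetic periods and flags constants", {
  saw <- rep(seq_len(40), 6)                      # period 40 sawtooth
  rh <- cbind(saw, rev(saw))
  est <- estimate_cycle_length(rh, sampling_interval = 1000)
  expect_equal(unname(est$per_agent), c(40000, 40000))
  expect_equal(est$mean_cycle_length, 40000)
  # constant series: no-cycle marker
  est2 <- estimate_cycle_length(cbind(rep(3, 50)), 1000)
  expect_true(is.na(est2$mean_cycle_length))
  expect_error(estimate_cycle_length(rh[1:2, ], 1000), "at least 3")
})

test_that("cycle estimator tolerates moderate additive noise", {
  set.seed(703)
  period <- 25
  base <- 10 + 9 * sin(2 * pi * seq_len(300) / period)
  for (k in 1:5) {
    noisy <- base + rnorm(300, sd = 0.1 * 18)  # SD = 10% of the range
    est <- estimate_cycle_length(cbind(noisy), sampling_interval = 1)
    expect_true(abs(est$mean_cycle_length - period) <= 1)
  }
})

test_that("welfare and inequality summarise accumulated payoffs", {
  expect_equal(gini(c(1, 1, 1, 1)), 0)
  expect_equal(gini(c(0, 0, 0, 1)), 0.75)
  expect_equal(gini(numeric(5)), 0)
  expect_error(gini(c(-1, 2)), "non-negative")
  wi <- welfare_and_inequality(c(2, 4, 6))
  expect_equal(wi$total_welfare, 12)
  expect_equal(wi$inequality_index, gini(c(2, 4, 6)))
  expect_equal(wi$payoff_variance, 4)
})

test_that("population convention requires a majority of non-bullies", {
  expect_equal(population_convention(rep("host_guest", 10)), "host_guest")
  expect_equal(population_convention(c(rep("pure_hawk", 6),
                                       rep("ownership", 3), "mixed")),
               "ownership")
  expect_equal(population_convention(c(rep("host_guest", 5),
                                       rep("ownership", 5))), "unresolved")
})
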