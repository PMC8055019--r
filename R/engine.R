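#' Simulation configuration
#'
#' Assembles and validates all parameters of one simulation run.
#'
#' The three model variants share the same round structure — every agent
#' makes exactly one visit per round, actions are drawn from role-specific
#' strategy weights, and all weights are updated simultaneously at the end
#' of the round — and differ only in how partners and ranks evolve:
#'
#' * `random_interaction`: the visit network is frozen at its uniform
#'   initialization (no network learning), so partners are effectively
#'   drawn uniformly at random; ranks are a fixed random permutation.
#' * `partner_choice`: outgoing tie weights are reinforced by visit payoffs
#'   (scaled by `v`), so agents learn whom to visit; ranks stay fixed.
#' * `dynamic_ranks`: partner choice plus ranks recomputed from the payoff
#'   accumulator every `rank_update_interval` rounds.
#'
#' @param variant One of `"partner_choice"`, `"random_interaction"`,
#'   `"dynamic_ranks"`.
#' @param N Population size.
#' @param rounds Number of rounds to simulate.
#' @param payoffs A [payoff_params()] object.
#' @param learning A [learning_params()] object.
#' @param rank_update_interval Rounds between rank updates (dynamic variant
#'   only). The default of 1,000 rounds averages out tremble noise.
#' @param snapshot_every Rounds between recorded snapshots (outcome counts
#'   and network centralization).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state untouched.
#' @param discount_rank_accumulator If `FALSE` (default) the accumulator
#'   that drives rank updates is the raw cumulative payoff sum, so rank
#'   reflects total accumulated wealth: below the critical power asymmetry
#'   the ordering freezes, and above it bullies are overtaken only once the
#'   cooperators' steady income outgrows the bully's hoard. If `TRUE` the
#'   accumulator decays like the learning weights,
#'   `C <- (1 - delta) * C + payoff`, making rank track recent income
#'   instead; this shortens and noisies the rank dynamics considerably.
#' @return An object of class `hd_config`.
#' @examples
#' cfg <- sim_config("partner_choice", rounds = 1000,
#'                   payoffs = payoff_params(f = 0.6), seed = 1)
#' @export
sim_config <- function(variant = c("partner_choice", "random_interaction",
                                   "dynamic_ranks"),
                       N = 20, rounds = 1e6,
                       payoffs = payoff_params(),
                       learning = learning_params(),
                       rank_update_interval = 1000,
                       snapshot_every = 1000,
                       seed = NULL,
                       discount_rank_accumulator = FALSE) {
  variant <- match.arg(variant)
  if (!inherits(payoffs, "hd_payoffs")) payoffs <- do.call(payoff_params,
                                                           payoffs)
  if (!inherits(learning, "hd_learning")) learning <- do.call(learning_params,
                                                              learning)
  N <- as.integer(N); rounds <- as.integer(rounds)
  rank_update_interval <- as.integer(rank_update_interval)
  snapshot_every <- as.integer(snapshot_every)
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  if (rounds < 1) stop("rounds must be at least 1", call. = FALSE)
  if (rank_update_interval < 1) stop("rank_update_interval must be >= 1",
                                     call. = FALSE)
  if (snapshot_every < 1) stop("snapshot_every must be >= 1", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(variant = variant, N = N, rounds = rounds,
                 payoffs = payoffs, learning = learning,
                 rank_update_interval = rank_update_interval,
                 snapshot_every = snapshot_every, seed = seed,
                 discount_rank_accumulator = isTRUE(discount_rank_accumulator)),
            class = "hd_config")
}

#' @export
print.hd_config <- function(x, ...) {
  cat("Simulation config:", x$variant, "| N =", x$N, "| rounds =", x$rounds,
      "| seed =", if (is.null(x$seed)) "none" else x$seed, "\n")
  print(x$payoffs); print(x$learning)
  if (x$variant == "dynamic_ranks") {
    cat("Rank updates every", x$rank_update_interval, "rounds\n")
  }
  invisible(x)
}

#' Run a full simulation
#'
#' Executes `config$rounds` rounds of the configured model variant and
#' returns the trajectory: final agent states, per-block interaction
#' outcome counts, the network-centralization time series, and (for the
#' dynamic-ranks variant) the rank history at every rank update.
#'
#' Runs are exactly reproducible from `(config, seed)`. All randomness is
#' consumed from R's RNG stream in a fixed, documented order: first the
#' initial rank permutation, then per round (1) visit targets for agents
#' `1..N`, (2) visitor actions for agents `1..N`, (3) host actions grouped
#' by host index ascending and, within a host, by visitor index ascending.
#' The compiled engine and the pure-R reference engine consume the stream
#' identically and produce bit-identical trajectories.
#'
#' @param config An [sim_config()] object.
#' @param record_interactions If `TRUE`, keep the full per-visit log
#'   (visitor, host, actions, payoffs, rank relation). Memory grows as
#'   `rounds * N`; intended for short diagnostic runs.
#' @param engine `"compiled"` (default) or `"reference"` — the straight-line
#'   loop-per-agent R implementation, useful for verification.
#' @return An object of class `hd_trajectory`; see Details.
#'
#' @details The returned list contains:
#' * `config`, `initial_ranks`
#' * `final`: `strategy` (N x 4 weights `w_H, w_D, w_h, w_d`), `network`
#'   (N x N tie weights), `ranks`, `rank_accumulator`,
#'   `cumulative_payoff` (undiscounted per-agent totals)
#' * `outcome_counts`: one row per snapshot block, columns `hawk_hawk`,
#'   `host_guest`, `ownership`, `dove_dove`
#' * `centralization`: network centralization at each snapshot
#' * `snapshot_rounds`: round index of each snapshot
#' * `rank_history`, `rank_history_rounds`: ranks at initialization and
#'   after each rank update (dynamic variant; initial ranks only otherwise)
#' * `interactions`: per-visit data frame if recorded, else `NULL`
#' @examples
#' cfg <- sim_config("partner_choice", N = 6, rounds = 500,
#'                   payoffs = payoff_params(f = 0.6), seed = 42)
#' traj <- run_simulation(cfg)
#' interaction_fractions(traj, window = c(0.5, 1))
#' @export
run_simulation <- function(config, record_interactions = FALSE,
                           engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  if (!inherits(config, "hd_config")) stop("config must be an hd_config",
                                           call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- initialize_weights(config$N, config$learning$L)
  ranks0 <- sample.int(config$N)

  if (engine == "compiled") {
    res <- engine_run_cpp(
      N = config$N, rounds = config$rounds,
      variant = match(config$variant, c("random_interaction",
                                        "partner_choice",
                                        "dynamic_ranks")) - 1L,
      f = config$payoffs$f, hd = config$payoffs$hd, dd = config$payoffs$dd,
      dh = config$payoffs$dh, hh = config$payoffs$hh,
      delta = config$learning$delta, epsilon = config$learning$epsilon,
      v = config$learning$v,
      strategy0 = init$strategy, network0 = init$network,
      ranks0 = ranks0,
      rank_interval = config$rank_update_interval,
      snapshot_every = config$snapshot_every,
      rank_discount = if (config$discount_rank_accumulator)
        config$learning$delta else 0,
      record_interactions = record_interactions)
  } else {
    res <- engine_run_reference(config, init, ranks0, record_interactions)
  }

  colnames(res$outcome_counts) <- c("hawk_hawk", "host_guest", "ownership",
                                    "dove_dove")
  colnames(res$final_strategy) <- c("w_H", "w_D", "w_h", "w_d")
  interactions <- NULL
  if (record_interactions) {
    interactions <- data.frame(
      round = res$log_round, visitor = res$log_visitor, host = res$log_host,
      visitor_action = c("dove", "hawk")[res$log_visitor_action + 1L],
      host_action = c("dove", "hawk")[res$log_host_action + 1L],
      visitor_payoff = res$log_visitor_payoff,
      host_payoff = res$log_host_payoff,
      rank_relation = c("host_outranks", "visitor_outranks",
                        "tied")[res$log_relation + 1L])
  }
  structure(list(
    config = config,
    initial_ranks = ranks0,
    final = list(strategy = res$final_strategy,
                 network = res$final_network,
                 ranks = as.integer(res$final_ranks),
                 rank_accumulator = res$rank_accumulator,
                 cumulative_payoff = res$cumulative_payoff),
    outcome_counts = res$outcome_counts,
    centralization = as.numeric(res$centralization),
    snapshot_rounds = as.numeric(res$snapshot_rounds),
    rank_history = res$rank_history,
    rank_history_rounds = as.numeric(res$rank_history_rounds),
    interactions = interactions), class = "hd_trajectory")
}

#' @export
print.hd_trajectory <- function(x, ...) {
  cat("hawk-dove trajectory:", x$config$variant, "| N =", x$config$N,
      "| rounds =", x$config$rounds, "\n")
  fr <- interaction_fractions(x, window = c(0.9, 1))
  cat("Final-10% outcome fractions:",
      paste(sprintf("%s=%.3f", names(fr), fr), collapse = " "), "\n")
  invisible(x)
}

#' Tremble-free strategy probabilities of each agent
#'
#' @param x An `hd_trajectory` or an `N x 4` strategy-weight matrix with
#'   columns `w_H, w_D, w_h, w_d`.
#' @return Data frame with columns `p_hawk_host` and `p_hawk_visit`
#'   (probabilities at `epsilon = 0`).
#' @export
strategy_probabilities <- function(x) {
  w <- if (inherits(x, "hd_trajectory")) x$final$strategy else x
  data.frame(p_hawk_host = w[, "w_H"] / (w[, "w_H"] + w[, "w_D"]),
             p_hawk_visit = w[, "w_h"] / (w[, "w_h"] + w[, "w_d"]))
}
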