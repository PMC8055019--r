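# Straight-line, loop-per-agent reference engine. Consumes the RNG stream
# in exactly the same order and with exactly the same floating-point
# arithmetic as the compiled engine, so trajectories match bit for bit.
# Used for verification and for the exported single-round operation.

hawk_prob_ <- function(wh, wd, eps) {
  tw <- wh + wd
  if (tw > 0) (1 - eps) * (wh / tw) + eps * 0.5 else 0.5
}

#' Execute one round of the simulation (reference implementation)
#'
#' Runs a single round of the model on an explicit agent state: every agent
#' draws a visit target from its outgoing tie weights (uniformly in the
#' random-interaction variant), visitor and host actions are drawn from the
#' role-specific strategy weights, payoffs are resolved through the
#' rank-order contest, and all weights are updated simultaneously from the
#' pre-round state. Visitors reinforce their visiting strategy and the tie
#' they used; hosts reinforce only their hosting strategy.
#'
#' RNG draw order: visit targets for agents `1..N`, visitor actions
#' `1..N`, then host actions grouped by host index ascending (visitors
#' ascending within a host).
#'
#' This is the loop-per-agent reference implementation; [run_simulation()]
#' with `engine = "compiled"` runs the same round logic in C++ and matches
#' it bit for bit. Rank updates are a between-round operation handled by
#' the simulation loop, not by the round itself.
#'
#' @param state List with elements `strategy` (N x 4 weights
#'   `w_H, w_D, w_h, w_d`), `network` (N x N), `ranks` (permutation),
#'   `rank_accumulator`, `cumulative_payoff`.
#' @param config An [sim_config()] object.
#' @return List with `state` (updated) and `record`, a data frame of the
#'   round's visits: visitor, host, actions, payoffs, rank relation.
#' @examples
#' cfg <- sim_config("partner_choice", N = 4, rounds = 1,
#'                   payoffs = payoff_params(f = 0.6), seed = 7)
#' set.seed(7)
#' st <- c(initialize_weights(4, cfg$learning$L),
#'         list(ranks = sample.int(4), rank_accumulator = numeric(4),
#'              cumulative_payoff = numeric(4)))
#' run_round(st, cfg)$record
#' @export
run_round <- function(state, config) {
  N <- config$N
  eps <- config$learning$epsilon
  delta <- config$learning$delta
  v <- config$learning$v
  p <- config$payoffs
  dynamic <- config$variant == "dynamic_ranks"
  uniform_p <- 1 / (N - 1)
  strategy <- state$strategy
  network <- state$network
  ranks <- state$ranks
  rank_acc <- state$rank_accumulator

  # (1) visit targets
  target <- integer(N)
  for (i in seq_len(N)) {
    u <- stats::runif(1)
    chosen <- -1L
    if (config$variant == "random_interaction") {
      acc <- 0
      for (j in seq_len(N)) {
        if (j == i) next
        acc <- acc + uniform_p
        if (u <= acc) { chosen <- j; break }
      }
    } else {
      total <- 0
      for (j in seq_len(N)) total <- total + network[i, j]
      acc <- 0
      if (total > 0) {
        scale <- (1 - eps) / total
        tremble_add <- eps * uniform_p
        for (j in seq_len(N)) {
          if (j == i) next
          acc <- acc + (scale * network[i, j] + tremble_add)
          if (u <= acc) { chosen <- j; break }
        }
      } else {
        for (j in seq_len(N)) {
          if (j == i) next
          acc <- acc + uniform_p
          if (u <= acc) { chosen <- j; break }
        }
      }
    }
    if (chosen < 0) chosen <- if (i == N) N - 1L else N
    target[i] <- chosen
  }

  # (2) visitor actions
  vis_hawk <- logical(N)
  for (i in seq_len(N)) {
    pH <- hawk_prob_(strategy[i, 3], strategy[i, 4], eps)
    vis_hawk[i] <- stats::runif(1) <= pH
  }

  # (3) host actions and payoff resolution, hosts ascending
  p_hawk_host <- numeric(N)
  for (i in seq_len(N)) p_hawk_host[i] <- hawk_prob_(strategy[i, 1],
                                                     strategy[i, 2], eps)
  vis_pay <- numeric(N)
  host_pi_hawk <- numeric(N); host_pi_dove <- numeric(N)
  round_total <- numeric(N)
  rec_v <- integer(0); rec_h <- integer(0)
  rec_va <- character(0); rec_ha <- character(0)
  rec_vp <- numeric(0); rec_hp <- numeric(0); rec_rel <- character(0)
  for (h in seq_len(N)) {
    for (i in seq_len(N)) {
      if (target[i] != h) next
      host_hawk <- stats::runif(1) <= p_hawk_host[h]
      tied <- dynamic && rank_acc[i] == rank_acc[h]
      if (vis_hawk[i] && host_hawk) {
        if (tied) { pv <- p$f / 3; ph <- p$f / 3; rel <- "tied" }
        else if (ranks[i] < ranks[h]) {
          pv <- p$f; ph <- p$hh; rel <- "visitor_outranks"
        } else { pv <- p$hh; ph <- p$f; rel <- "host_outranks" }
      } else {
        rel <- if (tied) "tied" else if (ranks[i] < ranks[h])
          "visitor_outranks" else "host_outranks"
        if (vis_hawk[i]) { pv <- p$hd; ph <- p$dh }
        else if (host_hawk) { pv <- p$dh; ph <- p$hd }
        else { pv <- p$dd; ph <- p$dd }
      }
      vis_pay[i] <- pv
      if (host_hawk) host_pi_hawk[h] <- host_pi_hawk[h] + ph
      else host_pi_dove[h] <- host_pi_dove[h] + ph
      round_total[i] <- round_total[i] + pv
      round_total[h] <- round_total[h] + ph
      rec_v <- c(rec_v, i); rec_h <- c(rec_h, h)
      rec_va <- c(rec_va, if (vis_hawk[i]) "hawk" else "dove")
      rec_ha <- c(rec_ha, if (host_hawk) "hawk" else "dove")
      rec_vp <- c(rec_vp, pv); rec_hp <- c(rec_hp, ph)
      rec_rel <- c(rec_rel, rel)
    }
  }

  # (4) simultaneous updates from pre-round weights
  strategy[, 1] <- (1 - delta) * strategy[, 1] + host_pi_hawk
  strategy[, 2] <- (1 - delta) * strategy[, 2] + host_pi_dove
  strategy[, 3] <- (1 - delta) * strategy[, 3] + ifelse(vis_hawk, vis_pay, 0)
  strategy[, 4] <- (1 - delta) * strategy[, 4] + ifelse(vis_hawk, 0, vis_pay)
  if (config$variant != "random_interaction") {
    network <- (1 - delta) * network
    for (i in seq_len(N)) {
      network[i, target[i]] <- network[i, target[i]] + v * vis_pay[i]
    }
  }
  rank_discount <- if (config$discount_rank_accumulator)
    config$learning$delta else 0
  state$strategy <- strategy
  state$network <- network
  state$cumulative_payoff <- state$cumulative_payoff + round_total
  state$rank_accumulator <- (1 - rank_discount) * rank_acc + round_total

  list(state = state,
       record = data.frame(visitor = rec_v, host = rec_h,
                           visitor_action = rec_va, host_action = rec_ha,
                           visitor_payoff = rec_vp, host_payoff = rec_hp,
                           rank_relation = rec_rel))
}

# Full reference run; returns the same field layout as the compiled engine.
engine_run_reference <- function(config, init, ranks0, record_interactions) {
  N <- config$N
  state <- list(strategy = init$strategy, network = init$network,
                ranks = ranks0, rank_accumulator = numeric(N),
                cumulative_payoff = numeric(N))
  n_snap <- ceiling(config$rounds / config$snapshot_every)
  outcome_counts <- matrix(0, n_snap, 4)
  centralization <- numeric(n_snap)
  snapshot_rounds <- numeric(n_snap)
  dynamic <- config$variant == "dynamic_ranks"
  rank_history <- matrix(ranks0, nrow = 1)
  rank_history_rounds <- 0
  block <- numeric(4)
  snap_row <- 0
  logs <- if (record_interactions) vector("list", config$rounds) else NULL

  for (r in seq_len(config$rounds)) {
    step <- run_round(state, config)
    state <- step$state
    rec <- step$record
    vh <- rec$visitor_action == "hawk"; hh_ <- rec$host_action == "hawk"
    block <- block + c(sum(vh & hh_), sum(vh & !hh_), sum(!vh & hh_),
                       sum(!vh & !hh_))
    if (record_interactions) {
      rec$round <- r
      logs[[r]] <- rec
    }
    if (dynamic && r %% config$rank_update_interval == 0) {
      state$ranks <- update_ranks(state$rank_accumulator, state$ranks)
      rank_history <- rbind(rank_history, state$ranks)
      rank_history_rounds <- c(rank_history_rounds, r)
    }
    if (r %% config$snapshot_every == 0 || r == config$rounds) {
      snap_row <- snap_row + 1
      outcome_counts[snap_row, ] <- block
      block <- numeric(4)
      centralization[snap_row] <- network_centralization(state$network)
      snapshot_rounds[snap_row] <- r
    }
  }

  out <- list(final_strategy = state$strategy,
              final_network = state$network,
              final_ranks = state$ranks,
              rank_accumulator = state$rank_accumulator,
              cumulative_payoff = state$cumulative_payoff,
              outcome_counts = outcome_counts,
              centralization = centralization,
              snapshot_rounds = snapshot_rounds,
              rank_history = rank_history,
              rank_history_rounds = rank_history_rounds)
  if (record_interactions) {
    all <- do.call(rbind, logs)
    out$log_round <- all$round
    out$log_visitor <- all$visitor
    out$log_host <- all$host
    out$log_visitor_action <- as.integer(all$visitor_action == "hawk")
    out$log_host_action <- as.integer(all$host_action == "hawk")
    out$log_relation <- match(all$rank_relation,
                              c("host_outranks", "visitor_outranks",
                                "tied")) - 1L
    out$log_visitor_payoff <- all$visitor_payoff
    out$log_host_payoff <- all$host_payoff
  }
  out
}
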