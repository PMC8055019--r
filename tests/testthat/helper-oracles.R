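# Independent oracles used across test files.

# Closed-form Roth-Erev weight after k rounds of constant payoff pi to one
# action: geometric decay of the start weight plus the geometric sum of
# reinforcements.
geometric_weight <- function(w0, pi, delta, k) {
  (1 - delta)^k * w0 + pi * sum((1 - delta)^(0:(k - 1)))
}

# Brute-force dominance check on an explicit 2x2 payoff matrix
# (rows = own action hawk/dove, cols = opponent action): hawk is dominant
# iff it is at least as good against both opponent actions (and the game
# ordering makes it strictly better against dove).
hawk_dominant_bruteforce <- function(game) {
  game["hawk", "hawk"] >= game["dove", "hawk"] &&
    game["hawk", "dove"] >= game["dove", "dove"]
}

# Expected payoff of playing hawk/dove against an opponent who plays hawk
# with probability p, in the expected per-rank game.
best_response_is_dove <- function(game, p) {
  u_hawk <- p * game["hawk", "hawk"] + (1 - p) * game["hawk", "dove"]
  u_dove <- p * game["dove", "hawk"] + (1 - p) * game["dove", "dove"]
  u_dove > u_hawk
}

# Recompute final strategy weights from a full interaction log by replaying
# the per-round discounted reinforcement per role. Independent of the
# engine's internal update path.
replay_strategy_weights <- function(interactions, N, rounds, delta) {
  w <- matrix(1, N, 4, dimnames = list(NULL, c("w_H", "w_D", "w_h", "w_d")))
  for (r in seq_len(rounds)) {
    rec <- interactions[interactions$round == r, , drop = FALSE]
    pi_mat <- matrix(0, N, 4)
    for (k in seq_len(nrow(rec))) {
      i <- rec$visitor[k]; h <- rec$host[k]
      vcol <- if (rec$visitor_action[k] == "hawk") 3 else 4
      hcol <- if (rec$host_action[k] == "hawk") 1 else 2
      pi_mat[i, vcol] <- pi_mat[i, vcol] + rec$visitor_payoff[k]
      pi_mat[h, hcol] <- pi_mat[h, hcol] + rec$host_payoff[k]
    }
    w <- (1 - delta) * w + pi_mat
  }
  w
}

# Random valid payoff parameters satisfying hd > dd > dh > hh >= 0 and
# f >= hh.
random_payoffs <- function() {
  vals <- sort(runif(4, 0, 2))
  payoff_params(f = runif(1, vals[1], 3), hd = vals[4], dd = vals[3],
                dh = vals[2], hh = vals[1])
}

# Small standard config for engine tests.
small_config <- function(variant = "partner_choice", N = 6, rounds = 120,
                         f = 0.6, seed = 99, ...) {
  sim_config(variant, N = N, rounds = rounds,
             payoffs = payoff_params(f = f),
             snapshot_every = 40, rank_update_interval = 30,
             seed = seed, ...)
}
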