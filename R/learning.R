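#' Roth-Erev learning parameters
#'
#' @param delta Per-round geometric discount applied to every reinforcement
#'   weight (strategy and network), chosen and unchosen alike.
#' @param epsilon Tremble rate: the probability mass spread uniformly over
#'   the available choices, modelling errors/exploration.
#' @param v Network-learning speed multiplier: the payoff reinforcing a
#'   network tie is `v * payoff`, leaving strategy learning untouched.
#'   `v > 1` makes partner choice faster than strategy learning, `v < 1`
#'   slower.
#' @param L Initialization scale for network weights: every off-diagonal tie
#'   starts at `L / (N - 1)`, so that total outgoing weight is `L`
#'   regardless of population size. The default `L = 19` gives starting tie
#'   weights of 1 in the standard population of `N = 20`.
#'
#' @return An object of class `hd_learning`.
#' @export
learning_params <- function(delta = 0.01, epsilon = 0.01, v = 1, L = 19) {
  p <- list(delta = as.numeric(delta), epsilon = as.numeric(epsilon),
            v = as.numeric(v), L = as.numeric(L))
  if (!is.finite(p$delta) || p$delta < 0 || p$delta >= 1) {
    stop("delta must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(p$epsilon) || p$epsilon < 0 || p$epsilon > 1) {
    stop("epsilon must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(p$v) || p$v <= 0) stop("v must be > 0", call. = FALSE)
  if (!is.finite(p$L) || p$L <= 0) stop("L must be > 0", call. = FALSE)
  structure(p, class = "hd_learning")
}

#' @export
print.hd_learning <- function(x, ...) {
  cat("Roth-Erev learning: delta =", x$delta, " epsilon =", x$epsilon,
      " v =", x$v, " L =", x$L, "\n")
  invisible(x)
}

#' Convert reinforcement weights to choice probabilities
#'
#' The probability of choice `s` is `(1 - epsilon) * w_s / sum(w) +
#' epsilon / |S|`: weight-proportional choice with a uniform tremble floor.
#' An all-zero weight vector (reachable only with `epsilon = 0` and
#' `delta > 0`) falls back to the uniform distribution so the process stays
#' well defined.
#'
#' @param weights Non-negative numeric vector of reinforcement weights.
#' @param epsilon Tremble rate in `[0, 1]`.
#' @return Probability vector of the same length; sums to 1, every entry at
#'   least `epsilon / length(weights)`.
#' @examples
#' choice_probabilities(c(3, 1), epsilon = 0.1)  # 0.725 0.275
#' @export
choice_probabilities <- function(weights, epsilon = 0) {
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]",
                                       call. = FALSE)
  k <- length(weights)
  total <- sum(weights)
  if (total > 0) {
    (1 - epsilon) * weights / total + epsilon / k
  } else {
    rep(1 / k, k)
  }
}

#' Update one role's strategy weights after a round
#'
#' Every weight in the role is discounted by `(1 - delta)`; each action
#' additionally gains the summed payoff it earned this round (zero for
#' unchosen actions). The other role's weights are never touched: payoffs
#' earned hosting reinforce only the hosting pair `(w_H, w_D)` and payoffs
#' earned visiting only the visiting pair `(w_h, w_d)`.
#'
#' @param weights Named numeric vector `c(hawk = , dove = )` for one role.
#' @param payoff_by_action Named numeric vector of this round's summed
#'   payoffs per action in the same role; missing actions count as 0.
#' @param delta Discount rate.
#' @return Updated weight vector.
#' @examples
#' update_strategy_weights(c(hawk = 2, dove = 1), c(hawk = 0.6), delta = 0.01)
#' @export
update_strategy_weights <- function(weights, payoff_by_action = numeric(),
                                    delta = 0.01) {
  pi_s <- stats::setNames(numeric(length(weights)), names(weights))
  if (length(payoff_by_action)) {
    bad <- setdiff(names(payoff_by_action), names(weights))
    if (length(bad)) {
      stop("payoff_by_action names must match the role's actions",
           call. = FALSE)
    }
    pi_s[names(payoff_by_action)] <- pi_s[names(payoff_by_action)] +
      payoff_by_action
  }
  (1 - delta) * weights + pi_s
}

#' Update one agent's outgoing network weights after a visit
#'
#' All outgoing ties are discounted by `(1 - delta)`; the tie to the visited
#' host additionally gains `v * payoff`, where `payoff` is what the visitor
#' earned on that visit. The self-tie stays identically zero.
#'
#' @param w_row Numeric vector of outgoing tie weights for one agent
#'   (its own entry must be 0).
#' @param self Index of the agent itself within `w_row`.
#' @param visited Index of the visited host.
#' @param payoff Payoff the visitor received on the visit.
#' @param delta Discount rate.
#' @param v Network-learning speed multiplier.
#' @return Updated outgoing weight vector.
#' @export
update_network_weights <- function(w_row, self, visited, payoff,
                                   delta = 0.01, v = 1) {
  if (visited == self) stop("an agent cannot visit itself", call. = FALSE)
  if (w_row[self] != 0) stop("the self-tie weight must be 0", call. = FALSE)
  out <- (1 - delta) * w_row
  out[visited] <- out[visited] + v * payoff
  out
}

#' Initialize strategy and network weights
#'
#' Strategy weights start at 1 for all four role-action pairs; network
#' weights start uniform at `L / (N - 1)` off the diagonal (0 on it), so
#' the variance of initial in-weights is exactly 0.
#'
#' @param N Population size (`>= 2`).
#' @param L Network initialization scale; see [learning_params()].
#' @return List with `strategy` (an `N x 4` matrix with columns
#'   `w_H`, `w_D`, `w_h`, `w_d`: hawk/dove as host, hawk/dove as visitor)
#'   and `network` (an `N x N` matrix of outgoing tie weights).
#' @examples
#' w <- initialize_weights(N = 20, L = 19)
#' w$network[1, 2]  # 1
#' @export
initialize_weights <- function(N, L = 19) {
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  strategy <- matrix(1, nrow = N, ncol = 4,
                     dimnames = list(NULL, c("w_H", "w_D", "w_h", "w_d")))
  network <- matrix(L / (N - 1), nrow = N, ncol = N)
  diag(network) <- 0
  list(strategy = strategy, network = network)
}
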