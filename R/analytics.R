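#' Probability of outranking a uniformly random opponent
#'
#' Under random matching, an agent of rank `r` (1 = top) outranks
#' `(N - r)` of its `N - 1` possible opponents, so
#' `R = (N - r) / (N - 1)`.
#'
#' @param rank Rank(s) in `1:N`.
#' @param N Population size.
#' @return Numeric vector of outranking probabilities in `[0, 1]`.
#' @export
outranking_probability <- function(rank, N) {
  if (any(rank < 1 | rank > N)) stop("rank must lie in 1..N", call. = FALSE)
  (N - rank) / (N - 1)
}

#' Expected 2x2 game faced by an agent of a given rank
#'
#' Under random interaction an agent of rank `r` faces, in expectation over
#' a uniformly random opponent, a 2x2 game identical to the base game except
#' in the hawk-hawk cell, which becomes `R * f + (1 - R) * hh` with
#' `R = (N - r)/(N - 1)`: the agent wins the rank contest with probability
#' `R`. Rank thus deforms only the cost of mutual aggression, and for
#' `f = 0`, `hh = 0` all ranks face the same baseline game of conflict.
#'
#' @param rank Rank of the focal agent (1 = top).
#' @param N Population size.
#' @param params A [payoff_params()] object.
#' @return A 2x2 matrix of the focal agent's expected payoffs, rows = own
#'   action (`hawk`, `dove`), columns = opponent action.
#' @examples
#' expected_game_by_rank(11, 20, payoff_params(f = 0.8))["hawk", "hawk"]
#' @export
expected_game_by_rank <- function(rank, N, params) {
  R <- outranking_probability(rank, N)
  m <- matrix(c(R * params$f + (1 - R) * params$hh, params$hd,
                params$dh, params$dd),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("hawk", "dove"), c("hawk", "dove")))
  m
}

#' Ranks for which hawk is a dominant strategy
#'
#' In the expected game of [expected_game_by_rank()], hawk strictly beats
#' dove against a dove opponent whenever `hd > dd` (always true here), so
#' hawk is dominant exactly when the expected hawk-hawk payoff is at least
#' `dh`: `R * f + (1 - R) * hh >= dh`. The set is empty for `f < dh` (with
#' `hh < dh`), first becomes non-empty at exactly `f = dh` (rank 1, where
#' `R = 1`), and grows from the top of the hierarchy downward as `f`
#' increases — the phase transition of all three model variants.
#'
#' @param params A [payoff_params()] object.
#' @param N Population size.
#' @return Integer vector of ranks (possibly empty), sorted ascending.
#' @examples
#' dominance_solvable_ranks(payoff_params(f = 0.8), N = 20)  # 1:10
#' @export
dominance_solvable_ranks <- function(params, N) {
  r <- seq_len(N)
  R <- outranking_probability(r, N)
  hawk_hawk <- R * params$f + (1 - R) * params$hh
  r[hawk_hawk >= params$dh]
}

#' Opponent-hawk-probability threshold above which dove is preferred
#'
#' For an outranked individual facing opponents who play hawk with
#' probability `P`, dove is the better reply in both roles once
#' `P > (hd - dd) / ((dh - dd) - (R * f - hd))`, where `R` is the chance of
#' outranking the opponent. The threshold rises with `R * f`: the more an
#' agent stands to win in contests, the more widespread aggression must be
#' before deference pays.
#'
#' @param params A [payoff_params()] object.
#' @param R Probability of outranking the opponent, in `[0, 1]`.
#' @return The threshold probability.
#' @examples
#' dove_preference_threshold(payoff_params(f = 0.6), R = 0)  # 0.5
#' @export
dove_preference_threshold <- function(params, R) {
  if (R < 0 || R > 1) stop("R must lie in [0, 1]", call. = FALSE)
  denom <- (params$dh - params$dd) - (R * params$f - params$hd)
  if (abs(denom) < .Machine$double.eps * 4) {
    stop("degenerate parameters: threshold denominator vanishes",
         call. = FALSE)
  }
  (params$hd - params$dd) / denom
}

#' Phase-boundary table for the expected per-rank game
#'
#' Tabulates, over a grid of `f` values, which ranks face a
#' dominance-solvable expected game (hawk dominant). Useful for printing
#' the analytic phase diagram.
#'
#' @param N Population size.
#' @param f_grid Numeric vector of `f` values.
#' @param params Base payoffs; the `f` element is replaced by each grid
#'   value in turn.
#' @return Data frame with columns `f`, `rank`, `R`, `expected_hawk_hawk`,
#'   `hawk_dominant`.
#' @export
phase_boundary_table <- function(N = 20, f_grid = seq(0, 1, by = 0.1),
                                 params = payoff_params()) {
  rows <- lapply(f_grid, function(f) {
    p <- payoff_params(f = f, hd = params$hd, dd = params$dd,
                       dh = params$dh, hh = params$hh)
    r <- seq_len(N)
    R <- outranking_probability(r, N)
    data.frame(f = f, rank = r, R = R,
               expected_hawk_hawk = R * p$f + (1 - R) * p$hh,
               hawk_dominant = r %in% dominance_solvable_ranks(p, N))
  })
  do.call(rbind, rows)
}
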