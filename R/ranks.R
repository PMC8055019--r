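#' Recompute ranks from accumulated payoffs
#'
#' Ranks agents by their payoff accumulator, rank 1 being the agent with the
#' highest accumulated payoff. Ties are broken by the previous rank order
#' (a stable sort), so an update with unchanged accumulators leaves the
#' ranking untouched and repeated updates are idempotent.
#'
#' Used by the dynamic-ranks model variant, where ranks are recomputed every
#' `rank_update_interval` rounds; in the static variants ranks are a fixed
#' random permutation and this function is never called by the engine.
#'
#' @param cumulative_payoffs Numeric vector of per-agent payoff accumulators.
#' @param previous_ranks Integer permutation of `1:N`; the ranks in force
#'   before the update (1 = top).
#'
#' @return Integer vector of new ranks (a permutation of `1:N`).
#' @examples
#' update_ranks(c(5, 3, 9), previous_ranks = c(1, 2, 3))  # c(2, 3, 1)
#' @export
update_ranks <- function(cumulative_payoffs, previous_ranks) {
  n <- length(cumulative_payoffs)
  if (length(previous_ranks) != n) {
    stop("cumulative_payoffs and previous_ranks must have equal length",
         call. = FALSE)
  }
  if (!setequal(previous_ranks, seq_len(n))) {
    stop("previous_ranks must be a permutation of 1..N", call. = FALSE)
  }
  if (any(!is.finite(cumulative_payoffs))) {
    stop("cumulative_payoffs must be finite", call. = FALSE)
  }
  ord <- order(-cumulative_payoffs, previous_ranks)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  ranks
}
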