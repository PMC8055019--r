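#' Payoff parameters for the asymmetric hawk-dove game
#'
#' Bundles the four payoffs of the 2x2 game of conflict together with the
#' rank-contest reward `f`. When two hawks meet, the higher-ranked
#' ("ranking") agent wins the whole contested reward `f` while the outranked
#' agent receives `hh`; all other cells are independent of rank. The payoffs
#' must satisfy the strict game-of-conflict ordering `hd > dd > dh > hh`,
#' `f >= hh`, and non-negativity.
#'
#' @param f Reward to the ranking agent in a hawk-hawk contest. `f = 0`
#'   recovers the baseline symmetric game in which rank plays no role.
#' @param hd Payoff to a hawk facing a dove (the full resource).
#' @param dd Payoff to each dove in a dove-dove meeting (shared resource).
#' @param dh Payoff to a dove facing a hawk (deference).
#' @param hh Payoff to the outranked agent in a hawk-hawk contest.
#'
#' @return An object of class `hd_payoffs`: a named list with elements
#'   `f`, `hd`, `dd`, `dh`, `hh`.
#'
#' @examples
#' p <- payoff_params(f = 0.6)
#' resolve_interaction("hawk", "hawk", "visitor_outranks", p)
#' @export
payoff_params <- function(f = 0, hd = 1, dd = 0.6, dh = 0.4, hh = 0) {
  p <- list(f = as.numeric(f), hd = as.numeric(hd), dd = as.numeric(dd),
            dh = as.numeric(dh), hh = as.numeric(hh))
  validate_payoff_params(p)
  structure(p, class = "hd_payoffs")
}

validate_payoff_params <- function(p) {
  vals <- unlist(p[c("f", "hd", "dd", "dh", "hh")])
  if (any(!is.finite(vals))) {
    stop("payoff parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("payoff parameters must be non-negative", call. = FALSE)
  }
  if (!(p$hd > p$dd && p$dd > p$dh && p$dh > p$hh)) {
    stop("payoffs must satisfy hd > dd > dh > hh", call. = FALSE)
  }
  if (p$f < p$hh) {
    stop("the rank-contest reward f must satisfy f >= hh", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.hd_payoffs <- function(x, ...) {
  cat("Hawk-dove payoffs: hd =", x$hd, " dd =", x$dd, " dh =", x$dh,
      " hh =", x$hh, " | rank contest f =", x$f, "\n")
  invisible(x)
}

#' Resolve a single visitor-host interaction
#'
#' Applies the asymmetric hawk-dove payoff matrix to one pairwise
#' interaction. Rank only matters in hawk-hawk contests: the ranking side
#' receives `f` and the outranked side `hh`. If the two contestants are tied
#' (identical payoff accumulators under dynamic ranks), each receives `f/3`,
#' representing an even chance of winning net of a conflict cost. All other
#' action pairs ignore `rank_relation`.
#'
#' @param action_visitor,action_host `"hawk"` or `"dove"`.
#' @param rank_relation One of `"visitor_outranks"`, `"host_outranks"`,
#'   `"tied"`.
#' @param params A [payoff_params()] object.
#'
#' @return Named numeric vector `c(visitor = , host = )` of payoffs.
#' @examples
#' p <- payoff_params(f = 0.6)
#' resolve_interaction("hawk", "hawk", "tied", p)  # both get f/3 = 0.2
#' @export
resolve_interaction <- function(action_visitor, action_host, rank_relation,
                                params) {
  action_visitor <- match.arg(action_visitor, c("hawk", "dove"))
  action_host <- match.arg(action_host, c("hawk", "dove"))
  rank_relation <- match.arg(rank_relation,
                             c("visitor_outranks", "host_outranks", "tied"))
  if (action_visitor == "hawk" && action_host == "hawk") {
    out <- switch(rank_relation,
      visitor_outranks = c(params$f, params$hh),
      host_outranks = c(params$hh, params$f),
      tied = c(params$f / 3, params$f / 3))
  } else if (action_visitor == "hawk") {
    out <- c(params$hd, params$dh)
  } else if (action_host == "hawk") {
    out <- c(params$dh, params$hd)
  } else {
    out <- c(params$dd, params$dd)
  }
  c(visitor = out[1], host = out[2])
}
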