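#' Classify an agent's strategy from its tremble-free choice probabilities
#'
#' Agents are classed by their probability of playing hawk in each role,
#' computed from the strategy weights with the tremble excluded
#' (`epsilon = 0`). Pure hawks play hawk with likelihood at least
#' `threshold` both at home and away (the conservative bully definition);
#' pure doves symmetrically. `ownership` is hawk-at-home / dove-away (the
#' "bourgeois" convention), `host_guest` is dove-at-home / hawk-away (the
#' "paradoxical" convention). Anything else is `mixed`.
#'
#' @param p_hawk_host,p_hawk_visit Probabilities of playing hawk when
#'   hosting and when visiting (vectors of equal length).
#' @param threshold Classification likelihood threshold, default 0.8.
#' @return Character vector of classes: `pure_hawk`, `pure_dove`,
#'   `ownership`, `host_guest`, or `mixed`.
#' @export
classify_agent_strategy <- function(p_hawk_host, p_hawk_visit,
                                    threshold = 0.8) {
  stopifnot(length(p_hawk_host) == length(p_hawk_visit))
  if (any(p_hawk_host < 0 | p_hawk_host > 1 |
          p_hawk_visit < 0 | p_hawk_visit > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  host_hawk <- p_hawk_host >= threshold
  host_dove <- (1 - p_hawk_host) >= threshold
  visit_hawk <- p_hawk_visit >= threshold
  visit_dove <- (1 - p_hawk_visit) >= threshold
  out <- rep("mixed", length(p_hawk_host))
  out[host_hawk & visit_hawk] <- "pure_hawk"
  out[host_dove & visit_dove] <- "pure_dove"
  out[host_hawk & visit_dove] <- "ownership"
  out[host_dove & visit_hawk] <- "host_guest"
  out
}

#' Label the population's convention
#'
#' The population follows the host-guest (resp. ownership) convention when
#' more than half of the agents that are not pure hawks fall in that class;
#' otherwise the label is `unresolved`.
#'
#' @param classes Character vector from [classify_agent_strategy()].
#' @return `"host_guest"`, `"ownership"`, or `"unresolved"`.
#' @export
population_convention <- function(classes) {
  non_bully <- classes[classes != "pure_hawk"]
  if (!length(non_bully)) return("unresolved")
  if (mean(non_bully == "host_guest") > 0.5) return("host_guest")
  if (mean(non_bully == "ownership") > 0.5) return("ownership")
  "unresolved"
}

#' Network centralization of a weighted visit network
#'
#' Centralization is the sample variance of the in-weight sums of the
#' row-normalized visit-probability matrix (tremble excluded). Each row of
#' the weight matrix is scaled to sum to 1 (an agent's total visiting
#' probability); column sums then give the expected number of visitors per
#' round for each agent, and their variance measures how hub-like the
#' network is. The uniform initial network scores exactly 0; a star of
#' `N = 20` (19 spokes visiting the hub with probability 1, the hub
#' spreading 1/19 to each spoke) scores 17.95.
#'
#' @param network_weights `N x N` non-negative weight matrix with zero
#'   diagonal; entry `(i, j)` is agent `i`'s propensity to visit `j`.
#' @return Non-negative scalar (sample variance, denominator `N - 1`).
#' @export
network_centralization <- function(network_weights) {
  w <- as.matrix(network_weights)
  n <- nrow(w)
  stopifnot(ncol(w) == n)
  if (any(diag(w) != 0)) stop("diagonal must be 0", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  totals <- rowSums(w)
  p <- w / ifelse(totals > 0, totals, 1)
  # rows with no positive weight fall back to uniform choice
  zero <- totals == 0
  if (any(zero)) {
    p[zero, ] <- 1 / (n - 1)
    p[cbind(which(zero), which(zero))] <- 0
  }
  stats::var(colSums(p))
}

#' Fractions of interaction outcomes in a trajectory window
#'
#' Partitions the pairwise interactions of a window into the four outcome
#' types: `hawk_hawk` (costly conflict), `host_guest` (visitor hawk, host
#' dove), `ownership` (visitor dove, host hawk), and `dove_dove`. The four
#' fractions sum to 1.
#'
#' @param x Either an `hd_trajectory` from [run_simulation()] (outcome
#'   counts recorded per snapshot block are used) or a data frame of
#'   interactions with columns `visitor_action` and `host_action`.
#' @param window Numeric length-2 vector of fractions `(from, to]` of the
#'   run over which to count, e.g. `c(0.9, 1)` for the final 10% of rounds.
#'   Ignored when `x` is a data frame.
#' @return Named numeric vector with entries `hawk_hawk`, `host_guest`,
#'   `ownership`, `dove_dove`.
#' @export
interaction_fractions <- function(x, window = c(0.9, 1)) {
  if (inherits(x, "hd_trajectory")) {
    counts <- x$outcome_counts
    nb <- nrow(counts)
    from <- max(1L, floor(window[1] * nb) + 1L)
    to <- min(nb, ceiling(window[2] * nb))
    if (from > to) stop("empty trajectory window", call. = FALSE)
    tot <- colSums(counts[from:to, , drop = FALSE])
  } else {
    df <- as.data.frame(x)
    if (!nrow(df)) stop("empty interaction window", call. = FALSE)
    vh <- df$visitor_action == "hawk"
    hh <- df$host_action == "hawk"
    tot <- c(hawk_hawk = sum(vh & hh), host_guest = sum(vh & !hh),
             ownership = sum(!vh & hh), dove_dove = sum(!vh & !hh))
  }
  tot / sum(tot)
}

#' Dominant period of rank trajectories
#'
#' Estimates the cycle length of each agent's rank time series as the lag
#' of the first local maximum of its autocorrelation function beyond lag
#' zero, at the resolution of the rank-update interval, then averages over
#' agents. Series with no local maximum above the significance floor (in
#' particular constant series) contribute a no-cycle marker (`NA`).
#'
#' @param rank_history Matrix of ranks, one row per rank update, one column
#'   per agent.
#' @param sampling_interval Rounds between successive rows (the rank-update
#'   interval); cycle lengths are reported in rounds.
#' @param floor Minimum autocorrelation for a peak to count as evidence of
#'   a cycle. Defaults to the approximate 95% white-noise band
#'   `1.96 / sqrt(T)`.
#' @return List with `mean_cycle_length` (rounds; `NA` if no agent cycles)
#'   and `per_agent` (vector of per-agent cycle lengths in rounds).
#' @export
estimate_cycle_length <- function(rank_history, sampling_interval = 1000,
                                  floor = NULL) {
  rh <- as.matrix(rank_history)
  T_ <- nrow(rh)
  if (T_ < 3) stop("need at least 3 rank updates to estimate cycles",
                   call. = FALSE)
  if (is.null(floor)) floor <- 1.96 / sqrt(T_)
  per_agent <- apply(rh, 2, function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    a <- stats::acf(x - mean(x), lag.max = floor(T_ / 2), plot = FALSE,
                    demean = FALSE)$acf[, 1, 1]
    # a[1] is lag 0; search lags >= 2 for the first interior local maximum
    for (k in 3:(length(a) - 1)) {
      if (a[k] > a[k - 1] && a[k] >= a[k + 1] && a[k] > floor) {
        return((k - 1) * sampling_interval)
      }
    }
    NA_real_
  })
  mean_len <- if (all(is.na(per_agent))) NA_real_ else
    mean(per_agent, na.rm = TRUE)
  list(mean_cycle_length = mean_len, per_agent = per_agent)
}

#' Gini coefficient
#'
#' Mean absolute difference between all pairs, normalized by twice the
#' mean; 0 is perfect equality. An all-zero vector is defined to have
#' Gini 0.
#'
#' @param x Non-negative numeric vector.
#' @return Scalar in `[0, 1)`.
#' @export
gini <- function(x) {
  if (any(x < 0)) stop("Gini is defined here for non-negative values",
                       call. = FALSE)
  n <- length(x)
  m <- mean(x)
  if (m == 0) return(0)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * m)
}

#' Total welfare and inequality of accumulated payoffs
#'
#' @param cumulative_payoffs Non-negative per-agent accumulated payoffs.
#' @return List with `total_welfare` (sum), `inequality_index` (Gini), and
#'   `payoff_variance` (sample variance, an alternative dispersion
#'   measure).
#' @export
welfare_and_inequality <- function(cumulative_payoffs) {
  list(total_welfare = sum(cumulative_payoffs),
       inequality_index = gini(cumulative_payoffs),
       payoff_variance = stats::var(cumulative_payoffs))
}
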