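#' Summarise one simulation run
#'
#' Condenses a trajectory into the summary statistics used to characterise
#' outcomes: the per-agent strategy classification and population
#' convention, outcome fractions over a late window, network
#' centralization (final and running maximum), mean rank-cycle length
#' (dynamic variant), total welfare, and the Gini index of accumulated
#' payoffs.
#'
#' @param traj An `hd_trajectory` from [run_simulation()].
#' @param window Fraction-of-run window `(from, to]` for the outcome
#'   fractions; default the final 10% of rounds.
#' @param threshold Likelihood threshold for
#'   [classify_agent_strategy()].
#' @return One-row data frame.
#' @export
summarize_run <- function(traj, window = c(0.9, 1), threshold = 0.8) {
  cfg <- traj$config
  probs <- strategy_probabilities(traj)
  classes <- classify_agent_strategy(probs$p_hawk_host, probs$p_hawk_visit,
                                     threshold)
  fr <- interaction_fractions(traj, window)
  cyc <- NA_real_
  if (cfg$variant == "dynamic_ranks" && nrow(traj$rank_history) >= 3) {
    cyc <- estimate_cycle_length(traj$rank_history,
                                 cfg$rank_update_interval)$mean_cycle_length
  }
  wi <- welfare_and_inequality(traj$final$cumulative_payoff)
  data.frame(
    variant = cfg$variant, N = cfg$N, rounds = cfg$rounds,
    f = cfg$payoffs$f, v = cfg$learning$v,
    seed = if (is.null(cfg$seed)) NA_integer_ else cfg$seed,
    pure_hawk_fraction = mean(classes == "pure_hawk"),
    pure_dove_fraction = mean(classes == "pure_dove"),
    host_guest_agent_fraction = mean(classes == "host_guest"),
    ownership_agent_fraction = mean(classes == "ownership"),
    mixed_fraction = mean(classes == "mixed"),
    convention = population_convention(classes),
    hawk_hawk_fraction = unname(fr["hawk_hawk"]),
    host_guest_fraction = unname(fr["host_guest"]),
    ownership_fraction = unname(fr["ownership"]),
    dove_dove_fraction = unname(fr["dove_dove"]),
    final_centralization = traj$centralization[length(traj$centralization)],
    max_centralization = max(traj$centralization),
    mean_cycle_length = cyc,
    total_welfare = wi$total_welfare,
    gini = wi$inequality_index,
    stringsAsFactors = FALSE)
}

#' Run a parameter sweep
#'
#' Runs one simulation per (grid row, seed) combination and returns one
#' summary row each. Cells are fully deterministic given their seed; a
#' failing cell is reported in the `error` column rather than aborting the
#' sweep.
#'
#' @param base_config An [sim_config()] template; grid columns override its
#'   fields.
#' @param grid Data frame whose columns may include `f`, `v`, `N`,
#'   `variant`, `rounds`. Each row is one grid point. An empty grid yields
#'   an empty result.
#' @param seeds Integer vector of distinct seeds; duplicates are rejected
#'   to keep cells independent.
#' @param window,threshold Passed to [summarize_run()].
#' @return Data frame of summary rows with an `error` column (`NA` on
#'   success).
#' @export
run_sweep <- function(base_config, grid, seeds, window = c(0.9, 1),
                      threshold = 0.8) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct", call. = FALSE)
  grid <- as.data.frame(grid)
  if (!nrow(grid)) return(data.frame())
  allowed <- c("f", "v", "N", "variant", "rounds")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) stop("unsupported grid columns: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    for (s in seeds) {
      cfg <- base_config
      if (!is.null(grid$f)) cfg$payoffs$f <- grid$f[g]
      if (!is.null(grid$v)) cfg$learning$v <- grid$v[g]
      if (!is.null(grid$N)) cfg$N <- as.integer(grid$N[g])
      if (!is.null(grid$variant)) cfg$variant <- as.character(grid$variant[g])
      if (!is.null(grid$rounds)) cfg$rounds <- as.integer(grid$rounds[g])
      cfg$seed <- as.integer(s)
      validate_payoff_params(cfg$payoffs)
      row <- tryCatch({
        out <- summarize_run(run_simulation(cfg), window, threshold)
        out$error <- NA_character_
        out
      }, error = function(e) {
        data.frame(variant = cfg$variant, N = cfg$N, rounds = cfg$rounds,
                   f = cfg$payoffs$f, v = cfg$learning$v, seed = s,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
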