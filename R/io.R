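#' Load a simulation configuration from a YAML or JSON file
#'
#' Reads a structured-text config, fills in defaults, validates every
#' field, and returns a full [sim_config()]. Recognised keys: `variant`
#' (required), `seed`, `N`, `rounds`, `rank_update_interval`,
#' `snapshot_every`, `discount_rank_accumulator`, the payoffs `f`, `hd`,
#' `dd`, `dh`, `hh`, and the learning parameters `delta`, `epsilon`, `v`,
#' `L`. Defaults: `N = 20`, `rounds = 1e6`, `delta = 0.01`,
#' `epsilon = 0.01`, `v = 1`, `L = 19`, `rank_update_interval = 1000`,
#' `dh = 0.4`, `dd = 0.6`, `hd = 1`, `hh = 0`, `f = 0`.
#'
#' Payoff-ordering violations (e.g. `dd <= dh`) and negative payoffs are
#' rejected with the offending field named.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `hd_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(raw)
}

#' Build a configuration from a named list
#'
#' The list form of [load_config()]; useful for programmatic construction
#' and for round-tripping a written config.
#'
#' @param raw Named list of config fields; see [load_config()].
#' @return An `hd_config`.
#' @export
config_from_list <- function(raw) {
  known <- c("variant", "seed", "N", "rounds", "rank_update_interval",
             "snapshot_every", "discount_rank_accumulator",
             "f", "hd", "dd", "dh", "hh", "delta", "epsilon", "v", "L")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  if (is.null(raw$variant)) stop("config field 'variant' is required",
                                 call. = FALSE)
  grab <- function(name, default) if (is.null(raw[[name]])) default
                                  else raw[[name]]
  payoffs <- tryCatch(
    payoff_params(f = grab("f", 0), hd = grab("hd", 1),
                  dd = grab("dd", 0.6), dh = grab("dh", 0.4),
                  hh = grab("hh", 0)),
    error = function(e) stop("invalid payoffs: ", conditionMessage(e),
                             call. = FALSE))
  learning <- tryCatch(
    learning_params(delta = grab("delta", 0.01),
                    epsilon = grab("epsilon", 0.01),
                    v = grab("v", 1), L = grab("L", 19)),
    error = function(e) stop("invalid learning parameters: ",
                             conditionMessage(e), call. = FALSE))
  sim_config(variant = raw$variant,
             N = grab("N", 20), rounds = grab("rounds", 1e6),
             payoffs = payoffs, learning = learning,
             rank_update_interval = grab("rank_update_interval", 1000),
             snapshot_every = grab("snapshot_every", 1000),
             seed = raw$seed,
             discount_rank_accumulator =
               grab("discount_rank_accumulator", FALSE))
}

#' Flatten a configuration to a writable named list
#'
#' Inverse of [config_from_list()]:
#' `config_from_list(config_as_list(cfg))` reproduces `cfg`.
#'
#' @param config An `hd_config`.
#' @return Named list of scalar fields.
#' @export
config_as_list <- function(config) {
  out <- list(variant = config$variant, N = config$N,
              rounds = config$rounds,
              rank_update_interval = config$rank_update_interval,
              snapshot_every = config$snapshot_every,
              discount_rank_accumulator = config$discount_rank_accumulator,
              f = config$payoffs$f, hd = config$payoffs$hd,
              dd = config$payoffs$dd, dh = config$payoffs$dh,
              hh = config$payoffs$hh,
              delta = config$learning$delta,
              epsilon = config$learning$epsilon,
              v = config$learning$v, L = config$learning$L)
  if (!is.null(config$seed)) out$seed <- config$seed
  out
}

#' Write trajectory outputs and a run manifest
#'
#' Serialises a run to plain-text files in `out_dir`: per-snapshot time
#' series (`timeseries.csv`: outcome counts and centralization per block),
#' final per-agent states (`agents.csv`: strategy weights, tremble-free
#' hawk probabilities, class, rank, payoffs), the rank history
#' (`rank_history.csv`, dynamic variant), the run summary (`summary.csv`),
#' and a JSON manifest (`manifest.json`) holding the full config, seed,
#' package version, and an inventory of the written files with checksums.
#' Outputs are deterministic: rerunning with the same trajectory rewrites
#' identical files.
#'
#' @param traj An `hd_trajectory`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_outputs <- function(traj, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- traj$config

  ts <- data.frame(round = traj$snapshot_rounds, traj$outcome_counts,
                   centralization = traj$centralization)
  utils::write.csv(ts, file.path(out_dir, "timeseries.csv"),
                   row.names = FALSE)

  probs <- strategy_probabilities(traj)
  agents <- data.frame(agent = seq_len(cfg$N), traj$final$strategy,
                       probs,
                       class = classify_agent_strategy(probs$p_hawk_host,
                                                       probs$p_hawk_visit),
                       rank = traj$final$ranks,
                       initial_rank = traj$initial_ranks,
                       cumulative_payoff = traj$final$cumulative_payoff,
                       rank_accumulator = traj$final$rank_accumulator)
  utils::write.csv(agents, file.path(out_dir, "agents.csv"),
                   row.names = FALSE)

  files <- c("timeseries.csv", "agents.csv", "summary.csv")
  if (cfg$variant == "dynamic_ranks") {
    rh <- data.frame(round = traj$rank_history_rounds, traj$rank_history)
    names(rh) <- c("round", paste0("agent_", seq_len(cfg$N)))
    utils::write.csv(rh, file.path(out_dir, "rank_history.csv"),
                     row.names = FALSE)
    files <- c(files, "rank_history.csv")
  }

  utils::write.csv(summarize_run(traj), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  inventory <- lapply(files, function(fn) {
    list(file = fn,
         md5 = unname(tools::md5sum(file.path(out_dir, fn))))
  })
  manifest <- list(config = config_as_list(cfg),
                   package_version =
                     as.character(utils::packageVersion("hawkdovenet")),
                   files = inventory)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
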