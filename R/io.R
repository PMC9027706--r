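#' @title Structured outputs, configuration files, and command entry points
#' @name cli_io
#'
#' @description
#' Long-format CSV writers for trajectories and sweep summaries, JSON
#' configuration and manifest handling, and the `cmd_*` functions behind
#' the `inst/cli/opinionet.R` command-line script. Output conventions:
#' trajectories and summaries as CSV, graphs as 0-based edge-list CSV,
#' manifests as JSON carrying everything needed to reproduce a run.
NULL

#' Write a trial's trajectories as long-format CSV
#'
#' Columns: `trial`, `t` (1-based timestep), `agent` (0-based id),
#' `q_idea1`, `tweet`, `attend` (0-based levels).
#'
#' @param trial An `opinion_trial`.
#' @param path Output file.
#' @param trial_id Value written in the `trial` column.
#' @export
write_trial_csv <- function(trial, path, trial_id = 1L) {
  TT <- nrow(trial$beliefs)
  N <- ncol(trial$beliefs)
  df <- data.frame(trial = trial_id,
                   t = rep(seq_len(TT), N),
                   agent = rep(seq_len(N) - 1L, each = TT),
                   q_idea1 = as.vector(trial$beliefs),
                   tweet = as.vector(trial$tweets),
                   attend = as.vector(trial$attends))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial configuration from JSON
#'
#' The file's keys must be a subset of [trial_config()]'s arguments
#' (`N`, `p`, `T_steps`, `gamma_mean`, `omega_soc_mean`, `omega_idea`,
#' `ph`, `eta`, `heterogeneity_variance`, `idea_init`, `seed`); unknown keys
#' raise an error naming them.
#'
#' @param path JSON file.
#' @return A `trial_config`.
#' @export
read_trial_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(trial_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    .stopf("unknown configuration key(s): %s (allowed: %s)",
           paste(bad, collapse = ", "), paste(allowed, collapse = ", "))
  do.call(trial_config, raw)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run: resolved configuration,
#' package version, seed, timestamp, and the output files written.
#'
#' @param config A `trial_config` or plain named list of settings.
#' @param files Character vector of output paths.
#' @param path Manifest destination.
#' @export
write_manifest <- function(config, files, path) {
  manifest <- list(
    package = "opinionet",
    version = as.character(utils::packageVersion("opinionet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    outputs = basename(files))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Predefined sweep experiment grids
#'
#' Returns the condition grid and fixed settings for the three standard
#' two-parameter sweeps, each a 15 x 15 grid (225 conditions) by default:
#' \describe{
#'   \item{`gamma_by_connectivity`}{confirmation bias 3.5..9 crossed with
#'     connection probability 0.2..0.8; `omega_soc_mean` 0.6, `eta` 0.}
#'   \item{`gamma_by_social_volatility`}{confirmation bias crossed with
#'     inverse social volatility 0.05..1.0; `p` 0.4, `eta` 0.}
#'   \item{`gamma_by_learning_rate`}{confirmation bias crossed with habit
#'     learning rate 0..0.9; `p` 0.4, `omega_soc_mean` 0.6.}
#' }
#'
#' @param experiment One of the names above.
#' @param n_levels Grid resolution per axis (default 15).
#' @return List with `grid` (data.frame) and `fixed` (named list for
#'   [trial_config()]).
#' @export
sweep_experiment <- function(experiment = c("gamma_by_connectivity",
                                            "gamma_by_social_volatility",
                                            "gamma_by_learning_rate"),
                             n_levels = 15L) {
  experiment <- match.arg(experiment)
  gamma <- seq(3.5, 9.0, length.out = n_levels)
  switch(experiment,
    gamma_by_connectivity = list(
      grid = expand.grid(gamma_mean = gamma,
                         p = seq(0.2, 0.8, length.out = n_levels)),
      fixed = list(omega_soc_mean = 0.6, eta = 0, N = 15L, T_steps = 100L)),
    gamma_by_social_volatility = list(
      grid = expand.grid(gamma_mean = gamma,
                         omega_soc_mean = seq(0.05, 1.0, length.out = n_levels)),
      fixed = list(p = 0.4, eta = 0, N = 15L, T_steps = 100L)),
    gamma_by_learning_rate = list(
      grid = expand.grid(gamma_mean = gamma,
                         eta = seq(0, 0.9, length.out = n_levels)),
      fixed = list(p = 0.4, omega_soc_mean = 0.6, N = 15L, T_steps = 100L)))
}

#' Run the four-panel single-agent scenario and write its trajectories
#'
#' Runs [run_single_agent_scenario()] for every combination of the supplied
#' `gamma` and `omega_soc` values (defaults: both in \{3, 9\}, the four
#' canonical bias/volatility regimes) and writes one trajectory CSV per
#' panel plus a manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param gamma,omega_soc Numeric vectors of panel values.
#' @param T_steps Timesteps per run.
#' @param seed Integer seed (each panel derives its own stream from it).
#' @return Invisible character vector of files written.
#' @export
cmd_single_agent <- function(out_dir, gamma = c(3, 9), omega_soc = c(3, 9),
                             T_steps = 100L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0L)
  panels <- expand.grid(gamma = gamma, omega_soc = omega_soc)
  for (i in seq_len(nrow(panels))) {
    g <- panels$gamma[i]
    w <- panels$omega_soc[i]
    tr <- run_single_agent_scenario(g, w, T_steps = T_steps,
                                    seed = .mix_seed(seed, i))
    f <- file.path(out_dir, sprintf("single_agent_gamma%g_omegasoc%g.csv", g, w))
    df <- data.frame(t = seq_len(T_steps),
                     q_idea1 = tr$beliefs[, 1L],
                     q_mb1 = tr$mb[[1L]][, 1L],
                     q_mb2 = tr$mb[[1L]][, 2L],
                     tweet = tr$tweets[, 1L],
                     attend = tr$attends[, 1L])
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  mf <- file.path(out_dir, "manifest.json")
  write_manifest(list(command = "single_agent", gamma = gamma,
                      omega_soc = omega_soc, T_steps = T_steps, seed = seed),
                 files, mf)
  invisible(c(files, mf))
}

#' Run one configured multi-agent trial and write its outputs
#'
#' @param config_file JSON configuration (see [read_trial_config()]).
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the configuration's.
#' @return Invisible character vector of files written (trajectory CSV,
#'   topology edge list, manifest).
#' @export
cmd_run <- function(config_file, out_dir, seed = NULL) {
  cfg <- read_trial_config(config_file)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tr <- run_trial(cfg)
  f_traj <- file.path(out_dir, "trajectory.csv")
  f_topo <- file.path(out_dir, "topology.csv")
  f_mani <- file.path(out_dir, "manifest.json")
  write_trial_csv(tr, f_traj)
  write_topology_csv(tr$topology, f_topo)
  write_manifest(cfg, c(f_traj, f_topo), f_mani)
  invisible(c(f_traj, f_topo, f_mani))
}

#' Run a sweep experiment and write its summary
#'
#' @param experiment Name of a predefined experiment (see
#'   [sweep_experiment()]); ignored when `grid` is given.
#' @param out_dir Output directory.
#' @param S Trials per condition.
#' @param seed Base seed.
#' @param grid Optional explicit condition data.frame overriding
#'   `experiment`.
#' @param n_levels Grid resolution for predefined experiments.
#' @param ... Further fixed arguments forwarded to [run_sweep()].
#' @return Invisible character vector of files written (summary CSV,
#'   manifest).
#' @export
cmd_sweep <- function(experiment = NULL, out_dir, S = 100L, seed = 1L,
                      grid = NULL, n_levels = 15L, ...) {
  if (S < 1L) .stopf("`S` must be at least 1")
  if (is.null(grid)) {
    if (is.null(experiment))
      .stopf("supply `experiment` (one of %s) or an explicit `grid`",
             paste(eval(formals(sweep_experiment)$experiment), collapse = ", "))
    ex <- sweep_experiment(experiment, n_levels = n_levels)
    grid <- ex$grid
    fixed <- ex$fixed
    res <- do.call(run_sweep, c(list(grid = grid, S = S, base_seed = seed),
                                fixed, list(...)))
  } else {
    res <- run_sweep(grid, S = S, base_seed = seed, ...)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f_csv <- file.path(out_dir, "sweep_summary.csv")
  utils::write.csv(as.data.frame(res), f_csv, row.names = FALSE, quote = FALSE)
  f_mani <- file.path(out_dir, "manifest.json")
  write_manifest(list(command = "sweep", experiment = experiment,
                      S = S, seed = seed, conditions = nrow(grid)),
                 f_csv, f_mani)
  invisible(c(f_csv, f_mani))
}
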