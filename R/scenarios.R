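#' Scenario configuration
#'
#' Bundles everything one experiment needs: the founder pair, model
#' parameters, environment schedule, horizon and seed, plus the
#' speciation-procedure knobs used by the adaptive-radiation scenario.
#' Each scenario carries sensible defaults:
#'
#' * `clade_initiation`: constant environment at `gamma = 0`, `t_end = 1200`.
#' * `tracking_stochastic`: peak redrawn from `U(-2, 2)` every 5 time
#'   units, 100 replicate trials, `t_end = 600`.
#' * `tracking_deterministic`: `gamma(t) = sin(t / 50)`, `t_end = 1200`.
#' * `rescue`: step schedule (default a single step to `-4` at `t = 600`),
#'   founders start at `u0 = 4`, `t_end = 1200`.
#' * `disturbance_regime`: explicit step schedule (default shifts to `-4`
#'   at 900 and `-8` at 1800), outcome classified at `t_end = 2500`.
#' * `adaptive_radiation`: bounded competition kernel with
#'   `sigma_a2 = 2`, `t_end = 1500`, speciation loop enabled.
#'
#' @param scenario One of `"clade_initiation"`, `"tracking_stochastic"`,
#'   `"tracking_deterministic"`, `"rescue"`, `"disturbance_regime"`,
#'   `"adaptive_radiation"`.
#' @param u0 Initial strategy shared by both founders (scenario default if
#'   `NULL`; the canonical close/medium/far starts are 0.5, 4 and 10).
#' @param x0 Initial density per founder.
#' @param k_fast,k_slow Founder evolvabilities.
#' @param params [model_params()]; scenario default if `NULL` (the
#'   radiation scenario defaults to the bounded kernel with
#'   `sigma_a2 = 2`).
#' @param env Environment schedule; scenario default if `NULL`.
#' @param n_trials Replicates for the stochastic tracking scenario.
#' @param t_end Horizon; scenario default if `NULL`.
#' @param record_dt Sampling/extinction-check interval.
#' @param seed Master seed: replicate seeds and speciation offsets derive
#'   from it, and the stochastic environment consumes a dedicated stream.
#' @param max_species Radiation guard: the run stops once this many
#'   species are extant.
#' @param speciation_tol Distance to a convergent-stable minimum that
#'   triggers speciation (default 0.02).
#' @param speciation_offset Half-width of the daughter strategy offset
#'   (default 0.02).
#' @param offset_mode `"interval"` draws the daughter offset uniformly on
#'   `[-speciation_offset, +speciation_offset]`; `"two_point"` draws
#'   `-speciation_offset` or `+speciation_offset` with equal probability.
#' @param refractory Minimum time between successive speciations of one
#'   lineage.
#' @param daughter_density Initial density of a daughter species (default
#'   1, i.e. exactly the extinction threshold; extinction requires density
#'   strictly below the threshold, so newborns are viable).
#' @return An object of class `evodyn_scenario`.
#' @export
scenario_config <- function(scenario = c("clade_initiation",
                                         "tracking_stochastic",
                                         "tracking_deterministic",
                                         "rescue",
                                         "disturbance_regime",
                                         "adaptive_radiation"),
                            u0 = NULL, x0 = 10,
                            k_fast = 0.5, k_slow = 0.2,
                            params = NULL, env = NULL,
                            n_trials = 100, t_end = NULL, record_dt = 1,
                            seed = 1L,
                            max_species = 12,
                            speciation_tol = 0.02,
                            speciation_offset = 0.02,
                            offset_mode = c("interval", "two_point"),
                            refractory = 5,
                            daughter_density = 1) {
  scenario <- match.arg(scenario)
  offset_mode <- match.arg(offset_mode)
  stopifnot("n_trials must be >= 1" = n_trials >= 1,
            "x0 must be positive" = x0 > 0)

  if (is.null(u0)) u0 <- switch(scenario, rescue = 4, disturbance_regime = 4, 0.5)
  if (is.null(params)) {
    params <- if (scenario == "adaptive_radiation")
      model_params(sigma_a2 = 2, kernel = "bounded") else model_params()
  }
  if (is.null(env)) {
    env <- switch(scenario,
      clade_initiation = env_constant(0),
      tracking_stochastic = env_stochastic(),
      tracking_deterministic = env_sinusoidal(),
      rescue = env_steps(times = 600, gammas = -4),
      disturbance_regime = env_steps(times = c(900, 1800), gammas = c(-4, -8)),
      adaptive_radiation = env_constant(0)
    )
  }
  if (is.null(t_end)) {
    t_end <- switch(scenario,
      clade_initiation = 1200,
      tracking_stochastic = 600,
      tracking_deterministic = 1200,
      rescue = 1200,
      disturbance_regime = 2500,
      adaptive_radiation = 1500
    )
  }
  check_params(params)
  if (!is_env(env)) stop("`env` must be an evodyn_env", call. = FALSE)
  if (scenario %in% c("rescue", "disturbance_regime") && env$mode != "step")
    stop(scenario, " requires a step environment schedule", call. = FALSE)
  if (scenario == "tracking_stochastic" && env$mode != "stochastic")
    stop("tracking_stochastic requires a stochastic environment", call. = FALSE)

  structure(list(
    scenario = scenario, u0 = u0, x0 = x0, k_fast = k_fast, k_slow = k_slow,
    params = params, env = env, n_trials = n_trials, t_end = t_end,
    record_dt = record_dt, seed = seed, max_species = max_species,
    speciation_tol = speciation_tol, speciation_offset = speciation_offset,
    offset_mode = offset_mode, refractory = refractory,
    daughter_density = daughter_density
  ), class = "evodyn_scenario")
}

#' @export
print.evodyn_scenario <- function(x, ...) {
  cat(sprintf("scenario: %s (u0 = %g, x0 = %g, t_end = %g, seed = %s)\n",
              x$scenario, x$u0, x$x0, x$t_end, format(x$seed)))
  invisible(x)
}

check_scenario <- function(config, expected = NULL) {
  if (!inherits(config, "evodyn_scenario"))
    stop("`config` must be created by scenario_config()", call. = FALSE)
  if (!is.null(expected) && !config$scenario %in% expected)
    stop("config declares scenario '", config$scenario, "', expected ",
         paste(expected, collapse = " or "), call. = FALSE)
  config
}

config_founders <- function(config) {
  founder_pair(config$u0, config$x0, config$k_fast, config$k_slow)
}

#' Run the clade-initiation scenario
#'
#' Two founders (one fast, one slow evolver) enter a stable environment at
#' the same strategy and density and race toward the eco-evolutionary
#' equilibrium at the carrying-capacity peak.
#'
#' @param config A [scenario_config()] with scenario `"clade_initiation"`.
#' @return An `evodyn_trajectory`.
#' @export
run_clade_initiation <- function(config) {
  check_scenario(config, "clade_initiation")
  simulate_community(config_founders(config), config$env, config$params,
                     t_end = config$t_end, record_dt = config$record_dt,
                     seed = config$seed)
}

#' Run the evolutionary-tracking scenario
#'
#' Stochastic mode runs `n_trials` independent replicates of the
#' peak-redrawing environment (each replicate gets its own seed derived
#' from the master seed) and aggregates extinction statistics.
#' Deterministic (sinusoidal) mode runs a single trajectory.
#'
#' @param config A [scenario_config()] with scenario `"tracking_stochastic"`
#'   or `"tracking_deterministic"`.
#' @return A list with `trajectories` (list of `evodyn_trajectory`) and
#'   `summary` (see [extinction_summary()]).
#' @export
run_tracking <- function(config) {
  check_scenario(config, c("tracking_stochastic", "tracking_deterministic"))
  comm <- config_founders(config)
  if (config$scenario == "tracking_deterministic") {
    trs <- list(simulate_community(comm, config$env, config$params,
                                   t_end = config$t_end,
                                   record_dt = config$record_dt,
                                   seed = config$seed))
  } else {
    trial_seeds <- with_seed(config$seed,
                             sample.int(.Machine$integer.max, config$n_trials))
    trs <- lapply(trial_seeds, function(s)
      simulate_community(comm, config$env, config$params,
                         t_end = config$t_end, record_dt = config$record_dt,
                         seed = s))
  }
  list(trajectories = trs, summary = extinction_summary(trs))
}

#' Run the evolutionary-rescue scenario
#'
#' Identical to clade initiation (medium start, `u0 = 4`) until the step
#' schedule abruptly moves the carrying-capacity peak, leaving both
#' species far outside their niche; survival then depends on evolving a
#' viable strategy before the density crosses the extinction threshold.
#'
#' @param config A [scenario_config()] with scenario `"rescue"`.
#' @return An `evodyn_trajectory`.
#' @export
run_rescue <- function(config) {
  check_scenario(config, "rescue")
  simulate_community(config_founders(config), config$env, config$params,
                     t_end = config$t_end, record_dt = config$record_dt,
                     seed = config$seed)
}

#' Run a disturbance-regime experiment
#'
#' Applies an explicit step schedule of environmental shifts and
#' classifies the outcome at the horizon: which of the two founders (or
#' both) is still extant.  Rare disturbances favour the slow evolver,
#' frequent ones the fast evolver, and intermediate timings permit
#' transient coexistence with cyclical dynamics (a storage-effect-like
#' pattern driven by alternating disturbance and stasis).
#'
#' @param config A [scenario_config()] with scenario `"disturbance_regime"`.
#' @return A list with `trajectory` and `outcome` (one of
#'   `"slow_survives"`, `"fast_survives"`, `"coexistence"`, `"collapse"`).
#' @export
run_disturbance_regime <- function(config) {
  check_scenario(config, "disturbance_regime")
  tr <- simulate_community(config_founders(config), config$env, config$params,
                           t_end = config$t_end, record_dt = config$record_dt,
                           seed = config$seed)
  ext <- tr$community[tr$community$extant, , drop = FALSE]
  fast <- any(grepl("^fast", ext$id))
  slow <- any(grepl("^slow", ext$id))
  outcome <- if (fast && slow) "coexistence"
    else if (slow) "slow_survives"
    else if (fast) "fast_survives"
    else "collapse"
  list(trajectory = tr, outcome = outcome)
}

#' Aggregate extinction statistics over replicate trajectories
#'
#' Counts, per species, the replicates containing an extinction event and
#' reports the mean and sample standard deviation of the extinction times
#' over those replicates only.
#'
#' @param trajectories A list of `evodyn_trajectory` objects (or a single
#'   one).
#' @return A data frame with columns `species_id`, `n_trials`,
#'   `n_extinct`, `mean_time`, `sd_time` (`NA` when undefined).
#' @examples
#' # three replicates all losing species "a" at t = 10 give sd 0
#' @export
extinction_summary <- function(trajectories) {
  if (inherits(trajectories, "evodyn_trajectory"))
    trajectories <- list(trajectories)
  stopifnot("at least one trajectory is required" = length(trajectories) >= 1)
  ids <- unique(unlist(lapply(trajectories, function(tr) colnames(tr$density))))
  out <- lapply(ids, function(id) {
    times <- vapply(trajectories, extinction_time, numeric(1), id = id)
    times <- times[!is.na(times)]
    data.frame(
      species_id = id,
      n_trials = length(trajectories),
      n_extinct = length(times),
      mean_time = if (length(times)) mean(times) else NA_real_,
      sd_time = if (length(times) >= 2) stats::sd(times) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
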