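#' Environment schedules
#'
#' The environment enters the model solely through `gamma(t)`, the position
#' of the carrying-capacity peak.  Four schedule modes are available:
#'
#' * `env_constant()`: fixed peak (clade initiation, adaptive radiation).
#' * `env_stochastic()`: piecewise-constant peak redrawn uniformly from
#'   `redraw_bounds` every `redraw_interval` time units, starting at
#'   `t = redraw_interval` (the initial window keeps `gamma0`).
#' * `env_sinusoidal()`: `gamma(t) = amplitude * sin(t / period)`.
#' * `env_steps()`: an explicit list of `(time, gamma)` jumps — the
#'   disturbance schedules of the rescue and regime scenarios.
#'
#' @param gamma0 Initial peak position (strategy units).
#' @param redraw_interval Time between redraws (stochastic mode).
#' @param redraw_bounds Length-2 numeric, lower < upper (stochastic mode).
#' @param seed Optional RNG seed attached to a stochastic schedule; a seed
#'   passed to [simulate_community()] takes precedence.
#' @param amplitude,period Sinusoidal-mode parameters.
#' @param times,gammas Step mode: strictly increasing jump times and the
#'   peak positions that take effect at each.
#' @return An object of class `evodyn_env`.
#' @name environments
NULL

#' @rdname environments
#' @export
env_constant <- function(gamma0 = 0) {
  structure(list(mode = "constant", gamma0 = gamma0), class = "evodyn_env")
}

#' @rdname environments
#' @export
env_stochastic <- function(gamma0 = 0, redraw_interval = 5,
                           redraw_bounds = c(-2, 2), seed = NULL) {
  stopifnot(
    "redraw_interval must be positive" = redraw_interval > 0,
    "redraw_bounds must be length 2 with low < high" =
      length(redraw_bounds) == 2 && redraw_bounds[1] < redraw_bounds[2]
  )
  structure(list(mode = "stochastic", gamma0 = gamma0,
                 redraw_interval = redraw_interval,
                 redraw_bounds = redraw_bounds, seed = seed),
            class = "evodyn_env")
}

#' @rdname environments
#' @export
env_sinusoidal <- function(amplitude = 1, period = 50) {
  stopifnot("period must be positive" = period > 0)
  structure(list(mode = "sinusoidal", gamma0 = 0,
                 amplitude = amplitude, period = period),
            class = "evodyn_env")
}

#' @rdname environments
#' @export
env_steps <- function(times, gammas, gamma0 = 0) {
  stopifnot(
    "times and gammas must have equal length" = length(times) == length(gammas),
    "at least one step is required" = length(times) >= 1,
    "step times must be strictly increasing and positive" =
      all(times > 0) && all(diff(times) > 0)
  )
  structure(list(mode = "step", gamma0 = gamma0,
                 steps = data.frame(time = times, gamma = gammas)),
            class = "evodyn_env")
}

is_env <- function(x) inherits(x, "evodyn_env")

#' Resolve an environment schedule over a horizon
#'
#' Materialises `gamma(t)` on `[0, t_end]`: draws the stochastic sequence
#' (consuming its own dedicated RNG stream so community events elsewhere in
#' a simulation cannot shift it), and lists every discontinuity so the
#' integrator can be restarted there.
#'
#' @param env An `evodyn_env`.
#' @param t_end Horizon.
#' @param seed Seed for stochastic draws; overrides `env$seed`.
#' @return A list with `gamma_fun(t)` (vectorised), `breaks` (discontinuity
#'   times in `(0, t_end)`), and `schedule` (a `time`/`gamma` data frame of
#'   the realised piecewise-constant segments, or `NULL` for smooth modes).
#' @export
resolve_env <- function(env, t_end, seed = NULL) {
  if (!is_env(env)) stop("`env` must be created by an env_*() constructor", call. = FALSE)
  switch(env$mode,
    constant = list(
      gamma_fun = function(t) rep(env$gamma0, length(t)),
      breaks = numeric(0),
      schedule = data.frame(time = 0, gamma = env$gamma0)
    ),
    sinusoidal = list(
      gamma_fun = function(t) env$amplitude * sin(t / env$period),
      breaks = numeric(0),
      schedule = NULL
    ),
    step = {
      st <- env$steps[env$steps$time < t_end, , drop = FALSE]
      sched <- rbind(data.frame(time = 0, gamma = env$gamma0), st)
      list(
        gamma_fun = step_gamma_fun(sched),
        breaks = st$time,
        schedule = sched
      )
    },
    stochastic = {
      seed <- if (!is.null(seed)) seed else env$seed
      if (is.null(seed))
        stop("a stochastic environment needs a seed (env or simulate argument)",
             call. = FALSE)
      times <- seq(env$redraw_interval, t_end, by = env$redraw_interval)
      times <- times[times < t_end]
      draws <- with_seed(seed, stats::runif(length(times),
                                            env$redraw_bounds[1],
                                            env$redraw_bounds[2]))
      sched <- data.frame(time = c(0, times), gamma = c(env$gamma0, draws))
      list(
        gamma_fun = step_gamma_fun(sched),
        breaks = times,
        schedule = sched
      )
    },
    stop("unknown environment mode: ", env$mode, call. = FALSE)
  )
}

## Right-continuous piecewise-constant gamma(t) from a (time, gamma) table.
step_gamma_fun <- function(sched) {
  force(sched)
  function(t) sched$gamma[findInterval(t, sched$time)]
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.evodyn_env <- function(x, ...) {
  cat("environment schedule:", x$mode, "\n")
  switch(x$mode,
    constant = cat("  gamma =", x$gamma0, "\n"),
    stochastic = cat(sprintf("  gamma0 = %g, redraw U[%g, %g] every %g time units\n",
                             x$gamma0, x$redraw_bounds[1], x$redraw_bounds[2],
                             x$redraw_interval)),
    sinusoidal = cat(sprintf("  gamma(t) = %g * sin(t / %g)\n", x$amplitude, x$period)),
    step = { cat("  steps:\n"); print(x$steps) }
  )
  invisible(x)
}
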