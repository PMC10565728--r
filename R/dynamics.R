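#' Right-hand side of the coupled population/strategy ODE system
#'
#' For each extant species `i`, `dx_i/dt = x_i * G(v = u_i)` and
#' `du_i/dt = k_i * dG/dv` at `v = u_i`.  Extinct species contribute zero
#' derivatives and are excluded from every competition sum.
#'
#' @param state Numeric vector `c(x_1..x_n, u_1..u_n)` in community row
#'   order; densities and strategies here override those in `community`.
#' @param t Time (unused by the autonomous core; kept for ODE-solver
#'   compatibility).
#' @param community An `evodyn_community` supplying `k`, ids and extant
#'   flags.
#' @param gamma Current position of the carrying-capacity peak.
#' @param params [model_params()].
#' @return Derivative vector in the same layout as `state`.
#' @export
community_rhs <- function(state, t = 0, community, gamma, params) {
  community <- check_community(community)
  n <- nrow(community)
  stopifnot("state must be c(x, u) over the community" = length(state) == 2L * n)
  x <- state[seq_len(n)]
  u <- state[n + seq_len(n)]
  alive <- community$extant
  deriv <- numeric(2L * n)
  if (any(alive)) {
    d_alive <- rhs_core(x[alive], u[alive], community$k[alive], gamma, params)
    deriv[seq_len(n)][alive] <- d_alive$dx
    deriv[n + seq_len(n)][alive] <- d_alive$du
  }
  deriv
}

## Vectorised derivatives for the alive subset only.
rhs_core <- function(x, u, k, gamma, params) {
  kt <- cap_terms(u, gamma, params)
  cl <- comp_load(u, u, x, params)
  G <- params$r / kt$K * (kt$K - cl$S) - params$d * k
  grad <- -params$r * (cl$S1 / kt$K - cl$S * kt$K1 / kt$K^2)
  list(dx = x * G, du = k * grad)
}

#' Simulate the coupled eco-evolutionary dynamics
#'
#' Integrates the population/strategy ODEs with `deSolve::ode` (adaptive
#' lsoda), restarting the integrator at every environment discontinuity so
#' no step straddles a jump in `gamma`.  The extinction rule is checked at
#' every recorded sample: a species whose density falls strictly below
#' `params$extinction_threshold` is marked extinct at that sample time, its
#' density is set to 0 and its strategy frozen, and it leaves all
#' competition sums.  Extinction is absorbing.
#'
#' @param community Initial `evodyn_community`.
#' @param env An environment schedule (see [environments]).
#' @param params [model_params()].
#' @param t_end Simulation horizon (> 0).
#' @param record_dt Sampling interval of the returned series (default 1,
#'   also the cadence of the extinction check).
#' @param seed Seed for the stochastic environment stream (ignored by
#'   deterministic schedules).
#' @param rtol,atol Integrator tolerances.
#' @return An `evodyn_trajectory`: sample `times`, `density` and `strategy`
#'   matrices (one column per species, `NA` before a species is born),
#'   the realised `gamma` series, an `events` data frame (extinctions,
#'   environment changes), the final `community`, and the resolved
#'   configuration.
#' @examples
#' \donttest{
#' tr <- simulate_community(founder_pair(u0 = 10), env_constant(0),
#'                          model_params(), t_end = 50)
#' tr$events  # the slow evolver goes extinct at t = 11
#' }
#' @export
simulate_community <- function(community, env, params, t_end,
                               record_dt = 1, seed = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  community <- check_community(community)
  check_params(params)
  stopifnot("t_end must be positive" = t_end > 0,
            "record_dt must be positive" = record_dt > 0)

  resolved <- resolve_env(env, t_end, seed = seed)
  grid <- sort(unique(c(seq(0, t_end, by = record_dt), resolved$breaks, t_end)))
  n <- nrow(community)
  ids <- community$id

  dens <- matrix(NA_real_, length(grid), n, dimnames = list(NULL, ids))
  strat <- matrix(NA_real_, length(grid), n, dimnames = list(NULL, ids))
  gamma_rec <- resolved$gamma_fun(grid)

  state <- list(x = community$x, u = community$u, alive = community$extant)
  state$x[!state$alive] <- 0
  events <- data.frame(time = numeric(0), type = character(0),
                       species_id = character(0), stringsAsFactors = FALSE)
  ext_time <- community$extinction_time
  dens[1, ] <- state$x
  strat[1, ] <- state$u

  for (b in resolved$breaks) {
    events <- rbind(events, data.frame(
      time = b, type = "env_change", species_id = NA_character_,
      stringsAsFactors = FALSE))
  }

  seg_ends <- sort(unique(c(resolved$breaks, t_end)))
  t_cur <- 0
  k <- community$k
  thr <- params$extinction_threshold

  while (t_cur < t_end) {
    seg_end <- seg_ends[seg_ends > t_cur][1]
    if (!any(state$alive)) {
      ## everything extinct: series stay flat to the horizon
      idx <- which(grid > t_cur)
      dens[idx, ] <- rep(state$x, each = length(idx))
      strat[idx, ] <- rep(state$u, each = length(idx))
      t_cur <- t_end
      break
    }
    times <- grid[grid >= t_cur & grid <= seg_end]
    if (length(times) < 2L) { t_cur <- seg_end; next }

    alive <- state$alive
    k_al <- k[alive]
    gamma_fun <- resolved$gamma_fun
    func <- function(t, y, parms) {
      m <- length(y) / 2L
      d <- rhs_core(y[seq_len(m)], y[m + seq_len(m)], k_al, gamma_fun(t), params)
      list(c(d$dx, d$du))
    }
    y0 <- c(state$x[alive], state$u[alive])
    sol <- deSolve::ode(y = y0, times = times, func = func, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed on [", t_cur, ", ", seg_end,
           "]: tolerances not met", call. = FALSE)

    m <- sum(alive)
    stopped <- FALSE
    for (r in 2:nrow(sol)) {
      xr <- pmax(sol[r, 1 + seq_len(m)], 0)
      ur <- sol[r, 1 + m + seq_len(m)]
      tr <- sol[r, 1]
      row <- match(tr, grid)
      xf <- state$x; uf <- state$u
      xf[alive] <- xr; uf[alive] <- ur
      dead <- state$alive & xf < thr
      if (any(dead)) {
        xf[dead] <- 0
        for (i in which(dead)) {
          events <- rbind(events, data.frame(
            time = tr, type = "extinction", species_id = ids[i],
            stringsAsFactors = FALSE))
        }
        ext_time[dead] <- tr
        state$alive[dead] <- FALSE
        dens[row, ] <- xf
        strat[row, ] <- uf
        state$x <- xf; state$u <- uf
        t_cur <- tr
        stopped <- TRUE
        break
      }
      dens[row, ] <- xf
      strat[row, ] <- uf
      state$x <- xf; state$u <- uf
    }
    if (!stopped) t_cur <- seg_end
  }

  final <- community
  final$u <- state$u
  final$x <- state$x
  final$extant <- state$alive
  final$extinction_time <- ext_time
  class(final) <- c("evodyn_community", "data.frame")
  events <- events[order(events$time, events$type), , drop = FALSE]
  rownames(events) <- NULL

  structure(list(
    times = grid, density = dens, strategy = strat, gamma = gamma_rec,
    events = events, community = final, params = params, env = env,
    config = list(t_end = t_end, record_dt = record_dt, seed = seed,
                  rtol = rtol, atol = atol,
                  initial = data.frame(id = ids, k = k,
                                       u0 = community$u, x0 = community$x))
  ), class = "evodyn_trajectory")
}

#' Extinction time of a species in a trajectory
#' @param trajectory An `evodyn_trajectory`.
#' @param id Species id.
#' @return The recorded extinction time, or `NA` if the species is extant.
#' @export
extinction_time <- function(trajectory, id) {
  ev <- trajectory$events
  hit <- ev$time[ev$type == "extinction" & ev$species_id == id]
  if (length(hit)) hit[1] else NA_real_
}

#' @export
print.evodyn_trajectory <- function(x, ...) {
  n_ext <- sum(x$events$type == "extinction")
  n_spc <- sum(x$events$type == "speciation")
  cat(sprintf("eco-evolutionary trajectory: %d species, t in [0, %g], %d samples\n",
              ncol(x$density), max(x$times), length(x$times)))
  cat(sprintf("  events: %d extinction(s), %d speciation(s)\n", n_ext, n_spc))
  ext <- x$community[!x$community$extant, , drop = FALSE]
  if (nrow(ext))
    cat("  extinct:", paste(sprintf("%s @ %g", ext$id, ext$extinction_time),
                            collapse = ", "), "\n")
  invisible(x)
}
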