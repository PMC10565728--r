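#' Run the adaptive-radiation scenario with its speciation loop
#'
#' With a bounded competition kernel narrower than the resource kernel
#' (`sigma_a2 < sigma_k2`) the adaptive landscape develops convergent-stable
#' minima: strategy dynamics are attracted to them, but selection there is
#' disruptive, so a lineage that reaches one can branch.  The event loop:
#'
#' 1. Integrate the community one recording step.
#' 2. Apply the extinction rule to *established* lineages — those whose
#'    density has exceeded the threshold at least once.  Founders start
#'    established; a daughter is born exactly at the threshold and dips
#'    slightly below it while disruptive selection carries it away from
#'    its parent, so the threshold (a proxy for demographic stochasticity
#'    in established populations) only starts to apply once the daughter
#'    has grown past it.
#' 3. Recompute the singular points of the current landscape (their
#'    locations are shared by all `k`, since the cost term is linear).
#' 4. If an extant species has newly come within `speciation_tol` of a
#'    convergent-stable minimum (it must have left the neighbourhood since
#'    its last branching — speciation is triggered by *approaching* a
#'    minimum, not by sitting at one — and be past its refractory period),
#'    it speciates: the daughter inherits `k`, takes strategy
#'    `u_parent + offset` with the offset drawn uniformly from
#'    `[-speciation_offset, +speciation_offset]` (or a two-point draw, see
#'    [scenario_config()]), and starts at `daughter_density`.
#'    At most one speciation is processed per step, closest-to-minimum
#'    first (ties by community order).
#'
#' The run stops at `t_end` or as soon as `max_species` species are extant.
#' Daughters are named `fast_n`/`slow_n` after their founding G-function,
#' numbered in speciation order across the whole community.
#'
#' @param config A [scenario_config()] with scenario `"adaptive_radiation"`.
#' @return A list with `trajectory` (an `evodyn_trajectory`; series are
#'   `NA` before a lineage is born) and `phylogeny` (an
#'   `evodyn_phylogeny`).
#' @export
run_adaptive_radiation <- function(config) {
  check_scenario(config, "adaptive_radiation")
  params <- config$params
  t_end <- config$t_end
  record_dt <- config$record_dt

  resolved <- resolve_env(config$env, t_end, seed = config$seed)
  grid <- sort(unique(c(seq(0, t_end, by = record_dt), resolved$breaks, t_end)))
  gamma_fun <- resolved$gamma_fun

  founders <- config_founders(config)
  st <- list(
    id = founders$id, k = founders$k, u = founders$u, x = founders$x,
    alive = rep(TRUE, 2), parent = rep(NA_character_, 2),
    birth = rep(0, 2), ext_time = rep(NA_real_, 2),
    armed = rep(FALSE, 2),            # must first leave a minimum's vicinity
    last_spec = rep(-Inf, 2),
    ## the extinction threshold applies only to established lineages: those
    ## whose density has exceeded it at least once (founders at birth);
    ## an incipient daughter starts exactly at the threshold and dips
    ## slightly below it before disruptive selection carries it away
    established = founders$x > params$extinction_threshold
  )
  n_max_guess <- config$max_species + 2
  dens <- matrix(NA_real_, length(grid), n_max_guess)
  strat <- matrix(NA_real_, length(grid), n_max_guess)
  dens[1, 1:2] <- st$x
  strat[1, 1:2] <- st$u
  events <- data.frame(time = numeric(0), type = character(0),
                       species_id = character(0), stringsAsFactors = FALSE)
  for (b in resolved$breaks)
    events <- rbind(events, data.frame(time = b, type = "env_change",
                                       species_id = NA_character_,
                                       stringsAsFactors = FALSE))
  thr <- params$extinction_threshold
  last_row <- length(grid)

  with_seed(config$seed, {
    for (row in 2:length(grid)) {
      t0 <- grid[row - 1]
      t1 <- grid[row]
      al <- which(st$alive)
      k_al <- st$k[al]
      func <- function(t, y, parms) {
        m <- length(y) / 2L
        d <- rhs_core(y[seq_len(m)], y[m + seq_len(m)], k_al, gamma_fun(t), params)
        list(c(d$dx, d$du))
      }
      sol <- deSolve::ode(y = c(st$x[al], st$u[al]), times = c(t0, t1),
                          func = func, parms = NULL, method = "lsoda",
                          rtol = 1e-8, atol = 1e-10)
      if (attr(sol, "istate")[1] < 0)
        stop("ODE integration failed on [", t0, ", ", t1, "]", call. = FALSE)
      m <- length(al)
      st$x[al] <- pmax(sol[2, 1 + seq_len(m)], 0)
      st$u[al] <- sol[2, 1 + m + seq_len(m)]

      st$established <- st$established | st$x > thr
      dead <- which(st$alive & st$established & st$x < thr)
      if (length(dead)) {
        st$x[dead] <- 0
        st$alive[dead] <- FALSE
        st$ext_time[dead] <- t1
        events <- rbind(events, data.frame(
          time = t1, type = "extinction", species_id = st$id[dead],
          stringsAsFactors = FALSE))
      }

      dens[row, seq_along(st$id)] <- st$x
      strat[row, seq_along(st$id)] <- st$u

      if (sum(st$alive) >= config$max_species) { last_row <- row; break }
      if (!any(st$alive)) { last_row <- row; break }

      ## --- speciation check -------------------------------------------
      comm <- radiation_community(st)
      gamma_now <- gamma_fun(t1)
      sp <- find_singular_points(st$k[st$alive][1], comm, gamma_now, params)
      mins <- sp$v_star[sp$kind == "convergent_minimum"]
      cand_i <- integer(0); cand_d <- numeric(0)
      for (i in which(st$alive)) {
        d_i <- if (length(mins)) min(abs(st$u[i] - mins)) else Inf
        if (d_i > config$speciation_tol) {
          st$armed[i] <- TRUE
        } else if (st$armed[i] && t1 - st$last_spec[i] >= config$refractory) {
          cand_i <- c(cand_i, i); cand_d <- c(cand_d, d_i)
        }
      }
      if (length(cand_i)) {
        i <- cand_i[which.min(cand_d)]
        off <- if (config$offset_mode == "interval")
          stats::runif(1, -config$speciation_offset, config$speciation_offset)
        else
          sample(c(-1, 1), 1) * config$speciation_offset
        new_id <- paste0(sub("_.*$", "", st$id[i]), "_", length(st$id) - 1)
        st$id <- c(st$id, new_id)
        st$k <- c(st$k, st$k[i])
        st$u <- c(st$u, st$u[i] + off)
        st$x <- c(st$x, config$daughter_density)
        st$alive <- c(st$alive, TRUE)
        st$parent <- c(st$parent, st$id[i])
        st$birth <- c(st$birth, t1)
        st$ext_time <- c(st$ext_time, NA_real_)
        st$armed[i] <- FALSE
        st$armed <- c(st$armed, FALSE)
        st$last_spec[i] <- t1
        st$last_spec <- c(st$last_spec, t1)
        st$established <- c(st$established,
                            config$daughter_density > thr)
        events <- rbind(events, data.frame(
          time = t1, type = "speciation", species_id = new_id,
          stringsAsFactors = FALSE))
        if (length(st$id) > ncol(dens)) {
          dens <- cbind(dens, NA_real_)
          strat <- cbind(strat, NA_real_)
        }
        dens[row, length(st$id)] <- config$daughter_density
        strat[row, length(st$id)] <- st$u[length(st$id)]
      }
    }
  })

  n <- length(st$id)
  grid <- grid[seq_len(last_row)]
  dens <- dens[seq_len(last_row), seq_len(n), drop = FALSE]
  strat <- strat[seq_len(last_row), seq_len(n), drop = FALSE]
  colnames(dens) <- colnames(strat) <- st$id

  final <- data.frame(
    id = st$id, k = st$k, u = st$u, x = st$x, extant = st$alive,
    parent_id = st$parent, birth_time = st$birth,
    extinction_time = st$ext_time, stringsAsFactors = FALSE
  )
  class(final) <- c("evodyn_community", "data.frame")
  events <- events[order(events$time, events$type), , drop = FALSE]
  rownames(events) <- NULL

  trajectory <- structure(list(
    times = grid, density = dens, strategy = strat,
    gamma = gamma_fun(grid), events = events, community = final,
    params = params, env = config$env,
    config = list(t_end = t_end, record_dt = record_dt, seed = config$seed,
                  rtol = 1e-8, atol = 1e-10,
                  max_species = config$max_species,
                  speciation_tol = config$speciation_tol,
                  speciation_offset = config$speciation_offset,
                  offset_mode = config$offset_mode,
                  refractory = config$refractory,
                  daughter_density = config$daughter_density,
                  initial = data.frame(id = founders$id, k = founders$k,
                                       u0 = founders$u, x0 = founders$x))
  ), class = "evodyn_trajectory")

  nodes <- as.data.frame(final)[, c("id", "parent_id", "birth_time",
                                    "extinction_time", "k")]
  nodes$u_final <- final$u
  list(trajectory = trajectory,
       phylogeny = phylogeny(nodes, t_end = max(grid)))
}

radiation_community <- function(st) {
  out <- data.frame(
    id = st$id, k = st$k, u = st$u, x = st$x, extant = st$alive,
    stringsAsFactors = FALSE
  )
  class(out) <- c("evodyn_community", "data.frame")
  out
}
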