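#' Carrying capacity as a function of strategy
#'
#' Gaussian resource kernel: `K(v) = Km * exp(-(v - gamma)^2 / (2 * sigma_k2))`.
#' The environmental optimum `gamma` is the strategy that maximises carrying
#' capacity; a moving `gamma(t)` is how the environment scenarios drive the
#' system.
#'
#' @param v Focal strategy (vectorised).
#' @param gamma Current position of the carrying-capacity peak.
#' @param params [model_params()].
#' @return Carrying capacity, strictly positive, maximal (`Km`) at `v = gamma`.
#' @export
carrying_capacity <- function(v, gamma, params) {
  check_params(params)
  params$Km * exp(-(v - gamma)^2 / (2 * params$sigma_k2))
}

#' Competition coefficient between strategies
#'
#' Like competes most with like: the coefficient declines in a Gaussian
#' fashion as strategies diverge, and equals 1 when `v == u`.  The
#' `"bounded"` variant, `floor + (1 - floor) * exp(...)`, keeps a minimum
#' level of competition between arbitrarily distant strategies and is used
#' in the adaptive-radiation regime (`sigma_a2 < sigma_k2`) to rule out
#' unlimited niche packing.
#'
#' @param v Focal strategy (vectorised).
#' @param u Competitor strategy (vectorised, recycled against `v`).
#' @inheritParams carrying_capacity
#' @return Competition coefficient in `(0, 1]` (gaussian) or
#'   `[floor, 1]` (bounded).
#' @export
competition_coeff <- function(v, u, params) {
  check_params(params)
  e <- exp(-(v - u)^2 / (2 * params$sigma_a2))
  if (params$kernel == "bounded") {
    params$kernel_floor + (1 - params$kernel_floor) * e
  } else {
    e
  }
}

## Kernel terms shared by fitness and its derivatives.  `v` is a vector,
## `u`/`x` describe the extant community.  Returns the competition load
## S(v) = sum_j a(v, u_j) x_j and its first two derivatives in v.
comp_load <- function(v, u, x, params) {
  if (length(u) == 0L) {
    z <- numeric(length(v))
    return(list(S = z, S1 = z, S2 = z))
  }
  D <- outer(v, u, "-")                  # |v| x n
  e <- exp(-D^2 / (2 * params$sigma_a2))
  if (params$kernel == "bounded") {
    f <- params$kernel_floor
    a  <- f + (1 - f) * e
    a1 <- (1 - f) * e * (-D / params$sigma_a2)
    a2 <- (1 - f) * e * (D^2 / params$sigma_a2^2 - 1 / params$sigma_a2)
  } else {
    a  <- e
    a1 <- e * (-D / params$sigma_a2)
    a2 <- e * (D^2 / params$sigma_a2^2 - 1 / params$sigma_a2)
  }
  list(S = drop(a %*% x), S1 = drop(a1 %*% x), S2 = drop(a2 %*% x))
}

## K(v) and its first two derivatives in v.
cap_terms <- function(v, gamma, params) {
  K <- params$Km * exp(-(v - gamma)^2 / (2 * params$sigma_k2))
  w <- (v - gamma) / params$sigma_k2
  list(K = K, K1 = -K * w, K2 = K * (w^2 - 1 / params$sigma_k2))
}

community_uxe <- function(community) {
  community <- check_community(community)
  ext <- community$extant & community$x > 0
  list(u = community$u[ext], x = community$x[ext])
}

#' Per-capita growth rate of a focal strategy (the G-function)
#'
#' `G(v) = (r / K(v)) * (K(v) - sum_j a(v, u_j) x_j) - d * k_focal`: logistic
#' growth toward a strategy-dependent carrying capacity, discounted by
#' competition from every extant species (including the focal one) and by
#' the linear cost of evolvability.  The adaptive landscape is `G` as a
#' function of `v` at a fixed community state.
#'
#' @param v Focal strategy (vectorised).
#' @param k_focal Evolvability of the focal individual (enters only through
#'   the cost term `d * k_focal`).
#' @param community An `evodyn_community`; only extant species contribute to
#'   the competition sum.  May be empty.
#' @inheritParams carrying_capacity
#' @return Per-capita growth rate at each `v`.
#' @examples
#' p <- model_params()
#' comm <- community(species("s", k = 0.2, u = 0, x = 96))
#' fitness(0, k_focal = 0.2, community = comm, gamma = 0, params = p)  # ~ 0
#' @export
fitness <- function(v, k_focal, community, gamma, params) {
  check_params(params)
  ce <- community_uxe(community)
  K <- carrying_capacity(v, gamma, params)
  S <- comp_load(v, ce$u, ce$x, params)$S
  params$r / K * (K - S) - params$d * k_focal
}

#' Selection gradient of the G-function
#'
#' First derivative of [fitness()] in the focal strategy, evaluated
#' analytically (the cost term `d * k` is constant in `v` and drops out).
#' This is the slope each species climbs: `du_i/dt = k_i * dG/dv` at
#' `v = u_i`.
#'
#' @param u_i Strategy at which to evaluate the gradient (vectorised).
#' @inheritParams fitness
#' @param k_focal Unused by the derivative (kept for interface symmetry
#'   with [fitness()]).
#' @return `dG/dv` at each `u_i`.
#' @export
selection_gradient <- function(u_i, k_focal = 0, community, gamma, params) {
  check_params(params)
  ce <- community_uxe(community)
  kt <- cap_terms(u_i, gamma, params)
  cl <- comp_load(u_i, ce$u, ce$x, params)
  ## d/dv [ -r S/K ] = -r (S'/K - S K'/K^2)
  -params$r * (cl$S1 / kt$K - cl$S * kt$K1 / kt$K^2)
}

#' Curvature of the adaptive landscape
#'
#' Second derivative of [fitness()] in the focal strategy, evaluated
#' analytically.  Negative curvature at a zero of the selection gradient
#' marks an ESS peak; positive curvature marks a fitness minimum, which if
#' convergent stable is an evolutionary branching point.
#'
#' @inheritParams selection_gradient
#' @param v Strategy at which to evaluate the curvature (vectorised).
#' @return `d2G/dv2` at each `v`.
#' @export
landscape_curvature <- function(v, k_focal = 0, community, gamma, params) {
  check_params(params)
  ce <- community_uxe(community)
  kt <- cap_terms(v, gamma, params)
  cl <- comp_load(v, ce$u, ce$x, params)
  K <- kt$K; K1 <- kt$K1; K2 <- kt$K2
  -params$r * (cl$S2 / K - 2 * cl$S1 * K1 / K^2 -
                 cl$S * K2 / K^2 + 2 * cl$S * K1^2 / K^3)
}

#' Analytic single-species eco-evolutionary equilibrium
#'
#' For one resident species the equilibrium solves `G = 0` and `dG/dv = 0`
#' jointly: the strategy settles on the carrying-capacity peak,
#' `u* = gamma`, and since the self-competition coefficient is 1 the density
#' is `x* = K(u*) * (1 - d k / r)`.  Requires `d k < r`, otherwise the cost
#' of evolvability exceeds the maximum growth rate and no positive
#' equilibrium exists.
#'
#' @param k Evolvability of the resident.
#' @inheritParams carrying_capacity
#' @return A list with elements `u_star` and `x_star`.
#' @examples
#' equilibrium_single_species(k = 0.2, gamma = 0, params = model_params())
#' # u* = 0, x* = 96
#' @export
equilibrium_single_species <- function(k, gamma = 0, params) {
  check_params(params)
  if (params$d * k >= params$r)
    stop("no viable equilibrium: d * k >= r (cost of evolvability exceeds growth)",
         call. = FALSE)
  list(u_star = gamma,
       x_star = carrying_capacity(gamma, gamma, params) * (1 - params$d * k / params$r))
}
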