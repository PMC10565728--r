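#' Locate and classify singular strategies of the adaptive landscape
#'
#' Scans the selection gradient over a grid, brackets every sign change,
#' refines each root by bisection, and classifies it by the curvature of
#' the landscape and by convergence stability:
#'
#' * `ess_peak`: negative curvature — a fitness maximum satisfying the ESS
#'   maximum principle.
#' * `convergent_minimum`: positive curvature *and* convergent stable — an
#'   evolutionary branching point: strategy dynamics approach it, yet
#'   selection there is disruptive.
#' * `other`: anything else (e.g. a transient minimum that the resident's
#'   own dynamics would not converge to).
#'
#' Convergence stability is tested on the resident nearest the root (ties
#' broken by smallest `|u_i - v_star|`, then community order): the resident
#' is moved to the root and the derivative of its own selection gradient
#' with respect to its position must be negative.
#'
#' With an empty community the landscape itself is flat (no competition),
#' but a vanishingly rare founder would grow and climb toward the
#' carrying-capacity peak; the analysis therefore places a phantom resident
#' with evolvability `k_focal` at its single-species equilibrium and
#' reports the singular point of that configuration (`v_star = gamma`).
#'
#' @param k_focal Evolvability of the focal G-function.  The cost term is
#'   linear in `k`, so root locations and curvatures are shared by all
#'   species; `k_focal` matters only for the phantom resident of an empty
#'   community.
#' @param community An `evodyn_community`.
#' @param gamma Position of the carrying-capacity peak.
#' @param params [model_params()].
#' @param search_interval Numeric length-2 bracket for the grid scan.
#' @param grid_step Grid spacing for sign-change detection.
#' @param root_tol Bisection tolerance on `v_star`.
#' @return A data frame with one row per singular point: `v_star`,
#'   `gradient` (residual), `curvature`, `convergent_stable`, `kind`.
#'   Zero rows when no root lies in the interval.
#' @export
find_singular_points <- function(k_focal, community, gamma, params,
                                 search_interval = c(-20, 20),
                                 grid_step = 1e-2, root_tol = 1e-8) {
  check_params(params)
  stopifnot("search_interval must be finite, length 2" =
              length(search_interval) == 2 && all(is.finite(search_interval)),
            "grid_step must be positive" = grid_step > 0)
  community <- check_community(community)
  if (!any(community$extant)) {
    eq <- equilibrium_single_species(k_focal, gamma, params)
    community <- species("phantom", k = k_focal, u = eq$u_star, x = eq$x_star)
  }

  grad <- function(v) selection_gradient(v, k_focal, community, gamma, params)
  vg <- seq(search_interval[1], search_interval[2], by = grid_step)
  gv <- grad(vg)
  flip <- which(gv[-length(gv)] * gv[-1] <= 0 & gv[-length(gv)] != 0)

  roots <- numeric(0)
  for (i in flip) {
    root <- stats::uniroot(grad, lower = vg[i], upper = vg[i + 1],
                           tol = root_tol)$root
    roots <- c(roots, root)
  }
  ## exact zeros on the grid
  roots <- sort(unique(c(roots, vg[gv == 0])))
  if (!length(roots)) {
    return(data.frame(v_star = numeric(0), gradient = numeric(0),
                      curvature = numeric(0), convergent_stable = logical(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  ## collapse near-duplicates from adjacent brackets
  roots <- roots[c(TRUE, diff(roots) > 10 * root_tol)]

  curv <- landscape_curvature(roots, k_focal, community, gamma, params)
  conv <- vapply(roots, function(v)
    convergence_stable(v, community, gamma, params), logical(1))
  kind <- ifelse(curv < 0, "ess_peak",
                 ifelse(curv > 0 & conv, "convergent_minimum", "other"))
  data.frame(v_star = roots, gradient = grad(roots), curvature = curv,
             convergent_stable = conv, kind = kind, stringsAsFactors = FALSE)
}

#' Convergence stability of a candidate singular strategy
#'
#' Moves the extant resident nearest `v_star` to `v_star` (densities held
#' fixed) and differentiates that resident's own selection gradient with
#' respect to its position (central difference).  A negative derivative
#' means strategy dynamics are attracted to the point.
#'
#' @inheritParams find_singular_points
#' @param v_star Candidate root of the selection gradient.
#' @param h Step of the central difference.
#' @return Logical.
#' @export
convergence_stable <- function(v_star, community, gamma, params, h = 1e-5) {
  community <- check_community(community)
  ext_idx <- which(community$extant)
  if (!length(ext_idx)) stop("convergence test needs an extant resident", call. = FALSE)
  i <- ext_idx[which.min(abs(community$u[ext_idx] - v_star))]
  own_grad <- function(ui) {
    comm <- community
    comm$u[i] <- ui
    selection_gradient(ui, community$k[i], comm, gamma, params)
  }
  (own_grad(v_star + h) - own_grad(v_star - h)) / (2 * h) < 0
}

#' Check the ESS conditions for each extant species
#'
#' At an eco-evolutionary equilibrium every extant species must sit at zero
#' fitness (`G = 0`), zero selection gradient, and (for a true ESS) on a
#' peak of its adaptive landscape (negative curvature).  Reports all three
#' per species; a community resting at convergent-stable minima passes the
#' first two but fails the peak condition.
#'
#' @param community An `evodyn_community` at a candidate equilibrium.
#' @param gamma Position of the carrying-capacity peak.
#' @param params [model_params()].
#' @param tol Tolerance for the zero-fitness and zero-gradient conditions.
#' @return A data frame with one row per extant species: `id`, `fitness`,
#'   `gradient`, `curvature`, and logicals `zero_fitness`, `zero_gradient`,
#'   `is_peak`, `is_ess`.
#' @export
verify_ess <- function(community, gamma, params, tol = 1e-6) {
  community <- check_community(community)
  ext <- extant_community(community)
  G <- vapply(seq_len(nrow(ext)), function(i)
    fitness(ext$u[i], ext$k[i], community, gamma, params), numeric(1))
  gr <- selection_gradient(ext$u, 0, community, gamma, params)
  cv <- landscape_curvature(ext$u, 0, community, gamma, params)
  out <- data.frame(
    id = ext$id, fitness = G, gradient = gr, curvature = cv,
    zero_fitness = abs(G) < tol, zero_gradient = abs(gr) < tol,
    is_peak = cv < 0, stringsAsFactors = FALSE
  )
  out$is_ess <- out$zero_fitness & out$zero_gradient & out$is_peak
  out
}
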