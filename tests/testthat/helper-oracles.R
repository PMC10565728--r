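# Finite-difference oracles for the analytic derivatives of the G-function,
# and generators for random model configurations used by property tests.

fd_gradient <- function(v, k_focal, comm, gamma, params, h = 1e-4) {
  (fitness(v + h, k_focal, comm, gamma, params) -
     fitness(v - h, k_focal, comm, gamma, params)) / (2 * h)
}

# second differences lose precision to cancellation at very small h, so the
# curvature oracle uses a larger step than the gradient oracle
fd_curvature <- function(v, k_focal, comm, gamma, params, h = 1e-3) {
  (fitness(v + h, k_focal, comm, gamma, params) -
     2 * fitness(v, k_focal, comm, gamma, params) +
     fitness(v - h, k_focal, comm, gamma, params)) / h^2
}

# A random community of 1..4 extant species with moderate strategies and
# densities, paired with random (valid) model parameters.
random_config <- function(kernel = c("gaussian", "bounded")) {
  kernel <- match.arg(kernel)
  n <- sample(1:4, 1)
  comm <- do.call(community, lapply(seq_len(n), function(i)
    species(paste0("s", i), k = runif(1, 0, 0.6), u = runif(1, -6, 6),
            x = runif(1, 1, 120))))
  params <- model_params(
    r = runif(1, 0.1, 0.5), Km = runif(1, 50, 200), d = runif(1, 0, 0.1),
    sigma_k2 = runif(1, 2, 20), sigma_a2 = runif(1, 1, 120),
    kernel = kernel
  )
  list(comm = comm, params = params, gamma = runif(1, -3, 3))
}

# Equilibrium single-resident community for the standard parameters.
equilibrium_resident <- function(k = 0.2, gamma = 0, params = model_params()) {
  eq <- equilibrium_single_species(k, gamma, params)
  community(species("resident", k = k, u = eq$u_star, x = eq$x_star))
}
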