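test_that("the ODE right-hand side vanishes at equilibrium and respects structural zeros", {
  p <- model_params()
  comm <- equilibrium_resident(0.2)
  d <- community_rhs(c(comm$x, comm$u), 0, comm, gamma = 0, params = p)
  expect_true(all(abs(d) < 1e-9))

  # dx/dt is multiplicative in x
  comm2 <- community(species("a", k = 0.2, u = 2, x = 0),
                     species("b", k = 0.5, u = -1, x = 40))
  d2 <- community_rhs(c(comm2$x, comm2$u), 0, comm2, gamma = 0, params = p)
  expect_identical(d2[1], 0)

  # k = 0 freezes the strategy whatever the gradient
  comm3 <- community(species("a", k = 0, u = 5, x = 20))
  d3 <- community_rhs(c(comm3$x, comm3$u), 0, comm3, gamma = 0, params = p)
  expect_identical(d3[2], 0)

  # extinct species contribute nothing and receive zero derivatives
  comm4 <- community(species("a", k = 0.2, u = 2, x = 30),
                     species("dead", k = 0.5, u = 1, x = 0,
                             extant = FALSE, extinction_time = 3))
  d4 <- community_rhs(c(30, 50, 2, 1), 0, comm4, gamma = 0, params = p)
  expect_identical(d4[c(2, 4)], c(0, 0))
  alone <- community(species("a", k = 0.2, u = 2, x = 30))
  d_alone <- community_rhs(c(30, 2), 0, alone, gamma = 0, params = p)
  expect_equal(d4[c(1, 3)], d_alone)
})

test_that("a single founder converges monotonically to the analytic equilibrium", {
  p <- model_params()
  comm <- community(species("s", k = 0.2, u = 4, x = 10))
  tr <- simulate_community(comm, env_constant(0), p, t_end = 2500)
  n <- length(tr$times)
  expect_lt(abs(tr$strategy[n, "s"] - 0), 1e-3)
  expect_lt(abs(tr$density[n, "s"] - 96), 1e-3)
  # |u - gamma| shrinks monotonically under a constant environment
  expect_true(all(diff(abs(tr$strategy[, "s"])) <= 1e-12))
})

test_that("identical twins remain identical for all time", {
  p <- model_params(d = 0)
  comm <- community(species("a", k = 0.2, u = 3, x = 10),
                    species("b", k = 0.2, u = 3, x = 10))
  tr <- simulate_community(comm, env_constant(0), p, t_end = 200)
  expect_equal(tr$density[, "a"], tr$density[, "b"])
  expect_equal(tr$strategy[, "a"], tr$strategy[, "b"])
  expect_equal(nrow(tr$events), 0L)
})

test_that("densities stay non-negative and extinction is absorbing", {
  tr <- simulate_community(founder_pair(10), env_constant(0), model_params(),
                           t_end = 100)
  expect_true(all(tr$density >= 0))
  t_ext <- extinction_time(tr, "slow_0")
  expect_false(is.na(t_ext))
  after <- tr$times > t_ext
  expect_true(all(tr$density[after, "slow_0"] == 0))
  # strategy frozen after extinction
  u_frozen <- tr$strategy[match(t_ext, tr$times), "slow_0"]
  expect_true(all(tr$strategy[after, "slow_0"] == u_frozen))
  expect_false(tr$community$extant[tr$community$id == "slow_0"])
})

test_that("extinction timing is robust to recording cadence and solver tolerances", {
  p <- model_params()
  tr1 <- simulate_community(founder_pair(0.5), env_constant(0), p, t_end = 340)
  tr2 <- simulate_community(founder_pair(0.5), env_constant(0), p, t_end = 340,
                            record_dt = 0.5, rtol = 1e-9, atol = 1e-11)
  t1 <- extinction_time(tr1, "fast_0")
  t2 <- extinction_time(tr2, "fast_0")
  expect_lt(abs(t1 - t2) / t1, 0.01)
})

test_that("environment schedules drive the recorded gamma and restart events", {
  p <- model_params()
  env <- env_steps(times = c(20.25, 40), gammas = c(-1, 2))
  tr <- simulate_community(founder_pair(0.5), env, p, t_end = 60)
  # off-grid step time is itself a sample
  expect_true(20.25 %in% tr$times)
  expect_equal(tr$gamma[tr$times < 20.25], rep(0, sum(tr$times < 20.25)))
  expect_equal(tr$gamma[tr$times >= 20.25 & tr$times < 40],
               rep(-1, sum(tr$times >= 20.25 & tr$times < 40)))
  expect_equal(tr$gamma[tr$times >= 40], rep(2, sum(tr$times >= 40)))
  expect_equal(sum(tr$events$type == "env_change"), 2L)

  env_s <- env_sinusoidal(amplitude = 1, period = 50)
  trs <- simulate_community(founder_pair(0.5), env_s, p, t_end = 30)
  expect_equal(trs$gamma, sin(trs$times / 50))
})

test_that("stochastic environments use a dedicated, reproducible stream", {
  env <- env_stochastic()
  r1 <- resolve_env(env, 50, seed = 99)
  set.seed(1234)  # unrelated global state must not matter
  r2 <- resolve_env(env, 50, seed = 99)
  expect_identical(r1$schedule, r2$schedule)
  expect_equal(r1$schedule$time, seq(0, 45, by = 5))
  expect_equal(r1$schedule$gamma[1], 0)  # gamma0 held until the first redraw
  expect_true(all(abs(r1$schedule$gamma) <= 2))
  expect_error(resolve_env(env, 50), "seed")
  # resolving does not disturb the caller's RNG stream
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(resolve_env(env, 50, seed = 99)); x2 <- runif(1)
  expect_identical(x1, x2)
})
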