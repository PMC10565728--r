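test_that("clade initiation: the winner flips with distance from equilibrium", {
  close <- run_clade_initiation(scenario_config("clade_initiation",
                                                u0 = 0.5, t_end = 400))
  expect_false(is.na(extinction_time(close, "fast_0")))
  expect_true(close$community$extant[close$community$id == "slow_0"])

  far <- run_clade_initiation(scenario_config("clade_initiation",
                                              u0 = 10, t_end = 50))
  expect_false(is.na(extinction_time(far, "slow_0")))
  expect_true(far$community$extant[far$community$id == "fast_0"])
})

test_that("a neutral founder pair (equal k, no cost) never loses a species", {
  cfg <- scenario_config("clade_initiation", u0 = 4, t_end = 300,
                         k_fast = 0.2, k_slow = 0.2,
                         params = model_params(d = 0))
  tr <- run_clade_initiation(cfg)
  expect_equal(sum(tr$events$type == "extinction"), 0L)
  expect_equal(tr$density[, "fast_0"], tr$density[, "slow_0"])
})

test_that("extinction summary reports count, mean and sample sd per species", {
  fake_traj <- function(ext_times) {
    ids <- names(ext_times)
    gone <- !is.na(unlist(ext_times))
    ev <- data.frame(time = unname(unlist(ext_times))[gone],
                     type = rep("extinction", sum(gone)),
                     species_id = ids[gone],
                     stringsAsFactors = FALSE)
    structure(list(
      times = 0:20,
      density = matrix(1, 2, length(ids), dimnames = list(NULL, ids)),
      events = ev
    ), class = "evodyn_trajectory")
  }
  trs <- list(fake_traj(list(a = 10, b = NA)),
              fake_traj(list(a = 10, b = 5)),
              fake_traj(list(a = 10, b = 15)))
  s <- extinction_summary(trs)
  a <- s[s$species_id == "a", ]
  expect_equal(a$n_extinct, 3L)
  expect_equal(a$mean_time, 10)
  expect_equal(a$sd_time, 0)
  b <- s[s$species_id == "b", ]
  expect_equal(b$n_extinct, 2L)
  expect_equal(b$mean_time, 10)
  expect_equal(b$sd_time, sqrt(50))  # sample sd of (5, 15) = 7.071...

  none <- extinction_summary(list(fake_traj(list(a = NA, b = NA))))
  expect_equal(none$n_extinct, c(0L, 0L))
  expect_true(all(is.na(none$mean_time)))
})

test_that("tracking runs are reproducible from the master seed", {
  cfg <- scenario_config("tracking_stochastic", u0 = 0.5, n_trials = 2,
                         t_end = 60, seed = 21)
  r1 <- run_tracking(cfg)
  r2 <- run_tracking(cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$trajectories[[2]]$density, r2$trajectories[[2]]$density)
  # replicates differ from each other
  expect_false(identical(r1$trajectories[[1]]$gamma, r1$trajectories[[2]]$gamma))
})

test_that("sinusoidal tracking from a close start: slow persists, fast oscillates more", {
  cfg <- scenario_config("tracking_deterministic", u0 = 0.5, t_end = 1200)
  res <- run_tracking(cfg)
  tr <- res$trajectories[[1]]
  expect_true(tr$community$extant[tr$community$id == "slow_0"])
  t_fast <- extinction_time(tr, "fast_0")
  expect_false(is.na(t_fast))
  expect_gt(t_fast, 315)  # outlasts the constant-environment close case
  w <- tr$times >= 100 & tr$times <= 300
  expect_gt(stats::sd(tr$strategy[w, "fast_0"]),
            stats::sd(tr$strategy[w, "slow_0"]))
})

test_that("rescue: early shifts doom the slow evolver, late shifts allow recovery", {
  early <- run_rescue(scenario_config("rescue",
                                      env = env_steps(600, -4), t_end = 1200))
  expect_false(is.na(extinction_time(early, "slow_0")))
  fast_end <- early$community[early$community$id == "fast_0", ]
  expect_true(fast_end$extant)
  expect_lt(abs(fast_end$u - (-4)), 0.1)  # survivor tracks the new optimum

  late <- run_rescue(scenario_config("rescue",
                                     env = env_steps(900, -4), t_end = 3000))
  slow_end <- late$community[late$community$id == "slow_0", ]
  expect_true(slow_end$extant)
  expect_lt(abs(slow_end$u - (-4)), 0.1)
  # the slow evolver recovers after the crash that follows the disturbance
  x_slow <- late$density[, "slow_0"]
  dip <- min(x_slow[late$times >= 900 & late$times <= 1500])
  expect_gt(slow_end$x, 10 * dip)
})

test_that("disturbance regimes: rare favours slow, frequent favours fast, intermediate coexists", {
  cfg_dir <- system.file("extdata", "configs", package = "evodyn")
  outcomes <- vapply(c("regime_rare", "regime_intermediate", "regime_frequent"),
                     function(f) {
                       cfg <- read_scenario_config(file.path(cfg_dir, paste0(f, ".yaml")))
                       run_disturbance_regime(cfg)$outcome
                     }, character(1))
  expect_equal(unname(outcomes),
               c("slow_survives", "coexistence", "fast_survives"))
})

test_that("scenario configs load from YAML and validate", {
  cfg_dir <- system.file("extdata", "configs", package = "evodyn")
  cfg <- read_scenario_config(file.path(cfg_dir, "rescue_750.yaml"))
  expect_s3_class(cfg, "evodyn_scenario")
  expect_equal(cfg$scenario, "rescue")
  expect_equal(cfg$u0, 4)
  expect_equal(cfg$env$steps$time, 750)
  expect_equal(cfg$env$steps$gamma, -4)

  rad <- read_scenario_config(file.path(cfg_dir, "radiation.yaml"))
  expect_equal(rad$params$kernel, "bounded")
  expect_equal(rad$params$sigma_a2, 2)

  expect_error(scenario_config("rescue", env = env_constant(0)),
               "step environment")
  expect_error(scenario_config("tracking_stochastic", env = env_constant(0)),
               "stochastic environment")
})
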