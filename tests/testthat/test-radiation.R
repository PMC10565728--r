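# One moderately sized radiation run shared by the tests in this file.
rad_run <- run_adaptive_radiation(
  scenario_config("adaptive_radiation", t_end = 1500, max_species = 8,
                  seed = 7))

test_that("only fast lineages speciate and the slow evolver persists", {
  nodes <- rad_run$phylogeny$nodes
  daughters <- nodes[!is.na(nodes$parent_id), ]
  expect_gte(nrow(daughters), 1L)
  expect_true(all(grepl("^fast", daughters$parent_id)))
  expect_true(all(grepl("^fast", daughters$id)))
  comm <- rad_run$trajectory$community
  expect_true(comm$extant[comm$id == "slow_0"])
})

test_that("daughters start within the offset bound of their parent and at density 1", {
  tr <- rad_run$trajectory
  nodes <- rad_run$phylogeny$nodes
  daughters <- nodes[!is.na(nodes$parent_id), ]
  for (i in seq_len(nrow(daughters))) {
    row <- match(daughters$birth_time[i], tr$times)
    u_d <- tr$strategy[row, daughters$id[i]]
    u_p <- tr$strategy[row, daughters$parent_id[i]]
    expect_lte(abs(u_d - u_p), 0.02 + 1e-12)
    expect_equal(unname(tr$density[row, daughters$id[i]]), 1)
    # no samples before birth
    if (row > 1) expect_true(all(is.na(tr$density[1:(row - 1), daughters$id[i]])))
  }
})

test_that("the phylogeny is well formed and serialises to parseable Newick", {
  phy <- rad_run$phylogeny
  nodes <- phy$nodes
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent_id[i]
    if (!is.na(p))
      expect_lte(nodes$birth_time[match(p, nodes$id)], nodes$birth_time[i])
  }
  nwk <- as_newick(phy)
  expect_match(nwk, ";$")
  tree <- ape::read.tree(text = nwk)
  expect_false(is.null(tree))
  # one leaf per lineage: founders + speciation events
  expect_equal(ape::Ntip(tree), nrow(nodes))
  expect_true(all(tree$edge.length >= 0))
  expect_true(all(nodes$id %in% tree$tip.label))
  # root-to-tip depth equals elapsed simulation time for extant lineages
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  extant <- is.na(nodes$extinction_time[match(tree$tip.label, nodes$id)])
  expect_true(all(abs(depths[extant] - phy$t_end) < 1e-9))
})

test_that("each daughter lineage diverges from its parent (diffuse coevolution)", {
  # near a convergent-stable minimum two residents at almost the same
  # strategy first track the minimum together; divergence builds on the
  # slower density timescale as the daughter's growth reshapes the
  # landscape, so the comparison is birth vs last common sample
  tr <- rad_run$trajectory
  nodes <- rad_run$phylogeny$nodes
  daughters <- nodes[!is.na(nodes$parent_id), ]
  last <- nrow(tr$strategy)
  for (i in seq_len(nrow(daughters))) {
    r0 <- match(daughters$birth_time[i], tr$times)
    d_birth <- abs(tr$strategy[r0, daughters$id[i]] -
                     tr$strategy[r0, daughters$parent_id[i]])
    d_end <- abs(tr$strategy[last, daughters$id[i]] -
                   tr$strategy[last, daughters$parent_id[i]])
    expect_gte(d_end, d_birth)
  }
  # established lineages occupy separated niches
  u <- tr$strategy[last, ]
  x <- tr$density[last, ]
  est <- !is.na(x) & x > tr$params$extinction_threshold
  expect_gte(sum(est), 3L)
  expect_gt(min(dist(u[est])), 0.5)
})

test_that("a broad Gaussian kernel never triggers speciation", {
  cfg <- scenario_config("adaptive_radiation", params = model_params(),
                         t_end = 600, seed = 7)
  res <- run_adaptive_radiation(cfg)
  expect_equal(sum(res$trajectory$events$type == "speciation"), 0L)
  expect_equal(nrow(res$phylogeny$nodes), 2L)
})

test_that("the two-resident equilibrium is independent of the founding strategy", {
  # property of the uncapped ODE flow: from a far start the transient dips
  # below the usual extinction threshold, so the threshold is set to a
  # negligible value here
  p <- model_params(sigma_a2 = 2, kernel = "bounded",
                    extinction_threshold = 1e-6)
  finals <- lapply(c(0.5, 4, 10), function(u0) {
    tr <- simulate_community(founder_pair(u0), env_constant(0), p,
                             t_end = 12000, record_dt = 5)
    tr$community[, c("u", "x")]
  })
  for (i in 2:3) {
    expect_equal(finals[[i]]$u, finals[[1]]$u, tolerance = 1e-4)
    expect_equal(finals[[i]]$x, finals[[1]]$x, tolerance = 1e-4)
  }
  # the fast and slow evolver occupy distinct niches
  expect_gt(abs(finals[[1]]$u[1] - finals[[1]]$u[2]), 1)
})

test_that("the two-point offset mode draws exactly +/- the offset", {
  cfg <- scenario_config("adaptive_radiation", t_end = 300, max_species = 3,
                         seed = 3, offset_mode = "two_point")
  res <- run_adaptive_radiation(cfg)
  nodes <- res$phylogeny$nodes
  daughters <- nodes[!is.na(nodes$parent_id), ]
  if (nrow(daughters)) {
    tr <- res$trajectory
    for (i in seq_len(nrow(daughters))) {
      row <- match(daughters$birth_time[i], tr$times)
      off <- abs(tr$strategy[row, daughters$id[i]] -
                   tr$strategy[row, daughters$parent_id[i]])
      expect_equal(unname(off), 0.02, tolerance = 1e-12)
    }
  }
})
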