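# Event-driven co-simulation engine.

p0 <- kinetic_params()

test_that("initialization is uniform, range-respecting and reproducible", {
  g <- grid_spec(20, 20, "cylindrical")
  cfg <- simulation_config(g, seed = 123,
                           init_ranges = list(D = c(0, 1)))
  s1 <- init_states(cfg)
  s2 <- init_states(cfg)
  expect_identical(s1, s2)
  expect_false(identical(
    s1, init_states(simulation_config(g, seed = 124,
                                      init_ranges = list(D = c(0, 1))))))
  # uniform-distribution check: mean of 400 draws on [0, 1]
  expect_lt(abs(mean(s1["D", ]) - 0.5), 3 / sqrt(12 * 400))
  rng <- cfg$init_ranges
  for (sp in dn_species())
    expect_true(all(s1[sp, ] >= rng[sp, "low"] & s1[sp, ] <= rng[sp, "high"]))

  zero_cfg <- simulation_config(g, init_ranges = cbind(low = rep(0, 6),
                                                       high = rep(0, 6)))
  expect_true(all(init_states(zero_cfg) == 0))
  expect_error(simulation_config(g, init_ranges = list(D = c(2, 1))),
               "low exceeds high")
})

test_that("an isolated cell crosses at the closed-form time and equilibrates", {
  cfg <- simulation_config(grid_spec(1, 1, "bounded"),
                           init_ranges = cbind(low = rep(0, 6),
                                               high = rep(0, 6)),
                           rtol = 1e-10, atol = 1e-12)
  res <- suppressWarnings(run_simulation(cfg))
  expect_equal(res$termination, "equilibrium")
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$direction, "up")
  expect_equal(res$events$time, unstimulated_crossing_time(p0),
               tolerance = 1e-8)
  expect_equal(as.numeric(res$final_delta), delta_steady_state(p0),
               tolerance = 1e-4)
  expect_identical(as.integer(res$final_logic), 1L)
})

test_that("a quiescent grid reports no event up to the horizon", {
  g <- grid_spec(2, 2, "bounded")
  # quorum of 6 can never fire on a 2x2 grid, so the unstimulated fixed
  # point is a true fixed point of the coupled system for any logic state
  cfg <- simulation_config(g, rule = logic_rule(1, 6))
  ss <- cell_steady_state(p0, DE = 0)
  states <- matrix(ss, 6, 4, dimnames = list(dn_species(), NULL))
  adv <- advance_to_next_event(states, rep(1L, 4), 0, cfg, horizon = 30)
  expect_false(adv$root_found)
  expect_equal(nrow(adv$events), 0L)
  expect_equal(adv$t, 30)
  expect_equal(adv$states, states, tolerance = 1e-6)
})

test_that("symmetric twin cells cross in the same epoch", {
  g <- grid_spec(1, 2, "bounded")
  cfg <- simulation_config(g, rtol = 1e-10, atol = 1e-12)
  states <- matrix(0, 6, 2, dimnames = list(dn_species(), NULL))
  adv <- advance_to_next_event(states, c(0L, 0L), 0, cfg, horizon = 20)
  expect_true(adv$root_found)
  expect_equal(nrow(adv$events), 2L)
  expect_equal(adv$events$time,
               rep(unstimulated_crossing_time(p0), 2), tolerance = 1e-8)
  expect_equal(adv$events$direction, c("up", "up"))
  expect_equal(adv$logic, c(1L, 1L))
  # cell exchange symmetry: both columns identical at the event
  expect_equal(adv$states[, 1], adv$states[, 2])
})

test_that("a strongly asymmetric pair settles into the (1, 0) fate pattern", {
  g <- grid_spec(1, 2, "bounded")
  cfg <- simulation_config(g, rtol = 1e-9, atol = 1e-11)
  states <- matrix(0, 6, 2, dimnames = list(dn_species(), NULL))
  states["D", ] <- c(0.95 * delta_steady_state(p0), 0.05)
  res <- run_simulation(cfg, initial_states = states)
  expect_equal(res$termination, "equilibrium")
  expect_equal(as.integer(res$final_logic), c(1L, 0L))
  expect_equal(res$final_delta[1, 1], delta_steady_state(p0),
               tolerance = 1e-4)
  expect_lt(res$final_delta[1, 2], p0$Th)
})

test_that("event-driven engine matches the monolithic oracle on tiny grids", {
  for (key in c("1x1", "1x2", "2x2")) {
    dims <- as.integer(strsplit(key, "x")[[1]])
    g <- grid_spec(dims[1], dims[2], "bounded")
    cfg <- simulation_config(g, seed = 31, t_max = 120,
                             rtol = 1e-10, atol = 1e-12)
    states0 <- init_states(cfg)
    res <- suppressWarnings(run_simulation(cfg))
    orc <- oracle_run(states0, p0, oracle_neighbors(key), theta = 1L,
                      t_max = 120)
    expect_equal(nrow(res$events), nrow(orc$events), info = key)
    if (nrow(res$events)) {
      expect_equal(res$events$time, orc$events$time, tolerance = 1e-6,
                   info = key)
      expect_equal(cell_id(g, res$events$row, res$events$col),
                   orc$events$cell, info = key)
      expect_equal(res$events$direction, orc$events$direction, info = key)
    }
    expect_identical(as.integer(t(res$final_logic)), orc$final_logic,
                     info = key)
  }
})

test_that("t_max = 0 returns the initial state untouched", {
  cfg <- simulation_config(grid_spec(3, 3, "bounded"), seed = 2, t_max = 0)
  res <- run_simulation(cfg)
  expect_equal(res$termination, "t_max")
  expect_equal(nrow(res$events), 0L)
  expect_equal(res$trajectories$times, 0)
  expect_equal(res$trajectories$states[[1]], init_states(cfg))
})

test_that("identical config and seed give identical event logs", {
  cfg <- simulation_config(grid_spec(4, 4, "cylindrical"), seed = 5,
                           record_trajectories = FALSE)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$final_logic, r2$final_logic)
  expect_identical(r1$termination, r2$termination)
})

test_that("small-tissue runs reach valid lateral-inhibition equilibria", {
  rule <- logic_rule(1, 1)
  for (seed in 1:2) {
    cfg <- simulation_config(grid_spec(6, 6, "cylindrical"), rule = rule,
                             seed = seed, record_trajectories = FALSE)
    res <- run_simulation(cfg)
    expect_equal(res$termination, "equilibrium")
    chk <- check_lateral_inhibition(res$final_logic, rule, cfg$grid)
    expect_true(chk$valid)
    # final logic is the binarization of the final Delta matrix
    expect_identical(res$final_logic,
                     binarize(res$final_delta, p0$Th))
    # event times strictly ordered within the run
    expect_true(all(diff(res$events$time) >= 0))
    expect_true(all(diff(res$epoch_times) > 0))
  }
})

test_that("snapshot times are honored and lie inside the run", {
  cfg <- simulation_config(grid_spec(3, 3, "cylindrical"), seed = 4,
                           snapshot_times = c(0, 1.5, 20))
  res <- run_simulation(cfg)
  expect_setequal(names(res$snapshots),
                  sprintf("%.6f", c(0, 1.5, 20)))
  expect_equal(dim(res$snapshots[["1.500000"]]), c(3L, 3L))
  # snapshot at t=0 equals the initial Delta grid
  expect_equal(res$snapshots[["0.000000"]],
               matrix(init_states(cfg)["D", ], 3, 3, byrow = TRUE))
})

test_that("an unreachable quorum warns and leaves the grid input-free", {
  cfg <- simulation_config(grid_spec(2, 2, "bounded"),
                           rule = logic_rule(1, 6), seed = 1)
  expect_warning(res <- run_simulation(cfg), "never fire")
  # with no possible input every cell relaxes to the unstimulated state
  expect_equal(as.numeric(res$final_delta),
               rep(delta_steady_state(p0), 4), tolerance = 1e-4)
})
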