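# Intracellular six-species cell model.

p0 <- kinetic_params()
zero_state <- stats::setNames(rep(0, 6), dn_species())

test_that("free membrane Notch follows the conservation relation", {
  p <- p0
  expect_equal(notch_free(zero_state, p), p$Ntot)
  s <- zero_state; s["NC"] <- p$Ntot
  expect_equal(notch_free(s, p), 0)
  s <- zero_state; s["NN"] <- p$Ntot * p$VC / p$VN
  expect_equal(notch_free(s, p), 0)
  s <- zero_state; s[c("NC", "NN")] <- c(10, 20)
  expect_equal(notch_free(s, p), p$Ntot - 10 - 20 * p$VN / p$VC)
})

test_that("rhs reproduces the Hill-term anchor points", {
  p <- p0
  d <- dn_rhs(zero_state, DE = 0, params = p)
  expect_equal(unname(d[c("NC", "NN", "HNmRNA", "HCp", "HNp")]),
               rep(0, 5))
  expect_equal(unname(d["D"]), p$ktD) # empty repressor: full transcription
  s <- zero_state; s["NN"] <- p$KH
  expect_equal(unname(dn_rhs(s, 0, params = p)["HNmRNA"]), p$ktH / 2)
  s <- zero_state; s["HNp"] <- p$KD
  expect_equal(unname(dn_rhs(s, 0, params = p)["D"]), p$ktD / 2)
  expect_error(dn_rhs(zero_state - 1, 0, params = p), "negative")
})

test_that("rhs matches an independent hand transcription on random states", {
  p <- kinetic_params(Th = 3)
  set.seed(42)
  for (i in seq_len(1000L)) {
    s <- stats::setNames(stats::runif(6, 0, 50), dn_species())
    DE <- sample(c(0, p$DEmax), 1L)
    W <- stats::runif(1, 0, 20)
    expect_equal(dn_rhs(s, DE, W, p), oracle_rhs(s, DE, W, p),
                 tolerance = 1e-14)
  }
})

test_that("wnt factor is a decreasing repression Hill function", {
  p <- p0
  expect_equal(wnt_factor(0, p), 1)
  expect_equal(wnt_factor(p$KW, p), 0.5)
  expect_lt(wnt_factor(100 * p$KW, p), 1e-4)
  w <- sort(stats::runif(20, 0, 50))
  expect_true(all(diff(wnt_factor(w, p)) < 0))
})

test_that("unstimulated Delta converges to ktD/muD from the zero state", {
  p <- p0
  expect_equal(delta_steady_state(p), p$ktD / p$muD)
  expect_equal(delta_steady_state(kinetic_params(ktD = 2, muD = 1, Th = 1)),
               2)
  tr <- integrate_cell(zero_state, DE = 0, params = p, t_span = c(0, 60),
                       rtol = 1e-10, atol = 1e-12)
  Dend <- unname(tr$states[nrow(tr$states), "D"])
  expect_equal(Dend, p$ktD / p$muD, tolerance = 1e-6)
})

test_that("closed-form steady states agree with long integrations", {
  p <- p0
  for (DE in c(0, p$DEmax)) {
    ss <- cell_steady_state(p, DE = DE)
    tr <- integrate_cell(zero_state, DE = DE, params = p,
                         t_span = c(0, 400), rtol = 1e-10, atol = 1e-12)
    got <- tr$states[nrow(tr$states), ]
    expect_equal(unname(got), unname(ss), tolerance = 1e-5)
    expect_equal(unname(dn_rhs(ss, DE, 0, p)), rep(0, 6), tolerance = 1e-9)
  }
})

test_that("threshold crossing time matches the scalar closed form", {
  p <- p0
  tstar <- unstimulated_crossing_time(p)
  expect_equal(tstar, -(1 / p$muD) * log(1 - p$Th * p$muD / p$ktD))
  tr <- integrate_cell(zero_state, DE = 0, params = p, t_span = c(0, 20),
                       rtol = 1e-12, atol = 1e-14)
  expect_equal(nrow(tr$crossings), 1L)
  expect_equal(tr$crossings$direction, "up")
  expect_equal(tr$crossings$time, tstar, tolerance = 1e-8)
})

test_that("a cell at the unstimulated fixed point generates no event", {
  p <- p0
  s <- zero_state; s["D"] <- p$ktD / p$muD
  tr <- integrate_cell(s, DE = 0, params = p, t_span = c(0, 50))
  expect_equal(nrow(tr$crossings), 0L)
  expect_equal(max(abs(tr$states[, "D"] - p$ktD / p$muD)), 0,
               tolerance = 1e-6)
})

test_that("ligand stimulation keeps Delta below the unstimulated trajectory", {
  p <- p0
  t_out <- c(0, 30)
  tr0 <- integrate_cell(zero_state, DE = 0, params = p, t_span = t_out,
                        n_out = 301L, rtol = 1e-10, atol = 1e-12)
  tr1 <- integrate_cell(zero_state, DE = p$DEmax, params = p,
                        t_span = t_out, n_out = 301L,
                        rtol = 1e-10, atol = 1e-12)
  # identical until Hes protein arrives, then strictly below
  expect_true(all(tr1$states[-1L, "D"] <= tr0$states[-1L, "D"] + 1e-8))
  late <- tr0$times > 2
  expect_true(all(tr1$states[late, "D"] < tr0$states[late, "D"]))
})

test_that("trajectories stay non-negative and conserve the Notch pool bound", {
  p <- p0
  set.seed(7)
  hi <- default_init_ranges(p)[, "high"]
  for (i in 1:15) {
    s0 <- stats::setNames(stats::runif(6, 0, hi), dn_species())
    DE <- sample(c(0, p$DEmax), 1L)
    tr <- integrate_cell(s0, DE = DE, params = p, t_span = c(0, 40))
    expect_gte(min(tr$states), -1e-7)
    nf <- notch_free(t(tr$states), p)
    expect_true(all(nf >= -1e-6 & nf <= p$Ntot + 1e-6))
  }
})

test_that("with no ligand the Notch/Hes arm decays to zero from any start", {
  p <- p0
  set.seed(8)
  for (i in 1:5) {
    s0 <- stats::setNames(stats::runif(6, 0, 30), dn_species())
    tr <- integrate_cell(s0, DE = 0, params = p, t_span = c(0, 150),
                         rtol = 1e-10, atol = 1e-12)
    arm <- tr$states[nrow(tr$states), c("NC", "NN", "HNmRNA", "HCp", "HNp")]
    expect_equal(unname(arm), rep(0, 5), tolerance = 1e-6)
  }
})

test_that("parameter validation enforces positivity and threshold reachability", {
  expect_error(kinetic_params(muD = -1), "muD")
  expect_error(kinetic_params(ktD = 0), "ktD")
  expect_error(kinetic_params(Th = 10, ktD = 10, muD = 1), "Th")
})
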