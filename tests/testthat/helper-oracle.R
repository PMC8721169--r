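# Independent oracles: a scalar hand transcription of the six cell
# equations, and a monolithic brute-force tissue integrator with hand-derived
# neighbor lists and manually switched inputs. Both are deliberately written
# without reusing the package's vectorized model code or grid geometry.

oracle_rhs <- function(state, DE, W, p) {
  with(as.list(c(state, unclass(p))), {
    Nfree <- Ntot - NC - NN * VN / VC
    if (Nfree < 0) Nfree <- 0
    wnt <- KW^nW / (KW^nW + W^nW)
    c(NC = kcl * Nfree * DE + ktrP / VC * (NN - NC) - ktrA / VC * NC -
        muN * NC,
      NN = ktrP / VN * (NC - NN) + ktrA / VN * NC - muN * NN,
      HNmRNA = wnt * ktH * NN^2 / (NN^2 + KH^2) - muHmRNA * HNmRNA,
      HCp = kHp * HNmRNA * VN / VC + ktrP / VC * (HNp - HCp) - muHp * HCp,
      HNp = -ktrP / VN * (HNp - HCp) - muHp * HNp,
      D = ktD * KD^2 / (KD^2 + HNp^2) - muD * D)
  })
}

# Hand-derived ring-1 neighbor lists (odd-r offset, bounded boundary),
# cells in row-major id order.
oracle_neighbors <- function(key) {
  switch(key,
         "1x1" = list(integer(0)),
         "1x2" = list(2L, 1L),
         "2x2" = list(c(2L, 3L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(2L, 3L)),
         stop("no hand-derived neighbor list for ", key))
}

# Monolithic event-driven integration of a whole tiny tissue: stacked ODEs
# built from oracle_rhs, inputs switched by hand whenever some Delta crosses
# the threshold.
oracle_run <- function(states0, p, nbrs, theta = 1L, t_max = 200,
                       rtol = 1e-10, atol = 1e-12) {
  n <- length(nbrs)
  sp <- c("NC", "NN", "HNmRNA", "HCp", "HNp", "D")
  states <- states0
  logic <- as.integer(states[6L, ] >= p$Th)
  t <- 0
  ev_time <- numeric(0)
  ev_cell <- integer(0)
  ev_dir <- character(0)
  repeat {
    DE <- vapply(seq_len(n), function(i)
      if (sum(logic[nbrs[[i]]]) >= theta) p$DEmax else 0, numeric(1))
    f <- function(tt, y, parms) {
      S <- matrix(y, 6L)
      d <- vapply(seq_len(n), function(i)
        oracle_rhs(stats::setNames(S[, i], sp), DE[i], 0, p), numeric(6))
      list(as.vector(d))
    }
    g <- function(tt, y, parms) y[seq.int(6L, 6L * n, by = 6L)] - p$Th
    out <- deSolve::lsodar(as.vector(states), c(t, t_max), f, NULL,
                           rootfunc = g, rtol = rtol, atol = atol)
    tstar <- out[nrow(out), 1L]
    states <- matrix(out[nrow(out), -1L], 6L)
    iroot <- attr(out, "iroot")
    if (is.null(iroot) || all(iroot == 0)) break
    crossed <- sort(unique(c(which(iroot != 0),
                             which(abs(states[6L, ] - p$Th) <=
                                     1e-8 * p$Th))))
    for (i in crossed) {
      logic[i] <- 1L - logic[i]
      ev_time <- c(ev_time, tstar)
      ev_cell <- c(ev_cell, i)
      ev_dir <- c(ev_dir, if (logic[i] == 1L) "up" else "down")
    }
    t <- tstar
    if (t >= t_max) break
  }
  list(events = data.frame(time = ev_time, cell = ev_cell,
                           direction = ev_dir),
       final_logic = as.integer(states[6L, ] >= p$Th),
       final_states = states)
}
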