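# Six-species intracellular Delta-Notch cascade.
#
# State variables (canonical order, see dn_species()):
#   NC      cytoplasmic Notch intracellular domain (NICD)
#   NN      nuclear NICD
#   HNmRNA  nuclear Hes mRNA
#   HCp     cytoplasmic Hes protein
#   HNp     nuclear Hes protein
#   D       Delta (mRNA read-out)
#
# The cell has two compartments, cytoplasm (volume VC) and nucleus (VN).
# Ligand binding cleaves NICD off a conserved membrane Notch pool (Ntot);
# nuclear NICD activates Hes transcription through an activation Hill term,
# nuclear Hes protein represses Delta transcription through a repression
# Hill term, closing the lateral-inhibition loop through the neighbors.

.DN_SPECIES <- c("NC", "NN", "HNmRNA", "HCp", "HNp", "D")

#' Canonical species order of the Delta-Notch cell model
#'
#' @return Character vector of the six state-variable names, in the order
#'   used by state vectors and matrices throughout the package.
#' @export
dn_species <- function() .DN_SPECIES

#' Kinetic parameters of the intracellular Delta-Notch model
#'
#' Builds a validated parameter set. All rates are per hour, volumes and
#' concentrations in consistent arbitrary units (nominally nM). The defaults
#' are a package-chosen reference set — not measured values — calibrated once
#' so that (a) the quantization threshold `Th` lies strictly between the
#' Delta steady state of a ligand-stimulated cell and that of an unstimulated
#' cell (`ktD/muD`), and (b) a two-cell system is bistable, one cell
#' stabilizing Delta-positive and the other Delta-negative. Every value can
#' be overridden here or in a YAML run configuration.
#'
#' @param VC,VN Cytoplasmic and nuclear volumes.
#' @param Ntot Total membrane Notch pool (conserved).
#' @param kcl NICD cleavage rate constant (per concentration per hour),
#'   multiplying `notch_free * DE`.
#' @param ktrP Passive nuclear transport rate (concentration-gradient
#'   driven), shared by NICD and Hes protein.
#' @param ktrA Active nuclear import rate of cytoplasmic NICD.
#' @param muN,muHmRNA,muHp,muD First-order degradation rates of NICD, Hes
#'   mRNA, Hes protein and Delta.
#' @param ktH Maximal Hes transcription rate; `KH` its half-saturation
#'   constant in nuclear NICD.
#' @param kHp Hes translation rate.
#' @param ktD Maximal Delta transcription rate; `KD` the half-repression
#'   constant in nuclear Hes protein.
#' @param DEmax Amplitude of the binary ligand input delivered when the
#'   neighborhood logic rule fires.
#' @param Th Delta quantization threshold: a cell is Delta-positive when
#'   `D >= Th`. Must satisfy `0 < Th < ktD/muD`, else no threshold crossing
#'   can ever occur.
#' @param nH Hill exponent of both transcription Hill terms (fixed at 2 in
#'   the reference model; exposed only for sensitivity exploration).
#' @param KW Half-inhibition constant of the Wnt input; `nW` its Hill
#'   exponent. See [wnt_factor()].
#' @return An object of class `"kinetic_params"` (a named list).
#' @examples
#' p <- kinetic_params()
#' delta_steady_state(p) # unstimulated Delta fixed point ktD/muD
#' @export
kinetic_params <- function(VC = 1, VN = 0.5, Ntot = 100,
                           kcl = 0.05, ktrP = 1, ktrA = 4, muN = 0.3,
                           ktH = 2, KH = 25, muHmRNA = 0.3,
                           kHp = 4, muHp = 0.3,
                           ktD = 10, KD = 0.1, muD = 1,
                           DEmax = 10, Th = 3,
                           nH = 2, KW = 5, nW = 2) {
  p <- list(VC = VC, VN = VN, Ntot = Ntot, kcl = kcl, ktrP = ktrP,
            ktrA = ktrA, muN = muN, ktH = ktH, KH = KH,
            muHmRNA = muHmRNA, kHp = kHp, muHp = muHp, ktD = ktD,
            KD = KD, muD = muD, DEmax = DEmax, Th = Th, nH = nH,
            KW = KW, nW = nW)
  bad <- names(p)[!vapply(p, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("kinetic parameters must be strictly positive finite scalars; ",
         "invalid: ", paste(bad, collapse = ", "), call. = FALSE)
  if (p$Th >= p$ktD / p$muD)
    stop("`Th` must satisfy 0 < Th < ktD/muD (= ",
         format(p$ktD / p$muD),
         "), otherwise the Delta threshold is unreachable from below",
         call. = FALSE)
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> Delta-Notch cell model parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}

.as_state_matrix <- function(state) {
  if (is.matrix(state)) {
    if (nrow(state) != 6L)
      stop("a state matrix must have 6 rows (one per species)",
           call. = FALSE)
    S <- state
  } else {
    if (length(state) != 6L)
      stop("a cell state has exactly 6 components", call. = FALSE)
    if (!is.null(names(state))) {
      if (!setequal(names(state), .DN_SPECIES))
        stop("state names must be ", paste(.DN_SPECIES, collapse = ", "),
             call. = FALSE)
      state <- state[.DN_SPECIES]
    }
    S <- matrix(as.numeric(state), nrow = 6L)
  }
  rownames(S) <- .DN_SPECIES
  S
}

#' Free membrane Notch
#'
#' Total Notch is conserved, so the receptor still available at the membrane
#' is what has not been cleaved into cytoplasmic or nuclear NICD:
#' `Ntot - NC - NN * VN / VC` (the nuclear amount is converted to
#' cytoplasmic concentration units by the volume ratio). At coarse solver
#' tolerance the expression can transiently dip marginally below zero; the
#' cleavage flux in [dn_rhs()] uses its value clipped at zero so that a
#' negative excursion can never fabricate Notch.
#'
#' @param state Named numeric state vector (see [dn_species()]) or a 6-row
#'   state matrix with one column per cell.
#' @param params A [kinetic_params()] object.
#' @return Numeric free-Notch concentration(s), unclipped.
#' @export
notch_free <- function(state, params) {
  S <- .as_state_matrix(state)
  unname(params$Ntot - S["NC", ] - S["NN", ] * params$VN / params$VC)
}

#' Wnt inhibition factor
#'
#' Positional Wnt input inhibits the transcriptional activity of nuclear
#' NICD. The inhibition is modeled as a multiplicative repression Hill
#' factor `KW^nW / (KW^nW + W^nW)` on the Hes transcription term: 1 at
#' `W = 0`, 1/2 at `W = KW`, strictly decreasing to 0 as `W` grows.
#'
#' @param W Non-negative Wnt concentration (vectorized).
#' @param params A [kinetic_params()] object (uses `KW`, `nW`).
#' @return Dimensionless factor in (0, 1].
#' @export
wnt_factor <- function(W, params) {
  if (any(W < 0)) stop("`W` must be non-negative", call. = FALSE)
  params$KW^params$nW / (params$KW^params$nW + W^params$nW)
}

# Vectorized right-hand side: S is a 6 x n state matrix, DE and W scalars or
# length-n vectors. Returns a 6 x n derivative matrix. This is the single
# place the model equations are written; everything else calls it.
.dn_rhs_mat <- function(S, DE, W, p) {
  NC <- S[1L, ]; NN <- S[2L, ]; Hm <- S[3L, ]
  HC <- S[4L, ]; HN <- S[5L, ]; D <- S[6L, ]
  nfree <- pmax(p$Ntot - NC - NN * p$VN / p$VC, 0)
  dNC <- p$kcl * nfree * DE + (p$ktrP / p$VC) * (NN - NC) -
    (p$ktrA / p$VC) * NC - p$muN * NC
  dNN <- (p$ktrP / p$VN) * (NC - NN) + (p$ktrA / p$VN) * NC - p$muN * NN
  NNh <- NN^p$nH
  dHm <- wnt_factor(W, p) * p$ktH * NNh / (NNh + p$KH^p$nH) -
    p$muHmRNA * Hm
  dHC <- p$kHp * Hm * (p$VN / p$VC) + (p$ktrP / p$VC) * (HN - HC) -
    p$muHp * HC
  dHN <- -(p$ktrP / p$VN) * (HN - HC) - p$muHp * HN
  dD <- p$ktD * p$KD^p$nH / (p$KD^p$nH + HN^p$nH) - p$muD * D
  rbind(NC = dNC, NN = dNN, HNmRNA = dHm, HCp = dHC, HNp = dHN, D = dD)
}

#' Time derivatives of the Delta-Notch cell model
#'
#' Evaluates the six coupled ODEs of one cell under a given ligand input
#' `DE` and positional Wnt concentration `W`:
#' \deqn{dNC/dt = kcl\,Notch_{free}\,DE + (ktrP/VC)(NN-NC) - (ktrA/VC)NC - \mu_N NC}
#' \deqn{dNN/dt = (ktrP/VN)(NC-NN) + (ktrA/VN)NC - \mu_N NN}
#' \deqn{dHNmRNA/dt = w(W)\,ktH\,NN^2/(NN^2+KH^2) - \mu_{HmRNA} HNmRNA}
#' \deqn{dHCp/dt = kHp\,HNmRNA\,(VN/VC) + (ktrP/VC)(HNp-HCp) - \mu_{Hp} HCp}
#' \deqn{dHNp/dt = -(ktrP/VN)(HNp-HCp) - \mu_{Hp} HNp}
#' \deqn{dD/dt = ktD\,KD^2/(KD^2+HNp^2) - \mu_D D}
#' where `w(W)` is [wnt_factor()] (1 when `W = 0`).
#'
#' @param state Named non-negative numeric state vector, see [dn_species()].
#' @param DE Ligand input; `0` or `DEmax` when driven by the logic layer,
#'   any non-negative value accepted.
#' @param W Non-negative Wnt concentration (default 0).
#' @param params A [kinetic_params()] object.
#' @return Named numeric vector of the six time derivatives.
#' @export
dn_rhs <- function(state, DE, W = 0, params) {
  S <- .as_state_matrix(state)
  if (any(S < 0))
    stop("negative state component passed to dn_rhs()", call. = FALSE)
  if (any(DE < 0)) stop("`DE` must be non-negative", call. = FALSE)
  dS <- .dn_rhs_mat(S, DE, W, params)
  if (ncol(dS) == 1L) stats::setNames(dS[, 1L], .DN_SPECIES) else dS
}

#' Unstimulated Delta steady state
#'
#' With no ligand input (`DE = 0`) the whole Notch/Hes arm decays to zero,
#' the Delta repression Hill term equals 1, and Delta relaxes to the fixed
#' point `ktD / muD`. This closed form anchors several package tests.
#'
#' @param params A [kinetic_params()] object.
#' @return The Delta concentration `ktD / muD`.
#' @export
delta_steady_state <- function(params) params$ktD / params$muD

#' Full steady state of one cell under constant inputs
#'
#' Closed-form fixed point of the cell model for a constant ligand input
#' `DE` and Wnt level `W`. The NICD pair solves a 2x2 linear system (the
#' free-Notch relation is linear in the state), after which the Hes arm and
#' Delta follow by direct substitution. Assumes the fixed point has
#' non-negative free Notch, which holds throughout the parameter regime the
#' package targets.
#'
#' @param params A [kinetic_params()] object.
#' @param DE Constant ligand input (default 0).
#' @param W Constant Wnt concentration (default 0).
#' @return Named numeric steady-state vector in [dn_species()] order.
#' @export
cell_steady_state <- function(params, DE = 0, W = 0) {
  p <- params
  # kcl*DE*(Ntot - NC - NN*VN/VC) + ktrP/VC*(NN - NC) - (ktrA/VC + muN)*NC = 0
  # (ktrP + ktrA)/VN * NC - (ktrP/VN + muN) * NN = 0
  A <- rbind(
    c(-(p$kcl * DE + p$ktrP / p$VC + p$ktrA / p$VC + p$muN),
      p$ktrP / p$VC - p$kcl * DE * p$VN / p$VC),
    c((p$ktrP + p$ktrA) / p$VN, -(p$ktrP / p$VN + p$muN))
  )
  ncnn <- solve(A, c(-p$kcl * DE * p$Ntot, 0))
  NN <- ncnn[2L]
  Hm <- wnt_factor(W, p) * p$ktH * NN^p$nH / (NN^p$nH + p$KH^p$nH) /
    p$muHmRNA
  # dHNp = 0  =>  HCp = HNp * (1 + muHp * VN / ktrP)
  cc <- 1 + p$muHp * p$VN / p$ktrP
  HNp <- (p$kHp * Hm * p$VN / p$VC) /
    ((p$ktrP / p$VC) * (cc - 1) + p$muHp * cc)
  HCp <- HNp * cc
  D <- (p$ktD / p$muD) * p$KD^p$nH / (p$KD^p$nH + HNp^p$nH)
  stats::setNames(c(ncnn[1L], NN, Hm, HCp, HNp, D), .DN_SPECIES)
}

#' Closed-form unstimulated threshold-crossing time
#'
#' From the zero state with `DE = 0`, the Hes arm stays identically zero and
#' Delta obeys the scalar linear ODE `dD/dt = ktD - muD * D`, so the upward
#' crossing of the quantization threshold occurs at
#' `t* = -(1/muD) * log(1 - Th * muD / ktD)`.
#'
#' @param params A [kinetic_params()] object.
#' @return Crossing time in hours.
#' @export
unstimulated_crossing_time <- function(params) {
  -(1 / params$muD) * log(1 - params$Th * params$muD / params$ktD)
}

#' Integrate one cell under constant inputs
#'
#' Stiff-capable integration (`deSolve::lsodar`) of a single cell with a
#' frozen ligand input `DE` and Wnt level `W`, reporting every crossing of
#' the Delta quantization threshold `Th` in either direction. Integration
#' does not stop at crossings; all are located by the solver's root finder
#' and returned with a direction tag.
#'
#' @param state0 Non-negative initial state (named vector, see
#'   [dn_species()]).
#' @param DE,W Constant inputs (non-negative scalars).
#' @param params A [kinetic_params()] object.
#' @param t_span Length-2 numeric `c(t0, t1)`, hours.
#' @param rtol,atol Solver tolerances.
#' @param n_out Number of equally spaced output times across `t_span`.
#' @return A list of class `"cell_trajectory"`: `times`, `states` (matrix,
#'   one row per output time, columns in species order) and `crossings`
#'   (data frame with `time` and `direction`, `"up"` or `"down"`).
#' @export
integrate_cell <- function(state0, DE = 0, W = 0, params,
                           t_span, rtol = 1e-6, atol = 1e-9, n_out = 201L) {
  S0 <- .as_state_matrix(state0)
  if (any(S0 < 0)) stop("`state0` must be non-negative", call. = FALSE)
  if (!is.numeric(t_span) || length(t_span) != 2L || t_span[2L] < t_span[1L])
    stop("`t_span` must be c(t0, t1) with t1 >= t0", call. = FALSE)
  p <- params
  times <- seq(t_span[1L], t_span[2L], length.out = max(2L, n_out))
  func <- function(t, y, parms)
    list(as.vector(.dn_rhs_mat(matrix(y, nrow = 6L), DE, W, p)))
  rootfunc <- function(t, y, parms) y[6L] - p$Th
  out <- deSolve::lsodar(
    y = as.vector(S0[, 1L]), times = times, func = func, parms = NULL,
    rootfunc = rootfunc,
    events = list(func = function(t, y, parms) y, root = TRUE),
    rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop("cell integration failed (lsodar istate ", istate[1L], ")",
         call. = FALSE)
  troot <- attr(out, "troot")
  crossings <- data.frame(time = numeric(0), direction = character(0))
  if (length(troot)) {
    dirs <- vapply(troot, function(tt) {
      y <- vapply(seq_len(7L)[-1L], function(j)
        stats::approx(out[, 1L], out[, j], xout = tt, ties = "ordered")$y,
        numeric(1))
      dD <- .dn_rhs_mat(matrix(pmax(y, 0), nrow = 6L), DE, W, p)[6L, 1L]
      if (dD >= 0) "up" else "down"
    }, character(1))
    crossings <- data.frame(time = as.numeric(troot), direction = dirs)
  }
  states <- out[, -1L, drop = FALSE]
  colnames(states) <- .DN_SPECIES
  structure(list(times = out[, 1L], states = states, crossings = crossings),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cell_trajectory> %d time points over [%g, %g] h, %d threshold crossing(s)\n",
    length(x$times), min(x$times), max(x$times), nrow(x$crossings)))
  invisible(x)
}
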