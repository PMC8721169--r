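# Event-driven co-simulation of the tissue.
#
# Between threshold crossings every cell's ligand input DE is constant, so
# the whole grid is one smooth (block-diagonal) ODE system: all cells are
# advanced together as a single stacked system, the solver's root finder
# locates the earliest Delta/threshold crossing exactly, the logic matrix and
# every DE are refreshed there, and the loop repeats until grid equilibrium
# or the time horizon. Advancing the stacked system is exact, not an
# operator-splitting approximation, precisely because inputs are frozen
# within an epoch.

`%||%` <- function(a, b) if (is.null(a)) b else a

.grid_to_vec <- function(M) as.vector(t(M))
.vec_to_grid <- function(grid, v) matrix(v, grid$n_rows, grid$n_cols,
                                         byrow = TRUE)

#' Default initialization ranges
#'
#' Per-species `[low, high]` intervals for random initial conditions. The
#' default "biological range" of each species spans the envelope of the two
#' cell-autonomous fixed points: the unstimulated steady state (`DE = 0`;
#' all zero except Delta at `ktD/muD`) and the fully stimulated one
#' (`DE = DEmax`). Lows are 0, highs the componentwise maximum of the two.
#'
#' @param params A [kinetic_params()] object.
#' @return A 6 x 2 numeric matrix, rows named as [dn_species()], columns
#'   `low` and `high`.
#' @export
default_init_ranges <- function(params) {
  s0 <- cell_steady_state(params, DE = 0)
  s1 <- cell_steady_state(params, DE = params$DEmax)
  cbind(low = rep(0, 6L), high = pmax(s0, s1))
}

.normalize_init_ranges <- function(init_ranges, params) {
  if (is.null(init_ranges)) return(default_init_ranges(params))
  if (is.list(init_ranges)) {
    base <- default_init_ranges(params)
    unknown <- setdiff(names(init_ranges), .DN_SPECIES)
    if (length(unknown))
      stop("unknown species in init ranges: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    for (nm in names(init_ranges)) base[nm, ] <- init_ranges[[nm]]
    init_ranges <- base
  }
  if (!is.matrix(init_ranges) || nrow(init_ranges) != 6L ||
      ncol(init_ranges) != 2L)
    stop("`init_ranges` must be a 6 x 2 matrix or a named list of ",
         "[low, high] pairs", call. = FALSE)
  if (is.null(rownames(init_ranges))) rownames(init_ranges) <- .DN_SPECIES
  colnames(init_ranges) <- c("low", "high")
  if (any(init_ranges[, "low"] < 0))
    stop("init range lows must be non-negative", call. = FALSE)
  if (any(init_ranges[, "low"] > init_ranges[, "high"]))
    stop("init range low exceeds high for: ",
         paste(rownames(init_ranges)[
           init_ranges[, "low"] > init_ranges[, "high"]], collapse = ", "),
         call. = FALSE)
  init_ranges[.DN_SPECIES, , drop = FALSE]
}

#' Configure a tissue simulation
#'
#' Collects everything one run needs: grid geometry, neighborhood logic
#' rule, kinetic parameters, optional positional Wnt field, initialization
#' ranges, RNG seed and stop conditions.
#'
#' @param grid A [grid_spec()].
#' @param rule A [logic_rule()].
#' @param params A [kinetic_params()] object.
#' @param wnt Optional positional Wnt input: `NULL` (none), a full
#'   `n_rows x n_cols` concentration matrix, or a list
#'   `list(Wmax =, axis =)` passed to [wnt_field()].
#' @param init_ranges Optional per-species `[low, high]` initialization
#'   intervals: a 6 x 2 matrix (rows in [dn_species()] order) or a named
#'   list overriding individual species; defaults to
#'   [default_init_ranges()].
#' @param seed Integer RNG seed; the only source of randomness in a run.
#' @param t_max Maximum simulated time (hours).
#' @param equilibrium_window Event-free time (hours) after which the grid is
#'   tested for equilibrium (see [run_simulation()]).
#' @param snapshot_times Optional numeric vector of times at which full-grid
#'   Delta snapshots are recorded.
#' @param rtol,atol Solver tolerances (defaults 1e-6 and 1e-9).
#' @param record_trajectories Keep per-cell states at every epoch boundary
#'   (default `TRUE`).
#' @param max_epochs Safety cap on the number of event epochs; default
#'   scales with grid size.
#' @param verbose Emit per-epoch progress messages.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(grid, rule = logic_rule(),
                              params = kinetic_params(), wnt = NULL,
                              init_ranges = NULL, seed = 1L,
                              t_max = 500, equilibrium_window = 50,
                              snapshot_times = NULL,
                              rtol = 1e-6, atol = 1e-9,
                              record_trajectories = TRUE,
                              max_epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), inherits(rule, "logic_rule"),
            inherits(params, "kinetic_params"))
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max < 0)
    stop("`t_max` must be a non-negative time in hours", call. = FALSE)
  if (!is.numeric(equilibrium_window) || length(equilibrium_window) != 1L ||
      equilibrium_window <= 0)
    stop("`equilibrium_window` must be a positive time in hours",
         call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("`seed` must be an integer", call. = FALSE)
  Th <- rule$Th %||% params$Th
  if (Th >= params$ktD / params$muD)
    stop("threshold `Th` must be below the unstimulated Delta steady ",
         "state ktD/muD", call. = FALSE)
  wnt_spec <- NULL
  if (is.list(wnt) && !is.matrix(wnt)) {
    wnt_spec <- list(Wmax = wnt$Wmax, axis = wnt$axis %||% "row")
    wnt <- wnt_field(grid, Wmax = wnt_spec$Wmax, axis = wnt_spec$axis)
  }
  if (!is.null(wnt)) {
    if (!is.matrix(wnt) || nrow(wnt) != grid$n_rows ||
        ncol(wnt) != grid$n_cols || any(wnt < 0))
      stop("`wnt` must be a non-negative n_rows x n_cols matrix",
           call. = FALSE)
  }
  if (!is.null(snapshot_times)) {
    if (!is.numeric(snapshot_times) || any(snapshot_times < 0))
      stop("`snapshot_times` must be non-negative times", call. = FALSE)
    snapshot_times <- sort(unique(snapshot_times))
  }
  init_ranges <- .normalize_init_ranges(init_ranges, params)
  structure(list(
    grid = grid, rule = rule, params = params, wnt = wnt,
    init_ranges = init_ranges, seed = as.integer(seed), t_max = t_max,
    equilibrium_window = equilibrium_window,
    snapshot_times = snapshot_times, rtol = rtol, atol = atol,
    record_trajectories = isTRUE(record_trajectories),
    max_epochs = as.integer(max_epochs %||% (200L + 30L * n_cells(grid))),
    verbose = isTRUE(verbose)),
    class = "simulation_config",
    wnt_spec = wnt_spec)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d x %d %s grid | rule dist=%d theta=%d | seed %d | t_max %g h%s\n",
    x$grid$n_rows, x$grid$n_cols, x$grid$boundary, x$rule$dist,
    x$rule$theta, x$seed, x$t_max,
    if (is.null(x$wnt)) "" else " | Wnt gradient"))
  invisible(x)
}

#' Draw random initial states for every cell
#'
#' Each of the six species of each cell is drawn independently and uniformly
#' from its configured `[low, high]` range, reproducibly from the config
#' seed. Species are drawn in canonical order, all cells (linear id order)
#' per species.
#'
#' @param config A [simulation_config()].
#' @return A 6 x `n_cells` numeric state matrix (rows [dn_species()]).
#' @export
init_states <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- n_cells(config$grid)
  set.seed(config$seed)
  S <- matrix(0, 6L, n, dimnames = list(.DN_SPECIES, NULL))
  for (i in seq_len(6L))
    S[i, ] <- stats::runif(n, config$init_ranges[i, "low"],
                           config$init_ranges[i, "high"])
  S
}

# Effective rule constants: overrides on the rule win over kinetic params.
.rule_consts <- function(config) {
  list(Th = config$rule$Th %||% config$params$Th,
       DEmax = config$rule$DEmax %||% config$params$DEmax,
       theta = config$rule$theta)
}

.wnt_vec <- function(config) {
  if (is.null(config$wnt)) rep(0, n_cells(config$grid))
  else .grid_to_vec(config$wnt)
}

#' Advance the grid to the next threshold-crossing event
#'
#' Integrates all cells simultaneously as one stacked ODE system under
#' frozen ligand inputs (computed from `logic` through the config's rule)
#' and the static Wnt field, from `t0` until the earliest crossing of the
#' Delta quantization threshold by any cell, or until `horizon` if no cell
#' crosses. All cells' states are reported at exactly the stopping time;
#' every cell crossing within the simultaneity tolerance of that time is
#' committed in the same epoch.
#'
#' A hysteresis band of `1e-6 * Th` guards against chattering: a cell whose
#' Delta starts an epoch inside the band (as it does right after its own
#' crossing) is re-armed only once it leaves the band, and its logic value
#' is refreshed at the exit side.
#'
#' @param states 6 x `n_cells` state matrix.
#' @param logic Integer 0/1 vector of current logic values (linear cell id
#'   order), consistent with `binarize()` of the Delta row of `states` up to
#'   hysteresis.
#' @param t0 Epoch start time (hours).
#' @param config A [simulation_config()].
#' @param horizon Latest time to integrate to; defaults to the config's
#'   `t_max`.
#' @param adjacency Optional precomputed [ring_adjacency()] matrix for the
#'   rule's distance (computed on the fly when `NULL`).
#' @param snapshot_times Times within `(t0, horizon)` at which output rows
#'   are requested.
#' @return A list: `t` (stopping time), `states` (6 x n matrix at `t`),
#'   `logic` (updated 0/1 vector), `events` (data frame `time`, `row`,
#'   `col`, `direction`, `new_value`), `root_found` (logical), `out_times`
#'   and `out_states` (requested intermediate output, one 6 x n matrix per
#'   time).
#' @export
advance_to_next_event <- function(states, logic, t0, config, horizon = NULL,
                                  adjacency = NULL,
                                  snapshot_times = numeric(0)) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- config$grid
  p <- config$params
  n <- n_cells(grid)
  if (!is.matrix(states) || nrow(states) != 6L || ncol(states) != n)
    stop("`states` must be a 6 x n_cells matrix", call. = FALSE)
  if (length(logic) != n || !all(logic %in% c(0L, 1L)))
    stop("`logic` must be a 0/1 vector with one entry per cell",
         call. = FALSE)
  if (is.null(adjacency)) adjacency <- ring_adjacency(grid, config$rule$dist)
  horizon <- horizon %||% config$t_max
  rc <- .rule_consts(config)
  DE <- .dependent_input_all(logic, adjacency, rc$theta, rc$DEmax)
  W <- .wnt_vec(config)
  band <- 1e-6 * rc$Th
  armed <- abs(states["D", ] - rc$Th) > band
  iD <- seq.int(6L, 6L * n, by = 6L)

  func <- function(t, y, parms)
    list(as.vector(.dn_rhs_mat(matrix(y, nrow = 6L), DE, W, p)))
  rootfunc <- function(t, y, parms) {
    g <- y[iD] - rc$Th
    if (!all(armed)) g[!armed] <- abs(g[!armed]) - band
    g
  }
  times <- sort(unique(c(
    t0, snapshot_times[snapshot_times > t0 & snapshot_times < horizon],
    horizon)))
  out <- deSolve::lsodar(as.vector(states), times, func, parms = NULL,
                         rootfunc = rootfunc,
                         rtol = config$rtol, atol = config$atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0)
    stop(sprintf("grid integration failed at t = %g (lsodar istate %d)",
                 out[nrow(out), 1L], istate[1L]), call. = FALSE)

  tstar <- unname(out[nrow(out), 1L])
  Sstar <- matrix(out[nrow(out), -1L], nrow = 6L,
                  dimnames = list(.DN_SPECIES, NULL))
  iroot <- attr(out, "iroot")
  root_found <- !is.null(iroot) && any(iroot != 0)

  new_logic <- logic
  ev_cell <- integer(0)
  ev_dir <- character(0)
  ev_val <- integer(0)
  if (root_found) {
    Dst <- Sstar["D", ]
    fired <- which(iroot != 0)
    # simultaneity sweep: commit every armed cell sitting on the threshold
    fired <- sort(unique(c(fired,
                           which(armed & abs(Dst - rc$Th) <= 1e-8 * rc$Th))))
    for (i in fired) {
      if (armed[i]) {
        v <- 1L - logic[i]
      } else {
        # hysteresis-band exit: refresh at the exit side
        v <- as.integer(Dst[i] >= rc$Th)
      }
      if (v != logic[i]) {
        ev_cell <- c(ev_cell, i)
        ev_dir <- c(ev_dir, if (v == 1L) "up" else "down")
        ev_val <- c(ev_val, v)
        new_logic[i] <- v
      }
    }
  }
  cells <- if (length(ev_cell)) id_to_cell(grid, ev_cell) else
    cbind(row = integer(0), col = integer(0))
  events <- data.frame(time = rep(tstar, length(ev_cell)),
                       row = cells[, "row"], col = cells[, "col"],
                       direction = ev_dir, new_value = ev_val)

  keep <- out[, 1L] %in% snapshot_times
  list(t = tstar, states = Sstar, logic = new_logic, events = events,
       root_found = root_found,
       out_times = out[keep, 1L],
       out_states = lapply(which(keep), function(k)
         matrix(out[k, -1L], nrow = 6L,
                dimnames = list(.DN_SPECIES, NULL))))
}

#' Run a hybrid logic-ODE tissue simulation
#'
#' The main loop: starting from random initial conditions, repeatedly (i)
#' binarize every cell's Delta into the logic matrix, (ii) apply the
#' neighborhood quorum rule to set every cell's ligand input, (iii)
#' integrate the whole grid until the earliest threshold crossing, (iv)
#' commit the crossing events and refresh the logic values. The run stops at
#' *equilibrium* — no events for `equilibrium_window` hours and a maximal
#' state derivative below `1e-6 * ktD` at the window's end — or when `t_max`
#' is reached.
#'
#' @param config A [simulation_config()].
#' @param verbose Override the config's verbosity.
#' @param initial_states Optional 6 x `n_cells` state matrix to start from,
#'   bypassing the random initialization (e.g. to continue a run or probe a
#'   hand-built tissue state).
#' @return An object of class `"simulation_result"`: a list with `events`
#'   (data frame `time`, `row`, `col`, `direction`, `new_value`, ties within
#'   an epoch ordered by row-major cell id), `epoch_times`, `logic_history`
#'   (integer matrix, one row per epoch boundary, cells in linear id order),
#'   `trajectories` (`times` plus a list of 6 x n state matrices, or `NULL`),
#'   `snapshots` (named list of Delta grid matrices at the requested times),
#'   `final_states`, `final_delta`, `final_logic` (grid-shaped), and
#'   `termination` (`"equilibrium"`, `"t_max"` or `"error"`).
#' @examples
#' cfg <- simulation_config(grid_spec(4, 4, "toroidal"), seed = 7,
#'                          record_trajectories = FALSE)
#' \donttest{
#' res <- run_simulation(cfg)
#' res$termination
#' summarize_pattern(res$final_logic, cfg$grid)
#' }
#' @export
run_simulation <- function(config, verbose = config$verbose,
                           initial_states = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  grid <- config$grid
  p <- config$params
  rc <- .rule_consts(config)
  n <- n_cells(grid)
  adjacency <- ring_adjacency(grid, config$rule$dist)
  max_ring <- max(rowSums(adjacency))
  if (rc$theta > max_ring)
    warning(sprintf(
      "quorum theta = %d exceeds the largest ring size (%d) on this grid; the rule can never fire",
      rc$theta, max_ring))

  if (is.null(initial_states)) {
    states <- init_states(config)
  } else {
    if (!is.matrix(initial_states) || nrow(initial_states) != 6L ||
        ncol(initial_states) != n || any(initial_states < 0))
      stop("`initial_states` must be a non-negative 6 x n_cells matrix",
           call. = FALSE)
    states <- initial_states
    rownames(states) <- .DN_SPECIES
  }
  t <- 0
  logic <- as.integer(binarize(states["D", ], rc$Th))
  W <- .wnt_vec(config)

  events <- list()
  epoch_times <- 0
  logic_history <- list(logic)
  traj_times <- 0
  traj_states <- if (config$record_trajectories) list(states) else NULL
  snapshots <- list()
  pending_snaps <- config$snapshot_times %||% numeric(0)
  record_snap <- function(tt, S) {
    snapshots[[sprintf("%.6f", tt)]] <<- .vec_to_grid(grid, S["D", ])
  }
  for (ts in pending_snaps[pending_snaps <= 0]) record_snap(ts, states)
  pending_snaps <- pending_snaps[pending_snaps > 0]

  termination <- if (config$t_max == 0) "t_max" else NULL
  epoch <- 0L
  while (is.null(termination)) {
    epoch <- epoch + 1L
    if (epoch > config$max_epochs) {
      warning("maximum number of epochs reached before a break condition; ",
              "returning with termination = \"error\"")
      termination <- "error"
      break
    }
    horizon <- min(t + config$equilibrium_window, config$t_max)
    adv <- advance_to_next_event(states, logic, t, config, horizon,
                                 adjacency, pending_snaps)
    for (k in seq_along(adv$out_times))
      record_snap(adv$out_times[k], adv$out_states[[k]])
    pending_snaps <- pending_snaps[pending_snaps > adv$t]
    states <- adv$states
    t <- adv$t
    if (config$record_trajectories) {
      traj_times <- c(traj_times, t)
      traj_states <- c(traj_states, list(states))
    }
    if (adv$root_found) {
      logic <- adv$logic
      if (nrow(adv$events)) {
        events[[length(events) + 1L]] <- adv$events
        epoch_times <- c(epoch_times, t)
        logic_history <- c(logic_history, list(logic))
      }
      if (verbose)
        message(sprintf("epoch %d | t = %.3f h | %d event(s) | %d Delta+",
                        epoch, t, nrow(adv$events), sum(logic)))
      if (t >= config$t_max * (1 - 1e-12)) termination <- "t_max"
    } else {
      # event-free window: test for grid equilibrium
      DE <- .dependent_input_all(logic, adjacency, rc$theta, rc$DEmax)
      derivs <- .dn_rhs_mat(states, DE, W, p)
      if (max(abs(derivs)) < 1e-6 * p$ktD) {
        termination <- "equilibrium"
      } else if (t >= config$t_max * (1 - 1e-12)) {
        termination <- "t_max"
      }
    }
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), row = integer(0), col = integer(0),
               direction = character(0), new_value = integer(0))
  final_delta <- .vec_to_grid(grid, states["D", ])
  structure(list(
    events = events,
    epoch_times = epoch_times,
    logic_history = do.call(rbind, logic_history),
    trajectories = if (config$record_trajectories)
      list(times = traj_times, states = traj_states) else NULL,
    snapshots = snapshots,
    final_states = states,
    final_delta = final_delta,
    final_logic = binarize(final_delta, rc$Th),
    termination = termination,
    n_epochs = epoch,
    config = config),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  g <- x$config$grid
  cat(sprintf(
    "<simulation_result> %d x %d %s grid | %d event(s) in %d epoch(s) | t = %.2f h | termination: %s\n",
    g$n_rows, g$n_cols, g$boundary, nrow(x$events), x$n_epochs,
    if (nrow(x$events)) max(x$events$time) else 0, x$termination))
  cat(sprintf("  Delta-positive cells at end: %d / %d\n",
              sum(x$final_logic), n_cells(g)))
  invisible(x)
}

#' Long-format trajectory data
#'
#' Flattens the epoch-boundary state samples of a run into a long data frame
#' suitable for CSV export or plotting.
#'
#' @param result A [run_simulation()] result with recorded trajectories.
#' @return Data frame with columns `time`, `row`, `col`, `species`, `value`.
#' @export
trajectory_df <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  if (is.null(result$trajectories))
    stop("this run was configured with record_trajectories = FALSE",
         call. = FALSE)
  grid <- result$config$grid
  cells <- all_cells(grid)
  n <- n_cells(grid)
  blocks <- lapply(seq_along(result$trajectories$times), function(k) {
    S <- result$trajectories$states[[k]]
    data.frame(time = result$trajectories$times[k],
               row = rep(cells[, "row"], each = 6L),
               col = rep(cells[, "col"], each = 6L),
               species = rep(.DN_SPECIES, times = n),
               value = as.vector(S))
  })
  do.call(rbind, blocks)
}
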