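# Logic layer: binarization of cell outputs, neighborhood quorum rules for
# the dependent ligand input DE, and the position-only Wnt field.

#' Neighborhood quorum rule for the ligand input
#'
#' A cell receives the ligand input `DE = DEmax` when at least `theta` of the
#' cells in its ring at hexagonal distance `dist` are Delta-positive (logic
#' value 1), and `DE = 0` otherwise. The neighbor set is the exact ring at
#' distance `dist`, not the cumulative disk. `DEmax` and the binarization
#' threshold `Th` default to the values in the run's [kinetic_params()];
#' supply them here only to override.
#'
#' @param dist Integer ring distance, at least 1.
#' @param theta Integer quorum, at least 1: minimum number of Delta-positive
#'   ring members required for the input to fire.
#' @param DEmax,Th Optional overrides of the kinetic parameter values.
#' @return An object of class `"logic_rule"`.
#' @examples
#' logic_rule(dist = 1, theta = 1) # classic lateral inhibition
#' logic_rule(dist = 3, theta = 10) # long-range quorum rule
#' @export
logic_rule <- function(dist = 1L, theta = 1L, DEmax = NULL, Th = NULL) {
  if (!is.numeric(dist) || length(dist) != 1L || dist < 1 ||
      dist != round(dist))
    stop("`dist` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 1 ||
      theta != round(theta))
    stop("`theta` must be an integer >= 1", call. = FALSE)
  for (v in list(DEmax = DEmax, Th = Th))
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0))
      stop("rule overrides `DEmax` and `Th` must be positive scalars",
           call. = FALSE)
  structure(list(dist = as.integer(dist), theta = as.integer(theta),
                 DEmax = DEmax, Th = Th),
            class = "logic_rule")
}

#' @export
print.logic_rule <- function(x, ...) {
  cat(sprintf(
    "<logic_rule> DE = DEmax if >= %d of the ring-%d neighbors are Delta-positive\n",
    x$theta, x$dist))
  invisible(x)
}

#' Binarize Delta concentrations into a logic matrix
#'
#' Thresholds every cell's Delta read-out at the quantization threshold:
#' logic value 1 (Delta-positive) where `D >= Th`, 0 where `D < Th`. The
#' boundary case `D == Th` maps to 1.
#'
#' @param delta Numeric vector or matrix of Delta concentrations.
#' @param Th Positive quantization threshold.
#' @return Integer 0/1 object of the same shape as `delta`.
#' @examples
#' binarize(c(0, 1, 2), Th = 1)
#' @export
binarize <- function(delta, Th) {
  if (!is.numeric(Th) || length(Th) != 1L || Th <= 0)
    stop("`Th` must be a positive scalar", call. = FALSE)
  out <- (delta >= Th) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Dependent ligand input of one cell
#'
#' Applies a [logic_rule()] to the binarized grid: sums the logic values over
#' the cell's ring at the rule's distance and returns `DEmax` when the sum
#' reaches the quorum `theta`, else 0.
#'
#' @param V Logic matrix: 0/1 values in grid shape (`n_rows` x `n_cols`).
#' @param cell Length-2 integer vector `c(row, col)`, 0-based.
#' @param rule A [logic_rule()].
#' @param grid A [grid_spec()].
#' @param DEmax Ligand amplitude; defaults to the rule's override or, if that
#'   is `NULL`, must be supplied.
#' @return `DEmax` or 0.
#' @export
dependent_input <- function(V, cell, rule, grid, DEmax = rule$DEmax) {
  stopifnot(inherits(rule, "logic_rule"), inherits(grid, "grid_spec"))
  if (is.null(DEmax))
    stop("`DEmax` is not set on the rule; supply it explicitly",
         call. = FALSE)
  if (!is.matrix(V) || nrow(V) != grid$n_rows || ncol(V) != grid$n_cols)
    stop("logic matrix shape does not match the grid", call. = FALSE)
  if (!all(V %in% c(0L, 1L)))
    stop("logic matrix entries must be 0 or 1", call. = FALSE)
  nb <- ring(grid, cell, rule$dist)
  s <- if (nrow(nb) == 0L) 0L else sum(V[cbind(nb[, 1L] + 1L, nb[, 2L] + 1L)])
  if (s >= rule$theta) DEmax else 0
}

# Vectorized version used by the engine: logic and result are per-cell
# vectors in linear id order, adjacency a precomputed ring_adjacency matrix.
.dependent_input_all <- function(logic, adjacency, theta, DEmax) {
  DEmax * (as.vector(adjacency %*% logic) >= theta)
}

#' Positional Wnt field
#'
#' Builds the position-only (independent) input: a linear gradient of Wnt
#' concentration along the chosen grid axis, 0 at the first row (or column)
#' and `Wmax` at the last. The field is constant in time. A degenerate grid
#' (a single row with `axis = "row"`) carries no positional information, so
#' a zero field is returned with a warning.
#'
#' @param grid A [grid_spec()].
#' @param Wmax Maximal Wnt concentration (non-negative).
#' @param axis `"row"` (default) or `"col"`: gradient direction.
#' @return Numeric `n_rows` x `n_cols` matrix of Wnt concentrations.
#' @examples
#' wnt_field(grid_spec(5, 4), Wmax = 10)
#' @export
wnt_field <- function(grid, Wmax, axis = c("row", "col")) {
  stopifnot(inherits(grid, "grid_spec"))
  axis <- match.arg(axis)
  if (!is.numeric(Wmax) || length(Wmax) != 1L || Wmax < 0)
    stop("`Wmax` must be a non-negative scalar", call. = FALSE)
  n <- if (axis == "row") grid$n_rows else grid$n_cols
  if (n == 1L) {
    warning("degenerate grid axis for Wnt gradient; returning a zero field")
    return(matrix(0, grid$n_rows, grid$n_cols))
  }
  lev <- Wmax * (seq_len(n) - 1L) / (n - 1L)
  if (axis == "row")
    matrix(lev, grid$n_rows, grid$n_cols, byrow = FALSE)
  else
    matrix(lev, grid$n_rows, grid$n_cols, byrow = TRUE)
}
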