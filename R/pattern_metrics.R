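# Quantitative descriptors of terminal grid patterns.

#' Check a logic matrix for lateral-inhibition equilibrium
#'
#' Operationalizes the completed salt-and-pepper pattern as a
#' quorum-generalized maximal-independent-set condition on the ring graph:
#' (a) every Delta-positive cell has fewer than `theta` Delta-positive cells
#' in its ring at the rule's distance (it receives no inhibiting input), and
#' (b) every Delta-negative cell has at least `theta` Delta-positive ring
#' members (something keeps it repressed). Cells listed in `exempt` are
#' excused from condition (b) — a hook for positional inputs that fix a
#' cell's fate independently of its neighbors.
#'
#' @param logic Integer 0/1 matrix in grid shape.
#' @param rule A [logic_rule()].
#' @param grid A [grid_spec()].
#' @param exempt Optional logical matrix (grid shape): cells exempt from
#'   condition (b).
#' @return A list: `valid` (logical) and `violations`, a data frame with
#'   columns `row`, `col` and `type` (`"inhibited_positive"` for (a)
#'   failures, `"unforced_negative"` for (b) failures).
#' @examples
#' g <- grid_spec(3, 3, "bounded")
#' check_lateral_inhibition(matrix(0L, 3, 3), logic_rule(1, 1), g)$valid
#' @export
check_lateral_inhibition <- function(logic, rule, grid, exempt = NULL) {
  stopifnot(inherits(rule, "logic_rule"), inherits(grid, "grid_spec"))
  if (!is.matrix(logic) || nrow(logic) != grid$n_rows ||
      ncol(logic) != grid$n_cols || !all(logic %in% c(0L, 1L)))
    stop("`logic` must be a 0/1 matrix in grid shape", call. = FALSE)
  if (!is.null(exempt))
    stopifnot(is.logical(exempt), dim(exempt) == dim(logic))
  v <- .grid_to_vec(logic)
  A <- ring_adjacency(grid, rule$dist)
  npos <- as.vector(A %*% v)
  bad_pos <- v == 1L & npos >= rule$theta
  bad_neg <- v == 0L & npos < rule$theta
  if (!is.null(exempt)) bad_neg <- bad_neg & !.grid_to_vec(exempt)
  ids <- c(which(bad_pos), which(bad_neg))
  type <- c(rep("inhibited_positive", sum(bad_pos)),
            rep("unforced_negative", sum(bad_neg)))
  cells <- if (length(ids)) id_to_cell(grid, ids) else
    cbind(row = integer(0), col = integer(0))
  violations <- data.frame(row = cells[, "row"], col = cells[, "col"],
                           type = type)
  violations <- violations[order(violations$row, violations$col), ,
                           drop = FALSE]
  rownames(violations) <- NULL
  list(valid = nrow(violations) == 0L, violations = violations)
}

#' Summary statistics of a terminal pattern
#'
#' Counts Delta-positive cells and measures how tightly they pack: the
#' minimal pairwise hexagonal distance between positive cells, computed with
#' the grid's boundary mode (wrapped distances on cylindrical and toroidal
#' grids). With fewer than two positive cells the minimal distance is
#' reported as `Inf`.
#'
#' @param logic Integer 0/1 matrix in grid shape.
#' @param grid A [grid_spec()].
#' @param rule Optional [logic_rule()]; when given, the summary also reports
#'   whether the pattern satisfies [check_lateral_inhibition()].
#' @return A one-row data frame: `n_positive`, `fraction_positive`,
#'   `min_positive_distance` and (if `rule` is given)
#'   `is_valid_lateral_inhibition`.
#' @export
summarize_pattern <- function(logic, grid, rule = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(logic) || nrow(logic) != grid$n_rows ||
      ncol(logic) != grid$n_cols || !all(logic %in% c(0L, 1L)))
    stop("`logic` must be a 0/1 matrix in grid shape", call. = FALSE)
  v <- .grid_to_vec(logic)
  ids <- which(v == 1L)
  mind <- Inf
  if (length(ids) >= 2L) {
    cells <- id_to_cell(grid, ids)
    for (k in seq_len(length(ids) - 1L)) {
      d <- hex_distance(grid, cells[k, ],
                        cells[(k + 1L):length(ids), , drop = FALSE])
      mind <- min(mind, d)
    }
  }
  out <- data.frame(
    n_positive = length(ids),
    fraction_positive = length(ids) / n_cells(grid),
    min_positive_distance = mind)
  if (!is.null(rule))
    out$is_valid_lateral_inhibition <-
      check_lateral_inhibition(logic, rule, grid)$valid
  out
}
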