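# Hexagonal lattice geometry: addressing, neighbor rings, boundary wrapping.
#
# External addressing is the "odd-r" offset convention (0-based row/col,
# odd rows shifted half a cell to the right); internally cells are mapped to
# axial coordinates, which make graph distance and ring enumeration cheap.

#' Specify a hexagonal cell grid
#'
#' Defines the geometry of the epithelial sheet: number of rows and columns of
#' hexagonal cells and the boundary condition used to mitigate edge artifacts.
#' `"cylindrical"` joins the two lateral (column) borders by a single fold,
#' `"toroidal"` additionally joins top and bottom, and `"bounded"` leaves all
#' borders free, so border cells simply have fewer neighbors.
#'
#' Toroidal grids require an even `n_rows`: wrapping an odd number of offset
#' rows vertically breaks hexagonal adjacency (row parity would flip across
#' the seam), so such configurations are rejected.
#'
#' @param n_rows,n_cols Positive integers, grid dimensions.
#' @param boundary One of `"cylindrical"` (default), `"toroidal"`, `"bounded"`.
#' @return An object of class `"grid_spec"`.
#' @examples
#' g <- grid_spec(6, 6, "toroidal")
#' nrow(ring(g, c(2, 2), 1)) # 6 nearest neighbors
#' @export
grid_spec <- function(n_rows, n_cols,
                      boundary = c("cylindrical", "toroidal", "bounded")) {
  boundary <- match.arg(boundary)
  for (v in list(n_rows = n_rows, n_cols = n_cols)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < 1 || v != round(v))
      stop("grid dimensions must be positive integers", call. = FALSE)
  }
  if (boundary == "toroidal" && n_rows %% 2 != 0)
    stop("toroidal grids require an even `n_rows`: ",
         "vertical wrapping of an odd number of offset rows breaks ",
         "hexagonal adjacency", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 boundary = boundary),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d hexagonal grid, %s boundary\n",
              x$n_rows, x$n_cols, x$boundary))
  invisible(x)
}

#' Number of cells on a grid
#' @param grid A [grid_spec()].
#' @return Integer cell count.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$n_rows * grid$n_cols
}

#' Linear cell identifiers
#'
#' Cells are addressed externally by 0-based `(row, col)` offset pairs and
#' internally by 1-based row-major linear ids. These helpers convert between
#' the two.
#'
#' @param grid A [grid_spec()].
#' @param row,col Integer vectors of 0-based coordinates.
#' @param id Integer vector of 1-based linear ids.
#' @return `cell_id()` returns integer ids; `id_to_cell()` a two-column
#'   integer matrix with columns `row`, `col`.
#' @export
cell_id <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols))
    stop("cell index out of range for this grid", call. = FALSE)
  as.integer(1L + row * grid$n_cols + col)
}

#' @rdname cell_id
#' @export
id_to_cell <- function(grid, id) {
  stopifnot(inherits(grid, "grid_spec"))
  if (any(id < 1L | id > n_cells(grid)))
    stop("cell id out of range for this grid", call. = FALSE)
  id <- as.integer(id) - 1L
  cbind(row = id %/% grid$n_cols, col = id %% grid$n_cols)
}

#' All cell coordinates of a grid
#' @param grid A [grid_spec()].
#' @return Two-column integer matrix (`row`, `col`), one row per cell, in
#'   row-major (linear id) order.
#' @export
all_cells <- function(grid) {
  id_to_cell(grid, seq_len(n_cells(grid)))
}

.check_cell <- function(grid, cell) {
  if (!is.numeric(cell) || length(cell) != 2L || any(cell != round(cell)))
    stop("a cell index is a length-2 integer vector c(row, col)",
         call. = FALSE)
  if (cell[1L] < 0 || cell[1L] >= grid$n_rows ||
      cell[2L] < 0 || cell[2L] >= grid$n_cols)
    stop(sprintf("cell (%d, %d) is not on a %d x %d grid",
                 cell[1L], cell[2L], grid$n_rows, grid$n_cols),
         call. = FALSE)
  invisible(as.integer(cell))
}

# odd-r offset <-> axial conversion; valid for any integer row (floor-style
# %% / %/% keep the map consistent across wrapped images).
.offset_to_axial <- function(row, col) {
  cbind(q = col - (row - (row %% 2L)) %/% 2L, r = row)
}

.axial_to_offset <- function(q, r) {
  cbind(row = r, col = q + (r - (r %% 2L)) %/% 2L)
}

.axial_norm <- function(dq, dr) (abs(dq) + abs(dr) + abs(dq + dr)) %/% 2L

#' Hexagonal graph distance between cells
#'
#' Minimal number of adjacent-cell steps between `a` and `b`, taking the
#' grid's boundary condition into account: on cylindrical and toroidal grids
#' the distance is the minimum over all wrapped images of `b`.
#'
#' @param grid A [grid_spec()].
#' @param a Length-2 integer vector `c(row, col)`, 0-based.
#' @param b Length-2 vector or a two-column matrix of cells.
#' @return Integer vector of distances, one per row of `b`.
#' @export
hex_distance <- function(grid, a, b) {
  stopifnot(inherits(grid, "grid_spec"))
  a <- .check_cell(grid, a)
  if (is.null(dim(b))) b <- matrix(as.integer(b), nrow = 1L)
  apply(b, 1L, function(cell) .check_cell(grid, cell))
  row_shifts <- if (grid$boundary == "toroidal")
    c(-grid$n_rows, 0L, grid$n_rows) else 0L
  col_shifts <- if (grid$boundary != "bounded")
    c(-grid$n_cols, 0L, grid$n_cols) else 0L
  axa <- .offset_to_axial(a[1L], a[2L])
  best <- rep(.Machine$integer.max, nrow(b))
  for (dr in row_shifts) {
    for (dc in col_shifts) {
      ax <- .offset_to_axial(b[, 1L] + dr, b[, 2L] + dc)
      d <- .axial_norm(ax[, 1L] - axa[1L], ax[, 2L] - axa[2L])
      best <- pmin(best, d)
    }
  }
  as.integer(best)
}

#' Neighbor ring at exact hexagonal distance
#'
#' Returns every grid cell at exact hexagonal graph distance `dist` from
#' `cell`, after applying the grid's boundary wrapping. On bounded grids,
#' off-grid lattice positions are dropped. On small wrapped grids two lattice
#' positions can alias to the same grid cell; the result is deduplicated, so
#' a neighbor is seen (and its ligand counted) once. An interior cell of a
#' sufficiently large grid has `6 * dist` ring members: 6 at distance 1, 12
#' at distance 2, 18 at distance 3, and so on.
#'
#' @param grid A [grid_spec()].
#' @param cell Length-2 integer vector `c(row, col)`, 0-based.
#' @param dist Non-negative integer ring distance; `dist = 0` returns the
#'   cell itself.
#' @return Two-column integer matrix (`row`, `col`) of ring members, ordered
#'   by linear cell id; zero rows if the ring is empty.
#' @export
ring <- function(grid, cell, dist) {
  stopifnot(inherits(grid, "grid_spec"))
  cell <- .check_cell(grid, cell)
  if (!is.numeric(dist) || length(dist) != 1L || dist < 0 ||
      dist != round(dist))
    stop("`dist` must be a non-negative integer", call. = FALSE)
  dist <- as.integer(dist)
  if (dist == 0L)
    return(cbind(row = cell[1L], col = cell[2L]))

  ax0 <- .offset_to_axial(cell[1L], cell[2L])
  dq <- rep(-dist:dist, times = 2L * dist + 1L)
  dr <- rep(-dist:dist, each = 2L * dist + 1L)
  on_ring <- .axial_norm(dq, dr) == dist
  dq <- dq[on_ring]
  dr <- dr[on_ring]
  off <- .axial_to_offset(ax0[1L] + dq, ax0[2L] + dr)
  row <- off[, 1L]
  col <- off[, 2L]

  if (grid$boundary == "toroidal") {
    row <- row %% grid$n_rows
  } else {
    keep <- row >= 0L & row < grid$n_rows
    row <- row[keep]; col <- col[keep]
  }
  if (grid$boundary != "bounded") {
    col <- col %% grid$n_cols
  } else {
    keep <- col >= 0L & col < grid$n_cols
    row <- row[keep]; col <- col[keep]
  }
  if (length(row) == 0L)
    return(cbind(row = integer(0), col = integer(0)))

  ids <- sort(unique(cell_id(grid, row, col)))
  out <- id_to_cell(grid, ids)
  # wrapping can alias a ring position onto a cell that is in fact closer;
  # keep only cells whose true wrapped distance equals `dist`
  out[hex_distance(grid, cell, out) == dist, , drop = FALSE]
}

#' Ring adjacency matrix
#'
#' Precomputes, for a whole grid, which cells lie at exact hexagonal distance
#' `dist` of which: entry `[i, j] = 1` iff cell `j` is in `ring()` of cell
#' `i`. Used by the simulation engine so that neighborhood sums become a
#' single matrix-vector product per epoch.
#'
#' @param grid A [grid_spec()].
#' @param dist Positive integer ring distance.
#' @return A square 0/1 integer matrix of dimension `n_cells(grid)`.
#' @export
ring_adjacency <- function(grid, dist) {
  n <- n_cells(grid)
  cells <- all_cells(grid)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    nb <- ring(grid, cells[i, ], dist)
    if (nrow(nb) > 0L)
      A[i, cell_id(grid, nb[, 1L], nb[, 2L])] <- 1L
  }
  A
}
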