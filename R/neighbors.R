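## 2D cell-list spatial decomposition for O(N) pair-candidate generation.
##
## Cells tile the x,y plane with edge length equal to the interaction cutoff
## (plus an optional skin); each cell is an infinite column in z. The
## outermost ring of cells is unbounded outward, so every finite position
## maps to some cell. Cell occupancy is capped (default 32); atoms beyond the
## cap are excluded from pair generation but tracked in an overflow counter.

#' Assign atoms to a 2D cell grid
#'
#' Deterministic cell assignment: an atom at `(x, y)` belongs to cell
#' `floor((x - origin)/edge) + 1`, clamped into the grid, so an atom exactly
#' on a cell boundary belongs to the higher-index cell and atoms outside the
#' interior tiling land in the unbounded boundary cells. The cell edge is
#' `rc + skin`; the skin margin protects pair completeness between grid
#' refreshes against bounded per-step drift.
#'
#' @param pos N x 3 position matrix (finite).
#' @param rc geometric interaction cutoff (A).
#' @param cap maximum atoms kept per cell (default 32).
#' @param skin extra margin added to the cell edge for grid sizing only
#'   (default 0.3 A).
#' @param origin,n_cells optional fixed grid origin `c(x, y)` and cell counts
#'   `c(nx, ny)`; derived from the positions when omitted.
#' @param class optional per-atom class vector (e.g. metal vs molecule).
#'   When given, the occupancy cap applies to each class sublist of a cell
#'   separately, mirroring the separate molecule cell index of the parallel
#'   layout this models.
#' @return object of class `cell_grid`: `cell` (atom to cell id), `members`
#'   (per-cell in-capacity atom lists), `counts`, `overflow` (number of
#'   dropped atoms), `dropped` (their indices), grid geometry fields.
#' @export
cell_grid <- function(pos, rc, cap = 32L, skin = 0.3, origin = NULL,
                      n_cells = NULL, class = NULL) {
  if (rc <= 0) .stop_cond("steermd_bad_params", "cutoff must be > 0")
  if (any(!is.finite(pos)))
    .stop_cond("steermd_bad_input", "non-finite coordinate in cell assignment")
  edge <- rc + skin
  if (is.null(origin))
    origin <- c(min(pos[, 1]), min(pos[, 2])) - 1e-9
  if (is.null(n_cells)) {
    span <- c(max(pos[, 1]), max(pos[, 2])) - origin
    n_cells <- pmax(1L, as.integer(ceiling(span / edge)))
  }
  nx <- n_cells[1]; ny <- n_cells[2]
  cx <- pmin(nx, pmax(1L, floor((pos[, 1] - origin[1]) / edge) + 1L))
  cy <- pmin(ny, pmax(1L, floor((pos[, 2] - origin[2]) / edge) + 1L))
  cell <- (cy - 1L) * nx + cx

  members <- split(seq_len(nrow(pos)), factor(cell, levels = seq_len(nx * ny)))
  members <- lapply(members, sort)
  dropped <- integer(0)
  trunc_one <- function(m) {
    if (length(m) <= cap) return(m)
    dropped <<- c(dropped, m[-seq_len(cap)])
    m[seq_len(cap)]
  }
  if (is.null(class)) {
    members <- lapply(members, trunc_one)
  } else {
    members <- lapply(members, function(m) {
      if (length(m) <= cap) return(m)   # cannot overflow any class sublist
      sort(unlist(lapply(split(m, class[m]), trunc_one), use.names = FALSE))
    })
  }
  if (length(dropped) > 0) bump_counter("cell_overflow", length(dropped))
  structure(list(cell = cell, members = members,
                 counts = lengths(members), overflow = length(dropped),
                 dropped = sort(dropped), nx = nx, ny = ny,
                 origin = origin, edge = edge, rc = rc, cap = as.integer(cap)),
            class = "cell_grid")
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf("cell_grid: %dx%d cells, edge %.3f A, %d atoms, overflow %d\n",
              x$nx, x$ny, x$edge, length(x$cell), x$overflow))
  invisible(x)
}

#' Candidate atom pairs from a cell grid
#'
#' Yields every unordered pair of in-capacity atoms from the same cell or
#' from 8-adjacent cells, exactly once, in a deterministic order (half
#' neighborhood convention: within-cell pairs plus the east, north-east,
#' north and north-west neighbor cells). Since the cell edge is at least the
#' cutoff, this is a superset of all pairs within `rc`.
#'
#' @param grid a [cell_grid()].
#' @return two-column integer matrix with `i < j` per row, ordered by
#'   `(i, j)`.
#' @export
candidate_pairs <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  out <- vector("list", nx * ny * 5L)
  pos <- 1L
  offs <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  for (cyy in seq_len(ny)) {
    for (cxx in seq_len(nx)) {
      id <- (cyy - 1L) * nx + cxx
      mem <- grid$members[[id]]
      nmem <- length(mem)
      if (nmem == 0) next
      if (nmem >= 2) {
        pr <- utils::combn(seq_len(nmem), 2L)
        out[[pos]] <- cbind(mem[pr[1, ]], mem[pr[2, ]])
        pos <- pos + 1L
      }
      for (o in 1:4) {
        nxx <- cxx + offs[o, 1]; nyy <- cyy + offs[o, 2]
        if (nxx < 1 || nxx > nx || nyy < 1 || nyy > ny) next
        nb <- grid$members[[(nyy - 1L) * nx + nxx]]
        if (length(nb) == 0) next
        a <- rep(mem, times = length(nb))
        b <- rep(nb, each = nmem)
        out[[pos]] <- cbind(pmin(a, b), pmax(a, b))
        pos <- pos + 1L
      }
    }
  }
  res <- do.call(rbind, out[seq_len(pos - 1L)])
  if (is.null(res)) return(matrix(integer(0), 0, 2))
  res[order(res[, 1], res[, 2]), , drop = FALSE]
}

#' Brute-force pairs within a cutoff
#'
#' The O(N^2) all-pairs oracle: every unordered pair with separation at most
#' `rc`, in the same canonical order as the filtered cell-list pairs.
#'
#' @param pos N x 3 position matrix.
#' @param rc cutoff (A); `Inf` returns all pairs.
#' @return two-column integer matrix, `i < j`.
#' @export
brute_pairs_within <- function(pos, rc = Inf) {
  n <- nrow(pos)
  if (n < 2) return(matrix(integer(0), 0, 2))
  pr <- t(utils::combn(n, 2L))
  if (is.finite(rc)) {
    d <- pos[pr[, 1], , drop = FALSE] - pos[pr[, 2], , drop = FALSE]
    pr <- pr[rowSums(d * d) <= rc * rc, , drop = FALSE]
  }
  pr
}

#' Filter candidate pairs to the geometric cutoff
#'
#' @param pos position matrix.
#' @param pairs two-column candidate matrix.
#' @param rc cutoff.
#' @return the rows of `pairs` with separation at most `rc`.
#' @export
filter_pairs <- function(pos, pairs, rc) {
  if (nrow(pairs) == 0) return(pairs)
  d <- pos[pairs[, 1], , drop = FALSE] - pos[pairs[, 2], , drop = FALSE]
  pairs[rowSums(d * d) <= rc * rc, , drop = FALSE]
}

#' Cell-list refresh policy
#'
#' The cell index and count lists are rebuilt only every `interval` steps
#' (default 20), counted from step 0.
#'
#' @param step integer step counter (0-based).
#' @param interval refresh interval, >= 1.
#' @return logical: rebuild now?
#' @export
refresh_policy <- function(step, interval = 20L) {
  if (interval < 1) .stop_cond("steermd_bad_params", "refresh interval must be >= 1")
  step %% interval == 0
}
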