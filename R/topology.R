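## Molecular graphs and canonical enumeration of bonded interaction tuples.

#' Build a validated molecular graph
#'
#' A molecular graph holds the atoms (element, mass) of a single covalently
#' bonded molecule and its bond set. Single, double and triple covalent bonds
#' all count as one graph edge. The default degree cap of 3 restricts input to
#' planar molecules, the regime the simultaneous per-atom force evaluation
#' scheme is laid out for; `max_degree = 4` admits tetrahedral centers.
#'
#' @param atoms a data.frame with columns `element` and optionally `mass`
#'   (amu; filled from a built-in table when missing). Extra columns such as
#'   `x`, `y`, `z` are carried through untouched.
#' @param bonds a two-column matrix (or coercible) of 1-based atom indices,
#'   one row per covalent bond.
#' @param max_degree maximum number of bonds allowed on any atom (default 3).
#' @param require_connected error on multi-fragment input (default TRUE).
#' @return an object of class `molecular_graph`: list with `atoms`, `bonds`
#'   (canonical i<j rows, sorted), `degree`, `adj` (adjacency list) and
#'   `max_degree`.
#' @examples
#' g <- molecular_graph(data.frame(element = c("C", "C")), rbind(c(1, 2)))
#' g$degree
#' @export
molecular_graph <- function(atoms, bonds, max_degree = 3L,
                            require_connected = TRUE) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$element))
    .stop_cond("steermd_bad_atoms", "atoms must have an 'element' column")
  atoms$element <- as.character(atoms$element)
  unknown <- setdiff(atoms$element, names(.element_masses))
  if (length(unknown) > 0)
    .stop_cond("steermd_bad_atoms",
               paste0("unsupported element(s): ", paste(unique(unknown), collapse = ", ")))
  if (is.null(atoms$mass)) atoms$mass <- unname(.element_masses[atoms$element])
  na_mass <- is.na(atoms$mass)
  atoms$mass[na_mass] <- unname(.element_masses[atoms$element[na_mass]])
  n <- nrow(atoms)

  bonds <- bond_matrix(bonds)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L | bonds > n))
      .stop_cond("steermd_index_error", "bond index out of range")
    if (any(bonds[, 1] == bonds[, 2]))
      .stop_cond("steermd_self_bond", "self-bond (i,i) is not allowed")
    bonds <- t(apply(bonds, 1, sort))
    dim(bonds) <- c(length(bonds) %/% 2L, 2L)
    key <- bonds[, 1] * (n + 1) + bonds[, 2]
    if (anyDuplicated(key))
      .stop_cond("steermd_duplicate_bond", "duplicate bond in bond list")
    bonds <- bonds[order(key), , drop = FALSE]
  }
  deg <- tabulate(bonds, nbins = n)
  if (any(deg > max_degree))
    .stop_cond("steermd_degree_error",
               sprintf("atom %d has degree %d > max_degree %d",
                       which.max(deg), max(deg), max_degree))

  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, sort)

  if (require_connected && n > 1) {
    seen <- logical(n); seen[1] <- TRUE; queue <- 1L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (!all(seen))
      .stop_cond("steermd_disconnected",
                 sprintf("molecule is not connected (%d of %d atoms reachable from atom 1)",
                         sum(seen), n))
  }

  structure(list(atoms = atoms, bonds = bonds, degree = deg, adj = adj,
                 max_degree = as.integer(max_degree)),
            class = "molecular_graph")
}

bond_matrix <- function(bonds) {
  if (is.list(bonds) && !is.data.frame(bonds))
    bonds <- do.call(rbind, lapply(bonds, as.integer))
  if (is.null(bonds) || length(bonds) == 0)
    return(matrix(integer(0), 0, 2))
  bonds <- as.matrix(bonds)
  storage.mode(bonds) <- "integer"
  if (ncol(bonds) != 2)
    .stop_cond("steermd_bad_bonds", "bonds must have two columns")
  bonds
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("molecular_graph: %d atoms (%s), %d bonds, max degree %d/%d\n",
              nrow(x$atoms),
              paste(names(sort(table(x$atoms$element), decreasing = TRUE)), collapse = ""),
              nrow(x$bonds), max(c(0L, x$degree)), x$max_degree))
  invisible(x)
}

#' Enumerate canonical angle triples
#'
#' One angle per unordered pair of bonds sharing a central atom j, reported as
#' `(i, j, k)` with `i < k`. The total count equals
#' `sum(choose(degree, 2))` over all atoms.
#'
#' @param g a [molecular_graph()].
#' @return integer matrix with columns `i`, `j`, `k` (0 rows when no angles).
#' @export
enumerate_angles <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  out <- vector("list", length(g$adj))
  for (j in seq_along(g$adj)) {
    nb <- g$adj[[j]]
    if (length(nb) >= 2) {
      pr <- utils::combn(nb, 2)      # columns already i < k (adj is sorted)
      out[[j]] <- cbind(i = pr[1, ], j = j, k = pr[2, ])
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "k")))
  res[order(res[, 2], res[, 1], res[, 3]), , drop = FALSE]
}

#' Enumerate canonical proper-dihedral quads
#'
#' One quad `(i, j, k, l)` per path of three distinct bonds
#' `(i,j), (j,k), (k,l)`, with the central bond canonically ordered `j < k`
#' and the degenerate back-path `i == l` (possible only in triangles)
#' excluded. Improper (out-of-plane) dihedrals are not generated.
#'
#' @param g a [molecular_graph()].
#' @return integer matrix with columns `i`, `j`, `k`, `l`.
#' @export
enumerate_dihedrals <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  out <- list()
  bonds <- g$bonds
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1]; k <- bonds[r, 2]   # canonical j < k
    is <- setdiff(g$adj[[j]], k)
    ls <- setdiff(g$adj[[k]], j)
    if (length(is) == 0 || length(ls) == 0) next
    grid <- expand.grid(i = is, l = ls, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[grid$i != grid$l, , drop = FALSE]
    if (nrow(grid) > 0)
      out[[length(out) + 1L]] <- cbind(i = grid$i, j = j, k = k, l = grid$l)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(integer(0), 0, 4, dimnames = list(NULL, c("i", "j", "k", "l")))
  res[order(res[, 2], res[, 3], res[, 1], res[, 4]), , drop = FALSE]
}

#' All bonded interaction tuples of a molecular graph
#'
#' @param g a [molecular_graph()].
#' @return list with elements `bonds`, `angles`, `dihedrals` (canonical
#'   integer matrices).
#' @export
bonded_tuples <- function(g) {
  list(bonds = g$bonds, angles = enumerate_angles(g),
       dihedrals = enumerate_dihedrals(g))
}

#' Per-atom participation counts in bonded tuples
#'
#' For each atom, how many bond, angle and dihedral force terms it appears in
#' (in any position). These are the per-atom work counts that a
#' fixed-width parallel force layout has to budget for.
#'
#' @param g a [molecular_graph()].
#' @return data.frame with columns `n_bond`, `n_angle`, `n_dihedral`,
#'   one row per atom.
#' @export
tuple_participation <- function(g) {
  n <- nrow(g$atoms)
  tp <- bonded_tuples(g)
  data.frame(
    n_bond = tabulate(tp$bonds, nbins = n),
    n_angle = tabulate(tp$angles, nbins = n),
    n_dihedral = tabulate(tp$dihedrals, nbins = n)
  )
}

#' Closed-form per-atom maxima of bonded force counts
#'
#' For molecules in which every atom has at most `n` bonds, the number of
#' bonded force terms any single atom can participate in is bounded by
#' `n_b = n` bond terms, `n_a = (3/2) n (n-1)` angle terms and
#' `n_t = 2 n (n-1)^2` dihedral terms. For `n = 3` (planar molecules) this
#' gives (3, 9, 24); for `n = 4`, (4, 18, 72). The bounds are sharp: they are
#' attained, e.g., by the cube graph (`n = 3`) and by K4,4 (`n = 4`), and
#' [observed_count_maxima()] reproduces them by exhaustive enumeration.
#'
#' @param n maximum number of bonds per atom (integer >= 1).
#' @return named integer vector `c(n_b, n_a, n_t)`.
#' @examples
#' max_counts_per_atom(3) # 3 9 24
#' @export
max_counts_per_atom <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n))
    .stop_cond("steermd_domain_error", "n must be a single integer >= 1")
  n <- as.integer(n)
  c(n_b = n, n_a = as.integer(3 * n * (n - 1) / 2), n_t = as.integer(2 * n * (n - 1)^2))
}
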