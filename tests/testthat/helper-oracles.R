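# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) wherever they stand in judgement
# over them.

# central-difference gradient of a scalar function of flattened coordinates
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

max_rel_dev <- function(a, b) {
  max(abs(a - b)) / max(abs(b), 1e-12)
}

# brute-force enumeration of angle triples: all unordered pairs of bonds
# sharing an atom (no reliance on adjacency-list code)
brute_angles <- function(bonds, n) {
  if (nrow(bonds) < 2) return(matrix(integer(0), 0, 3))
  out <- list()
  for (r1 in seq_len(nrow(bonds) - 1)) {
    for (r2 in (r1 + 1):nrow(bonds)) {
      shared <- intersect(bonds[r1, ], bonds[r2, ])
      if (length(shared) == 1) {
        j <- shared
        ik <- sort(c(setdiff(bonds[r1, ], j), setdiff(bonds[r2, ], j)))
        out[[length(out) + 1]] <- c(ik[1], j, ik[2])
      }
    }
  }
  unique(do.call(rbind, out))
}

# brute-force proper dihedrals: all paths of three distinct bonds, all four
# atoms distinct, deduplicated by orientation
brute_dihedrals <- function(bonds, n) {
  adj <- lapply(seq_len(n), function(i) {
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
  })
  out <- list()
  for (j in seq_len(n)) for (k in adj[[j]]) {
    if (j >= k) next
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i != l) out[[length(out) + 1]] <- c(i, j, k, l)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), 0, 4))
  unique(do.call(rbind, out))
}

# all permutations of 1..n (small n), base R only
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# labeled brute-force enumeration of connected degree-bounded graphs on
# exactly n vertices, counted up to isomorphism via explicit permutation
# canonicalization -- independent oracle for the augmentation enumerator
brute_connected_classes <- function(n, max_degree) {
  if (n == 1) return(1L)
  prs <- t(combn(n, 2))
  m <- nrow(prs)
  pm <- perms_of(n)
  keys <- character(0)
  for (mask in seq_len(2^m) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    if (length(sel) < n - 1) next
    ed <- prs[sel, , drop = FALSE]
    deg <- tabulate(ed, nbins = n)
    if (any(deg > max_degree)) next
    # connectivity
    seen <- logical(n); seen[1] <- TRUE
    repeat {
      hit <- seen[ed[, 1]] | seen[ed[, 2]]
      new <- unique(c(ed[hit, 1], ed[hit, 2]))
      if (all(seen[new])) break
      seen[new] <- TRUE
    }
    if (!all(seen)) next
    # canonical key: lexicographic minimum over all relabelings
    best <- NULL
    for (p in seq_len(nrow(pm))) {
      e2 <- matrix(pm[p, ][ed], ncol = 2)
      e2 <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
      e2 <- e2[order(e2[, 1], e2[, 2]), , drop = FALSE]
      key <- paste(e2[, 1], e2[, 2], collapse = ";")
      if (is.null(best) || key < best) best <- key
    }
    keys <- c(keys, best)
  }
  length(unique(keys))
}

# a small vacuum molecule system (no metal) for integrator tests
vacuum_molecule_system <- function() {
  mol <- bipyridylbenzene()
  mp <- as.matrix(mol$graph$atoms[, c("x", "y", "z")])
  n <- nrow(mp)
  steermd:::new_md_system(
    mp, mol$graph$atoms$mass, mol$graph$atoms$element,
    rep("molecule", n), rep(FALSE, n), rep(FALSE, n),
    matrix(NA_real_, n, 3), graph = mol$graph, overrides = mol$overrides)
}

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
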