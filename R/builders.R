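## Construction of simulation-ready systems: fcc(111) slab, pyramidal tip,
## molecule placement and the combined md_system container.

#' Build an fcc(111) metal slab
#'
#' ABC-stacked close-packed layers with in-plane nearest-neighbor distance
#' `a/sqrt(2)` and interlayer spacing `a/sqrt(3)`. Layer 1 is the bottom
#' layer; the bottom `frozen_layers` layers are flagged frozen to anchor the
#' slab.
#'
#' @param nx,ny atoms per layer along the two lattice directions.
#' @param layers number of (111) layers.
#' @param a cubic lattice constant (A); default 4.08, the standard value for
#'   gold.
#' @param frozen_layers how many bottom layers to freeze (default 1).
#' @param species element symbol (default "Au").
#' @return list with `pos` (N x 3), `species`, `role` ("substrate"),
#'   `frozen`, `top_z` and the geometry constants.
#' @examples
#' s <- build_fcc111_slab(10, 10, 3)
#' nrow(s$pos) # 300
#' @export
build_fcc111_slab <- function(nx, ny, layers, a = 4.08, frozen_layers = 1L,
                              species = "Au") {
  if (nx < 1 || ny < 1 || layers < 1 || a <= 0)
    .stop_cond("steermd_bad_params", "slab dimensions must be positive")
  ann <- a / sqrt(2)            # nearest-neighbor distance
  dz <- a / sqrt(3)             # (111) interlayer spacing
  b1 <- c(ann, 0)
  b2 <- c(ann / 2, ann * sqrt(3) / 2)
  soff <- c(ann / 2, ann / (2 * sqrt(3)))  # ABC stacking shift per layer
  ix <- rep(seq_len(nx) - 1L, times = ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  pos <- vector("list", layers)
  for (L in seq_len(layers)) {
    sh <- ((L - 1L) %% 3L) * soff
    pos[[L]] <- cbind(ix * b1[1] + iy * b2[1] + sh[1],
                      iy * b2[2] + sh[2],
                      (L - 1L) * dz)
  }
  pos <- do.call(rbind, pos)
  n <- nrow(pos)
  frozen <- rep(rep(seq_len(layers) <= frozen_layers, each = nx * ny))
  list(pos = pos, species = rep(species, n), role = rep("substrate", n),
       frozen = frozen, top_z = (layers - 1L) * dz, a = a, ann = ann, dz = dz)
}

#' Build a pyramidal tip
#'
#' A stack of square layers narrowing to a single apex atom at the bottom:
#' layer j above the apex is a (j+1) x (j+1) grid with nearest-neighbor
#' spacing `a/sqrt(2)`. The top layer is the steering handle; every tip atom
#' carries a harmonic anchor at its construction position.
#'
#' @param layers number of layers including the apex (>= 2).
#' @param a cubic lattice constant (A).
#' @param apex apex position `c(x, y, z)`.
#' @param species element symbol (default "Au").
#' @return list with `pos`, `species`, `role` ("tip"), `handle` (logical,
#'   top-layer flag), `anchor` (initial positions) and `apex_index`.
#' @examples
#' nrow(build_tip(2, apex = c(0, 0, 10))$pos) # 5
#' @export
build_tip <- function(layers, a = 4.08, apex = c(0, 0, 12), species = "Au") {
  if (layers < 2) .stop_cond("steermd_bad_params", "tip needs at least 2 layers")
  ann <- a / sqrt(2)
  dz <- a / sqrt(3)
  pos <- list(matrix(apex, 1, 3))
  for (j in seq_len(layers - 1L)) {
    w <- j + 1L
    g <- expand.grid(x = seq_len(w) - (w + 1) / 2, y = seq_len(w) - (w + 1) / 2)
    pos[[j + 1L]] <- cbind(apex[1] + g$x * ann, apex[2] + g$y * ann,
                           apex[3] + j * dz)
  }
  sizes <- vapply(pos, nrow, integer(1))
  pos <- do.call(rbind, pos)
  n <- nrow(pos)
  handle <- rep(FALSE, n)
  handle[(n - sizes[length(sizes)] + 1L):n] <- TRUE
  list(pos = pos, species = rep(species, n), role = rep("tip", n),
       handle = handle, anchor = pos, apex_index = 1L)
}

#' Bundled planar molecule: 1,4-bis(4-pyridyl)benzene
#'
#' The test molecule of the manipulation setup: a central benzene ring with
#' two 4-pyridyl rings attached para, giving an N anchoring atom at each end
#' (C16 H12 N2, 30 atoms). The geometry is idealized-planar: every aromatic
#' ring is a regular hexagon with 1.39 A edges, C-H bonds are 1.08 A and the
#' inter-ring single bonds are 1.48 A (encoded as per-bond rest-length
#' overrides), which makes the construction an exact mechanical equilibrium
#' of the default bonded force field.
#'
#' @return list with `graph` (a [molecular_graph()] whose `atoms` carry
#'   `x`, `y`, `z` columns) and `overrides` (per-bond parameters).
#' @export
bipyridylbenzene <- function() {
  rring <- 1.39; rch <- 1.08; rlink <- 1.48
  hexa <- function(cx) {
    ang <- (0:5) * pi / 3
    cbind(cx + rring * cos(ang), rring * sin(ang), 0)
  }
  atoms <- list(); bonds <- list(); el <- character(0)
  add_atoms <- function(p, e) {
    atoms[[length(atoms) + 1L]] <<- p
    el <<- c(el, e)
  }
  ring_bonds <- function(off) cbind(off + 1:6, off + c(2:6, 1))

  ## central benzene: vertices at angles 0..300; para positions 1 (0 deg)
  ## and 4 (180 deg) carry the inter-ring bonds, the rest carry H
  c0 <- hexa(0)
  add_atoms(c0, rep("C", 6))
  bonds[[1]] <- ring_bonds(0L)
  h_on <- c(2, 3, 5, 6)
  ## H sites: ring vertices scaled radially outward from the ring center
  add_atoms(c0[h_on, ] * ((rring + rch) / rring), rep("H", 4))
  bonds[[2]] <- cbind(h_on, 6L + 1:4)

  cx_r <- 2 * rring + rlink
  pyridyl <- function(cx, attach_angle_idx, n_idx, off) {
    ## ring vertex order: angles 0, 60, ..., 300 around center cx
    p <- hexa(cx)
    elr <- rep("C", 6); elr[n_idx] <- "N"
    add_atoms(p, elr)
    bonds[[length(bonds) + 1L]] <<- ring_bonds(off)
    hs <- setdiff(1:6, c(attach_angle_idx, n_idx))
    hp <- p[hs, , drop = FALSE]
    dirs <- hp - cbind(cx, 0, 0)[rep(1, length(hs)), , drop = FALSE]
    add_atoms(hp + dirs * (rch / rring), rep("H", length(hs)))
    bonds[[length(bonds) + 1L]] <<- cbind(off + hs, off + 6L + seq_along(hs))
  }
  pyridyl(cx_r, attach_angle_idx = 4L, n_idx = 1L, off = 10L)   # right ring: attach at 180 deg, N at 0 deg
  pyridyl(-cx_r, attach_angle_idx = 1L, n_idx = 4L, off = 20L)  # left ring: attach at 0 deg, N at 180 deg
  ## inter-ring bonds: central vertex 1 (at +1.39) to right attach (10+4);
  ## central vertex 4 (at -1.39) to left attach (20+1)
  link <- rbind(c(1L, 14L), c(4L, 21L))
  bonds[[length(bonds) + 1L]] <- link

  pos <- do.call(rbind, atoms)
  df <- data.frame(element = el, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  g <- molecular_graph(df, do.call(rbind, bonds), max_degree = 3L)
  list(graph = g,
       overrides = data.frame(i = link[, 1], j = link[, 2], r0 = rlink))
}

## ---- combined system container --------------------------------------------

new_md_system <- function(pos, mass, species, role, handle, frozen, anchor,
                          graph = NULL, mol_offset = 0L, overrides = NULL,
                          ff = default_forcefield()) {
  n <- nrow(pos)
  dimnames(pos) <- NULL; dimnames(anchor) <- NULL
  stopifnot(length(mass) == n, length(species) == n, length(role) == n,
            length(handle) == n, length(frozen) == n, nrow(anchor) == n)
  bonded <- NULL
  mol_idx <- integer(0)
  if (!is.null(graph)) {
    bonded <- resolve_bonded_params(graph, ff, overrides)
    for (nm in c("bonds", "angles", "dihedrals"))
      bonded$tuples[[nm]] <- bonded$tuples[[nm]] + mol_offset
    mol_idx <- mol_offset + seq_len(nrow(graph$atoms))
  }
  structure(list(pos = pos, vel = matrix(0, n, 3), force = NULL,
                 mass = mass, species = species, role = role,
                 handle = handle, frozen = frozen, anchor = anchor,
                 graph = graph, mol_idx = mol_idx, bonded = bonded,
                 ff = ff, step = 0L, time = 0),
            class = "md_system")
}

#' @export
print.md_system <- function(x, ...) {
  cat(sprintf("md_system: %d atoms (%d substrate, %d tip, %d molecule), %d frozen, t = %.1f fs\n",
              nrow(x$pos), sum(x$role == "substrate"), sum(x$role == "tip"),
              sum(x$role == "molecule"), sum(x$frozen), tu_to_fs(x$time)))
  invisible(x)
}

#' Place a molecule (and optionally a tip) over a slab
#'
#' Assembles the combined simulation system: slab atoms, tip atoms and the
#' molecule lying flat (its plane parallel to the surface) at the adsorption
#' height. The pose must be collision-free: any molecule-to-metal distance
#' below 1.5 A is an error naming the offending pair.
#'
#' @param slab output of [build_fcc111_slab()].
#' @param molecule output of [bipyridylbenzene()] or an equivalent list with
#'   `graph` (+ coordinate columns) and optional `overrides`; `NULL` for a
#'   metal-only system.
#' @param tip output of [build_tip()], or `NULL`.
#' @param height adsorption height of the molecule plane above the top slab
#'   layer (A, default 3.0).
#' @param center `c(x, y)` position of the molecule's coordinate origin on
#'   the surface; defaults to the slab center.
#' @param ff force field (default [default_forcefield()]).
#' @return an `md_system`.
#' @export
place_molecule <- function(slab, molecule = NULL, tip = NULL, height = 3.0,
                           center = NULL, ff = default_forcefield()) {
  pos <- slab$pos; species <- slab$species; role <- slab$role
  frozen <- slab$frozen
  handle <- rep(FALSE, nrow(pos))
  anchor <- matrix(NA_real_, nrow(pos), 3)
  if (!is.null(tip)) {
    pos <- rbind(pos, tip$pos)
    species <- c(species, tip$species); role <- c(role, tip$role)
    frozen <- c(frozen, rep(FALSE, nrow(tip$pos)))
    handle <- c(handle, tip$handle)
    anchor <- rbind(anchor, tip$anchor)
  }
  graph <- NULL; mol_offset <- nrow(pos); overrides <- NULL
  if (!is.null(molecule)) {
    graph <- molecule$graph; overrides <- molecule$overrides
    mp <- as.matrix(graph$atoms[, c("x", "y", "z")])
    if (is.null(center))
      center <- c(mean(range(slab$pos[, 1])), mean(range(slab$pos[, 2])))
    mp[, 1] <- mp[, 1] + center[1]
    mp[, 2] <- mp[, 2] + center[2]
    mp[, 3] <- mp[, 3] - mean(mp[, 3]) + slab$top_z + height
    nm <- nrow(mp)
    if (nrow(pos) > 0) {
      for (k in seq_len(nm)) {
        d2 <- rowSums((pos - matrix(mp[k, ], nrow(pos), 3, byrow = TRUE))^2)
        if (any(d2 < 1.5^2)) {
          .stop_cond("steermd_collision",
                     sprintf("molecule atom %d within 1.5 A of system atom %d",
                             k, which.min(d2)))
        }
      }
    }
    graph$atoms$x <- mp[, 1]; graph$atoms$y <- mp[, 2]; graph$atoms$z <- mp[, 3]
    pos <- rbind(pos, mp)
    species <- c(species, graph$atoms$element)
    role <- c(role, rep("molecule", nm))
    frozen <- c(frozen, rep(FALSE, nm))
    handle <- c(handle, rep(FALSE, nm))
    anchor <- rbind(anchor, matrix(NA_real_, nm, 3))
  }
  new_md_system(pos, mass = unname(.element_masses[species]),
                species = species, role = role, handle = handle,
                frozen = frozen, anchor = anchor, graph = graph,
                mol_offset = mol_offset, overrides = overrides, ff = ff)
}

#' Anchoring-species atom indices of the molecule
#'
#' @param sys an `md_system`.
#' @return indices of molecule atoms whose metal interaction is the Morse
#'   anchoring potential (N, S by default).
#' @export
anchoring_atoms <- function(sys) {
  kinds <- vapply(sys$ff$pair, function(p) p$kind, character(1))
  anch <- names(kinds)[kinds == "morse"]
  sys$mol_idx[sys$species[sys$mol_idx] %in% anch]
}

#' Interface metal atoms
#'
#' The metal atoms dynamically coupled to the molecule: all tip or substrate
#' atoms within `interface_factor * cutoff` of any anchoring molecule atom.
#' Re-evaluated at every cell-grid refresh during a run.
#'
#' @param sys an `md_system`.
#' @return integer vector of metal atom indices (possibly empty).
#' @export
interface_atoms <- function(sys) {
  anch <- anchoring_atoms(sys)
  metal <- which(sys$role %in% c("substrate", "tip"))
  if (length(anch) == 0 || length(metal) == 0) return(integer(0))
  rcut <- sys$ff$interface_factor * sys$ff$cutoff
  keep <- rep(FALSE, length(metal))
  for (a in anch) {
    d2 <- rowSums((sys$pos[metal, , drop = FALSE] -
                     matrix(sys$pos[a, ], length(metal), 3, byrow = TRUE))^2)
    keep <- keep | d2 <= rcut^2
  }
  metal[keep]
}

#' Partition the system into the MTS subsystems
#'
#' @param sys an `md_system`.
#' @return list with `gold` (all metal atoms), `extended` (molecule plus
#'   interface metal atoms), `interface` (their intersection) and `frozen`
#'   indices.
#' @export
subsystem_split <- function(sys) {
  gold <- which(sys$role %in% c("substrate", "tip"))
  interface <- interface_atoms(sys)
  split <- list(gold = gold,
                extended = sort(c(sys$mol_idx, interface)),
                interface = interface,
                frozen = which(sys$frozen))
  uncovered <- setdiff(seq_len(nrow(sys$pos)), union(split$gold, split$extended))
  if (length(uncovered) > 0)
    .stop_cond("steermd_split_error",
               paste("atoms in neither subsystem:", paste(uncovered, collapse = ",")))
  split
}
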