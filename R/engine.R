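## Full-system force assembly and the subsystem force engines used by the
## multi-time-step integrator.
##
## Interaction roster:
##   substrate-substrate : second-moment metal potential (within cutoff)
##   tip atoms           : harmonic anchor restraints (no metal-metal term)
##   molecule internal   : harmonic bonds/angles + periodic dihedrals
##   molecule-metal      : Morse (anchoring species) or LJ, scaled by the
##                         tip/substrate affinity table, shifted-force cutoff

## classify candidate pairs by interaction type; returns index matrices
classify_pairs <- function(sys, pairs) {
  r1 <- sys$role[pairs[, 1]]; r2 <- sys$role[pairs[, 2]]
  mm <- r1 == "substrate" & r2 == "substrate"
  mol1 <- r1 == "molecule" & (r2 %in% c("substrate", "tip"))
  mol2 <- r2 == "molecule" & (r1 %in% c("substrate", "tip"))
  xm <- rbind(pairs[mol1, c(1, 2), drop = FALSE],
              pairs[mol2, c(2, 1), drop = FALSE])   # col 1 = molecule atom
  if (nrow(xm) > 1) xm <- xm[order(xm[, 1], xm[, 2]), , drop = FALSE]
  list(mm = pairs[mm, , drop = FALSE], xm = xm)
}

#' Build the pair lists for force assembly
#'
#' Either from a cell grid (`engine = "cell"`, the production path) or from
#' the brute-force all-pairs oracle (`engine = "brute"`). Both return pairs
#' in the same canonical order, so assembled forces agree to numerical
#' identity when no cell overflows.
#'
#' @param sys an `md_system`.
#' @param engine `"cell"` or `"brute"`.
#' @param grid optional pre-built [cell_grid()] (rebuilt when `NULL`).
#' @return list with `mm` (substrate-substrate) and `xm` (molecule-metal,
#'   molecule atom in column 1) candidate pair matrices, plus `grid`.
#' @export
build_pairs <- function(sys, engine = c("cell", "brute"), grid = NULL) {
  engine <- match.arg(engine)
  if (engine == "cell") {
    if (is.null(grid))
      grid <- cell_grid(sys$pos, sys$ff$cutoff,
                        class = sys$role == "molecule")
    cand <- candidate_pairs(grid)
  } else {
    cand <- brute_pairs_within(sys$pos, Inf)
  }
  cl <- classify_pairs(sys, cand)
  c(cl, list(grid = grid))
}

## molecule-metal cross forces; reaction on the metal side reported
## separately so the MTS engines can route it per subsystem
cross_forces <- function(pos, sys, xm) {
  n <- nrow(pos)
  Fm <- matrix(0, n, 3); Fg <- matrix(0, n, 3)
  if (nrow(xm) == 0) return(list(energy = 0, F_mol = Fm, F_metal = Fg, n_pairs = 0L))
  rc <- sys$ff$cutoff
  d <- pos[xm[, 1], , drop = FALSE] - pos[xm[, 2], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  keep <- r <= rc
  xm <- xm[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]; r <- r[keep]
  if (nrow(xm) == 0) return(list(energy = 0, F_mol = Fm, F_metal = Fg, n_pairs = 0L))
  sp <- sys$species[xm[, 1]]
  rl <- ifelse(sys$role[xm[, 2]] == "tip", "tip", "substrate")
  grp <- paste(sp, rl)
  E <- 0
  for (gname in unique(grp)) {   # first-occurrence order: deterministic
    sel <- grp == gname
    p <- resolve_pair_potential(sp[sel][1], rl[sel][1], sys$ff)
    ev <- if (p$kind == "morse")
      morse_energy_force(r[sel], p$D, p$a, p$re, rc, shift = "force")
    else
      lj_energy_force(r[sel], p$eps, p$sigma, rc, shift = "force")
    E <- E + sum(ev$energy)
    Fpair <- d[sel, , drop = FALSE] * (ev$force / r[sel])
    Fm <- acc_force(Fm, xm[sel, 1], Fpair)
    Fg <- acc_force(Fg, xm[sel, 2], -Fpair)
  }
  list(energy = E, F_mol = Fm, F_metal = Fg, n_pairs = nrow(xm))
}

#' Assemble total forces and potential energy
#'
#' Evaluates every interaction term of the combined system and returns the
#' per-atom total force, the total potential energy and the individual
#' components (so callers can compose subsystem engines from one
#' evaluation). Deterministic for a fixed input ordering; every pair term
#' obeys Newton's third law by construction.
#'
#' @param sys an `md_system`.
#' @param engine `"cell"` (cell-list candidates) or `"brute"` (all-pairs
#'   oracle).
#' @param pairs optional pre-built pair lists from [build_pairs()].
#' @param pos optional position matrix overriding `sys$pos` (same atom
#'   ordering), used by the integrator's trial evaluations.
#' @return list with `energy` (total potential, eV), `forces` (N x 3,
#'   eV/A), `parts` (named list of component force matrices) and
#'   `energies` (per-component).
#' @export
assemble_forces <- function(sys, engine = c("cell", "brute"), pairs = NULL,
                            pos = NULL,
                            terms = c("metal", "restraint", "bonded", "cross")) {
  engine <- match.arg(engine)
  if (is.null(pairs)) pairs <- build_pairs(sys, engine)
  if (is.null(pos)) pos <- sys$pos
  ff <- sys$ff
  zero <- function() matrix(0, nrow(pos), 3)

  met <- if ("metal" %in% terms)
    gupta_energy_forces(pos, pairs$mm, ff$metal, ff$cutoff)
  else list(energy = 0, forces = zero())
  tip_idx <- which(sys$role == "tip")
  res <- if ("restraint" %in% terms)
    tip_restraint_forces(pos, sys$anchor, ff$tip$k, tip_idx)
  else list(energy = 0, forces = zero())
  if (!is.null(sys$bonded) && "bonded" %in% terms) {
    bp <- sys$bonded
    bb <- harmonic_bond_forces(pos, bp$tuples$bonds, bp$bond$k, bp$bond$r0)
    aa <- harmonic_angle_forces(pos, bp$tuples$angles, bp$angle$k, bp$angle$theta0)
    dd <- dihedral_forces(pos, bp$tuples$dihedrals, bp$dihedral$k,
                          bp$dihedral$m, bp$dihedral$phi0)
    Fb <- bb$forces + aa$forces + dd$forces
    Eb <- bb$energy + aa$energy + dd$energy
  } else {
    Fb <- zero(); Eb <- 0
  }
  cr <- if ("cross" %in% terms) cross_forces(pos, sys, pairs$xm)
  else list(energy = 0, F_mol = zero(), F_metal = zero(), n_pairs = 0L)

  energies <- c(metal = met$energy, restraint = res$energy, bonded = Eb,
                cross = cr$energy)
  list(energy = sum(energies),
       forces = met$forces + res$forces + Fb + cr$F_mol + cr$F_metal,
       parts = list(metal = met$forces, restraint = res$forces, bonded = Fb,
                    cross_mol = cr$F_mol, cross_metal = cr$F_metal),
       energies = energies)
}

#' Subsystem force engines for the multi-time-step cycle
#'
#' Builds closures evaluating, for given positions:
#' \describe{
#'   \item{`full`}{all force terms (the single-timescale reference).}
#'   \item{`gold`}{the gold-only subsystem: metal-metal term, tip
#'     restraints, and the static-molecule field acting on non-interface
#'     metal atoms. Interface atoms' molecule interaction is deliberately
#'     excluded here -- they receive it in the extended subsystem, so each
#'     force term is integrated exactly once.}
#'   \item{`extended`}{the extended-molecule subsystem: intramolecular
#'     terms, molecule-metal forces on the molecule, and the molecule-side
#'     reaction on interface metal atoms only.}
#' }
#' By construction `gold(pos) + extended(pos) == full(pos)` for every
#' configuration.
#'
#' @param sys an `md_system`.
#' @param pairs pair lists from [build_pairs()].
#' @param split subsystem partition from [subsystem_split()].
#' @return list of three functions `pos -> list(energy, forces)`.
#' @export
make_engines <- function(sys, pairs, split) {
  iface <- split$interface
  n <- nrow(sys$pos)
  iface_mask <- rep(FALSE, n); iface_mask[iface] <- TRUE
  list(
    full = function(pos) {
      a <- assemble_forces(sys, pairs = pairs, pos = pos)
      list(energy = a$energy, forces = a$forces)
    },
    gold = function(pos) {
      a <- assemble_forces(sys, pairs = pairs, pos = pos,
                           terms = c("metal", "restraint", "cross"))
      Fcm <- a$parts$cross_metal
      Fcm[iface_mask, ] <- 0
      list(energy = unname(a$energies["metal"] + a$energies["restraint"]),
           forces = a$parts$metal + a$parts$restraint + Fcm)
    },
    extended = function(pos) {
      a <- assemble_forces(sys, pairs = pairs, pos = pos,
                           terms = c("bonded", "cross"))
      Fcm <- a$parts$cross_metal
      Fcm[!iface_mask, ] <- 0
      list(energy = unname(a$energies["bonded"] + a$energies["cross"]),
           forces = a$parts$bonded + a$parts$cross_mol + Fcm)
    }
  )
}
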