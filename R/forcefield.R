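## Potential-energy terms and their analytic forces.
##
## Unit system: angstrom / amu / eV throughout; radial "force" always means
## -dV/dr, so a positive value pushes a pair apart.

#' Default force-field parameter set
#'
#' All potential parameters used by the engine, keyed by species, species
#' pair or tuple pattern. The functional forms are the standard families for
#' this kind of metal--organic junction model: harmonic bonds and angles, a
#' periodic cosine dihedral, 12-6 Lennard-Jones for non-anchoring
#' molecule-metal pairs, a Morse potential for anchoring species (N, S), a
#' second-moment (Gupta-style) many-body potential for the metallic substrate
#' (Cleri-Rosato gold constants) and harmonic position restraints for tip
#' atoms. Every numeric value is a representative, overridable package
#' default (`provenance = "package"`), not a fitted constant; the few
#' structural settings fixed by the method itself (cell capacity 32, refresh
#' interval 20, degree cap 3) are marked `provenance = "method"`.
#'
#' The `affinity` table assigns, per molecule species and metal role
#' (tip or substrate), the applicable pair potential and a scale factor on
#' its well depth; by default the anchoring N atom binds the tip 3x more
#' strongly than the substrate, emulating the enhanced reactivity of the
#' low-coordinated apex.
#'
#' @return nested list of class `steermd_forcefield`.
#' @export
default_forcefield <- function() {
  ff <- list(
    cutoff = 6.0,              # A; pair cutoff == cell edge of the neighbor grid
    bonded = list(
      bond = list(
        `C-C` = list(k = 32, r0 = 1.39),   # aromatic ring CC
        `C-N` = list(k = 35, r0 = 1.39),   # aromatic ring CN (idealized hexagon)
        `C-H` = list(k = 29, r0 = 1.08),
        default = list(k = 30, r0 = 1.50)
      ),
      angle = list(default = list(k = 6.0, theta0 = 2 * pi / 3)),
      dihedral = list(default = list(k = 0.25, m = 2L, phi0 = pi))
    ),
    pair = list(                # molecule species -> any metal atom
      N = list(kind = "morse", D = 0.35, a = 1.70, re = 2.35),
      S = list(kind = "morse", D = 0.50, a = 1.50, re = 2.45),
      C = list(kind = "lj", eps = 0.035, sigma = 3.2),
      H = list(kind = "lj", eps = 0.020, sigma = 2.9),
      O = list(kind = "lj", eps = 0.030, sigma = 3.0)
    ),
    affinity = data.frame(       # scale multiplies the well depth (D or eps)
      species = rep(c("N", "S", "C", "H", "O"), each = 2),
      role = rep(c("tip", "substrate"), times = 5),
      scale = c(3, 1, 3, 1, 1, 1, 1, 1, 1, 1),
      stringsAsFactors = FALSE
    ),
    metal = list(                # Cleri-Rosato second-moment parameters for Au
      A = 0.2061, xi = 1.7900, p = 10.229, q = 4.036, r0 = 2.884,
      switch_width = 0.5         # A; C1 cosine switch-off window below cutoff
    ),
    tip = list(k = 5.0),         # eV/A^2 harmonic anchor stiffness, tip atoms
    interface_factor = 1.2,      # interface = metal within factor*cutoff of an anchor atom
    provenance = c(
      cell_cap = "method", refresh_interval = "method", max_degree = "method",
      cutoff = "package", bonded = "package", pair = "package",
      affinity = "package", metal = "package", tip = "package",
      interface_factor = "package"
    )
  )
  class(ff) <- "steermd_forcefield"
  validate_forcefield(ff)
  ff
}

#' Validate a force-field parameter set
#'
#' Checks positivity and range constraints on every parameter block.
#'
#' @param ff a force-field list as returned by [default_forcefield()].
#' @return `ff`, invisibly; errors on the first violated constraint.
#' @export
validate_forcefield <- function(ff) {
  chk <- function(ok, what)
    if (!isTRUE(ok)) .stop_cond("steermd_bad_params", paste("invalid force field:", what))
  chk(is.numeric(ff$cutoff) && ff$cutoff > 0, "cutoff must be > 0")
  for (nm in names(ff$bonded$bond)) {
    b <- ff$bonded$bond[[nm]]
    chk(b$k >= 0 && b$r0 > 0, paste("bond", nm))
  }
  for (nm in names(ff$bonded$angle)) {
    a <- ff$bonded$angle[[nm]]
    chk(a$k >= 0 && a$theta0 > 0 && a$theta0 <= pi, paste("angle", nm))
  }
  for (nm in names(ff$bonded$dihedral)) {
    d <- ff$bonded$dihedral[[nm]]
    chk(d$k >= 0 && d$m >= 1, paste("dihedral", nm))
  }
  for (nm in names(ff$pair)) {
    p <- ff$pair[[nm]]
    if (p$kind == "lj") chk(p$eps > 0 && p$sigma > 0, paste("pair", nm))
    else if (p$kind == "morse") chk(p$D > 0 && p$a > 0 && p$re > 0, paste("pair", nm))
    else chk(FALSE, paste("pair kind", p$kind))
  }
  m <- ff$metal
  chk(all(c(m$A, m$xi, m$p, m$q, m$r0) > 0), "metal parameters must be > 0")
  chk(m$switch_width > 0 && m$switch_width < ff$cutoff, "metal switch width")
  chk(ff$tip$k > 0, "tip restraint stiffness")
  af <- ff$affinity
  chk(all(table(paste(af$species, af$role)) == 1),
      "affinity table must resolve every (species, role) exactly once")
  chk(all(af$scale > 0), "affinity scales must be > 0")
  invisible(ff)
}

## ---- pair potentials -------------------------------------------------------

#' Lennard-Jones 12-6 energy and radial force
#'
#' `V(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6)`, truncated at `rc`. With
#' `shift = "force"` (the assembly default) both the energy and the radial
#' force `-dV/dr` go continuously to zero at the cutoff
#' (`V - V(rc) - (r - rc) V'(rc)`); `"energy"` subtracts `V(rc)` only;
#' `"none"` is the bare truncated potential.
#'
#' @param r distances (A), all > 0.
#' @param eps well depth (eV).
#' @param sigma zero-crossing distance (A).
#' @param rc cutoff radius (A).
#' @param shift one of "force", "energy", "none".
#' @return list with numeric vectors `energy` (eV) and `force`
#'   (eV/A, `-dV/dr`), zero beyond `rc`.
#' @export
lj_energy_force <- function(r, eps, sigma, rc, shift = c("force", "energy", "none")) {
  shift <- match.arg(shift)
  if (any(r <= 0)) .stop_cond("steermd_singularity", "LJ evaluated at r <= 0")
  lj_raw <- function(r) {
    s6 <- (sigma / r)^6
    list(V = 4 * eps * (s6^2 - s6), dV = 4 * eps * (-12 * s6^2 + 6 * s6) / r)
  }
  inside <- r < rc
  V <- F <- numeric(length(r))
  if (any(inside)) {
    raw <- lj_raw(r[inside])
    Vc <- lj_raw(rc)
    V[inside] <- switch(shift,
      none = raw$V,
      energy = raw$V - Vc$V,
      force = raw$V - Vc$V - (r[inside] - rc) * Vc$dV)
    F[inside] <- switch(shift,
      none = -raw$dV,
      energy = -raw$dV,
      force = -(raw$dV - Vc$dV))
  }
  list(energy = V, force = F)
}

#' Morse energy and radial force
#'
#' `V(r) = D ((1 - exp(-a (r - re)))^2 - 1)`: the well minimum is `-D` at
#' `r = re` and the dissociated limit is zero. Used for the anchoring bonds
#' between metal atoms and anchoring molecule species. Truncation and
#' shifting as in [lj_energy_force()].
#'
#' @param r distances (A), > 0.
#' @param D well depth (eV).
#' @param a stiffness (1/A).
#' @param re equilibrium distance (A).
#' @inheritParams lj_energy_force
#' @return list with `energy` and `force` vectors.
#' @export
morse_energy_force <- function(r, D, a, re, rc, shift = c("force", "energy", "none")) {
  shift <- match.arg(shift)
  if (any(r <= 0)) .stop_cond("steermd_singularity", "Morse evaluated at r <= 0")
  mo_raw <- function(r) {
    e <- exp(-a * (r - re))
    list(V = D * ((1 - e)^2 - 1), dV = 2 * D * a * (1 - e) * e)
  }
  inside <- r < rc
  V <- F <- numeric(length(r))
  if (any(inside)) {
    raw <- mo_raw(r[inside])
    Vc <- mo_raw(rc)
    V[inside] <- switch(shift,
      none = raw$V,
      energy = raw$V - Vc$V,
      force = raw$V - Vc$V - (r[inside] - rc) * Vc$dV)
    F[inside] <- switch(shift,
      none = -raw$dV,
      energy = -raw$dV,
      force = -(raw$dV - Vc$dV))
  }
  list(energy = V, force = F)
}

## deterministic per-atom accumulation of per-tuple force contributions
acc_force <- function(F, idx, contrib) {
  if (length(idx) == 0) return(F)
  s <- rowsum(contrib, idx, reorder = FALSE)
  ii <- as.integer(rownames(s))
  F[ii, ] <- F[ii, , drop = FALSE] + s
  F
}

## ---- bonded terms ----------------------------------------------------------

#' Harmonic bond energies and forces
#'
#' `V = 1/2 k (r - r0)^2` per bond; forces are equal and opposite along the
#' bond axis.
#'
#' @param pos N x 3 position matrix (A).
#' @param bonds two-column index matrix.
#' @param k,r0 per-bond stiffness (eV/A^2) and rest length (A), recycled.
#' @return list with `energy` (scalar, eV) and `forces` (N x 3, eV/A).
#' @export
harmonic_bond_forces <- function(pos, bonds, k, r0) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  if (nrow(bonds) == 0) return(list(energy = 0, forces = F))
  k <- rep_len(k, nrow(bonds)); r0 <- rep_len(r0, nrow(bonds))
  d <- pos[bonds[, 1], , drop = FALSE] - pos[bonds[, 2], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  if (any(r < 1e-10))
    .stop_cond("steermd_degenerate", "coincident positions in bonded pair")
  fmag <- -k * (r - r0) / r              # scalar multiplier on d = xi - xj
  Fi <- d * fmag
  F <- acc_force(F, bonds[, 1], Fi)
  F <- acc_force(F, bonds[, 2], -Fi)
  list(energy = sum(0.5 * k * (r - r0)^2), forces = F)
}

#' Harmonic angle energies and forces
#'
#' `V = 1/2 k (theta - theta0)^2` for the angle at the central atom `j` of
#' each `(i, j, k)` triple. Analytic gradient; collinear geometries are
#' evaluated with an epsilon-regularized `sin(theta)` (1e-12) and counted in
#' the `degenerate_geometry` diagnostic counter rather than returning NaN.
#'
#' @param pos N x 3 position matrix.
#' @param angles three-column index matrix `(i, j, k)`, `j` central.
#' @param k,theta0 per-angle stiffness (eV/rad^2) and rest angle (rad).
#' @return list with `energy` and `forces`.
#' @export
harmonic_angle_forces <- function(pos, angles, k, theta0) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  if (nrow(angles) == 0) return(list(energy = 0, forces = F))
  k <- rep_len(k, nrow(angles)); theta0 <- rep_len(theta0, nrow(angles))
  u <- pos[angles[, 1], , drop = FALSE] - pos[angles[, 2], , drop = FALSE]
  w <- pos[angles[, 3], , drop = FALSE] - pos[angles[, 2], , drop = FALSE]
  ru <- sqrt(rowSums(u * u)); rw <- sqrt(rowSums(w * w))
  if (any(ru < 1e-10) || any(rw < 1e-10))
    .stop_cond("steermd_degenerate", "zero-length angle arm")
  cth <- pmin(1, pmax(-1, rowSums(u * w) / (ru * rw)))
  th <- acos(cth)
  sth <- sqrt(pmax(0, 1 - cth^2))
  ndeg <- sum(sth < 1e-8)
  if (ndeg > 0) bump_counter("degenerate_geometry", ndeg)
  sth <- pmax(sth, 1e-12)
  coef <- k * (th - theta0) / sth        # = dV/dtheta / sin(theta)
  Fi <- coef * (w / (ru * rw) - cth * u / ru^2)
  Fk <- coef * (u / (ru * rw) - cth * w / rw^2)
  F <- acc_force(F, angles[, 1], Fi)
  F <- acc_force(F, angles[, 3], Fk)
  F <- acc_force(F, angles[, 2], -(Fi + Fk))
  list(energy = sum(0.5 * k * (th - theta0)^2), forces = F)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Periodic dihedral energies and forces
#'
#' `V = k (1 + cos(m phi - phi0))` for each proper dihedral `(i, j, k, l)`
#' around the central bond `(j, k)`. Analytic chain-rule gradient; near
#' collinear `i-j-k` or `j-k-l` arms the squared normal vectors are
#' regularized at 1e-12 and the degenerate-geometry counter is bumped.
#'
#' @param pos N x 3 position matrix.
#' @param dihedrals four-column index matrix.
#' @param k,m,phi0 per-tuple barrier (eV), integer multiplicity and phase
#'   (rad).
#' @return list with `energy` and `forces`.
#' @export
dihedral_forces <- function(pos, dihedrals, k, m, phi0) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  if (nrow(dihedrals) == 0) return(list(energy = 0, forces = F))
  nd <- nrow(dihedrals)
  k <- rep_len(k, nd); m <- rep_len(m, nd); phi0 <- rep_len(phi0, nd)
  xi <- pos[dihedrals[, 1], , drop = FALSE]; xj <- pos[dihedrals[, 2], , drop = FALSE]
  xk <- pos[dihedrals[, 3], , drop = FALSE]; xl <- pos[dihedrals[, 4], , drop = FALSE]
  b1 <- xj - xi; b2 <- xk - xj; b3 <- xl - xk
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  rb2 <- sqrt(rowSums(b2 * b2))
  n1sq <- rowSums(n1 * n1); n2sq <- rowSums(n2 * n2)
  ndeg <- sum(n1sq < 1e-16 | n2sq < 1e-16)
  if (ndeg > 0) bump_counter("degenerate_geometry", ndeg)
  n1sq <- pmax(n1sq, 1e-12); n2sq <- pmax(n2sq, 1e-12)
  phi <- atan2(rowSums(cross3(n1, n2) * b2) / rb2, rowSums(n1 * n2))
  dV <- -k * m * sin(m * phi - phi0)      # dV/dphi
  dphi_i <- -(rb2 / n1sq) * n1
  dphi_l <- (rb2 / n2sq) * n2
  c12 <- rowSums(b1 * b2) / rb2^2
  c32 <- rowSums(b3 * b2) / rb2^2
  dphi_j <- -(1 + c12) * dphi_i + c32 * dphi_l
  dphi_k <- c12 * dphi_i - (1 + c32) * dphi_l
  F <- acc_force(F, dihedrals[, 1], -dV * dphi_i)
  F <- acc_force(F, dihedrals[, 2], -dV * dphi_j)
  F <- acc_force(F, dihedrals[, 3], -dV * dphi_k)
  F <- acc_force(F, dihedrals[, 4], -dV * dphi_l)
  list(energy = sum(k * (1 + cos(m * phi - phi0))), forces = F)
}

## ---- metal many-body term --------------------------------------------------

## C1 cosine switching function on [rc - w, rc]
switch_fn <- function(r, rc, w) {
  rs <- rc - w
  t <- pmin(pmax((r - rs) / w, 0), 1)
  S <- 0.5 * (1 + cos(pi * t))
  dS <- -0.5 * pi / w * sin(pi * t)
  dS[t == 0 | t == 1] <- 0
  list(S = S, dS = dS)
}

#' Second-moment (Gupta-style) metal energy and forces
#'
#' Per-atom energy
#' `E_i = A sum_j exp(-p (r/r0 - 1)) - xi sqrt(sum_j exp(-2 q (r/r0 - 1)))`
#' over neighbors within the cutoff, with every pair contribution multiplied
#' by a C1 cosine switching function so energy and forces vanish continuously
#' at `rc`. Forces are the exact analytic gradient of the total energy,
#' including the cross terms through the many-body density. An isolated atom
#' (empty neighbor sum) has zero energy and force.
#'
#' @param pos N x 3 positions of the metal atoms.
#' @param pairs two-column candidate pair matrix (indices into `pos`);
#'   distance filtering to `rc` happens internally.
#' @param prm metal parameter list (`A`, `xi`, `p`, `q`, `r0`,
#'   `switch_width`).
#' @param rc cutoff radius (A).
#' @return list with `energy` (scalar), `forces` (N x 3) and `energies`
#'   (per-atom site energies).
#' @export
gupta_energy_forces <- function(pos, pairs, prm, rc) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(energy = 0, forces = F, energies = numeric(n)))
  d <- pos[pairs[, 1], , drop = FALSE] - pos[pairs[, 2], , drop = FALSE]
  r <- sqrt(rowSums(d * d))
  keep <- r < rc
  pairs <- pairs[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]; r <- r[keep]
  if (nrow(pairs) == 0) return(list(energy = 0, forces = F, energies = numeric(n)))
  u <- r / prm$r0 - 1
  ep <- exp(-prm$p * u); eq <- exp(-2 * prm$q * u)
  sw <- switch_fn(r, rc, prm$switch_width)
  psi <- ep * sw$S
  phi <- eq * sw$S
  dpsi <- (-prm$p / prm$r0) * ep * sw$S + ep * sw$dS
  dphi <- (-2 * prm$q / prm$r0) * eq * sw$S + eq * sw$dS

  both <- c(pairs[, 1], pairs[, 2])
  s <- rowsum(cbind(c(psi, psi), c(phi, phi)), both, reorder = FALSE)
  idx <- as.integer(rownames(s))
  rep_site <- numeric(n); rep_site[idx] <- prm$A * s[, 1]
  rho <- numeric(n); rho[idx] <- s[, 2]
  site <- rep_site - prm$xi * sqrt(rho)
  cfac <- ifelse(rho > 0, -prm$xi / (2 * sqrt(pmax(rho, 1e-300))), 0)

  dEdr <- 2 * prm$A * dpsi + (cfac[pairs[, 1]] + cfac[pairs[, 2]]) * dphi
  Fi <- d * (-dEdr / r)
  F <- acc_force(F, pairs[, 1], Fi)
  F <- acc_force(F, pairs[, 2], -Fi)
  list(energy = sum(site), forces = F, energies = site)
}

#' Harmonic tip restraint forces
#'
#' Every tip atom is tethered to an anchor site: `F = -k (x - x_anchor)`.
#' Handle-layer anchors follow the steering command; all other tip anchors
#' stay at their construction positions.
#'
#' @param pos N x 3 position matrix.
#' @param anchors N x 3 anchor matrix (rows outside `idx` ignored).
#' @param k spring constant (eV/A^2).
#' @param idx indices of the restrained (tip) atoms.
#' @return list with `energy` and `forces`.
#' @export
tip_restraint_forces <- function(pos, anchors, k, idx) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  if (length(idx) == 0) return(list(energy = 0, forces = F))
  if (any(!is.finite(anchors[idx, ])))
    .stop_cond("steermd_missing_anchor", "tip atom without a finite anchor site")
  dx <- pos[idx, , drop = FALSE] - anchors[idx, , drop = FALSE]
  F[idx, ] <- -k * dx
  list(energy = 0.5 * k * sum(dx * dx), forces = F)
}

## ---- parameter resolution --------------------------------------------------

pair_key <- function(e1, e2) {
  paste(pmin(e1, e2), pmax(e1, e2), sep = "-")
}

#' Resolve bonded parameters for every tuple of a molecular graph
#'
#' Bond parameters are looked up by sorted species pattern (e.g. `"C-N"`)
#' with an explicit `default` fallback; angles and dihedrals use the
#' pattern-keyed tables the same way. Per-bond overrides (columns `i`, `j`,
#' and any of `k`, `r0`) take precedence, which is how e.g. the longer
#' single bond linking two aromatic rings is encoded in a topology file.
#'
#' @param g a [molecular_graph()].
#' @param ff force field (see [default_forcefield()]).
#' @param overrides optional data.frame with columns `i`, `j` and `k`/`r0`.
#' @return list with per-tuple parameter vectors: `bond$k`, `bond$r0`,
#'   `angle$k`, `angle$theta0`, `dihedral$k`, `$m`, `$phi0`, plus the tuple
#'   matrices themselves.
#' @export
resolve_bonded_params <- function(g, ff, overrides = NULL) {
  tp <- bonded_tuples(g)
  el <- g$atoms$element
  look <- function(tbl, keys, field) {
    vapply(keys, function(kk) {
      entry <- tbl[[kk]]
      if (is.null(entry)) entry <- tbl$default
      if (is.null(entry))
        .stop_cond("steermd_param_lookup",
                   paste("no bonded parameters for pattern", kk, "and no default"))
      entry[[field]]
    }, numeric(1), USE.NAMES = FALSE)
  }
  bk <- pair_key(el[tp$bonds[, 1]], el[tp$bonds[, 2]])
  bond <- list(k = look(ff$bonded$bond, bk, "k"),
               r0 = look(ff$bonded$bond, bk, "r0"))
  if (!is.null(overrides) && nrow(tp$bonds) > 0 && nrow(overrides) > 0) {
    okey <- paste(pmin(overrides$i, overrides$j), pmax(overrides$i, overrides$j))
    tkey <- paste(tp$bonds[, 1], tp$bonds[, 2])
    hit <- match(tkey, okey)
    has <- which(!is.na(hit))
    if (!is.null(overrides$r0)) {
      v <- overrides$r0[hit[has]]
      bond$r0[has[!is.na(v)]] <- v[!is.na(v)]
    }
    if (!is.null(overrides$k)) {
      v <- overrides$k[hit[has]]
      bond$k[has[!is.na(v)]] <- v[!is.na(v)]
    }
  }
  ak <- if (nrow(tp$angles) > 0) el[tp$angles[, 2]] else character(0)
  angle <- list(k = look(ff$bonded$angle, ak, "k"),
                theta0 = look(ff$bonded$angle, ak, "theta0"))
  dk <- if (nrow(tp$dihedrals) > 0)
    pair_key(el[tp$dihedrals[, 2]], el[tp$dihedrals[, 3]]) else character(0)
  dihedral <- list(k = look(ff$bonded$dihedral, dk, "k"),
                   m = look(ff$bonded$dihedral, dk, "m"),
                   phi0 = look(ff$bonded$dihedral, dk, "phi0"))
  list(tuples = tp, bond = bond, angle = angle, dihedral = dihedral)
}

#' Resolve the molecule-metal pair potential for a species/role pair
#'
#' @param species molecule atom element symbol.
#' @param role metal role, `"tip"` or `"substrate"`.
#' @param ff force field.
#' @return list with `kind` and the scaled parameters.
#' @export
resolve_pair_potential <- function(species, role, ff) {
  p <- ff$pair[[species]]
  if (is.null(p))
    .stop_cond("steermd_param_lookup",
               paste("no metal-molecule pair potential for species", species))
  row <- ff$affinity$species == species & ff$affinity$role == role
  if (sum(row) != 1)
    .stop_cond("steermd_param_lookup",
               paste("affinity table does not resolve", species, "/", role))
  sc <- ff$affinity$scale[row]
  if (p$kind == "morse") p$D <- p$D * sc else p$eps <- p$eps * sc
  p
}
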