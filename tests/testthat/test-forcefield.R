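test_that("LJ reproduces its closed-form landmarks and truncation behavior", {
  eps <- 0.03; sig <- 3.2; rc <- 8
  at_min <- lj_energy_force(2^(1 / 6) * sig, eps, sig, rc, shift = "none")
  expect_equal(at_min$force, 0, tolerance = 1e-12)
  expect_equal(at_min$energy, -eps, tolerance = 1e-10)
  expect_equal(lj_energy_force(sig, eps, sig, rc, shift = "none")$energy, 0,
               tolerance = 1e-12)
  beyond <- lj_energy_force(rc + 0.1, eps, sig, rc)
  expect_identical(c(beyond$energy, beyond$force), c(0, 0))
  # shifted-force truncation: both energy and force continuous at rc
  close <- lj_energy_force(rc - 1e-8, eps, sig, rc, shift = "force")
  expect_lt(abs(close$energy), 1e-9)
  expect_lt(abs(close$force), 1e-9)
  expect_error(lj_energy_force(0, eps, sig, rc), class = "steermd_singularity")
})

test_that("Morse reproduces well depth, asymptote and truncation", {
  D <- 0.35; a <- 1.7; re <- 2.35; rc <- 30
  at_min <- morse_energy_force(re, D, a, re, rc, shift = "none")
  expect_equal(at_min$energy, -D)
  expect_equal(at_min$force, 0)
  far <- morse_energy_force(re + 20 / a, D, a, re, rc, shift = "none")
  expect_lt(abs(far$energy), 1e-8 * D)    # dissociated asymptote
  sf <- morse_energy_force(6 - 1e-8, D, a, re, 6, shift = "force")
  expect_lt(abs(sf$energy), 1e-9)
  expect_lt(abs(sf$force), 1e-9)
})

test_that("radial pair forces match central differences on random distances", {
  set.seed(21)
  rc <- 6
  r <- runif(100, 0.8 * 3.2, rc - 0.05)
  for (shift in c("none", "force")) {
    lj <- lj_energy_force(r, 0.03, 3.2, rc, shift = shift)
    fd <- vapply(r, function(ri) {
      h <- 1e-5
      -(lj_energy_force(ri + h, 0.03, 3.2, rc, shift = shift)$energy -
          lj_energy_force(ri - h, 0.03, 3.2, rc, shift = shift)$energy) / (2 * h)
    }, numeric(1))
    expect_lt(max_rel_dev(lj$force, fd), 1e-6)
    mo <- morse_energy_force(r, 0.35, 1.7, 2.35, rc, shift = shift)
    fdm <- vapply(r, function(ri) {
      h <- 1e-5
      -(morse_energy_force(ri + h, 0.35, 1.7, 2.35, rc, shift = shift)$energy -
          morse_energy_force(ri - h, 0.35, 1.7, 2.35, rc, shift = shift)$energy) / (2 * h)
    }, numeric(1))
    expect_lt(max_rel_dev(mo$force, fdm), 1e-6)
  }
})

test_that("bonded force terms are exact gradients with zero net force and torque", {
  set.seed(31)
  worst <- c(bond = 0, angle = 0, dihedral = 0)
  for (rep in 1:100) {
    pb <- matrix(rnorm(6, sd = 1.2), 2, 3)
    fb <- harmonic_bond_forces(pb, rbind(c(1, 2)), 20, 1.4)
    gb <- num_grad(function(p) harmonic_bond_forces(matrix(p, 2, 3),
                                                    rbind(c(1, 2)), 20, 1.4)$energy,
                   as.vector(pb))
    worst["bond"] <- max(worst["bond"], max_rel_dev(as.vector(fb$forces), -gb))

    pa <- matrix(rnorm(9, sd = 1.2), 3, 3)
    fa <- harmonic_angle_forces(pa, rbind(c(1, 2, 3)), 5, 1.9)
    ga <- num_grad(function(p) harmonic_angle_forces(matrix(p, 3, 3),
                                                     rbind(c(1, 2, 3)), 5, 1.9)$energy,
                   as.vector(pa))
    worst["angle"] <- max(worst["angle"], max_rel_dev(as.vector(fa$forces), -ga))
    expect_lt(max(abs(colSums(fa$forces))), 1e-12)
    # zero net torque about the central atom
    tq <- colSums(steermd:::cross3(sweep(pa, 2, pa[2, ]), fa$forces))
    expect_lt(max(abs(tq)), 1e-12)

    pd <- matrix(rnorm(12, sd = 1.2), 4, 3)
    fd <- dihedral_forces(pd, rbind(c(1, 2, 3, 4)), 0.3, 2, pi)
    gd <- num_grad(function(p) dihedral_forces(matrix(p, 4, 3),
                                               rbind(c(1, 2, 3, 4)), 0.3, 2, pi)$energy,
                   as.vector(pd))
    worst["dihedral"] <- max(worst["dihedral"], max_rel_dev(as.vector(fd$forces), -gd))
    expect_lt(max(abs(colSums(fd$forces))), 1e-10)
    tqd <- colSums(steermd:::cross3(pd, fd$forces))
    expect_lt(max(abs(tqd)), 1e-10)
  }
  expect_lt(worst[["bond"]], 1e-6)
  expect_lt(worst[["angle"]], 1e-6)
  expect_lt(worst[["dihedral"]], 1e-5)
})

test_that("angle and bond forces vanish at their rest geometry", {
  th0 <- 1.8
  pos <- rbind(c(cos(th0), sin(th0), 0), c(0, 0, 0), c(1, 0, 0))
  fa <- harmonic_angle_forces(pos, rbind(c(1, 2, 3)), 5, th0)
  expect_lt(max(abs(fa$forces)), 1e-12)
  pb <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  expect_lt(max(abs(harmonic_bond_forces(pb, rbind(c(1, 2)), 20, 1.4)$forces)), 1e-12)
  # Hooke: stretch by delta gives k*delta on each atom
  pb2 <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  fb2 <- harmonic_bond_forces(pb2, rbind(c(1, 2)), 20, 1.4)
  expect_equal(fb2$forces[2, 1], -20 * 0.1, tolerance = 1e-10)
  expect_equal(fb2$forces[1, 1], 20 * 0.1, tolerance = 1e-10)
  expect_error(harmonic_bond_forces(rbind(c(0, 0, 0), c(0, 0, 0)),
                                    rbind(c(1, 2)), 20, 1.4),
               class = "steermd_degenerate")
})

test_that("dihedral forces vanish at a minimum of the periodic potential", {
  # m=2, phi0=pi: minima at phi = 0 and pi; planar trans geometry has phi = pi
  pos <- rbind(c(-1, 1, 0), c(0, 0, 0), c(1.4, 0, 0), c(2.4, -1, 0))
  fd <- dihedral_forces(pos, rbind(c(1, 2, 3, 4)), 0.3, 2, pi)
  expect_lt(max(abs(fd$forces)), 1e-10)
  expect_lt(abs(fd$energy), 1e-12)
})

test_that("degenerate angle geometry is regularized, not NaN", {
  reset_counters()
  pos <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))  # collinear, theta = pi
  fa <- harmonic_angle_forces(pos, rbind(c(1, 2, 3)), 5, 1.9)
  expect_true(all(is.finite(fa$forces)))
  expect_gte(get_counters()[["degenerate_geometry"]], 1)
  reset_counters()
})

test_that("metal term: empty neighborhood, dimer equilibrium and gradients", {
  ff <- default_forcefield()
  prm <- ff$metal; rc <- ff$cutoff
  iso <- gupta_energy_forces(matrix(0, 1, 3), matrix(integer(0), 0, 2), prm, rc)
  expect_identical(iso$energy, 0)
  expect_true(all(iso$forces == 0))

  # dimer: equilibrium separation from an independent 1-D root find on the
  # pair energy (switching inactive well below the cutoff)
  dimer_E <- function(r) {
    2 * (prm$A * exp(-prm$p * (r / prm$r0 - 1)) -
           prm$xi * exp(-prm$q * (r / prm$r0 - 1)))
  }
  r_eq <- stats::uniroot(function(r) (dimer_E(r + 1e-6) - dimer_E(r - 1e-6)) / 2e-6,
                         c(1.5, 4), tol = 1e-12)$root
  pos <- rbind(c(0, 0, 0), c(r_eq, 0, 0))
  fd <- gupta_energy_forces(pos, rbind(c(1, 2)), prm, rc)
  expect_lt(max(abs(fd$forces)), 1e-6)
  expect_equal(fd$energy, dimer_E(r_eq), tolerance = 1e-10)

  set.seed(41)
  for (rep in 1:5) {
    pos <- matrix(rnorm(60, sd = 2.5), 20, 3)
    prs <- t(combn(20, 2))
    F <- gupta_energy_forces(pos, prs, prm, rc)$forces
    g <- num_grad(function(p) gupta_energy_forces(matrix(p, 20, 3), prs, prm, rc)$energy,
                  as.vector(pos))
    expect_lt(max_rel_dev(as.vector(F), -g), 1e-6)
  }
})

test_that("tip restraints restore toward anchors and follow steering", {
  pos <- rbind(c(0, 0, 10), c(1, 0, 10))
  anch <- pos
  f0 <- tip_restraint_forces(pos, anch, 5, 1:2)
  expect_true(all(f0$forces == 0))
  pos2 <- pos; pos2[1, ] <- pos2[1, ] + c(0.2, 0, 0)
  f1 <- tip_restraint_forces(pos2, anch, 5, 1:2)
  expect_equal(f1$forces[1, ], c(-1, 0, 0))
  anch2 <- anch; anch2[1, ] <- anch2[1, ] + c(0.2, 0, 0)  # steering moved it
  expect_true(all(tip_restraint_forces(pos2, anch2, 5, 1:2)$forces == 0))
  expect_error(tip_restraint_forces(pos, matrix(NA_real_, 2, 3), 5, 1:2),
               class = "steermd_missing_anchor")
})

test_that("affinity table scales the anchoring well depth by metal role", {
  ff <- default_forcefield()
  ptip <- resolve_pair_potential("N", "tip", ff)
  psub <- resolve_pair_potential("N", "substrate", ff)
  expect_equal(ptip$D / psub$D, 3)
  expect_equal(psub$D, ff$pair$N$D)
  expect_equal(resolve_pair_potential("C", "tip", ff)$kind, "lj")
  expect_error(resolve_pair_potential("Xe", "tip", ff),
               class = "steermd_param_lookup")
})

test_that("force-field validation catches out-of-range parameters", {
  ff <- default_forcefield()
  ff$pair$C$sigma <- -1
  expect_error(validate_forcefield(ff), class = "steermd_bad_params")
  ff2 <- default_forcefield()
  ff2$bonded$angle$default$theta0 <- 4
  expect_error(validate_forcefield(ff2), class = "steermd_bad_params")
})

test_that("assembled forces: relaxed fixture, invariances and third law", {
  sysm <- vacuum_molecule_system()
  ev <- assemble_forces(sysm, "brute")
  expect_lt(max(abs(ev$forces)), 1e-10)   # idealized geometry is the rest state

  slab <- build_fcc111_slab(6, 6, 2)
  sys <- place_molecule(slab, bipyridylbenzene(), height = 3.2)
  e1 <- assemble_forces(sys, "brute")
  expect_lt(max(abs(colSums(e1$forces[sys$role != "tip", , drop = FALSE]))), 1e-9)

  # rigid translation leaves energy and forces unchanged
  sys2 <- sys
  sys2$pos <- sweep(sys$pos, 2, c(3.7, -2.1, 5.0), `+`)
  sys2$anchor <- sweep(sys$anchor, 2, c(3.7, -2.1, 5.0), `+`)
  e2 <- assemble_forces(sys2, "brute")
  expect_equal(e2$energy, e1$energy, tolerance = 1e-12)
  expect_lt(max(abs(e2$forces - e1$forces)), 1e-9)

  # forces rotate covariantly under a global rotation (molecule only,
  # restraint-free system)
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  sysr <- vacuum_molecule_system()
  sysr$pos <- sysm$pos %*% t(R)
  er <- assemble_forces(sysr, "brute")
  ev0 <- assemble_forces(sysm, "brute")
  expect_lt(max(abs(er$forces - ev0$forces %*% t(R))), 1e-9)
  expect_equal(er$energy, ev0$energy, tolerance = 1e-10)
})
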