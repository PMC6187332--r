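make_free_system <- function(n = 1, mass = 1) {
  steermd:::new_md_system(matrix(0, n, 3), rep(mass, n), rep("Au", n),
                          rep("substrate", n), rep(FALSE, n), rep(FALSE, n),
                          matrix(NA_real_, n, 3))
}

zero_force <- function(pos) list(energy = 0, forces = matrix(0, nrow(pos), 3))

test_that("free drift is exact and frozen atoms never move", {
  sys <- make_free_system(2)
  sys$vel[1, ] <- c(0.3, -0.2, 0.1)
  sys$vel[2, ] <- c(1, 1, 1)
  sys$frozen[2] <- TRUE
  out <- vv_step(sys, dt = 0.7, zero_force)
  expect_equal(out$pos[1, ], c(0.3, -0.2, 0.1) * 0.7)
  expect_equal(out$pos[2, ], c(0, 0, 0))
  expect_equal(out$vel[1, ], sys$vel[1, ])
})

test_that("harmonic oscillator period converges at second order", {
  k <- 1; m <- 1
  spring <- function(pos) list(energy = 0.5 * k * pos[1, 1]^2,
                               forces = rbind(c(-k * pos[1, 1], 0, 0)))
  period_error <- function(dt) {
    sys <- make_free_system(1, mass = m)
    sys$pos[1, 1] <- 1
    prev <- 1; t_cross <- NA
    for (s in 1:ceiling(14 / dt)) {
      sys <- vv_step(sys, dt, spring)
      # starting from x = A, v = 0, the upward zero crossing of x happens
      # at 3/4 of the period
      if (prev < 0 && sys$pos[1, 1] >= 0 && sys$vel[1, 1] > 0) {
        frac <- prev / (prev - sys$pos[1, 1])
        t_cross <- (s - 1 + frac) * dt
        break
      }
      prev <- sys$pos[1, 1]
    }
    abs(t_cross * 4 / 3 - 2 * pi * sqrt(m / k))
  }
  e1 <- period_error(0.05)
  e2 <- period_error(0.025)
  expect_lt(e1, 0.01)
  expect_gt(e1 / e2, 3)   # Richardson: halving dt cuts the error ~4x
  expect_lt(e1 / e2, 5)
})

test_that("NVE vacuum-molecule run conserves energy (short horizon)", {
  set.seed(42)
  sys <- vacuum_molecule_system()
  kT <- 300 * steermd:::.kB_eV
  sys$vel <- matrix(rnorm(3 * nrow(sys$pos)), ncol = 3) * sqrt(kT / sys$mass)
  E0 <- kinetic_energy(sys)
  res <- reference_integrate(sys, 1000, fs_to_tu(0.25), gamma = 0,
                             engine = "brute",
                             record = function(s) s$energy + kinetic_energy(s))
  E <- unlist(res$trace)
  drift <- abs(mean(utils::tail(E, 100)) - mean(utils::head(E, 100))) / abs(E0)
  expect_lt(drift, 1e-4)
  expect_lt(max(abs(E - E[1])) / abs(E0), 5e-3)  # bounded Verlet fluctuation
})

test_that("constant-friction thermostat damps geometrically and validates input", {
  sys <- make_free_system(1)
  sys$vel[1, ] <- c(1, 0, 0)
  expect_identical(apply_thermostat(sys, 0, 0.1)$vel, sys$vel)
  out <- sys
  for (s in 1:10) out <- apply_thermostat(out, 0.5, 0.4)
  expect_equal(out$vel[1, 1], (1 - 0.5 * 0.4)^10)
  expect_error(apply_thermostat(sys, 3, 0.4), class = "steermd_bad_params")
})

test_that("non-finite state aborts with an integration failure", {
  sys <- make_free_system(1)
  sys$vel[1, 1] <- NaN
  expect_error(vv_step(sys, 0.1, zero_force),
               class = "steermd_integration_failure")
})

test_that("MTS with no molecule reduces to a plain large-step Verlet", {
  slab <- build_fcc111_slab(6, 6, 3)
  sys <- place_molecule(slab, NULL)
  sys$pos <- sys$pos + matrix(rnorm(length(sys$pos), sd = 0.02), nrow(sys$pos))
  cfg <- mts_config(dt_large = 5, alpha = 7, gamma = 0, thermostat = "none")
  split <- subsystem_split(sys)
  expect_length(split$extended, 0)
  pairs <- build_pairs(sys, "cell")
  m <- mts_cycle(sys, split, cfg, pairs = pairs)
  ref <- sys
  fn <- function(pos) assemble_forces(ref, pairs = pairs, pos = pos)
  r <- vv_step(ref, cfg$dt, fn)
  expect_equal(m$pos, r$pos, tolerance = 1e-14)
  expect_equal(m$vel, r$vel, tolerance = 1e-14)
})

test_that("MTS with fully frozen gold reduces to small-step molecule dynamics", {
  slab <- build_fcc111_slab(8, 8, 2, frozen_layers = 2)
  sys <- place_molecule(slab, bipyridylbenzene(), height = 3.2)
  cfg <- mts_config(dt_large = 2, alpha = 8, gamma = 0, thermostat = "none")
  split <- subsystem_split(sys)
  pairs <- build_pairs(sys, "cell")
  m <- mts_cycle(sys, split, cfg, pairs = pairs)
  # reference: the molecule alone integrated at dt/alpha with full forces
  ref <- sys
  fn <- function(pos) assemble_forces(ref, pairs = pairs, pos = pos)
  for (s in 1:8) ref <- vv_step(ref, cfg$dts, fn, mobile = sys$mol_idx)
  expect_equal(m$pos[sys$mol_idx, ], ref$pos[sys$mol_idx, ], tolerance = 1e-12)
  expect_equal(m$pos[-sys$mol_idx, ], sys$pos[-sys$mol_idx, ])
})

test_that("subsystem engines sum exactly to the full force assembly", {
  sys <- build_manipulation_system(slab_dims = c(8, 8, 3), tip_layers = 2)
  split <- subsystem_split(sys)
  expect_setequal(split$interface, intersect(split$gold, split$extended))
  pairs <- build_pairs(sys, "cell")
  eng <- make_engines(sys, pairs, split)
  full <- eng$full(sys$pos)$forces
  expect_equal(eng$gold(sys$pos)$forces + eng$extended(sys$pos)$forces, full,
               tolerance = 1e-15)
})

test_that("MTS trajectory converges to the single-timescale reference as dt shrinks", {
  slab <- build_fcc111_slab(7, 7, 2)
  sys <- place_molecule(slab, bipyridylbenzene(), height = 3.2)
  rms_dev <- function(dt_fs) {
    cfg <- mts_config(dt_large = dt_fs, alpha = 4, gamma = 0, thermostat = "none")
    split <- subsystem_split(sys)
    pairs <- build_pairs(sys, "cell")
    eng <- make_engines(sys, pairs, split)
    m <- sys
    n_cyc <- round(8 / dt_fs)
    for (cc in seq_len(n_cyc)) m <- mts_cycle(m, split, cfg, engines = eng, pairs = pairs)
    r <- reference_integrate(sys, n_cyc * 4, cfg$dts, gamma = 0,
                             refresh_interval = 1e6)$sys
    sqrt(mean((m$pos[sys$mol_idx, ] - r$pos[sys$mol_idx, ])^2))
  }
  d1 <- rms_dev(4)
  d2 <- rms_dev(2)
  expect_lt(d2, d1)          # refining the step tightens the match
  expect_lt(d2, 0.01)
})

test_that("atoms outside both subsystems are a split error", {
  sys <- build_manipulation_system(slab_dims = c(6, 6, 2), tip_layers = 2)
  sys$role[1] <- "molecule"   # role claims molecule but not in mol_idx
  expect_error(subsystem_split(sys), class = "steermd_split_error")
})

test_that("relaxation-time estimator reports convergence of a perturbed slab", {
  set.seed(9)
  slab <- build_fcc111_slab(6, 6, 3)
  sys <- place_molecule(slab, NULL)
  sys$pos <- sys$pos + matrix(rnorm(length(sys$pos), sd = 0.03), nrow(sys$pos))
  cfg <- mts_config(gamma = 5e-3)
  est <- estimate_relaxation_time(sys, cfg, ftol = 0.05, max_cycles = 600)
  expect_false(is.na(est$cycles))
  expect_lt(est$max_force, 0.05)
})
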