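## Velocity-Verlet stepping, constant-friction thermostat and the
## multi-time-step (MTS) cycle coupling the heavy-metal subsystem (large
## step) to the extended-molecule subsystem (small step).

#' Multi-time-step configuration
#'
#' @param dt_large large (metal) time step in fs; default 5 fs.
#' @param alpha integer ratio `dt_large / dt_small`; default 20, giving a
#'   0.25 fs small step. Both step defaults are package choices exposed here
#'   precisely because they are system-dependent.
#' @param gamma constant friction coefficient of the thermostat, in 1/fs
#'   (default 1e-3, i.e. a kinetic-energy decay time of roughly 0.5 ps).
#' @param k_cycles number of MTS cycles executed between two polls of the
#'   steering input (default 10).
#' @param refresh_interval rebuild the cell grid every this many cycles
#'   (default 20).
#' @param thermostat which subsystems are damped: "all", "gold",
#'   "extended" or "none".
#' @return list of class `mts_config` with times converted to internal
#'   units (`dt`, `dts`).
#' @export
mts_config <- function(dt_large = 5, alpha = 20L, gamma = 1e-3,
                       k_cycles = 10L, refresh_interval = 20L,
                       thermostat = c("all", "gold", "extended", "none")) {
  thermostat <- match.arg(thermostat)
  if (alpha < 1 || alpha != round(alpha))
    .stop_cond("steermd_bad_params", "alpha must be a positive integer")
  dt <- fs_to_tu(dt_large)
  dts <- dt / alpha
  g <- gamma * .tu_fs            # 1/fs -> 1/tu
  if (g * dt >= 1)
    .stop_cond("steermd_bad_params", "gamma * dt must be < 1")
  structure(list(dt = dt, dts = dts, alpha = as.integer(alpha), gamma = g,
                 k_cycles = as.integer(k_cycles),
                 refresh_interval = as.integer(refresh_interval),
                 thermostat = thermostat),
            class = "mts_config")
}

#' Kinetic energy of a system
#'
#' @param sys an `md_system`.
#' @return kinetic energy in eV.
#' @export
kinetic_energy <- function(sys) 0.5 * sum(sys$mass * rowSums(sys$vel^2))

check_finite_state <- function(sys) {
  if (any(!is.finite(sys$pos)) || any(!is.finite(sys$vel)))
    .stop_cond("steermd_integration_failure",
               sprintf("non-finite state at step %d (t = %.3f fs)",
                       sys$step, tu_to_fs(sys$time)))
  invisible(sys)
}

#' One velocity-Verlet step
#'
#' Standard kick-drift-kick update for the mobile atoms; frozen and
#' non-mobile atoms are untouched. Forces are cached on the state so each
#' step costs one force evaluation.
#'
#' @param sys an `md_system` (with `sys$force` optionally holding the
#'   forces consistent with `sys$pos`).
#' @param dt time step in internal units.
#' @param force_fn function `pos -> list(energy, forces)`.
#' @param mobile logical mask or index vector of atoms to integrate
#'   (default: all non-frozen atoms).
#' @return the advanced `md_system` (with `force` and `energy` fields
#'   updated).
#' @export
vv_step <- function(sys, dt, force_fn, mobile = NULL) {
  n <- nrow(sys$pos)
  mob <- rep(FALSE, n)
  if (is.null(mobile)) mob[!sys$frozen] <- TRUE else mob[mobile] <- TRUE
  mob <- mob & !sys$frozen
  if (is.null(sys$force)) {
    ev <- force_fn(sys$pos)
    sys$force <- ev$forces
  }
  a1 <- sys$force[mob, , drop = FALSE] / sys$mass[mob]
  sys$pos[mob, ] <- sys$pos[mob, ] + sys$vel[mob, , drop = FALSE] * dt +
    0.5 * a1 * dt^2
  ev2 <- force_fn(sys$pos)
  a2 <- ev2$forces[mob, , drop = FALSE] / sys$mass[mob]
  sys$vel[mob, ] <- sys$vel[mob, , drop = FALSE] + 0.5 * (a1 + a2) * dt
  sys$force <- ev2$forces
  sys$energy <- ev2$energy
  sys$time <- sys$time + dt
  check_finite_state(sys)
}

#' Constant-friction thermostat
#'
#' Multiplicative velocity damping `v <- (1 - gamma dt) v`, the first-order
#' discretization of a `-gamma m v` friction force. Removes the energy
#' pumped in by the hand-steered tip.
#'
#' @param sys an `md_system`.
#' @param gamma friction (1/internal time), >= 0.
#' @param dt time step (internal units) with `gamma * dt < 1`.
#' @param mobile optional mask/indices (default all non-frozen).
#' @return the damped system.
#' @export
apply_thermostat <- function(sys, gamma, dt, mobile = NULL) {
  if (gamma < 0 || gamma * dt >= 1)
    .stop_cond("steermd_bad_params", "need 0 <= gamma*dt < 1")
  if (gamma == 0) return(sys)
  n <- nrow(sys$pos)
  mob <- rep(FALSE, n)
  if (is.null(mobile)) mob[!sys$frozen] <- TRUE else mob[mobile] <- TRUE
  mob <- mob & !sys$frozen
  sys$vel[mob, ] <- sys$vel[mob, , drop = FALSE] * (1 - gamma * dt)
  sys
}

#' One multi-time-step cycle
#'
#' Advances the system by one large step `dt`: the gold-only subsystem takes
#' a single velocity-Verlet step of `dt` under metal-side forces (with the
#' molecule as a static field on non-interface atoms), while the
#' extended-molecule subsystem takes `alpha` small steps of `dt/alpha`
#' against the frozen cycle-start metal background. Interface metal atoms
#' are integrated in both: they carry their inertia in the gold subsystem
#' and accumulate the molecule-induced adjustment (from zero initial
#' velocity) in the extended subsystem; at cycle end their displacements and
#' velocity increments from the two subsystems are added. Molecule atoms
#' take the extended-subsystem result, all other metal atoms the gold
#' result.
#'
#' @param sys an `md_system`.
#' @param split partition from [subsystem_split()].
#' @param cfg an [mts_config()].
#' @param engines force engines from [make_engines()] (rebuilt when `NULL`).
#' @param pairs optional pair lists for engine construction.
#' @return the advanced system (time advanced by `dt`, step by 1).
#' @export
mts_cycle <- function(sys, split, cfg, engines = NULL, pairs = NULL) {
  if (is.null(engines)) {
    if (is.null(pairs)) pairs <- build_pairs(sys, "cell")
    engines <- make_engines(sys, pairs, split)
  }
  n <- nrow(sys$pos)
  x0 <- sys$pos
  damp_gold <- cfg$thermostat %in% c("all", "gold")
  damp_ext <- cfg$thermostat %in% c("all", "extended")

  ## --- gold-only subsystem: one large step -------------------------------
  sysA <- sys
  sysA$force <- NULL
  gold_mobile <- setdiff(split$gold, split$frozen)
  if (length(gold_mobile) > 0) {
    sysA <- vv_step(sysA, cfg$dt, engines$gold, mobile = gold_mobile)
    if (damp_gold) sysA <- apply_thermostat(sysA, cfg$gamma, cfg$dt, gold_mobile)
  } else {
    sysA$time <- sysA$time + cfg$dt
  }

  ## --- extended-molecule subsystem: alpha small steps --------------------
  sysB <- sys
  sysB$force <- NULL
  sysB$vel[split$interface, ] <- 0     # interface inertia lives in the gold subsystem
  ext_mobile <- setdiff(split$extended, split$frozen)
  if (length(ext_mobile) > 0) {
    for (s in seq_len(cfg$alpha)) {
      sysB <- vv_step(sysB, cfg$dts, engines$extended, mobile = ext_mobile)
      if (damp_ext) sysB <- apply_thermostat(sysB, cfg$gamma, cfg$dts, ext_mobile)
    }
  }

  ## --- compose -----------------------------------------------------------
  out <- sys
  out$pos <- sysA$pos                      # gold result everywhere ...
  out$vel <- sysA$vel
  mol <- sys$mol_idx
  out$pos[mol, ] <- sysB$pos[mol, , drop = FALSE]   # ... molecule from B ...
  out$vel[mol, ] <- sysB$vel[mol, , drop = FALSE]
  ifc <- split$interface                   # ... interface: additive
  if (length(ifc) > 0) {
    out$pos[ifc, ] <- sysA$pos[ifc, , drop = FALSE] +
      (sysB$pos[ifc, , drop = FALSE] - x0[ifc, , drop = FALSE])
    out$vel[ifc, ] <- sysA$vel[ifc, , drop = FALSE] + sysB$vel[ifc, , drop = FALSE]
  }
  out$force <- NULL
  out$time <- sys$time + cfg$dt
  out$step <- sys$step + 1L
  check_finite_state(out)
}

#' Single-timescale reference integration
#'
#' All atoms integrated with the full force assembly at one (small) time
#' step -- the oracle the MTS scheme is validated against.
#'
#' @param sys an `md_system`.
#' @param n_steps number of steps.
#' @param dt time step (internal units).
#' @param gamma thermostat friction (1/internal time, 0 = NVE).
#' @param engine `"cell"` or `"brute"`.
#' @param refresh_interval cell-grid refresh period (steps).
#' @param record optional function `sys -> value` evaluated after every
#'   step; results returned as a list.
#' @return list with the final `sys` and `trace`.
#' @export
reference_integrate <- function(sys, n_steps, dt, gamma = 0,
                                engine = "cell", refresh_interval = 20L,
                                record = NULL) {
  trace <- if (is.null(record)) NULL else vector("list", n_steps)
  pairs <- NULL
  for (s in seq_len(n_steps)) {
    if (refresh_policy(s - 1L, refresh_interval) || is.null(pairs)) {
      pairs <- build_pairs(sys, engine)
      sys$force <- NULL
    }
    fn <- function(pos) assemble_forces(sys, pairs = pairs, pos = pos)
    sys <- vv_step(sys, dt, fn)
    if (gamma > 0) sys <- apply_thermostat(sys, gamma, dt)
    sys$step <- sys$step + 1L
    if (!is.null(record)) trace[[s]] <- record(sys)
  }
  list(sys = sys, trace = trace)
}

#' Run MTS cycles with scripted steering
#'
#' The outer real-time loop: every `k_cycles` cycles the steering source is
#' polled once and the handle-layer anchors are moved to the commanded
#' position (rate-limited by the trajectory's quasi-static guard); between
#' polls, MTS cycles advance the physics, the cell grid and the subsystem
#' split being refreshed every `refresh_interval` cycles. Per-cycle
#' diagnostics are collected.
#'
#' @param sys an `md_system`.
#' @param cfg an [mts_config()].
#' @param trajectory a [tip_trajectory()], or `NULL` for a static tip.
#' @param n_cycles total number of MTS cycles to run (when `NULL`, runs
#'   until one poll past the trajectory's last waypoint, then stops
#'   cleanly).
#' @param diagnostics collect the per-cycle diagnostic table (default TRUE).
#' @return list with `sys` and `diag` (data.frame: cycle, time_fs, E_pot,
#'   E_kin, tip_cmd_z, apex_z, min_anchor_dist, handle_fz, max_force_mol,
#'   overflow).
#' @export
run_cycles <- function(sys, cfg, trajectory = NULL, n_cycles = NULL,
                       diagnostics = TRUE) {
  if (is.null(n_cycles)) {
    n_cycles <- if (is.null(trajectory)) cfg$k_cycles
    else (ceiling(max(trajectory$waypoints$t) / cfg$k_cycles) + 1L) * cfg$k_cycles
  }
  handle_idx <- which(sys$handle)
  tip_idx <- which(sys$role == "tip")
  tip_off <- NULL; cmd <- c(NA, NA, NA)
  if (length(handle_idx) > 0) {
    ## the command addresses the handle-layer center; the whole tip anchor
    ## lattice translates rigidly with it (each atom stays individually
    ## tethered, so the apex can still deform under molecular forces)
    hc <- colMeans(sys$anchor[handle_idx, , drop = FALSE])
    tip_off <- sweep(sys$anchor[tip_idx, , drop = FALSE], 2, hc)
    cmd_prev <- hc
  }
  anch <- anchoring_atoms(sys)
  tipall <- which(sys$role == "tip")
  rows <- if (diagnostics) vector("list", n_cycles) else NULL
  pairs <- NULL; split <- NULL; engines <- NULL

  for (cyc in seq_len(n_cycles)) {
    if (refresh_policy(cyc - 1L, cfg$refresh_interval) || is.null(pairs)) {
      split <- subsystem_split(sys)
      pairs <- build_pairs(sys, "cell")
      engines <- make_engines(sys, pairs, split)
    }
    if (!is.null(trajectory) && length(handle_idx) > 0 &&
        (cyc - 1L) %% cfg$k_cycles == 0) {
      cmd <- next_command(trajectory, cyc - 1L)
      step_cap <- trajectory$max_step * cfg$k_cycles
      delta <- cmd - cmd_prev
      dn <- sqrt(sum(delta^2))
      if (dn > step_cap) {
        bump_counter("steering_clamped")
        warning(sprintf("steering rate limited at cycle %d (%.3f > %.3f A/poll)",
                        cyc, dn, step_cap), call. = FALSE)
        delta <- delta * step_cap / dn
        cmd <- cmd_prev + delta
      }
      cmd_prev <- cmd
      sys$anchor[tip_idx, ] <- sweep(tip_off, 2, cmd, `+`)
      engines <- make_engines(sys, pairs, split)  # anchors entered the engines
    }
    sys <- mts_cycle(sys, split, cfg, engines = engines, pairs = pairs)

    if (diagnostics) {
      ev <- assemble_forces(sys, pairs = pairs)
      mad <- NA_real_
      if (length(anch) > 0 && length(tipall) > 0) {
        mad <- min(vapply(anch, function(a) {
          min(sqrt(rowSums((sys$pos[tipall, , drop = FALSE] -
                              matrix(sys$pos[a, ], length(tipall), 3, byrow = TRUE))^2)))
        }, numeric(1)))
      }
      fz <- if (length(handle_idx) > 0)
        sum(ev$parts$restraint[handle_idx, 3]) else NA_real_
      fmax <- if (length(sys$mol_idx) > 0)
        max(sqrt(rowSums(ev$forces[sys$mol_idx, , drop = FALSE]^2))) else NA_real_
      rows[[cyc]] <- data.frame(
        cycle = cyc, time_fs = tu_to_fs(sys$time), E_pot = ev$energy,
        E_kin = kinetic_energy(sys),
        tip_cmd_z = unname(cmd[3]),
        apex_z = if (length(tipall) > 0) sys$pos[tipall[1], 3] else NA_real_,
        min_anchor_dist = mad, handle_fz = fz, max_force_mol = fmax,
        overflow = unname(get_counters()["cell_overflow"]))
    }
  }
  list(sys = sys, diag = if (diagnostics) do.call(rbind, rows) else NULL)
}

#' Estimate the relaxation time after a perturbation
#'
#' Runs thermostatted reference dynamics until the maximum per-atom force on
#' the mobile atoms falls below `ftol`, and reports the number of steps
#' needed -- the quantity that must stay below the steering period for the
#' quasi-static regime to hold.
#'
#' @param sys an `md_system`.
#' @param cfg an [mts_config()].
#' @param ftol force tolerance (eV/A, default 0.05).
#' @param max_cycles give up after this many cycles (default 2000).
#' @return list with `cycles` (NA if not converged) and `max_force`.
#' @export
estimate_relaxation_time <- function(sys, cfg, ftol = 0.05, max_cycles = 2000L) {
  split <- subsystem_split(sys)
  pairs <- build_pairs(sys, "cell")
  engines <- make_engines(sys, pairs, split)
  mob <- !sys$frozen
  for (cyc in seq_len(max_cycles)) {
    if (refresh_policy(cyc - 1L, cfg$refresh_interval)) {
      split <- subsystem_split(sys)
      pairs <- build_pairs(sys, "cell")
      engines <- make_engines(sys, pairs, split)
    }
    sys <- mts_cycle(sys, split, cfg, engines = engines, pairs = pairs)
    fmax <- max(sqrt(rowSums(assemble_forces(sys, pairs = pairs)$forces[mob, , drop = FALSE]^2)))
    if (fmax < ftol) return(list(cycles = cyc, max_force = fmax))
  }
  list(cycles = NA_integer_, max_force = fmax)
}
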