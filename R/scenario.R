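## End-to-end manipulation scenario: approach - bond - drag - lift.
##
## This is the packaged counterpart of the interactive steering session: the
## tip apex is scripted to descend onto one pyridyl N atom, form the
## anchoring bond, drag the molecule laterally across the surface and then
## lift it off, while the engine reports the pull curve and per-phase
## summaries.

#' Build the standard manipulation system
#'
#' Slab + pyramidal tip + flat-lying bundled molecule, with the tip apex
#' positioned above one anchoring N atom.
#'
#' @param slab_dims `c(nx, ny, layers)`; default `c(12, 12, 3)`.
#' @param tip_layers tip layers (default 3).
#' @param height molecule adsorption height (A, default 3.2).
#' @param apex_clearance initial apex height above the molecule plane (A,
#'   default 4).
#' @param ff force field.
#' @return an `md_system`.
#' @export
build_manipulation_system <- function(slab_dims = c(12, 12, 3),
                                      tip_layers = 3, height = 3.2,
                                      apex_clearance = 4, ff = default_forcefield()) {
  slab <- build_fcc111_slab(slab_dims[1], slab_dims[2], slab_dims[3])
  mol <- bipyridylbenzene()
  center <- c(mean(range(slab$pos[, 1])), mean(range(slab$pos[, 2])))
  ## right-hand N sits at molecule-local x = +5.65
  n_local <- c(5.65, 0)
  apex_xy <- center + n_local
  tip <- build_tip(tip_layers, apex = c(apex_xy[1], apex_xy[2],
                                        slab$top_z + height + apex_clearance))
  place_molecule(slab, mol, tip = tip, height = height, center = center, ff = ff)
}

#' Scripted approach-bond-drag-lift manipulation
#'
#' Replays the canonical manipulation sequence under scripted steering:
#' relax, approach the apex to bonding distance above the N atom, hold while
#' the anchoring bond forms, drag laterally, then lift until the molecule
#' has fully detached from the surface. Phase boundaries and a per-phase
#' summary are logged; the full per-cycle diagnostics (including the pull
#' curve) are returned.
#'
#' @param sys system from [build_manipulation_system()] (built fresh when
#'   NULL).
#' @param cfg an [mts_config()]; the default uses a strong
#'   (quasi-static-friendly) friction of 5e-3 1/fs.
#' @param speed steering speed (A per cycle, default 0.01).
#' @param drag_dist lateral drag distance (A, default 3).
#' @param lift_height total lift (A, default 20).
#' @param relax_cycles thermostatted settling cycles before steering
#'   (default 150).
#' @param bond_cycles hold cycles at bonding distance (default 100).
#' @param approach_clearance apex-to-molecule-plane distance at the end of
#'   the approach (A, default 2.4).
#' @param verbose print phase summaries.
#' @return list with `sys` (final state), `diag` (per-cycle diagnostics
#'   with a `phase` column), `phases` (cycle ranges) and `summary`
#'   (lift success metrics: minimum molecule height above the surface,
#'   maximal relative bond strain).
#' @export
run_manipulation <- function(sys = NULL, cfg = NULL, speed = 0.01,
                             drag_dist = 3, lift_height = 20,
                             relax_cycles = 150L, bond_cycles = 100L,
                             approach_clearance = 2.4, verbose = FALSE) {
  if (is.null(sys)) sys <- build_manipulation_system()
  if (is.null(cfg)) cfg <- mts_config(gamma = 5e-3, k_cycles = 5L)
  handle_idx <- which(sys$handle)
  hc <- colMeans(sys$anchor[handle_idx, , drop = FALSE])
  top_z <- max(sys$pos[sys$role == "substrate", 3])
  mol_plane <- mean(sys$pos[sys$mol_idx, 3])
  apex0 <- sys$pos[which(sys$role == "tip")[1], ]
  drop <- (apex0[3] - mol_plane) - approach_clearance

  tr <- concat_trajectories(
    make_hold(hc, relax_cycles),
    make_drag(hc, hc - c(0, 0, drop), speed),
    make_hold(hc - c(0, 0, drop), bond_cycles),
    make_drag(hc - c(0, 0, drop), hc + c(drag_dist, 0, -drop), speed),
    make_lift(hc + c(drag_dist, 0, -drop), lift_height, speed)
  )
  wp <- tr$waypoints$t
  ## phase boundaries in cycles, in trajectory order
  b <- cumsum(c(relax_cycles + 1,
                ceiling(drop / speed) + 1, bond_cycles + 1,
                ceiling(drag_dist / speed) + 1,
                ceiling(lift_height / speed) + 1))
  phases <- data.frame(phase = c("relax", "approach", "bond", "drag", "lift"),
                       from = c(1, b[-5] + 1), to = b)

  res <- run_cycles(sys, cfg, tr, n_cycles = max(wp) + cfg$k_cycles)
  diag <- res$diag
  diag$phase <- cut(diag$cycle, breaks = c(0, b[-5], Inf),
                    labels = phases$phase)
  sysf <- res$sys

  bp <- sysf$bonded
  dvec <- sysf$pos[bp$tuples$bonds[, 1], ] - sysf$pos[bp$tuples$bonds[, 2], ]
  blen <- sqrt(rowSums(dvec^2))
  strain <- abs(blen - bp$bond$r0) / bp$bond$r0
  min_height <- min(sysf$pos[sysf$mol_idx, 3]) - top_z
  com_rise <- mean(sysf$pos[sysf$mol_idx, 3]) - mean(sys$pos[sys$mol_idx, 3])
  attached <- utils::tail(diag$min_anchor_dist, 1) < 3.5
  ## "lifted" requires genuine detachment, not just the adsorption height:
  ## every atom clears the surface by 2 A, the center of mass has risen
  ## well beyond the adsorbed state, the molecule still hangs off the tip,
  ## and every bond is within 20% of its rest length (intact)
  summary <- list(min_molecule_height = min_height,
                  com_rise = com_rise,
                  max_bond_strain = max(strain),
                  attached_to_tip = attached,
                  lifted = min_height > 2 && com_rise > 3 && attached &&
                    max(strain) < 0.2)
  if (verbose) {
    for (p in seq_len(nrow(phases))) {
      sel <- diag$phase == phases$phase[p]
      message(sprintf("%-9s cycles %5d-%5d  E_pot %8.2f eV  min anchor dist %.2f A",
                      phases$phase[p], phases$from[p], phases$to[p],
                      mean(diag$E_pot[sel]), min(diag$min_anchor_dist[sel])))
    }
    message(sprintf(
      "final: min molecule height %.2f A, com rise %.2f A, max bond strain %.1f%%",
      min_height, com_rise, 100 * max(strain)))
  }
  list(sys = sysf, diag = diag, phases = phases, summary = summary)
}
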