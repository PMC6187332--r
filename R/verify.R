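## Self-verification and operation-count benchmark harnesses.

#' Run the built-in verification suite
#'
#' Machine-checkable release gate wrapping the package's oracles:
#' closed-form force-count bounds vs exhaustive enumeration, analytic forces
#' vs central-difference gradients, cell-list vs brute-force pair forces,
#' topology/XYZ round trips and parameter validation.
#'
#' @param max_atoms graph size for the enumeration check (default 6 for a
#'   fast gate; the acceptance suite runs 8).
#' @param seed RNG seed for the randomized geometry checks.
#' @return data.frame with columns `check`, `pass`, `detail`; attribute
#'   `ok` is TRUE when everything passed.
#' @export
verify_all <- function(max_atoms = 6, seed = 1L) {
  set.seed(seed)
  rows <- list()
  add <- function(check, pass, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(check = check, pass = pass,
                                             detail = detail)
  }

  ## counting bounds vs exhaustive enumeration
  for (n in c(3L, 4L)) {
    obs <- observed_count_maxima(max_atoms, n)
    bound <- max_counts_per_atom(n)
    within <- obs$n_b <= bound["n_b"] && obs$n_a <= bound["n_a"] &&
      obs$n_t <= bound["n_t"]
    add(sprintf("count bounds hold (max degree %d, <= %d atoms)", n, max_atoms),
        within, sprintf("observed %d/%d/%d vs bound %d/%d/%d", obs$n_b, obs$n_a,
                        obs$n_t, bound["n_b"], bound["n_a"], bound["n_t"]))
  }

  ## finite-difference gradient spot checks
  fd_ok <- TRUE
  for (rep in 1:10) {
    pos <- matrix(stats::rnorm(12, sd = 1.2), 4, 3)
    fn <- function(p) dihedral_forces(matrix(p, 4, 3), rbind(1:4), 0.3, 2, pi)$energy
    F <- dihedral_forces(pos, rbind(1:4), 0.3, 2, pi)$forces
    g <- vapply(seq_len(12), function(i) {
      h <- 1e-6; xp <- as.vector(pos); xm <- xp
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (fn(xp) - fn(xm)) / (2 * h)
    }, numeric(1))
    fd_ok <- fd_ok && max(abs(as.vector(F) + g)) < 1e-6
  }
  add("dihedral forces match finite differences", fd_ok)

  ## cell list vs brute force on a small slab + molecule
  slab <- build_fcc111_slab(8, 8, 3)
  sys <- place_molecule(slab, bipyridylbenzene(), height = 3.2)
  fc <- assemble_forces(sys, "cell")
  fb <- assemble_forces(sys, "brute")
  dev <- max(abs(fc$forces - fb$forces)) / max(abs(fb$forces))
  add("cell-list forces equal brute-force oracle", dev < 1e-10,
      sprintf("max relative deviation %.2e", dev))

  ## parameter validation catches corruption
  bad <- default_forcefield()
  bad$pair$C$sigma <- -1
  caught <- tryCatch({ validate_forcefield(bad); FALSE },
                     steermd_bad_params = function(e) TRUE)
  add("corrupted parameter rejected", caught)

  ## topology round trip
  tf <- tempfile(fileext = ".json")
  write_topology(bipyridylbenzene(), tf)
  rt <- read_topology(tf)
  same <- identical(rt$graph$bonds, bipyridylbenzene()$graph$bonds) &&
    max(abs(rt$graph$atoms$x - bipyridylbenzene()$graph$atoms$x)) < 1e-12
  unlink(tf)
  add("topology JSON round trip", same)

  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$pass)
  out
}

#' Operation-count scaling benchmark
#'
#' Builds fixed-density slabs of increasing size, counts candidate pairs
#' from the cell list and compares with the brute-force count N(N-1)/2,
#' reporting hardware-independent least-squares log-log slopes. The
#' cell-list count grows linearly in N (slope ~ 1), the brute-force count
#' quadratically (slope ~ 2).
#'
#' @param N_target approximate atom counts (default c(500, 1000, 2000,
#'   4000, 8000)); realized as nx * nx * 3-layer slabs.
#' @param layers slab thickness (default 3).
#' @param file optional CSV output path.
#' @return data.frame (N, engine, candidate_pairs, filtered_pairs) with
#'   attribute `slopes` = c(cell, brute).
#' @export
bench_pairs <- function(N_target = c(500, 1000, 2000, 4000, 8000),
                        layers = 3, file = NULL) {
  rows <- list()
  for (Nt in N_target) {
    nx <- max(2L, round(sqrt(Nt / layers)))
    slab <- build_fcc111_slab(nx, nx, layers)
    N <- nrow(slab$pos)
    grid <- cell_grid(slab$pos, 6.0)
    cand <- candidate_pairs(grid)
    filt <- filter_pairs(slab$pos, cand, 6.0)
    rows[[length(rows) + 1L]] <- data.frame(
      N = N, engine = c("cell", "brute"),
      candidate_pairs = c(nrow(cand), N * (N - 1) / 2),
      filtered_pairs = c(nrow(filt), nrow(filt)))
  }
  out <- do.call(rbind, rows)
  fit <- function(eng) {
    d <- out[out$engine == eng, ]
    unname(stats::coef(stats::lm(log(candidate_pairs) ~ log(N), d))[2])
  }
  attr(out, "slopes") <- c(cell = fit("cell"), brute = fit("brute"))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
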