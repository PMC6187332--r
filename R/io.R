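## File formats: extended XYZ snapshots/trajectories, JSON molecular
## topologies and the validated run configuration.

#' Write and read extended XYZ
#'
#' Snapshot format: atom count line, a comment line declaring
#' `Properties=species:S:1:pos:R:3:role:S:1`, then one
#' `element x y z role` line per atom at fixed precision. A trajectory is a
#' concatenation of frames. `read_xyz` inverts `write_xyz` exactly for
#' finite coordinates at the written precision; malformed headers or count
#' mismatches raise a parse error with the offending line number.
#'
#' @param frames a single `md_system`, or a list of them (multi-frame
#'   trajectory), or a list with `pos`/`species`/`role`.
#' @param file path.
#' @param digits coordinate precision (default 10 significant digits).
#' @return `write_xyz` returns `file` invisibly; `read_xyz` returns a list
#'   of frames, each a list with `pos`, `species`, `role`, `comment`.
#' @export
write_xyz <- function(frames, file, digits = 10) {
  if (inherits(frames, "md_system") ||
      (is.list(frames) && !is.null(frames$pos))) frames <- list(frames)
  con <- file(file, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$pos)
    role <- if (is.null(fr$role)) rep("atom", n) else fr$role
    writeLines(as.character(n), con)
    writeLines(sprintf("Properties=species:S:1:pos:R:3:role:S:1 t_fs=%.6f",
                       if (is.null(fr$time)) 0 else tu_to_fs(fr$time)), con)
    writeLines(sprintf("%s %.*g %.*g %.*g %s", fr$species,
                       digits, fr$pos[, 1], digits, fr$pos[, 2],
                       digits, fr$pos[, 3], role), con)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n))
      .stop_cond("steermd_parse_error",
                 sprintf("line %d: expected atom count, got '%s'", i, lines[i]))
    if (i + 1L + n > length(lines))
      .stop_cond("steermd_parse_error",
                 sprintf("line %d: frame declares %d atoms but file ends early", i, n))
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(tok) < 4L)
    if (length(bad) > 0)
      .stop_cond("steermd_parse_error",
                 sprintf("line %d: malformed atom line", i + 1L + bad[1]))
    species <- vapply(tok, `[`, character(1), 1)
    pos <- suppressWarnings(
      matrix(as.numeric(unlist(lapply(tok, `[`, 2:4))), n, 3, byrow = TRUE))
    if (any(!is.finite(pos)))
      .stop_cond("steermd_parse_error",
                 sprintf("non-numeric coordinate in frame starting at line %d", i))
    role <- vapply(tok, function(x) if (length(x) >= 5) x[5] else "atom",
                   character(1))
    frames[[length(frames) + 1L]] <-
      list(pos = pos, species = species, role = role, comment = comment)
    i <- i + 2L + n
  }
  frames
}

#' Write and read JSON molecular topologies
#'
#' Schema: `{"atoms": [{"element", "mass", "x", "y", "z"}, ...],`
#' `"bonds": [[i, j], ...]}` with 0-based atom indices. A bond may instead
#' be an object `{"i", "j", "r0", "k"}` carrying per-bond harmonic parameter
#' overrides (how non-default bonds such as inter-ring single bonds are
#' encoded).
#'
#' @param molecule list with `graph` (a [molecular_graph()] whose atoms
#'   carry coordinates) and optional `overrides`, as from
#'   [bipyridylbenzene()].
#' @param file path.
#' @param max_degree,require_connected validation settings for the graph.
#' @return `read_topology` returns a list with `graph` and `overrides`.
#' @export
write_topology <- function(molecule, file) {
  g <- molecule$graph
  atoms <- lapply(seq_len(nrow(g$atoms)), function(i) {
    a <- g$atoms[i, ]
    list(element = a$element, mass = a$mass,
         x = if (is.null(a$x)) 0 else a$x,
         y = if (is.null(a$y)) 0 else a$y,
         z = if (is.null(a$z)) 0 else a$z)
  })
  ov <- molecule$overrides
  bonds <- lapply(seq_len(nrow(g$bonds)), function(r) {
    i <- g$bonds[r, 1]; j <- g$bonds[r, 2]
    hit <- if (is.null(ov)) integer(0)
    else which((ov$i == i & ov$j == j) | (ov$i == j & ov$j == i))
    if (length(hit) == 0) return(c(i, j) - 1L)
    out <- list(i = i - 1L, j = j - 1L)
    if (!is.null(ov$r0) && !is.na(ov$r0[hit[1]])) out$r0 <- ov$r0[hit[1]]
    if (!is.null(ov$k) && !is.na(ov$k[hit[1]])) out$k <- ov$k[hit[1]]
    out
  })
  jsonlite::write_json(list(atoms = atoms, bonds = bonds), file,
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_topology
#' @export
read_topology <- function(file, max_degree = 3L, require_connected = TRUE) {
  doc <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  if (is.null(doc$atoms) || is.null(doc$bonds))
    .stop_cond("steermd_parse_error", "topology JSON needs 'atoms' and 'bonds'")
  atoms <- do.call(rbind, lapply(doc$atoms, function(a)
    data.frame(element = a$element,
               mass = if (is.null(a$mass)) NA_real_ else a$mass,
               x = a$x %0% 0, y = a$y %0% 0, z = a$z %0% 0)))
  bonds <- matrix(0L, length(doc$bonds), 2)
  ov <- list()
  for (r in seq_along(doc$bonds)) {
    b <- doc$bonds[[r]]
    if (!is.null(names(b))) {
      bonds[r, ] <- c(b$i, b$j) + 1L
      o <- data.frame(i = b$i + 1L, j = b$j + 1L,
                      r0 = b$r0 %0% NA_real_, k = b$k %0% NA_real_)
      ov[[length(ov) + 1L]] <- o
    } else {
      bonds[r, ] <- unlist(b) + 1L
    }
  }
  overrides <- if (length(ov) > 0) do.call(rbind, ov) else NULL
  list(graph = molecular_graph(atoms, bonds, max_degree = max_degree,
                               require_connected = require_connected),
       overrides = overrides)
}

`%0%` <- function(a, b) if (is.null(a)) b else a

#' Validated run configuration
#'
#' Collects every tunable of a run with schema validation up front, and
#' tracks provenance: settings fixed by the method itself
#' (`cell capacity`, `refresh interval`, planar degree cap) versus package
#' defaults that users are expected to adapt. [dump_effective_config()]
#' writes the fully resolved configuration as JSON -- together with the
#' seed, this is sufficient to reproduce a single-threaded run bit for bit.
#'
#' @param slab `c(nx, ny, layers)` of the substrate.
#' @param tip_layers tip layer count (0 = no tip).
#' @param molecule `"bipyridylbenzene"`, a topology JSON path, or NA.
#' @param height adsorption height (A).
#' @param dt_large,alpha,gamma,k_cycles see [mts_config()].
#' @param cutoff,cap,refresh_interval,skin neighbor-search settings.
#' @param max_step quasi-static steering guard (A/cycle).
#' @param seed RNG seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(slab = c(12, 12, 3), tip_layers = 3,
                       molecule = "bipyridylbenzene", height = 3.0,
                       dt_large = 5, alpha = 20L, gamma = 1e-3,
                       k_cycles = 10L, cutoff = 6.0, cap = 32L,
                       refresh_interval = 20L, skin = 0.3,
                       max_step = 0.02, seed = 1L) {
  if (length(slab) != 3 || any(slab < 1))
    .stop_cond("steermd_bad_config", "slab must be c(nx, ny, layers), all >= 1")
  if (cutoff <= 0 || cap < 1 || refresh_interval < 1 || skin < 0)
    .stop_cond("steermd_bad_config", "invalid neighbor settings")
  if (max_step <= 0) .stop_cond("steermd_bad_config", "max_step must be > 0")
  mts <- mts_config(dt_large, alpha, gamma, k_cycles, refresh_interval)
  structure(list(slab = slab, tip_layers = tip_layers, molecule = molecule,
                 height = height, mts = mts, cutoff = cutoff,
                 cap = as.integer(cap),
                 refresh_interval = as.integer(refresh_interval), skin = skin,
                 max_step = max_step, seed = as.integer(seed),
                 provenance = c(cap = "method", refresh_interval = "method",
                                everything_else = "package")),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param file output JSON path.
#' @export
dump_effective_config <- function(cfg, file) {
  out <- unclass(cfg)
  out$mts <- unclass(out$mts)
  out$provenance <- as.list(out$provenance)
  out$package_version <- as.character(utils::packageVersion("steermd"))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
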