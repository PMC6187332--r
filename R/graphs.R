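## Exhaustive enumeration of small connected graphs with bounded degree.
##
## Used to validate the closed-form per-atom force-count bounds: the maxima
## observed over every isomorphism class of connected graphs with <= max_atoms
## vertices and degree <= max_degree must match max_counts_per_atom().

canonical_edge_key <- function(edges, n) {
  if (nrow(edges) == 0) return(paste0("n", n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)))
  perm <- igraph::canonical_permutation(g)$labeling
  e2 <- matrix(perm[edges], ncol = 2)
  e2 <- t(apply(e2, 1, sort))
  dim(e2) <- c(length(e2) %/% 2L, 2L)
  e2 <- e2[order(e2[, 1], e2[, 2]), , drop = FALSE]
  paste0("n", n, ":", paste(e2[, 1], e2[, 2], sep = "-", collapse = ","))
}

#' Exhaustively enumerate small connected bounded-degree graphs
#'
#' Generates one representative per isomorphism class of the connected simple
#' graphs with at most `max_atoms` vertices and maximum vertex degree at most
#' `max_degree`. Graphs are grown by vertex augmentation: every connected
#' graph on v+1 vertices arises from a connected graph on v vertices by adding
#' back a non-cut vertex together with its incident edges, so attaching a new
#' vertex to every admissible non-empty neighbor subset of every v-vertex
#' class and deduplicating by canonical form (BLISS, via igraph) is complete.
#'
#' @param max_atoms largest vertex count to enumerate (the single-vertex graph
#'   is included).
#' @param max_degree degree bound.
#' @return list of graphs, each a list with `n` (vertex count) and `edges`
#'   (two-column matrix, `i < j`).
#' @examples
#' length(enumerate_connected_graphs(4, 3)) # 1 + 1 + 2 + 6 classes
#' @export
enumerate_connected_graphs <- function(max_atoms, max_degree) {
  stopifnot(max_atoms >= 1, max_degree >= 1)
  empty <- matrix(integer(0), 0, 2)
  frontier <- list(list(n = 1L, edges = empty))
  out <- frontier
  v <- 1L
  while (v < max_atoms) {
    seen <- new.env(hash = TRUE, parent = emptyenv())
    nxt <- list()
    for (g in frontier) {
      deg <- tabulate(g$edges, nbins = g$n)
      open <- which(deg < max_degree)
      if (length(open) == 0) next
      for (sz in seq_len(min(max_degree, length(open)))) {
        subs <- utils::combn(seq_along(open), sz) # index combn: robust to length-1 'open'
        for (cc in seq_len(ncol(subs))) {
          s <- open[subs[, cc]]
          edges2 <- rbind(g$edges, cbind(s, g$n + 1L))
          key <- canonical_edge_key(edges2, g$n + 1L)
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- list(n = g$n + 1L, edges = edges2)
          }
        }
      }
    }
    out <- c(out, nxt)
    frontier <- nxt
    v <- v + 1L
  }
  out
}

#' Observed per-atom force-count maxima by exhaustive enumeration
#'
#' Enumerates every connected graph class with at most `max_atoms` atoms and
#' degree at most `max_degree`, counts for every atom the bond, angle and
#' dihedral tuples it participates in, and returns the maxima. With
#' `max_atoms = 8` this reproduces the closed-form bounds of
#' [max_counts_per_atom()] exactly, for both `max_degree = 3` and `4`.
#'
#' @inheritParams enumerate_connected_graphs
#' @return list with `n_b`, `n_a`, `n_t` (observed maxima), `n_graphs`
#'   (number of classes inspected) and `argmax` (graphs attaining each bound).
#' @export
observed_count_maxima <- function(max_atoms, max_degree) {
  graphs <- enumerate_connected_graphs(max_atoms, max_degree)
  best <- c(n_b = 0L, n_a = 0L, n_t = 0L)
  argmax <- list(n_b = NULL, n_a = NULL, n_t = NULL)
  for (g in graphs) {
    mg <- molecular_graph(data.frame(element = rep("C", g$n)), g$edges,
                          max_degree = max_degree)
    part <- tuple_participation(mg)
    cur <- c(n_b = max(part$n_bond), n_a = max(part$n_angle),
             n_t = max(part$n_dihedral))
    for (nm in names(best)) {
      if (cur[nm] > best[nm]) {
        best[nm] <- cur[nm]
        argmax[[nm]] <- g
      }
    }
  }
  list(n_b = unname(best["n_b"]), n_a = unname(best["n_a"]),
       n_t = unname(best["n_t"]), n_graphs = length(graphs), argmax = argmax)
}
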