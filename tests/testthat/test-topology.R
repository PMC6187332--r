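test_that("graph validation rejects malformed input with distinct errors", {
  at <- data.frame(element = c("C", "C", "C"))
  expect_s3_class(molecular_graph(at[1:2, , drop = FALSE], rbind(c(1, 2))),
                  "molecular_graph")
  expect_error(molecular_graph(at, rbind(c(1, 1))), class = "steermd_self_bond")
  expect_error(molecular_graph(at, rbind(c(1, 2), c(2, 1))),
               class = "steermd_duplicate_bond")
  expect_error(molecular_graph(at, rbind(c(1, 4))), class = "steermd_index_error")
  expect_error(
    molecular_graph(data.frame(element = rep("C", 5)),
                    rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5))),
    class = "steermd_degree_error")
  expect_error(molecular_graph(at, rbind(c(1, 2))),
               class = "steermd_disconnected")
  expect_error(molecular_graph(data.frame(element = "Xx"), NULL),
               class = "steermd_bad_atoms")
})

test_that("degrees and masses are computed on construction", {
  g <- molecular_graph(data.frame(element = c("C", "H")), rbind(c(1, 2)))
  expect_equal(g$degree, c(1L, 1L))
  expect_equal(g$atoms$mass, c(12.011, 1.008))
})

test_that("angle and dihedral enumeration matches brute-force path search", {
  cases <- list(
    path3 = list(n = 3, bonds = rbind(c(1, 2), c(2, 3))),
    path4 = list(n = 4, bonds = rbind(c(1, 2), c(2, 3), c(3, 4))),
    star3 = list(n = 4, bonds = rbind(c(1, 2), c(1, 3), c(1, 4))),
    benzeneH = list(n = 12, bonds = rbind(cbind(1:6, c(2:6, 1)), cbind(1:6, 7:12))),
    k4 = list(n = 4, bonds = t(combn(4, 2)))
  )
  expected_counts <- list(path3 = c(1, 0), path4 = c(2, 1), star3 = c(3, 0),
                          benzeneH = c(18, 24), k4 = c(12, 12))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    g <- molecular_graph(data.frame(element = rep("C", cs$n)), cs$bonds)
    ang <- enumerate_angles(g)
    dih <- enumerate_dihedrals(g)
    expect_equal(nrow(ang), expected_counts[[nm]][1], info = nm)
    expect_equal(nrow(dih), expected_counts[[nm]][2], info = nm)
    ba <- brute_angles(g$bonds, cs$n)
    expect_setequal(paste(ang[, 1], ang[, 2], ang[, 3]),
                    paste(ba[, 1], ba[, 2], ba[, 3]))
    bd <- brute_dihedrals(g$bonds, cs$n)
    canon_quad <- function(q) {
      flip <- q[, 2] > q[, 3] | (q[, 2] == q[, 3])
      out <- q
      out[flip, ] <- q[flip, 4:1]
      paste(out[, 1], out[, 2], out[, 3], out[, 4])
    }
    if (nrow(dih) > 0 || nrow(bd) > 0)
      expect_setequal(canon_quad(dih), canon_quad(bd))
    # canonical ordering invariants
    if (nrow(ang) > 0) expect_true(all(ang[, 1] < ang[, 3]))
    if (nrow(dih) > 0) expect_true(all(dih[, 2] < dih[, 3] & dih[, 1] != dih[, 4]))
    expect_equal(anyDuplicated(ang), 0)
    expect_equal(anyDuplicated(dih), 0)
  }
})

test_that("tuple count identities hold on random triangle-free graphs", {
  set.seed(7)
  for (rep in 1:20) {
    # random tree plus optional even cycle closure: triangle-free
    n <- sample(4:10, 1)
    bonds <- cbind(2:n, vapply(2:n, function(v) sample(v - 1, 1), integer(1)))
    g <- tryCatch(
      molecular_graph(data.frame(element = rep("C", n)), bonds, max_degree = n),
      error = function(e) NULL)
    if (is.null(g)) next
    deg <- g$degree
    expect_equal(nrow(enumerate_angles(g)), sum(choose(deg, 2)))
    expect_equal(nrow(enumerate_dihedrals(g)),
                 sum((deg[g$bonds[, 1]] - 1) * (deg[g$bonds[, 2]] - 1)))
  }
})

test_that("enumeration is invariant under atom relabeling", {
  set.seed(11)
  bonds <- rbind(cbind(1:6, c(2:6, 1)), cbind(1:6, 7:12))
  g <- molecular_graph(data.frame(element = rep("C", 12)), bonds)
  for (rep in 1:5) {
    p <- sample(12)
    g2 <- molecular_graph(data.frame(element = rep("C", 12)),
                          matrix(p[bonds], ncol = 2))
    a1 <- enumerate_angles(g); a2 <- enumerate_angles(g2)
    # map relabeled tuples back and compare as unordered angle sets
    back <- integer(12); back[p] <- 1:12
    a2b <- matrix(back[a2], ncol = 3)
    key <- function(a) paste(pmin(a[, 1], a[, 3]), a[, 2], pmax(a[, 1], a[, 3]))
    expect_setequal(key(a1), key(a2b))
    expect_equal(nrow(enumerate_dihedrals(g2)), nrow(enumerate_dihedrals(g)))
  }
})

test_that("closed-form per-atom maxima match the published planar and tetrahedral values", {
  expect_equal(max_counts_per_atom(3), c(n_b = 3L, n_a = 9L, n_t = 24L))
  expect_equal(max_counts_per_atom(4), c(n_b = 4L, n_a = 18L, n_t = 72L))
  expect_equal(max_counts_per_atom(1), c(n_b = 1L, n_a = 0L, n_t = 0L))
  expect_error(max_counts_per_atom(0), class = "steermd_domain_error")
  expect_error(max_counts_per_atom(2.5), class = "steermd_domain_error")
})

test_that("graph enumerator agrees with labeled brute-force classes (<= 5 atoms)", {
  for (dg in c(3L, 4L)) {
    gr <- enumerate_connected_graphs(5, dg)
    sizes <- vapply(gr, `[[`, integer(1), "n")
    for (n in 1:5) {
      expect_equal(sum(sizes == n), brute_connected_classes(n, dg),
                   info = sprintf("n=%d deg<=%d", n, dg))
    }
  }
})

test_that("participation never exceeds the closed-form bound on small graphs", {
  for (dg in 2:4) {
    bound <- max_counts_per_atom(dg)
    obs <- observed_count_maxima(6, dg)
    expect_lte(obs$n_b, bound[["n_b"]])
    expect_lte(obs$n_a, bound[["n_a"]])
    expect_lte(obs$n_t, bound[["n_t"]])
    # bond and angle bounds are already attained by 6-atom graphs
    expect_equal(obs$n_b, bound[["n_b"]])
    expect_equal(obs$n_a, bound[["n_a"]])
  }
})

test_that("the bundled molecule has the expected planar topology", {
  mol <- bipyridylbenzene()
  g <- mol$graph
  expect_equal(nrow(g$atoms), 30)
  expect_equal(table(g$atoms$element)[["C"]], 16)
  expect_equal(table(g$atoms$element)[["N"]], 2)
  expect_equal(table(g$atoms$element)[["H"]], 12)
  expect_equal(nrow(g$bonds), 32)
  expect_equal(max(g$degree), 3)
  expect_equal(nrow(enumerate_angles(g)), 50)
  expect_equal(nrow(enumerate_dihedrals(g)), 72)
  # against the independent brute-force path search
  expect_equal(nrow(brute_angles(g$bonds, 30)), 50)
  expect_equal(nrow(brute_dihedrals(g$bonds, 30)), 72)
  expect_true(all(g$atoms$z == 0))       # planar construction
})
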