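# UniFrac community distinctness and similarity-network assortativity.

test_that("unweighted UniFrac matches hand enumeration and boundaries", {
  tr <- read_tree("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(unifrac_unweighted(tr, c("A", "B"), c("A", "B")), 0)
  # disjoint root-partitioned subtrees -> 1
  expect_equal(unifrac_unweighted(tr, c("A", "B"), c("C", "D")), 1)
  # hand enumeration: unique {B, C, stem(CD)} over covered 5 branches
  expect_equal(unifrac_unweighted(tr, c("A", "B"), c("A", "C")), 0.6)
  # symmetry
  expect_equal(unifrac_unweighted(tr, c("A", "C"), c("A", "B")), 0.6)
  expect_error(unifrac_unweighted(tr, character(0), "A"), "non-empty")
  expect_error(unifrac_unweighted(tr, "Z", "A"), "not in tree")
})

test_that("UniFrac agrees with picante on random communities", {
  skip_if_not_installed("picante")
  set.seed(7)
  tr <- ape::rtree(40)
  for (i in 1:5) {
    a <- sample(tr$tip.label, 12)
    b <- sample(tr$tip.label, 15)
    comm <- matrix(0, 2, 40, dimnames = list(c("A", "B"), tr$tip.label))
    comm["A", a] <- 1
    comm["B", b] <- 1
    ref <- as.numeric(picante::unifrac(comm, tr))
    expect_equal(unifrac_unweighted(tr, a, b), ref, tolerance = 1e-10)
  }
})

test_that("moving a tip from shared to unique never decreases UniFrac", {
  set.seed(21)
  tr <- ape::rtree(30)
  a <- sample(tr$tip.label, 14)
  b <- sample(tr$tip.label, 14)
  shared <- intersect(a, b)
  d0 <- unifrac_unweighted(tr, a, b)
  for (tp in shared) {
    expect_gte(unifrac_unweighted(tr, a, setdiff(b, tp)), d0 - 1e-12)
  }
})

test_that("permutation significance is calibrated and reproducible", {
  set.seed(5)
  tr <- ape::rtree(100)
  # identical communities: distance 0, p about 1
  same <- list(s1 = tr$tip.label[1:30], s2 = tr$tip.label[1:30])
  r0 <- unifrac_significance(tr, same, n_perm = 99, seed = 1)
  expect_equal(r0$pairs$distance, 0)
  expect_equal(r0$pairs$p, 1)
  # perfectly partitioned communities reach the permutation minimum
  nt <- length(tr$tip.label)
  root_kids <- tr$edge[tr$edge[, 1] == nt + 1L, 2]
  side <- habtrans:::descendant_tips(tr, root_kids[1])
  part <- list(L = tr$tip.label[side], R = setdiff(tr$tip.label,
                                                   tr$tip.label[side]))
  r1 <- unifrac_significance(tr, part, n_perm = 1000, seed = 2)
  expect_equal(r1$pairs$distance, 1)
  expect_equal(r1$pairs$p, 1 / 1001)
  # seed-fixed reproducibility
  comm <- list(x = sample(tr$tip.label, 20), y = sample(tr$tip.label, 20),
               z = sample(tr$tip.label, 20))
  a <- unifrac_significance(tr, comm, n_perm = 49, seed = 11)
  b <- unifrac_significance(tr, comm, n_perm = 49, seed = 11)
  expect_identical(a$pairs, b$pairs)
  # Bonferroni across the three pairs
  expect_equal(a$pairs$p_adj, pmin(1, a$pairs$p * 3))
  # UPGMA dendrogram over the distance matrix
  dend <- unifrac_upgma(a$dist)
  expect_s3_class(dend, "phylo")
  expect_setequal(dend$tip.label, c("x", "y", "z"))
})

test_that("hit tables parse strictly and build filtered graphs", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "a1\ta2\t92\t450\t10\t2\t1\t450\t1\t450\t1e-50\t800",
    "a1\tb1\t85\t480\t20\t3\t1\t480\t1\t480\t1e-40\t700",
    "b1\tb2\t78\t400\t30\t4\t1\t400\t1\t400\t1e-30\t600",
    "a1\ta1\t100\t500\t0\t0\t1\t500\t1\t500\t0\t999"
  )
  writeLines(rows, tf)
  hits <- read_blast_hits(tf)
  expect_equal(nrow(hits), 4L)
  habs <- c(a1 = "marine", a2 = "marine", b1 = "non_marine",
            b2 = "non_marine")
  lens <- c(a1 = 500, a2 = 500, b1 = 500, b2 = 500)
  g <- build_graph(hits, habs, identity_threshold = 85,
                   coverage_threshold = 75, seq_lengths = lens)
  # identities {92, 85, 78} at threshold 85 -> 2 edges; self-hit dropped
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(sum(igraph::which_loop(g)), 0L)
  # raising the identity threshold never adds edges
  g2 <- build_graph(hits, habs, identity_threshold = 90,
                    coverage_threshold = 75, seq_lengths = lens)
  expect_lte(igraph::ecount(g2), igraph::ecount(g))
  # coverage filter: shrink b1-b2 alignment below 75% of 500
  writeLines(c(rows[1:2], "b1\tb2\t95\t300\t5\t0\t1\t300\t1\t300\t1e-20\t500"),
             tf)
  g3 <- build_graph(read_blast_hits(tf), habs, identity_threshold = 85,
                    coverage_threshold = 75, seq_lengths = lens)
  expect_equal(igraph::ecount(g3), 2L)  # 300/500 = 60% fails coverage
  # malformed rows are named by line
  writeLines(c(rows[1], "broken\trow"), tf)
  expect_error(read_blast_hits(tf), "line 2")
  # empty table -> empty graph
  writeLines(character(0), tf)
  g4 <- build_graph(read_blast_hits(tf), habs, identity_threshold = 80,
                    coverage_threshold = NULL)
  expect_equal(igraph::ecount(g4), 0L)
})

test_that("assortativity matches the mixing-matrix hand computation", {
  mk_graph <- function(edges, habs) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(
                                         name = names(habs),
                                         habitat = unname(habs)))
    g
  }
  habs <- c(a1 = "marine", a2 = "marine", b1 = "non_marine",
            b2 = "non_marine")
  # edges only within habitats -> 1
  g1 <- mk_graph(data.frame(from = c("a1", "b1"), to = c("a2", "b2")), habs)
  expect_equal(graph_assortativity(g1), 1)
  # complete bipartite across habitats -> -1
  g2 <- mk_graph(data.frame(from = c("a1", "a1", "a2", "a2"),
                            to = c("b1", "b2", "b1", "b2")), habs)
  expect_equal(graph_assortativity(g2), -1)
  # hand mixing matrix: {a1-a2, b1-b2, a1-b1} -> 1/3
  g3 <- mk_graph(data.frame(from = c("a1", "b1", "a1"),
                            to = c("a2", "b2", "b1")), habs)
  expect_equal(graph_assortativity(g3), 1 / 3, tolerance = 1e-12)
  # invariant under swapping the habitat labels
  habs_sw <- ifelse(habs == "marine", "non_marine", "marine")
  names(habs_sw) <- names(habs)
  g3s <- mk_graph(data.frame(from = c("a1", "b1", "a1"),
                             to = c("a2", "b2", "b1")), habs_sw)
  expect_equal(graph_assortativity(g3s), 1 / 3, tolerance = 1e-12)
  # edgeless graph is an error
  g0 <- mk_graph(data.frame(from = character(0), to = character(0)), habs)
  expect_error(graph_assortativity(g0), "edgeless")
})
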