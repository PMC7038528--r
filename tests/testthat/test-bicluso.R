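block_edges <- function(mirnas, genes) {
  expand.grid(mirna_id = mirnas, gene_id = genes, stringsAsFactors = FALSE)
}

test_that("tanimoto coefficient follows set arithmetic", {
  expect_equal(tanimoto(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(tanimoto(c("g1", "g2", "g3"), c("g2", "g3", "g4")), 0.5)
  expect_equal(tanimoto("a", "b"), 0.0)
  expect_equal(tanimoto(character(0), character(0)), 0.0)
})

test_that("folding connects miRNAs by shared-target count OR Tanimoto", {
  p <- bicluso_params()
  # u,v share 3 targets but tanimoto is low: relation number applies
  u_t <- sprintf("G%02d", 1:20)
  v_t <- c(sprintf("G%02d", 1:3), sprintf("H%02d", 1:15))
  g1 <- bipartite_graph(rbind(block_edges("u", u_t), block_edges("v", v_t)))
  expect_lt(tanimoto(u_t, v_t), p$tanimoto_min)
  f1 <- fold_bipartite(g1, p)
  expect_equal(nrow(f1$edges), 1L)

  # only 2 shared targets, but identical target sets: tanimoto applies
  g2 <- bipartite_graph(rbind(block_edges("u", c("G1", "G2")),
                              block_edges("v", c("G1", "G2"))))
  expect_equal(nrow(fold_bipartite(g2, p)$edges), 1L)

  # no shared targets: no association
  g3 <- bipartite_graph(rbind(block_edges("u", "G1"), block_edges("v", "G2")))
  expect_equal(nrow(fold_bipartite(g3, p)$edges), 0L)
})

test_that("folding matches a brute-force pair oracle and ignores edge order", {
  p <- bicluso_params()
  set.seed(17)
  for (rep in 1:20) {
    g <- rand_bipartite(sample(3:8, 1), sample(4:12, 1), stats::runif(1, 0.1, 0.6))
    f <- fold_bipartite(g, p)
    expect_equal(f$edges, fold_edges_oracle(g, p), ignore_attr = TRUE)
    # permuted edge list folds identically
    perm <- g$edges[sample(nrow(g$edges)), , drop = FALSE]
    g_perm <- bipartite_graph(perm, mirnas = g$mirnas, genes = g$genes)
    expect_equal(fold_bipartite(g_perm, p)$edges, f$edges)
    # symmetry: each edge stored once with u < v
    expect_true(all(f$edges$u < f$edges$v))
  }
})

triangle <- function() {
  g <- bipartite_graph(rbind(block_edges(c("a", "b"), sprintf("G%d", 1:3)),
                             block_edges(c("b", "c"), sprintf("H%d", 1:3)),
                             block_edges(c("a", "c"), sprintf("K%d", 1:3))))
  fold_bipartite(g, bicluso_params())
}

test_that("graph density follows 2E/(n(n-1)) with singleton convention", {
  f <- triangle()
  expect_equal(graph_density(c("a", "b", "c"), f), 1.0)
  expect_equal(graph_density("a", f), 1.0)
  expect_error(graph_density(c("a", "zz"), f), "zz")

  # path of 3: remove one association
  g <- bipartite_graph(rbind(block_edges(c("a", "b"), sprintf("G%d", 1:3)),
                             block_edges(c("b", "c"), sprintf("H%d", 1:3)),
                             block_edges("d", "X1"), block_edges("e", "X2")))
  f2 <- fold_bipartite(g, bicluso_params())
  expect_equal(graph_density(c("a", "b", "c"), f2), 2 / 3)
  expect_equal(graph_density(c("d", "e"), f2), 0.0)
})

test_that("cluster property normalizes connectivity by density and size", {
  # v adjacent to all of a triangle
  g <- bipartite_graph(rbind(
    block_edges(c("a", "b"), sprintf("G%d", 1:3)),
    block_edges(c("b", "c"), sprintf("H%d", 1:3)),
    block_edges(c("a", "c"), sprintf("K%d", 1:3)),
    block_edges(c("v", "a"), sprintf("P%d", 1:3)),
    block_edges(c("v", "b"), sprintf("Q%d", 1:3)),
    block_edges(c("v", "c"), sprintf("R%d", 1:3))))
  f <- fold_bipartite(g, bicluso_params())
  expect_equal(cluster_property("v", c("a", "b", "c"), f), 1.0)

  # 4-clique plus v adjacent to 2 of it
  g2 <- bipartite_graph(rbind(block_edges(c("a", "b", "c", "d"),
                                          sprintf("G%d", 1:4)),
                              block_edges(c("v", "a"), sprintf("P%d", 1:3)),
                              block_edges(c("v", "b"), sprintf("Q%d", 1:3))))
  f2 <- fold_bipartite(g2, bicluso_params())
  expect_equal(cluster_property("v", c("a", "b", "c", "d"), f2), 0.5)
  expect_equal(cluster_property("v", "c", f2), 0.0)
  expect_error(cluster_property("a", c("a", "b"), f2), "member")
})

test_that("density clustering finds cliques and allows overlap", {
  p <- bicluso_params()
  # empty graph
  g0 <- bipartite_graph(block_edges("a", "G1"))
  expect_length(dpcluso(fold_bipartite(g0, p), p), 0L)

  # a single triangle is one cluster of density 1
  cl <- dpcluso(triangle(), p)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, c("a", "b", "c"))
  expect_equal(cl[[1]]$density, 1.0)

  # two 4-cliques sharing one node: both found, shared node overlaps
  g <- bipartite_graph(rbind(block_edges(c("a", "b", "c", "s"), sprintf("G%d", 1:5)),
                             block_edges(c("s", "x", "y", "z"), sprintf("H%d", 1:5))))
  f <- fold_bipartite(g, p)
  cl2 <- dpcluso(f, p)
  keys <- vapply(cl2, function(c1) paste(c1$members, collapse = ","), character(1))
  expect_true("a,b,c,s" %in% keys)
  expect_true("s,x,y,z" %in% keys)
  expect_gte(sum(vapply(cl2, function(c1) "s" %in% c1$members, logical(1))), 2L)
})

test_that("every emitted cluster is dense and covers all non-isolated nodes", {
  p <- bicluso_params()
  set.seed(41)
  for (rep in 1:30) {
    g <- rand_bipartite(sample(4:10, 1), sample(5:15, 1),
                        sample(c(0.2, 0.35, 0.5), 1))
    f <- fold_bipartite(g, p)
    cl <- dpcluso(f, p)
    for (c1 in cl) {
      expect_gte(density_oracle(c1$members, f$edges) + 1e-12, p$density_min)
      expect_gte(length(c1$members), p$min_cluster_size)
      expect_true(c1$seed %in% c1$members)
    }
    non_isolated <- f$nodes[lengths(f$adj) > 0]
    in_any <- unique(unlist(lapply(cl, `[[`, "members")))
    expect_true(all(non_isolated %in% in_any))
    # no duplicate clusters
    keys <- vapply(cl, function(c1) paste(c1$members, collapse = ","), character(1))
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("gene attachment uses an inclusive majority-or-half threshold", {
  p <- bicluso_params()
  g <- bipartite_graph(rbind(block_edges(c("a", "b"), c("G1", "G2", "G3")),
                             block_edges("a", "G4"),
                             block_edges("zz", "G9")))
  f <- fold_bipartite(g, p)
  cl <- list(members = c("a", "b"), seed = "a", density = 1.0)
  bc <- attach_secondary(cl, g, p)
  # G1-G3 attach at ratio 1; G4 attaches at exactly 0.5 (inclusive); G9 not
  expect_setequal(bc$genes, c("G1", "G2", "G3", "G4"))

  strict <- bicluso_params(attachment_min = 0.6)
  expect_setequal(attach_secondary(cl, g, strict)$genes, c("G1", "G2", "G3"))
})

test_that("full biclustering recovers a planted complete block", {
  m <- planted_model(n_mirnas = 8, n_genes = 10,
                     blocks = list(list(mirnas = sprintf("mir%03d", 1:4),
                                        genes = sprintf("G%04d", 1:6))),
                     p_in = 1, p_out = 0, seed = 5)
  g <- generate_planted_mti(m)
  bcs <- run_bicluso(g$graph)
  expect_length(bcs, 1L)
  expect_equal(bcs[[1]]$mirnas, sprintf("mir%03d", 1:4))
  expect_equal(bcs[[1]]$genes, sprintf("G%04d", 1:6))
})

test_that("an unassociated graph yields no biclusters", {
  g <- bipartite_graph(data.frame(mirna_id = c("m1", "m2"),
                                  gene_id = c("G1", "G2")))
  expect_length(run_bicluso(g), 0L)
})

test_that("a miRNA shared by two planted blocks appears in both biclusters", {
  m <- planted_model(n_mirnas = 10, n_genes = 20,
                     blocks = list(list(mirnas = sprintf("mir%03d", 1:4),
                                        genes = sprintf("G%04d", 1:6)),
                                   list(mirnas = sprintf("mir%03d", 4:7),
                                        genes = sprintf("G%04d", 7:12))),
                     p_in = 1, p_out = 0, seed = 3)
  g <- generate_planted_mti(m)
  bcs <- run_bicluso(g$graph)
  with_shared <- Filter(function(b) "mir004" %in% b$mirnas, bcs)
  expect_gte(length(with_shared), 2L)
  keys <- vapply(bcs, function(b) paste(b$mirnas, collapse = ","), character(1))
  expect_true("mir001,mir002,mir003,mir004" %in% keys)
  expect_true("mir004,mir005,mir006,mir007" %in% keys)
})

test_that("gene-side folding transposes the roles of the two sides", {
  m <- planted_model(n_mirnas = 8, n_genes = 10,
                     blocks = list(list(mirnas = sprintf("mir%03d", 1:4),
                                        genes = sprintf("G%04d", 1:6))),
                     p_in = 1, p_out = 0, seed = 5)
  g <- generate_planted_mti(m)
  bcs <- run_bicluso(g$graph, side = "gene")
  expect_length(bcs, 1L)
  expect_equal(bcs[[1]]$mirnas, sprintf("mir%03d", 1:4))
  expect_equal(bcs[[1]]$genes, sprintf("G%04d", 1:6))
})

test_that("bicluster tables serialize one row per module", {
  m <- planted_model(n_mirnas = 20, n_genes = 40, n_blocks = 2,
                     p_in = 1, p_out = 0, seed = 9)
  g <- generate_planted_mti(m)
  bcs <- run_bicluso(g$graph)
  df <- biclusters_to_df(bcs)
  expect_equal(nrow(df), length(bcs))
  expect_true(all(df$density >= 0.5))
  path <- tempfile(fileext = ".tsv")
  write_biclusters_tsv(bcs, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$id, df$id)
})
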