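# PCC matrix, empirical cutoff, network construction, BFS leveling,
# level gene sets, z-score profiles

test_that("PCC matrix matches the direct formula and flags constants", {
  m <- tiny_matrix(rbind(1:5, c(2, 1, 4, 3, 6), 5:1, rep(7, 5)),
                   genes = c("x", "y", "negx", "flat"))
  p <- compute_pcc_matrix(m)
  # direct-formula oracle: r = 10 / sqrt(148)
  expect_equal(p$values["x", "y"], 10 / sqrt(148), tolerance = 1e-12)
  expect_equal(p$values["x", "y"], 0.8220, tolerance = 1e-4)
  expect_equal(p$values["x", "x"], 1)
  expect_equal(p$values["x", "negx"], -1)
  expect_identical(p$constant_genes, "flat")
  expect_false("flat" %in% rownames(p$values))
  expect_equal(p$values, t(p$values))

  expect_error(compute_pcc_matrix(m[, 1:2]), "3 columns")
  expect_error(compute_pcc_matrix(m, c("x", "ghost")), "ghost")
})

test_that("cutoff is the nearest-rank right-tail quantile", {
  # worked example: {0.00, 0.01, ..., 0.99} -> 0.94
  grid <- seq(0, 0.99, by = 0.01)
  expect_equal(nearest_rank_cutoff(grid, 0.05), 0.94)
  # degenerate cases
  expect_equal(nearest_rank_cutoff(rep(0.7, 10), 0.05), 0.7)
  expect_equal(nearest_rank_cutoff(0.5, 0.05), 0.5)

  # property on random multisets: member of the multiset, strict
  # exceedance below alpha, agrees with an independent characterization
  # (smallest member whose strict-exceedance fraction is < alpha)
  set.seed(3)
  for (i in 1:20) {
    vals <- round(runif(sample(5:400, 1), -1, 1), 3)
    cut <- nearest_rank_cutoff(vals, 0.05)
    expect_true(cut %in% vals)
    expect_lt(mean(vals > cut), 0.05)
    candidates <- sort(unique(vals))
    oracle <- min(candidates[vapply(candidates,
                                    function(v) mean(vals > v) < 0.05,
                                    logical(1))])
    expect_identical(cut, oracle)
  }

  # via a real PCC matrix
  set.seed(4)
  m <- tiny_matrix(matrix(rexp(50, 1 / 5), 10, 5))
  p <- compute_pcc_matrix(m)
  expect_equal(determine_cutoff(p, 0.05),
               sort(p$values[upper.tri(p$values)])[ceiling(0.95 * 45)])
  expect_error(determine_cutoff(p, 0), "alpha")
  expect_error(determine_cutoff(p, 1), "alpha")
})

test_that("network construction thresholds edges and keeps all nodes", {
  v <- matrix(c(1, 0.95, 0.5,
                0.95, 1, 0.91,
                0.5, 0.91, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  g <- build_gcn(fake_pcc(v), 0.9)
  expect_identical(g$edges$gene_a, c("A", "B"))
  expect_identical(g$edges$gene_b, c("B", "C"))
  expect_identical(g$nodes, c("A", "B", "C"))

  expect_equal(nrow(build_gcn(fake_pcc(v), 0.99)$edges), 0)
  expect_equal(nrow(build_gcn(fake_pcc(v), 0.5)$edges), 3)  # complete

  # monotonicity: raising the cutoff never adds edges
  set.seed(5)
  for (i in 1:10) {
    m <- tiny_matrix(matrix(rexp(48, 1 / 5), 8, 6))
    p <- compute_pcc_matrix(m)
    cuts <- sort(runif(2, 0.05, 0.95))
    lo <- build_gcn(p, cuts[1])$edges
    hi <- build_gcn(p, cuts[2])$edges
    key <- function(e) paste(e$gene_a, e$gene_b)
    expect_true(all(key(hi) %in% key(lo)))
  }
})

test_that("BFS levels equal max(1, shortest-path distance)", {
  nodes <- c("A", "B", "C", "D")
  path_net <- fake_network(nodes, edge_df(c("A", "B"), c("B", "C"),
                                          c("C", "D")))
  t1 <- assign_levels_bfs(path_net, "A")
  expect_equal(t1$levels, c(A = 1L, B = 1L, C = 2L, D = 3L))
  expect_identical(t1$unreached, character(0))

  # star: every node is a neighbor of the center
  star <- fake_network(c("hub", "s1", "s2", "s3"),
                       edge_df(c("hub", "s1"), c("hub", "s2"),
                               c("hub", "s3")))
  expect_true(all(assign_levels_bfs(star, "hub")$levels == 1L))

  # isolated seed: only the seed, with a warning
  iso <- fake_network(c("A", "B", "C"), edge_df(c("B", "C")))
  expect_warning(t_iso <- assign_levels_bfs(iso, "A"), "isolated")
  expect_equal(t_iso$levels, c(A = 1L))
  expect_identical(sort(t_iso$unreached), c("B", "C"))

  expect_error(assign_levels_bfs(path_net, "Z"), "not a node")
})

test_that("BFS agrees with an igraph oracle and ignores input order", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    g <- random_connected_edges(n)
    net <- fake_network(g$nodes, g$edges)
    seed <- sample(g$nodes, 1)
    got <- assign_levels_bfs(net, seed)
    want <- igraph_levels(g$nodes, g$edges, seed)
    expect_equal(unname(got$levels[g$nodes]), unname(want))

    # permuting nodes and edges changes nothing
    net2 <- fake_network(sample(g$nodes),
                         g$edges[sample(nrow(g$edges)), ])
    got2 <- assign_levels_bfs(net2, seed)
    expect_equal(got2$levels[g$nodes], got$levels[g$nodes])
  }
})

test_that("level gene sets honor the cutoff and allow multi-level genes", {
  # three TFs at levels 1, 2, 3 with orthogonal-ish profiles
  m <- tiny_matrix(rbind(c(10, 8, 2, 1, 0),
                         c(1, 6, 10, 6, 1),
                         c(0, 1, 2, 8, 10),
                         c(0, 1, 2, 8, 10),     # same as tf3
                         c(0.9, 6.1, 10, 6, 1.1), # close to tf2
                         c(5, 5.2, 5.1, 5, 5.3)), # unrelated
                   genes = c("tf1", "tf2", "tf3", "cand_l3", "cand_l2",
                             "cand_none"))
  t3 <- fake_togcn(c(tf1 = 1, tf2 = 2, tf3 = 3))
  t3$network <- fake_network(c("tf1", "tf2", "tf3"), NULL, cutoff = 0.95)
  sets <- assign_level_gene_sets(m, t3,
                                 candidates = c("cand_l3", "cand_l2",
                                                "cand_none"))
  expect_identical(sets[["3"]], "cand_l3")
  expect_identical(sets[["2"]], "cand_l2")
  expect_false("cand_none" %in% unlist(sets))

  # a gene passing the cutoff with TFs at two levels joins both sets
  m2 <- rbind(m, both = 0.5 * m["tf2", ] + 0.5 * m["tf3", ])
  sets2 <- assign_level_gene_sets(m2, t3, cutoff = 0.50,
                                  candidates = "both")
  expect_true("both" %in% sets2[["2"]] && "both" %in% sets2[["3"]])

  expect_warning(empty <- assign_level_gene_sets(m, t3,
                                                 candidates = character(0)),
                 "empty candidate")
  expect_true(all(lengths(empty) == 0))
})

test_that("mean z-score profiles standardize and average per level", {
  # two level-1 TFs whose z-vectors cancel
  m <- tiny_matrix(rbind(c(1, 3), c(3, 1), c(2, 8)),
                   genes = c("up", "down", "solo"),
                   samples = c("C1", "C2"))
  t2 <- fake_togcn(c(up = 1, down = 1, solo = 2))
  prof <- mean_zscore_profile(m, t2)
  expect_equal(unname(prof["1", ]), c(0, 0))
  # single-TF level equals that TF's z-vector (mean 0, pop SD 1)
  expect_equal(unname(prof["2", ]), c(-1, 1))

  set.seed(12)
  m5 <- tiny_matrix(matrix(rexp(20), 4, 5))
  t5 <- fake_togcn(stats::setNames(c(1, 1, 2, 2), rownames(m5)))
  p5 <- mean_zscore_profile(m5, t5)
  z1 <- (m5[1, ] - mean(m5[1, ])) / sqrt(mean((m5[1, ] - mean(m5[1, ]))^2))
  expect_equal(mean(z1), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean((z1 - mean(z1))^2)), 1, tolerance = 1e-9)

  # constant-profile TF excluded with a warning
  m5[2, ] <- 10
  expect_warning(mean_zscore_profile(m5, t5), rownames(m5)[2])
})

test_that("writers emit deterministic sorted TSV", {
  g <- fake_network(c("B", "A", "C"),
                    edge_df(c("B", "C", 0.93), c("A", "B", 0.95)))
  t_ <- assign_levels_bfs(g, "A")
  dir <- withr::local_tempdir()
  write_edge_list(g, file.path(dir, "e.tsv"))
  write_levels(t_, file.path(dir, "l.tsv"))
  e <- read.delim(file.path(dir, "e.tsv"))
  expect_identical(e$gene_a, c("A", "B"))
  l <- read.delim(file.path(dir, "l.tsv"))
  expect_identical(l$gene, c("A", "B", "C"))
  expect_identical(l$level, c(1L, 1L, 2L))
})
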