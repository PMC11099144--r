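# Shared in-code fixtures: tiny matrices, hand-built networks, and direct
# constructors for the S3 containers so unit tests can exercise one
# operation without running the whole pipeline.

tiny_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

tiny_sheet <- function(n_conditions = 5, replicates = 3,
                       prefix = "C") {
  conds <- sprintf("%s%d", prefix, seq_len(n_conditions))
  data.frame(
    sample_id = as.vector(t(outer(conds, seq_len(replicates), paste0))),
    condition = rep(conds, each = replicates),
    order = rep(seq_len(n_conditions), each = replicates),
    replicate = rep(sprintf("r%d", seq_len(replicates)), n_conditions),
    stringsAsFactors = FALSE)
}

# a pcc_matrix from an explicit symmetric matrix (dimnames required)
fake_pcc <- function(values, constant_genes = character(0)) {
  structure(list(values = values, gene_ids = rownames(values),
                 constant_genes = constant_genes),
            class = "pcc_matrix")
}

# a coexpression_network from an edge data.frame (gene_a, gene_b, pcc)
fake_network <- function(nodes, edges, cutoff = 0.9) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        pcc = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "coexpression_network")
}

edge_df <- function(...) {
  pairs <- list(...)
  data.frame(gene_a = vapply(pairs, `[[`, character(1), 1),
             gene_b = vapply(pairs, `[[`, character(1), 2),
             pcc = vapply(pairs, function(p) {
               if (length(p) > 2) as.numeric(p[[3]]) else 0.95
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

# a togcn directly from a named level vector
fake_togcn <- function(levels, seed = names(levels)[1],
                       unreached = character(0)) {
  structure(list(network = NULL, seed = seed,
                 levels = stats::setNames(as.integer(levels), names(levels)),
                 unreached = unreached),
            class = "togcn")
}

# random connected undirected graph as an edge data.frame over n nodes
random_connected_edges <- function(n, extra = n) {
  nodes <- sprintf("n%02d", seq_len(n))
  # random spanning tree, then extra random edges
  perm <- sample(nodes)
  a <- character(0); b <- character(0)
  for (i in seq_len(n - 1)) {
    a <- c(a, perm[sample.int(i, 1)])
    b <- c(b, perm[i + 1])
  }
  if (extra > 0) {
    ii <- sample.int(n, extra, replace = TRUE)
    jj <- sample.int(n, extra, replace = TRUE)
    keep <- ii != jj
    a <- c(a, nodes[ii[keep]])
    b <- c(b, nodes[jj[keep]])
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  ed <- unique(data.frame(gene_a = lo, gene_b = hi,
                          stringsAsFactors = FALSE))
  ed$pcc <- 0.95
  list(nodes = nodes, edges = ed)
}

# independent shortest-path oracle via igraph
igraph_levels <- function(nodes, edges, seed) {
  g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = nodes)
  d <- igraph::distances(g, v = seed, to = nodes)[1, ]
  d <- d[nodes]
  lev <- pmax(1, d)
  lev[is.infinite(lev)] <- NA
  lev
}

# exhaustive hypergeometric upper-tail oracle
enum_upper_tail <- function(k, term_size, draws, bg) {
  j <- seq(k, min(term_size, draws))
  sum(choose(term_size, j) * choose(bg - term_size, draws - j)) /
    choose(bg, draws)
}
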