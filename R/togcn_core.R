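# TO-GCN core: PCC matrix, empirical cutoff, co-expression graph, BFS time
# order, per-level gene sets, and level z-score profiles.

#' Pairwise Pearson correlation over a gene set
#'
#' Computes the full symmetric PCC matrix over the requested genes using
#' their expression profiles across columns (conditions or replicate-level
#' samples). Genes with constant profiles have no defined correlation; they
#' are excluded from the matrix and reported in `constant_genes`.
#'
#' @param m validated expression matrix (>= 3 columns).
#' @param genes character vector of gene IDs to correlate; must be rows of
#'   `m`.
#' @return an object of class `pcc_matrix`: list with `values` (symmetric
#'   numeric matrix, unit diagonal), `gene_ids`, and `constant_genes`.
#' @export
compute_pcc_matrix <- function(m, genes = rownames(m)) {
  validate_expression_matrix(m)
  if (ncol(m) < 3) {
    stop("need at least 3 columns to compute stable correlations",
         call. = FALSE)
  }
  unknown <- setdiff(genes, rownames(m))
  if (length(unknown) > 0) {
    stop("gene(s) not in matrix: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sub <- m[genes, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  constant <- rownames(sub)[sds == 0]
  keep <- rownames(sub)[sds > 0]
  vals <- stats::cor(t(sub[keep, , drop = FALSE]))
  diag(vals) <- 1
  structure(list(values = vals, gene_ids = keep, constant_genes = constant),
            class = "pcc_matrix")
}

#' @export
print.pcc_matrix <- function(x, ...) {
  cat(sprintf("PCC matrix over %d genes (%d constant gene(s) excluded)\n",
              length(x$gene_ids), length(x$constant_genes)))
  invisible(x)
}

#' Empirical co-expression cutoff
#'
#' Returns the nearest-rank (1 - alpha) quantile of the multiset of pairwise
#' PCC values (strict upper triangle): the value at ascending rank
#' `ceiling((1 - alpha) * n_pairs)`. By construction the returned value is a
#' realized pair PCC and the fraction of pairs strictly exceeding it is
#' below `alpha` — the "p < 0.05 from the right end of the empirical
#' distribution" rule.
#'
#' @param p a `pcc_matrix`.
#' @param alpha right-tail probability (default 0.05).
#' @return the cutoff, a single numeric value.
#' @export
determine_cutoff <- function(p, alpha = 0.05) {
  stopifnot(inherits(p, "pcc_matrix"))
  n_genes <- length(p$gene_ids)
  if (n_genes < 2) stop("need at least 2 genes to determine a cutoff",
                        call. = FALSE)
  nearest_rank_cutoff(p$values[upper.tri(p$values)], alpha = alpha)
}

#' Nearest-rank right-tail quantile of a value multiset
#'
#' Low-level routine behind [determine_cutoff()]: the element of `values`
#' at ascending rank `ceiling((1 - alpha) * length(values))`. Always a
#' realized member of the multiset.
#'
#' @param values numeric vector (e.g. pairwise PCCs).
#' @param alpha right-tail probability in (0, 1).
#' @return a single numeric value.
#' @export
nearest_rank_cutoff <- function(values, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  }
  if (length(values) == 0) stop("empty value multiset", call. = FALSE)
  sort(values)[ceiling((1 - alpha) * length(values))]
}

#' Build the co-expression network at a cutoff
#'
#' Edges are unordered gene pairs with PCC >= cutoff (closed threshold; ties
#' at the cutoff are kept). All genes of the PCC matrix stay as nodes;
#' isolated nodes are allowed and can be inspected from the edge list.
#'
#' @param p a `pcc_matrix`.
#' @param cutoff co-expression cutoff in (0, 1].
#' @return an object of class `coexpression_network`: list with `nodes`,
#'   `edges` (data.frame gene_a, gene_b, pcc with gene_a < gene_b,
#'   lexicographically sorted) and `cutoff`.
#' @export
build_gcn <- function(p, cutoff) {
  stopifnot(inherits(p, "pcc_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
      cutoff > 1) {
    stop("cutoff must be a single value in (0, 1]", call. = FALSE)
  }
  v <- p$values
  idx <- which(upper.tri(v) & v >= cutoff, arr.ind = TRUE)
  a <- rownames(v)[idx[, 1]]
  b <- colnames(v)[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(gene_a = a, gene_b = b,
                      pcc = v[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = p$gene_ids, edges = edges, cutoff = cutoff),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  iso <- setdiff(x$nodes, c(x$edges$gene_a, x$edges$gene_b))
  cat(sprintf("Co-expression network: %d nodes, %d edges (PCC >= %.4g), %d isolated\n",
              length(x$nodes), nrow(x$edges), x$cutoff, length(iso)))
  invisible(x)
}

#' Assign time-order levels by breadth-first search
#'
#' Starting from a seed TF assumed to be the first up-regulated gene, BFS
#' strata define the time order: the seed and its direct neighbors form
#' level 1, nodes at shortest-path distance k >= 2 form level k
#' (`level = max(1, distance)`). Nodes unreachable from the seed are
#' reported in `unreached` and carry no level.
#'
#' @param g a `coexpression_network`.
#' @param seed node ID of the seed TF.
#' @return an object of class `togcn`: list with `network`, `seed`, `levels`
#'   (named integer vector) and `unreached` (character vector).
#' @export
assign_levels_bfs <- function(g, seed) {
  stopifnot(inherits(g, "coexpression_network"))
  if (!(seed %in% g$nodes)) {
    stop("seed '", seed, "' is not a node of the network", call. = FALSE)
  }
  nodes <- g$nodes
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  if (nrow(g$edges) > 0) {
    for (k in seq_len(nrow(g$edges))) {
      a <- g$edges$gene_a[k]; b <- g$edges$gene_b[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  dist[seed] <- 0L
  queue <- seed
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    nb <- adj[[v]]
    new <- nb[is.na(dist[nb])]
    if (length(new) > 0) {
      dist[new] <- dist[v] + 1L
      queue <- c(queue, new)
    }
  }
  reached <- names(dist)[!is.na(dist)]
  levels <- dist[reached]
  levels[levels < 1L] <- 1L  # the seed joins its neighbors in level 1
  unreached <- names(dist)[is.na(dist)]
  if (length(reached) == 1) {
    warning("seed '", seed, "' is isolated; TO-GCN contains only the seed",
            call. = FALSE)
  }
  structure(list(network = g, seed = seed, levels = levels,
                 unreached = unreached),
            class = "togcn")
}

#' @export
print.togcn <- function(x, ...) {
  cat(sprintf("TO-GCN: seed '%s', %d leveled TFs over %d levels, %d unreached\n",
              x$seed, length(x$levels), max(x$levels), length(x$unreached)))
  tab <- table(x$levels)
  cat("TFs per level:", paste(sprintf("L%s:%d", names(tab), tab),
                              collapse = " "), "\n")
  invisible(x)
}

#' Construct a TO-GCN from a precomputed level assignment
#'
#' Wraps an existing gene -> level map (e.g. read back from a `levels.tsv`
#' written by [write_levels()]) as a `togcn` so the comparison operations
#' can run without rebuilding the network.
#'
#' @param levels named integer vector, names are gene IDs, values positive
#'   levels.
#' @param seed optional seed TF ID (defaults to a level-1 gene).
#' @return a `togcn` without an attached network.
#' @export
togcn_from_levels <- function(levels, seed = NULL) {
  if (is.null(names(levels)) || anyDuplicated(names(levels))) {
    stop("levels must be a named vector with unique gene IDs",
         call. = FALSE)
  }
  lv <- as.integer(levels)
  if (any(is.na(lv)) || any(lv < 1)) {
    stop("levels must be positive integers", call. = FALSE)
  }
  names(lv) <- names(levels)
  if (is.null(seed)) seed <- names(lv)[which(lv == 1L)[1]]
  structure(list(network = NULL, seed = seed, levels = lv,
                 unreached = character(0)), class = "togcn")
}

#' Per-level co-expressed gene sets
#'
#' A candidate gene joins the gene set of level L when its PCC with at least
#' one level-L TF reaches the cutoff; genes co-expressed with TFs of several
#' levels belong to every such set.
#'
#' @param m validated expression matrix holding both candidate genes and the
#'   leveled TFs (same columns used to build the network).
#' @param t a `togcn`.
#' @param cutoff co-expression cutoff (normally the network's).
#' @param candidates character vector of candidate (usually non-TF) gene
#'   IDs; must be rows of `m`.
#' @return named list (one element per level, `"1"` ... `"L"`) of sorted
#'   gene ID vectors, class `level_gene_sets`.
#' @export
assign_level_gene_sets <- function(m, t, cutoff = t$network$cutoff,
                                   candidates) {
  stopifnot(inherits(t, "togcn"))
  validate_expression_matrix(m)
  n_levels <- max(t$levels)
  sets <- stats::setNames(rep(list(character(0)), n_levels),
                          as.character(seq_len(n_levels)))
  if (length(candidates) == 0) {
    warning("empty candidate set; returning empty level gene sets",
            call. = FALSE)
    return(structure(sets, class = "level_gene_sets"))
  }
  unknown <- setdiff(candidates, rownames(m))
  if (length(unknown) > 0) {
    stop("candidate gene(s) not in matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tfs <- names(t$levels)
  miss_tf <- setdiff(tfs, rownames(m))
  if (length(miss_tf) > 0) {
    stop("leveled TF(s) not in matrix: ", paste(miss_tf, collapse = ", "),
         call. = FALSE)
  }
  cand <- m[candidates, , drop = FALSE]
  cand_sd <- apply(cand, 1, stats::sd)
  usable <- candidates[cand_sd > 0]
  if (length(usable) > 0) {
    pcc <- suppressWarnings(
      stats::cor(t(m[usable, , drop = FALSE]), t(m[tfs, , drop = FALSE])))
    for (lv in seq_len(n_levels)) {
      lv_tfs <- tfs[t$levels == lv]
      hit <- apply(pcc[, lv_tfs, drop = FALSE] >= cutoff, 1, any)
      hit[is.na(hit)] <- FALSE
      sets[[as.character(lv)]] <- sort(usable[hit])
    }
  }
  structure(sets, class = "level_gene_sets")
}

#' Mean z-score expression profile per level
#'
#' Each leveled TF's condition profile is standardized to mean 0 and
#' population SD 1; the level profile is the arithmetic mean of its member
#' z-vectors (the values behind per-level expression bar charts and
#' heatmaps). Constant-profile TFs have no defined z-score and are excluded
#' with a warning.
#'
#' @param m genes x conditions matrix (condition means, columns in
#'   time-course order).
#' @param t a `togcn`.
#' @return levels x conditions numeric matrix, rows `"1"` ... `"L"`.
#' @export
mean_zscore_profile <- function(m, t) {
  stopifnot(inherits(t, "togcn"))
  validate_expression_matrix(m)
  tfs <- names(t$levels)
  miss <- setdiff(tfs, rownames(m))
  if (length(miss) > 0) {
    stop("leveled TF(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  prof <- m[tfs, , drop = FALSE]
  mu <- rowMeans(prof)
  pop_sd <- sqrt(rowMeans((prof - mu)^2))
  if (any(pop_sd == 0)) {
    warning("constant-profile TF(s) excluded from z-scores: ",
            paste(tfs[pop_sd == 0], collapse = ", "), call. = FALSE)
  }
  ok <- pop_sd > 0
  z <- (prof[ok, , drop = FALSE] - mu[ok]) / pop_sd[ok]
  n_levels <- max(t$levels)
  out <- matrix(NA_real_, n_levels, ncol(m),
                dimnames = list(as.character(seq_len(n_levels)),
                                colnames(m)))
  lv_of <- t$levels[ok]
  for (lv in seq_len(n_levels)) {
    members <- z[lv_of == lv, , drop = FALSE]
    if (nrow(members) > 0) out[lv, ] <- colMeans(members)
  }
  out
}

# --- deterministic TSV writers -------------------------------------------

#' Write a network edge list as TSV (columns gene_a, gene_b, pcc)
#' @param g a `coexpression_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "coexpression_network"))
  edges <- g$edges[order(g$edges$gene_a, g$edges$gene_b), , drop = FALSE]
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write TO-GCN level assignments as TSV (columns gene, level)
#' @param t a `togcn`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_levels <- function(t, path) {
  stopifnot(inherits(t, "togcn"))
  out <- data.frame(gene = names(t$levels), level = as.integer(t$levels),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-level gene sets as TSV (columns level, gene)
#' @param sets a `level_gene_sets`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_level_sets <- function(sets, path) {
  stopifnot(inherits(sets, "level_gene_sets"))
  rows <- do.call(rbind, lapply(names(sets), function(lv) {
    if (length(sets[[lv]]) == 0) return(NULL)
    data.frame(level = as.integer(lv), gene = sort(sets[[lv]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(level = integer(0), gene = character(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a level x condition mean z-score profile as TSV
#' @param profile matrix from [mean_zscore_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_level_profile <- function(profile, path) {
  out <- data.frame(level = rownames(profile), profile, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
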