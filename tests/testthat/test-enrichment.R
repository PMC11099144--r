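# GMT parsing, hypergeometric over-representation, BH adjustment

test_that("GMT reader parses and validates", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc one\tg1\tg2", "T2\tdesc two\tg2\tg3\tg4"), path)
  terms <- read_gmt(path)
  expect_identical(terms[["T1"]], c("g1", "g2"))
  expect_identical(terms[["T2"]], c("g2", "g3", "g4"))
  expect_identical(unname(attr(terms, "descriptions")["T1"]), "desc one")

  writeLines(c("T1\tdesc\tg1", "T1\tdesc\tg2"), path)
  expect_error(read_gmt(path), "duplicate term_id")

  writeLines(c("T1\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 1")

  writeLines(character(0), path)
  expect_warning(empty <- read_gmt(path), "empty")
  expect_length(empty, 0)

  # round trip
  writeLines(c("T1\td1\tg1\tg2", "T2\td2\tg3"), path)
  t1 <- read_gmt(path)
  path2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(t1, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("BH adjustment matches hand calculation and is monotone", {
  # worked example: p_(i) * 4 / i = 0.04 for every i
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(21)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    # second oracle: the reference BH implementation
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm])
    # monotonicity: increasing one p never decreases any q
    j <- sample(length(p), 1)
    p2 <- p
    p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_true(all(bh_adjust(p2) >= q - 1e-12))
  }
})

test_that("enrichment p-values match exhaustive enumeration", {
  # worked example: background 20, term 5, level set 5, overlap 4
  bg <- sprintf("g%02d", 1:20)
  terms <- structure(list(T1 = bg[1:5]),
                     descriptions = c(T1 = "t"),
                     class = "term_collection")
  sets <- structure(list(`1` = c(bg[1:4], bg[10])),
                    class = "level_gene_sets")
  tab <- fisher_enrichment_per_level(sets, terms, bg)
  expect_equal(tab$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(tab$p_value, 0.004902, tolerance = 1e-4)
  expect_identical(tab$overlap, 4L)

  # term equal to the background is certain: p = 1
  terms_all <- structure(list(ALL = bg), descriptions = c(ALL = "all"),
                         class = "term_collection")
  tab_all <- fisher_enrichment_per_level(sets, terms_all, bg)
  expect_equal(tab_all$p_value, 1)

  # empty level set after intersection is skipped with a note
  sets_out <- structure(list(`1` = c("zz1", "zz2")),
                        class = "level_gene_sets")
  expect_message(tab_skip <- fisher_enrichment_per_level(sets_out, terms,
                                                         bg),
                 "empty gene set")
  expect_equal(nrow(tab_skip), 0)

  # exhaustive enumeration oracle over small backgrounds
  for (n_bg in c(5, 8)) {
    genes <- sprintf("x%02d", seq_len(n_bg))
    for (term_size in 1:n_bg) {
      for (draws in 1:n_bg) {
        k_min <- max(1, term_size + draws - n_bg)
        for (k in k_min:min(term_size, draws)) {
          tt <- structure(list(T = genes[seq_len(term_size)]),
                          descriptions = c(T = ""),
                          class = "term_collection")
          pick <- c(genes[seq_len(k)],
                    genes[term_size + seq_len(draws - k)])
          ss <- structure(list(`1` = pick), class = "level_gene_sets")
          tab <- fisher_enrichment_per_level(ss, tt, genes,
                                             min_term_size = 1,
                                             min_overlap = 1)
          expect_equal(tab$p_value,
                       enum_upper_tail(k, term_size, draws, n_bg),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("enrichment table structure, odds ratios and FDR scope", {
  bg <- sprintf("g%02d", 1:40)
  terms <- structure(list(T1 = bg[1:10], T2 = bg[11:20], T3 = bg[1:2]),
                     descriptions = c(T1 = "a", T2 = "b", T3 = "c"),
                     class = "term_collection")
  sets <- structure(list(`1` = bg[1:10], `2` = bg[c(1, 11:18)]),
                    class = "level_gene_sets")
  tab <- fisher_enrichment_per_level(sets, terms, bg)
  expect_true(all(tab$overlap <= pmin(tab$set_size, tab$term_size)))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  # sorted by (level, fdr, term_id)
  expect_false(is.unsorted(tab$level))
  # per-level BH equals applying bh_adjust inside each level
  for (lv in unique(tab$level)) {
    rows <- tab[tab$level == lv, ]
    expect_equal(rows$fdr, bh_adjust(rows$p_value))
  }
  # global scope adjusts across the whole table
  tab_g <- fisher_enrichment_per_level(sets, terms, bg, adjust = "global")
  expect_equal(tab_g$fdr[order(tab_g$level, tab_g$term_id)],
               bh_adjust(tab_g$p_value[order(tab_g$level, tab_g$term_id)]))

  # level 1 fully overlaps T1 (two zero cells): continuity-corrected OR
  # from the table a=10, b=0, c=0, d=30
  r11 <- tab[tab$level == 1 & tab$term_id == "T1", ]
  expect_equal(r11$odds_ratio, (10.5 * 30.5) / (0.5 * 0.5))

  expect_error(fisher_enrichment_per_level(sets, terms, character(0)),
               "empty background")
  # a term fully outside the background is skipped with a note
  terms_out <- structure(list(T1 = bg[1:5], TX = c("nope1", "nope2")),
                         descriptions = c(T1 = "", TX = ""),
                         class = "term_collection")
  expect_message(fisher_enrichment_per_level(sets, terms_out, bg), "TX")
})

test_that("level sets built from a planted TO-GCN enrich their own wave", {
  # noiseless planted waves over 6 conditions; TO-GCN built by hand so the
  # test isolates set->term logic from cutoff selection
  waves <- list(c(10, 6, 2, 1, 0, 0), c(2, 8, 10, 4, 1, 0),
                c(0, 1, 5, 10, 5, 1), c(0, 0, 1, 4, 9, 10))
  n_per <- 6
  gene_rows <- list(); gene_wave <- integer(0); ids <- character(0)
  for (w in seq_along(waves)) {
    for (j in seq_len(n_per)) {
      ids <- c(ids, sprintf("w%d_g%d", w, j))
      gene_rows[[length(ids)]] <- waves[[w]] * (0.5 + 0.2 * j)
      gene_wave <- c(gene_wave, w)
    }
  }
  tf_ids <- sprintf("w%d_tf", seq_along(waves))
  tf_rows <- lapply(waves, identity)
  m <- tiny_matrix(do.call(rbind, c(tf_rows, gene_rows)),
                   genes = c(tf_ids, ids))
  t_hand <- fake_togcn(stats::setNames(seq_along(waves), tf_ids))
  t_hand$network <- fake_network(tf_ids, NULL, cutoff = 0.95)
  sets <- assign_level_gene_sets(m, t_hand, candidates = ids)
  terms <- structure(stats::setNames(split(ids, gene_wave),
                                     sprintf("wave%d", seq_along(waves))),
                     descriptions = stats::setNames(
                       rep("", length(waves)),
                       sprintf("wave%d", seq_along(waves))),
                     class = "term_collection")
  tab <- fisher_enrichment_per_level(sets, terms, c(tf_ids, ids))
  for (lv in seq_along(waves)) {
    rows <- tab[tab$level == lv, ]
    expect_identical(rows$term_id[which.min(rows$fdr)],
                     sprintf("wave%d", lv))
    expect_lt(min(rows$fdr), 0.05)
  }
})
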