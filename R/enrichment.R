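# Per-level functional enrichment: GMT parsing, one-sided Fisher's exact
# (hypergeometric upper tail) over-representation, Benjamini-Hochberg FDR.

#' Read a GMT gene-set collection
#'
#' Standard GMT: one term per line, `term_id TAB description TAB gene TAB
#' gene ...`. Genes absent from the analysis background are kept here and
#' dropped at test time.
#'
#' @param path path to the GMT file.
#' @return an object of class `term_collection`: named list of character
#'   vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(structure(stats::setNames(list(), character(0)),
                     descriptions = character(0), class = "term_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate term_id(s) in GMT: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  descriptions <- stats::setNames(vapply(fields, `[[`, character(1), 2), ids)
  members <- stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                             ids)
  structure(members, descriptions = descriptions, class = "term_collection")
}

#' Write a term collection as GMT
#' @param terms a `term_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  desc <- attr(terms, "descriptions")
  lines <- vapply(names(terms), function(id) {
    paste(c(id, desc[[id]], terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: for ascending p-values, `q_(i) = min over j >= i of
#' p_(j) * m / j`, capped at 1, returned in the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values (FDR), aligned with the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  ord <- order(pvalues)
  scaled <- pvalues[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

#' Per-level Fisher's exact over-representation test
#'
#' For each (level, term) pair, tests over-representation of the term inside
#' the level's co-expressed gene set against the expressed-gene background:
#' one-sided p-value = upper hypergeometric tail `P(X >= overlap)` with
#' population `|background|`, successes `|term|`, draws `|level set|`.
#' Level sets and terms are intersected with the background first. The odds
#' ratio comes from the 2x2 table with a 0.5 continuity correction when any
#' cell is zero. FDR is BH-adjusted across terms within each level by
#' default (`adjust = "per_level"`) or across the whole table
#' (`adjust = "global"`).
#'
#' @param sets a `level_gene_sets`.
#' @param terms a `term_collection`.
#' @param background character vector: all expressed genes.
#' @param adjust `"per_level"` (default) or `"global"` BH scope.
#' @param min_term_size smallest in-background term tested (default 2).
#' @param min_overlap smallest overlap reported (default 1).
#' @return data.frame with columns level, term_id, term_name, overlap,
#'   set_size, term_size, background_size, odds_ratio, p_value, fdr; sorted
#'   by (level, fdr, term_id). Class `enrichment_table`.
#' @export
fisher_enrichment_per_level <- function(sets, terms, background,
                                        adjust = c("per_level", "global"),
                                        min_term_size = 2, min_overlap = 1) {
  adjust <- match.arg(adjust)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  background <- unique(background)
  n_bg <- length(background)
  term_in_bg <- lapply(terms, intersect, background)
  skipped <- names(terms)[vapply(term_in_bg, length, integer(1)) == 0]
  if (length(skipped) > 0) {
    message("term(s) fully outside background skipped: ",
            paste(skipped, collapse = ", "))
  }
  desc <- attr(terms, "descriptions")
  rows <- list()
  for (lv in names(sets)) {
    set_bg <- intersect(sets[[lv]], background)
    n_draw <- length(set_bg)
    if (n_draw == 0) {
      message("level ", lv, ": empty gene set after background intersection; skipped")
      next
    }
    lv_rows <- list()
    for (tid in names(terms)) {
      tset <- term_in_bg[[tid]]
      n_term <- length(tset)
      if (n_term < min_term_size) next
      k <- length(intersect(set_bg, tset))
      if (k < min_overlap) next
      # upper tail P(X >= k), X ~ Hypergeom(n_bg, n_term, n_draw)
      p <- stats::phyper(k - 1, n_term, n_bg - n_term, n_draw,
                         lower.tail = FALSE)
      a <- k
      b <- n_draw - k
      cc <- n_term - k
      d <- n_bg - n_term - n_draw + k
      if (any(c(a, b, cc, d) == 0)) {
        orat <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
      } else {
        orat <- (a * d) / (b * cc)
      }
      lv_rows[[tid]] <- data.frame(
        level = as.integer(lv), term_id = tid,
        term_name = if (!is.null(desc)) unname(desc[tid]) else "",
        overlap = as.integer(k), set_size = as.integer(n_draw),
        term_size = as.integer(n_term), background_size = as.integer(n_bg),
        odds_ratio = orat, p_value = p, fdr = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (length(lv_rows) > 0) {
      lv_tab <- do.call(rbind, lv_rows)
      if (adjust == "per_level") lv_tab$fdr <- bh_adjust(lv_tab$p_value)
      rows[[lv]] <- lv_tab
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(level = integer(0), term_id = character(0),
                      term_name = character(0), overlap = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      background_size = integer(0), odds_ratio = numeric(0),
                      p_value = numeric(0), fdr = numeric(0))
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  if (adjust == "global") out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$level, out$fdr, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#' @param tab an `enrichment_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
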