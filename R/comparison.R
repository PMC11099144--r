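# Dual-program comparison: per-TF level differences, the 1.5 x SD
# changed/unchanged classification, window-based type-specific TF calling,
# and the differential-expression filter on an externally supplied table.

#' Per-TF level differences between two TO-GCNs
#'
#' For every TF leveled in both networks, `d = level_A - level_B`. TFs
#' leveled in only one network are listed separately (`a_only` / `b_only`).
#' The summary holds the mean, the population SD of d and the histogram of
#' observed integer d values.
#'
#' @param t_a,t_b `togcn` objects for programs A and B.
#' @return object of class `level_comparison`: list with `table`
#'   (data.frame tf_id, level_a, level_b, d), `a_only`, `b_only`, `summary`.
#' @export
compute_level_differences <- function(t_a, t_b) {
  stopifnot(inherits(t_a, "togcn"), inherits(t_b, "togcn"))
  shared <- sort(intersect(names(t_a$levels), names(t_b$levels)))
  if (length(shared) == 0) stop("no shared TFs between the two TO-GCNs",
                                call. = FALSE)
  la <- as.integer(t_a$levels[shared])
  lb <- as.integer(t_b$levels[shared])
  d <- la - lb
  hist_tab <- table(factor(d, levels = seq(min(d), max(d))))
  summary <- list(mean_d = mean(d), sd_d = sqrt(mean((d - mean(d))^2)),
                  n_shared = length(shared),
                  histogram = stats::setNames(as.integer(hist_tab),
                                              names(hist_tab)))
  structure(list(
    table = data.frame(tf_id = shared, level_a = la, level_b = lb, d = d,
                       stringsAsFactors = FALSE),
    a_only = sort(setdiff(names(t_a$levels), shared)),
    b_only = sort(setdiff(names(t_b$levels), shared)),
    summary = summary), class = "level_comparison")
}

#' Classify TFs into changed / not-changed levels
#'
#' Threshold `t = max(1, ceiling(multiplier * popSD(d)))`; a TF is
#' "changed" when `|d| >= t`, otherwise "not_changed". With the original
#' study's d distribution this rule reproduces the "difference >= 3 changed
#' / <= 2 not changed" boundary (any SD in (4/3, 2] gives t = 3 at
#' multiplier 1.5). A zero SD classifies everything as not changed with a
#' warning.
#'
#' @param comparison a `level_comparison`.
#' @param multiplier SD multiplier (default 1.5).
#' @return the `level_comparison` with a `class` column added to `table`
#'   and `threshold` recorded in `summary`.
#' @export
classify_level_shift <- function(comparison, multiplier = 1.5) {
  stopifnot(inherits(comparison, "level_comparison"))
  if (nrow(comparison$table) < 2) {
    stop("need at least 2 shared TFs to classify level shifts",
         call. = FALSE)
  }
  sd_d <- comparison$summary$sd_d
  if (sd_d == 0) {
    warning("SD of level differences is 0; all TFs classified not_changed",
            call. = FALSE)
  }
  threshold <- max(1L, as.integer(ceiling(multiplier * sd_d)))
  comparison$table$class <- ifelse(abs(comparison$table$d) >= threshold,
                                   "changed", "not_changed")
  comparison$summary$threshold <- threshold
  comparison$summary$multiplier <- multiplier
  comparison
}

#' @export
print.level_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Level comparison: %d shared TFs, mean d = %.3f, pop SD = %.3f\n",
              s$n_shared, s$mean_d, s$sd_d))
  if (!is.null(s$threshold)) {
    cat(sprintf("threshold t = %d (multiplier %.2f): %d changed / %d not changed\n",
                s$threshold, s$multiplier,
                sum(x$table$class == "changed"),
                sum(x$table$class == "not_changed")))
  }
  invisible(x)
}

#' Call type-specific TFs inside a level window
#'
#' Using the late "keratinization" window (default levels 8-11): a TF is
#' B-specific when its level in B lies in the window while in A it is either
#' unleveled (when `allow_absent`) or leveled outside the window; A-specific
#' symmetrically; common when both levels fall in the window.
#'
#' @param t_a,t_b `togcn` objects for programs A and B.
#' @param window integer length-2 vector, inclusive level window (default
#'   `c(8, 11)`).
#' @param allow_absent should a TF absent from one network count as "not
#'   expressed at the window levels" there (default TRUE)? If FALSE, a TF
#'   must be leveled in both networks to be called specific.
#' @return object of class `specific_tf_report`: list with `a_specific`,
#'   `b_specific`, `common` (character vectors), `window`, `table`
#'   (data.frame tf_id, category, level_a, level_b).
#' @export
find_type_specific_tfs <- function(t_a, t_b, window = c(8L, 11L),
                                   allow_absent = TRUE) {
  stopifnot(inherits(t_a, "togcn"), inherits(t_b, "togcn"))
  if (length(window) != 2 || any(!is.finite(window)) ||
      window[1] > window[2]) {
    stop("window must be a non-empty interval c(lo, hi) with lo <= hi",
         call. = FALSE)
  }
  all_tfs <- sort(union(names(t_a$levels), names(t_b$levels)))
  la <- t_a$levels[all_tfs]
  lb <- t_b$levels[all_tfs]
  in_win <- function(lv) !is.na(lv) & lv >= window[1] & lv <= window[2]
  present_ok <- function(lv) if (allow_absent) TRUE else !is.na(lv)
  a_spec <- in_win(la) & !in_win(lb) & present_ok(lb)
  b_spec <- in_win(lb) & !in_win(la) & present_ok(la)
  common <- in_win(la) & in_win(lb)
  category <- rep("outside", length(all_tfs))
  category[a_spec] <- "a_specific"
  category[b_spec] <- "b_specific"
  category[common] <- "common"
  tab <- data.frame(tf_id = all_tfs, category = category,
                    level_a = as.integer(la), level_b = as.integer(lb),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$category != "outside", , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(a_specific = all_tfs[a_spec], b_specific = all_tfs[b_spec],
                 common = all_tfs[common], window = as.integer(window),
                 table = tab), class = "specific_tf_report")
}

#' @export
print.specific_tf_report <- function(x, ...) {
  cat(sprintf("Type-specific TFs in level window [%d, %d]: %d A-specific, %d B-specific, %d common\n",
              x$window[1], x$window[2], length(x$a_specific),
              length(x$b_specific), length(x$common)))
  invisible(x)
}

#' Read a differential-expression table from TSV
#'
#' Required columns: `gene_id`, `log2fc`, `padj`. The model fit that
#' produced it is out of scope; the table is only consumed by
#' [apply_deg_filter()].
#'
#' @param path path to the TSV file.
#' @return validated data.frame.
#' @export
read_deg_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           comment.char = "")
  need <- c("gene_id", "log2fc", "padj")
  miss <- setdiff(need, colnames(tab))
  if (length(miss) > 0) {
    stop("DEG table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab$gene_id <- as.character(tab$gene_id)
  tab$log2fc <- as.numeric(tab$log2fc)
  tab$padj <- as.numeric(tab$padj)
  if (anyDuplicated(tab$gene_id)) {
    dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
    stop("duplicate gene_id(s) in DEG table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(tab$padj) & (tab$padj < 0 | tab$padj > 1))) {
    stop("adjusted p-values must lie in [0, 1]", call. = FALSE)
  }
  tab
}

#' Filter a specific-TF report by differential expression
#'
#' Keeps TFs that are significant in the supplied table: adjusted
#' p < `padj_max` and `|log2FC| > lfc_min` (both strict, matching the
#' "adjusted p-value < 0.05 and absolute log2 fold change > 1" rule). TFs
#' absent from the table are dropped with a note.
#'
#' @param report a `specific_tf_report`.
#' @param deg data.frame from [read_deg_table()].
#' @param padj_max adjusted-p threshold (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 1).
#' @return the report with filtered subsets `a_specific_deg`,
#'   `b_specific_deg`, `common_deg` and a `passed_deg_filter` column in
#'   `table`.
#' @export
apply_deg_filter <- function(report, deg, padj_max = 0.05, lfc_min = 1) {
  stopifnot(inherits(report, "specific_tf_report"))
  passes <- function(ids) {
    idx <- match(ids, deg$gene_id)
    absent <- ids[is.na(idx)]
    if (length(absent) > 0) {
      message("TF(s) absent from DEG table dropped by filter: ",
              paste(absent, collapse = ", "))
    }
    ok <- !is.na(idx) &
      !is.na(deg$padj[idx]) & deg$padj[idx] < padj_max &
      !is.na(deg$log2fc[idx]) & abs(deg$log2fc[idx]) > lfc_min
    ids[ok]
  }
  report$a_specific_deg <- passes(report$a_specific)
  report$b_specific_deg <- passes(report$b_specific)
  report$common_deg <- passes(report$common)
  kept <- c(report$a_specific_deg, report$b_specific_deg,
            report$common_deg)
  report$table$passed_deg_filter <- report$table$tf_id %in% kept
  report$deg_params <- list(padj_max = padj_max, lfc_min = lfc_min)
  report
}

#' Write a level comparison as TSV plus a JSON summary
#'
#' The TSV has columns tf_id, level_a, level_b, d and, when classified,
#' class; the JSON holds mean, SD, threshold and histogram.
#'
#' @param comparison a `level_comparison`.
#' @param path output TSV path; the JSON is written next to it with
#'   extension `.summary.json`.
#' @return `path`, invisibly.
#' @export
write_level_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "level_comparison"))
  tab <- comparison$table[order(comparison$table$tf_id), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(comparison$summary,
                       sub("\\.tsv$", ".summary.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a specific-TF report as TSV
#'
#' Columns tf_id, category, level_a, level_b and (when a DEG filter was
#' applied) passed_deg_filter; rows sorted by (category, tf_id).
#'
#' @param report a `specific_tf_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_specific_tf_report <- function(report, path) {
  stopifnot(inherits(report, "specific_tf_report"))
  tab <- report$table[order(report$table$category, report$table$tf_id), ,
                      drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
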