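# Expression matrix and sample sheet I/O, filtering, normalization.
#
# The expression container is a plain numeric matrix (genes x samples, TPM
# units) with unique dimnames, the way limma and edgeR treat raw expression
# tables. validate_expression_matrix() enforces the invariants at the
# boundaries; downstream functions assume a validated matrix.

#' Validate a genes x samples expression matrix
#'
#' Checks the container invariants: numeric matrix, unique non-empty gene and
#' sample identifiers, and all values finite and non-negative.
#'
#' @param m numeric matrix, genes in rows, samples in columns, with dimnames.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g) > 0) {
    stop("duplicate gene ID(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_s) > 0) {
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value (%g) at gene '%s', sample '%s'",
                 m[bad[1], bad[2]], rownames(m)[bad[1]], colnames(m)[bad[2]]),
         call. = FALSE)
  }
  invisible(m)
}

#' Read a genes x samples expression matrix from TSV
#'
#' Expects a tab-separated, UTF-8 text file with a header row of sample IDs
#' and gene IDs in the first column ("." decimal, no thousands separators;
#' the first header cell is ignored). Values are TPM and must be
#' non-negative.
#'
#' @param path path to the TSV file.
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    stop("expression matrix must have at least one gene row and one sample column",
         call. = FALSE)
  }
  gene_ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (any(is.na(num) & !is.na(vals))) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 vals[bad[1], bad[2]], gene_ids[bad[1]],
                 colnames(vals)[bad[2]]), call. = FALSE)
  }
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], colnames(vals)[bad[2]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]; first header cell is `gene_id`.
#'
#' @param m validated expression matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m)
  out <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Required columns: `sample_id`, `condition`, `order` (positive integer
#' position of the condition in the time course) and `replicate`. Distinct
#' conditions must have distinct orders and a condition may not appear under
#' two different orders.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns sample_id, condition, order, replicate.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  validate_sample_sheet_df(tab)
}

validate_sample_sheet_df <- function(tab) {
  need <- c("sample_id", "condition", "order", "replicate")
  miss <- setdiff(need, colnames(tab))
  if (length(miss) > 0) {
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0) stop("no samples in sample sheet", call. = FALSE)
  sheet <- data.frame(sample_id = as.character(tab$sample_id),
                      condition = as.character(tab$condition),
                      order = suppressWarnings(as.integer(tab$order)),
                      replicate = as.character(tab$replicate),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sheet$sample_id)) {
    dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
    stop("duplicate sample_id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(sheet$order)) || any(sheet$order < 1)) {
    stop("sample sheet 'order' must be positive integers", call. = FALSE)
  }
  co <- unique(sheet[, c("condition", "order")])
  if (anyDuplicated(co$condition)) {
    bad <- unique(co$condition[duplicated(co$condition)])
    stop("condition(s) with more than one order: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(co$order)) {
    bad_o <- co$order[duplicated(co$order)]
    bad <- co$condition[co$order %in% bad_o]
    stop("conditions sharing one order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sheet
}

#' Write a sample sheet as TSV
#' @param sheet sample sheet data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet[, c("sample_id", "condition", "order", "replicate")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor gene list
#'
#' Plain text, one gene ID per line; `#` starts a comment and blank lines are
#' ignored.
#'
#' @param path path to the text file.
#' @return character vector of unique TF gene IDs.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- lines[nzchar(lines)]
  unique(ids)
}

#' Filter to expressed genes
#'
#' A gene is kept when its maximum TPM over samples reaches `tpm_min`
#' (default 1, the "TPM >= 1 in at least one transcriptome" rule). Row order
#' is preserved. If no gene survives, an empty matrix is returned with a
#' warning; downstream operations reject empty input.
#'
#' @param m validated expression matrix.
#' @param tpm_min minimum TPM a gene must reach in at least one sample.
#' @return row-subset of `m`.
#' @export
filter_expressed <- function(m, tpm_min = 1) {
  validate_expression_matrix(m)
  keep <- apply(m, 1, max) >= tpm_min
  if (!any(keep)) warning("no genes pass the expression filter", call. = FALSE)
  m[keep, , drop = FALSE]
}

#' Upper-quartile normalize samples
#'
#' Each sample is rescaled so that the 75th percentile of its strictly
#' positive values (linear interpolation between order statistics) equals the
#' geometric mean of all samples' upper quartiles. Zeros are excluded from
#' the quartile because they would otherwise dominate sparse RNA-seq
#' matrices; the geometric-mean target keeps the output on the scale of the
#' input data.
#'
#' @param m validated expression matrix; every sample needs at least one
#'   strictly positive value.
#' @return normalized matrix with equal per-sample upper quartiles.
#' @export
upper_quartile_normalize <- function(m) {
  validate_expression_matrix(m)
  uq <- vapply(seq_len(ncol(m)), function(j) {
    pos <- m[, j][m[, j] > 0]
    if (length(pos) == 0) {
      stop("sample '", colnames(m)[j], "' has no positive values",
           call. = FALSE)
    }
    stats::quantile(pos, 0.75, names = FALSE, type = 7)
  }, numeric(1))
  target <- exp(mean(log(uq)))
  sweep(m, 2, target / uq, `*`)
}

#' Collapse replicate samples to per-condition means
#'
#' Returns a genes x conditions matrix whose columns are the arithmetic means
#' over each condition's replicates, ordered by the condition order in the
#' sample sheet. Every matrix sample must appear in the sheet.
#'
#' @param m validated expression matrix (samples in columns).
#' @param sheet sample sheet as returned by [read_sample_sheet()].
#' @return genes x conditions matrix, columns in time-course order.
#' @export
condition_means <- function(m, sheet) {
  validate_expression_matrix(m)
  sheet <- validate_sample_sheet_df(sheet)
  missing <- setdiff(colnames(m), sheet$sample_id)
  if (length(missing) > 0) {
    stop("sample(s) absent from sample sheet: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sheet <- sheet[sheet$sample_id %in% colnames(m), , drop = FALSE]
  conds <- unique(sheet[order(sheet$order), "condition"])
  out <- vapply(conds, function(cc) {
    cols <- sheet$sample_id[sheet$condition == cc]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), conds))
  out
}
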