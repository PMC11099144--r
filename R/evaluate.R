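# Benchmarking utilities: score the pipeline against the planted truth of a
# synthetic dataset. Used by the acceptance checks and usable for parameter
# studies.

#' Score planted-wave recovery on a synthetic dataset
#'
#' Runs the full single-program pipeline (filter, upper-quartile
#' normalization, condition means, PCC, empirical cutoff, GCN, BFS from the
#' recommended seed) and compares assigned levels with the planted wave
#' indices. Unreached TFs count as misses.
#'
#' @param d a `synthetic_dataset`.
#' @param program `"a"` or `"b"`.
#' @param alpha right-tail probability for the cutoff (default 0.05).
#' @return list with `frac_within1` (fraction of all TFs leveled within +-1
#'   of their planted wave), `spearman` (level vs wave over leveled TFs),
#'   `frac_reached`, `cutoff`, `n_levels` and `n_tfs`.
#' @export
evaluate_level_recovery <- function(d, program = c("a", "b"),
                                    alpha = 0.05) {
  stopifnot(inherits(d, "synthetic_dataset"))
  program <- match.arg(program)
  m <- if (program == "a") d$matrix_a else d$matrix_b
  sheet <- if (program == "a") d$sheet_a else d$sheet_b
  seed_tf <- if (program == "a") d$recommended_seed_a else
    d$recommended_seed_b
  res <- run_togcn_pipeline(m, sheet, d$tf_ids, seed_tf, alpha = alpha)
  truth <- d$truth[d$truth$is_tf, ]
  wave <- if (program == "a") truth$wave_a else truth$wave_b
  lev <- res$togcn$levels[truth$gene_id]
  ok <- !is.na(lev)
  sp <- if (sum(ok) > 2 && stats::sd(lev[ok]) > 0 &&
            stats::sd(wave[ok]) > 0) {
    stats::cor(lev[ok], wave[ok], method = "spearman")
  } else NA_real_
  list(frac_within1 = mean(ok & abs(lev - wave) <= 1, na.rm = TRUE),
       spearman = sp, frac_reached = mean(ok), cutoff = res$cutoff,
       n_levels = max(res$togcn$levels), n_tfs = nrow(truth))
}

#' Score planted window-shift recovery on a synthetic dataset
#'
#' Builds both programs' TO-GCNs, calls type-specific TFs inside the level
#' window, and scores the calls against the planted truth (a TF is truly
#' A-specific when its planted wave lies inside the window in program A
#' only, and symmetrically for B).
#'
#' @param d a `synthetic_dataset` generated with a shift map.
#' @param window inclusive level window (default `c(8, 11)`).
#' @param alpha right-tail probability for the cutoff (default 0.05).
#' @return list with `precision`, `recall`, `n_called`, `n_true`,
#'   `n_correct`.
#' @export
evaluate_shift_recovery <- function(d, window = c(8L, 11L), alpha = 0.05) {
  stopifnot(inherits(d, "synthetic_dataset"))
  run1 <- function(program) {
    m <- if (program == "a") d$matrix_a else d$matrix_b
    sheet <- if (program == "a") d$sheet_a else d$sheet_b
    seed_tf <- if (program == "a") d$recommended_seed_a else
      d$recommended_seed_b
    run_togcn_pipeline(m, sheet, d$tf_ids, seed_tf, alpha = alpha)$togcn
  }
  report <- find_type_specific_tfs(run1("a"), run1("b"), window = window)
  truth <- d$truth[d$truth$is_tf, ]
  in_win <- function(w) w >= window[1] & w <= window[2]
  true_a <- truth$gene_id[in_win(truth$wave_a) & !in_win(truth$wave_b)]
  true_b <- truth$gene_id[in_win(truth$wave_b) & !in_win(truth$wave_a)]
  called_a <- intersect(report$a_specific, truth$gene_id)
  called_b <- intersect(report$b_specific, truth$gene_id)
  n_correct <- length(intersect(called_a, true_a)) +
    length(intersect(called_b, true_b))
  n_called <- length(called_a) + length(called_b)
  n_true <- length(true_a) + length(true_b)
  list(precision = if (n_called > 0) n_correct / n_called else NA_real_,
       recall = if (n_true > 0) n_correct / n_true else NA_real_,
       n_called = n_called, n_true = n_true, n_correct = n_correct)
}
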