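# One-call orchestration of the single-program TO-GCN pipeline.

#' Run the single-program TO-GCN pipeline
#'
#' Chains the canonical stages: expression filter (TPM >= `tpm_min` in at
#' least one sample), upper-quartile normalization, collapse to condition
#' means (unless `use_replicates`), TF-TF PCC matrix, empirical cutoff at
#' right-tail `alpha`, co-expression graph, and BFS time-order levels from
#' the seed TF.
#'
#' @param m raw genes x samples TPM matrix.
#' @param sheet sample sheet (see [read_sample_sheet()]).
#' @param tf_ids character vector of TF gene IDs.
#' @param seed_tf seed TF for the BFS; must survive the expression filter.
#' @param alpha right-tail probability for the cutoff (default 0.05).
#' @param tpm_min expression threshold (default 1).
#' @param use_replicates correlate over replicate-level columns instead of
#'   condition means (default FALSE, matching the five-point design).
#' @param cutoff optional fixed cutoff overriding [determine_cutoff()].
#' @return list with `expressed` (filtered normalized matrix), `profiles`
#'   (matrix used for PCC), `condition_profiles` (condition means, for
#'   z-score profiles), `pcc`, `cutoff`, `network`, `togcn`, and
#'   `background` (all expressed gene IDs).
#' @export
run_togcn_pipeline <- function(m, sheet, tf_ids, seed_tf, alpha = 0.05,
                               tpm_min = 1, use_replicates = FALSE,
                               cutoff = NULL) {
  expressed <- filter_expressed(m, tpm_min = tpm_min)
  if (nrow(expressed) == 0) stop("no expressed genes", call. = FALSE)
  norm <- upper_quartile_normalize(expressed)
  cond <- condition_means(norm, sheet)
  profiles <- if (use_replicates) norm else cond
  tf_present <- intersect(tf_ids, rownames(profiles))
  if (length(tf_present) < 2) {
    stop("fewer than 2 TFs survive the expression filter", call. = FALSE)
  }
  if (!(seed_tf %in% tf_present)) {
    stop("seed TF '", seed_tf, "' is not among the expressed TFs",
         call. = FALSE)
  }
  pcc <- compute_pcc_matrix(profiles, tf_present)
  if (is.null(cutoff)) cutoff <- determine_cutoff(pcc, alpha = alpha)
  network <- build_gcn(pcc, cutoff)
  togcn <- assign_levels_bfs(network, seed_tf)
  list(expressed = expressed, profiles = profiles,
       condition_profiles = cond, pcc = pcc, cutoff = cutoff,
       network = network, togcn = togcn,
       background = rownames(expressed))
}
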