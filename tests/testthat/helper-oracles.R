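# Independent oracles and small fixture builders shared across tests.

# mHG statistic computed from scratch (R only, no tie policy): minimum
# hypergeometric upper tail over prefixes 1..N-1, evaluated at the
# positions of the labelled items.
oracle_stat <- function(positions, N) {
  positions <- sort.int(positions)
  B <- length(positions)
  keep <- positions <= N - 1
  if (!any(keep)) return(1)
  b <- seq_len(B)[keep]
  min(1, min(phyper(b - 1, B, N - B, positions[keep], lower.tail = FALSE)))
}

# Exact mHG p-value by exhaustive enumeration of all C(N, B) label
# placements; ties on the discrete tail support compared with the same
# relative tolerance the implementation uses.
oracle_mhg_pvalue <- function(stat, N, B, tol = 1e-9) {
  placements <- utils::combn(N, B)
  stats <- apply(placements, 2, oracle_stat, N = N)
  mean(stats <= stat * (1 + tol))
}

# Raw count table from a guides-by-samples matrix plus design vectors.
make_counts <- function(mat, background, timepoint, replicate,
                        stage = "raw") {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  ids <- sprintf("%s_%s_r%d", substr(background, 1, 3), timepoint,
                 replicate)
  colnames(mat) <- ids
  samples <- tibble::tibble(sample_id = ids, background = background,
                            timepoint = timepoint,
                            replicate = as.integer(replicate))
  count_table(mat, samples, stage = stage)
}

# Normalized pooled table (one column per background/timepoint) straight
# from start/end vectors, for exercising log2FC and filtering in
# isolation.
make_norm <- function(ref_start, ref_end, mut_start = NULL,
                      mut_end = NULL, ids = NULL) {
  cols <- list(reference_start = ref_start, reference_end = ref_end)
  if (!is.null(mut_start))
    cols <- c(cols, list(mutant_start = mut_start, mutant_end = mut_end))
  mat <- do.call(cbind, cols)
  rownames(mat) <- if (is.null(ids)) sprintf("g%02d", seq_len(nrow(mat)))
    else ids
  bg <- sub("_(start|end)$", "", colnames(mat))
  tp <- sub("^.*_", "", colnames(mat))
  samples <- tibble::tibble(sample_id = colnames(mat), background = bg,
                            timepoint = tp, replicate = NA_integer_)
  count_table(mat, samples, stage = "normalized")
}

# Minimal annotation tibble: targeting guides per gene plus controls.
make_annotation <- function(genes, controls = character(0)) {
  tibble::tibble(
    guide_id = c(names(genes), controls),
    target_gene = c(unname(genes), rep(NA_character_, length(controls))),
    is_control = c(rep(FALSE, length(genes)), rep(TRUE, length(controls)))
  )
}

# Hand-built simulation truth for closed-form growth checks.
make_truth <- function(genes_tbl, guides_tbl, seed = 1L) {
  structure(list(genes = genes_tbl, guides = guides_tbl, seed = seed),
            class = "sim_truth")
}
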