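# Gene-level genetic-interaction scoring: per-guide fitness differences
# between the mutant and reference screens, ranked-list mHG testing in
# both directions, FDR control and tiered hit calling.

#' Per-guide fitness difference between screens
#'
#' For every guide passing the coverage filter in both backgrounds,
#' `delta = log2fc_centered(mutant) - log2fc_centered(reference)`.
#' Guides are ranked ascending, from the strongest synthetic-sick signal
#' (most negative) to the strongest suppressor signal, with deterministic
#' tie-breaking by guide id (byte order).  Guides failing a filter or
#' missing from one background are excluded and reported.
#'
#' @param fitness Fitness tibble from [compute_fitness()] with both
#'   backgrounds present.
#' @return List with `delta` — tibble `guide_id`, `delta`, `rank`
#'   (sorted ascending; `group` marks blocks of tied deltas) — and
#'   `excluded` — tibble `guide_id`, `reason`.
#' @export
guide_delta <- function(fitness) {
  need <- c("guide_id", "background", "log2fc_centered", "passed_filter")
  stopifnot(all(need %in% names(fitness)))
  ref <- fitness[fitness$background == "reference", ]
  mut <- fitness[fitness$background == "mutant", ]
  if (nrow(ref) == 0 || nrow(mut) == 0)
    stop("guide_delta: both backgrounds must be present", call. = FALSE)

  all_ids <- union(ref$guide_id, mut$guide_id)
  i_ref <- match(all_ids, ref$guide_id)
  i_mut <- match(all_ids, mut$guide_id)
  reason <- rep(NA_character_, length(all_ids))
  reason[is.na(i_ref)] <- "missing_in_reference"
  reason[is.na(i_mut)] <- "missing_in_mutant"
  ok <- is.na(reason)
  fail_ref <- ok & !ref$passed_filter[i_ref]
  fail_mut <- ok & !mut$passed_filter[i_mut]
  reason[fail_ref & fail_mut] <- "failed_filter_both"
  reason[fail_ref & !fail_mut] <- "failed_filter_reference"
  reason[!fail_ref & fail_mut] <- "failed_filter_mutant"
  keep <- is.na(reason)

  ids <- all_ids[keep]
  delta <- mut$log2fc_centered[i_mut[keep]] - ref$log2fc_centered[i_ref[keep]]
  ord <- order(delta, ids, method = "radix")
  ids <- ids[ord]
  delta <- delta[ord]
  n <- length(ids)
  group <- if (n > 0) cumsum(c(TRUE, delta[-1] != delta[-n])) else integer(0)
  list(
    delta = tibble::tibble(guide_id = ids, delta = delta,
                           rank = seq_len(n), group = as.integer(group)),
    excluded = tibble::tibble(guide_id = all_ids[!keep],
                              reason = reason[!keep])
  )
}

#' Score per-gene genetic interactions on the ranked guide differences
#'
#' For each gene with at least one guide in the ranked table: the GI
#' score is the signed median of its guides' deltas; the mHG test is run
#' on the ascending list (synthetic-sick direction) and on the reversed
#' list (suppressor direction), each calibrated with its exact null
#' p-value, and the reported p-value is the smaller of the two doubled
#' (Bonferroni over the two orientations, capped at 1).  Genes whose
#' guides were all filtered out are emitted with absent statistics.
#'
#' @param delta Ranked delta tibble from [guide_delta()] (the `$delta`
#'   element).
#' @param annotation Guide annotation tibble.
#' @param config A [pipeline_config()] (unused thresholds are applied
#'   later by [classify_hits()]).
#' @return Tibble `gene`, `n_guides`, `gi_score`, `mhg_stat`, `pvalue`,
#'   `direction` (`negative`/`positive`), in annotation gene order;
#'   `qvalue` and `tier` are added by [bh_adjust()] / [classify_hits()].
#' @export
score_genes <- function(delta, annotation, config = pipeline_config()) {
  stopifnot(all(c("guide_id", "delta", "rank") %in% names(delta)))
  if (nrow(delta) == 0) stop("score_genes: empty delta table", call. = FALSE)
  N <- nrow(delta)
  groups <- if ("group" %in% names(delta)) delta$group else
    as.integer(cumsum(c(TRUE, delta$delta[-1] != delta$delta[-N])))
  groups_rev <- rev(groups)

  targeting <- annotation[!annotation$is_control & !is.na(annotation$target_gene), ]
  genes <- unique(targeting$target_gene)
  rank_of <- structure(delta$rank, names = delta$guide_id)

  res <- lapply(genes, function(gene) {
    gids <- targeting$guide_id[targeting$target_gene == gene]
    r <- rank_of[gids]
    r <- unname(r[!is.na(r)])
    B <- length(r)
    if (B == 0) {
      return(tibble::tibble(gene = gene, n_guides = 0L,
                            gi_score = NA_real_, mhg_stat = NA_real_,
                            pvalue = NA_real_, direction = NA_character_))
    }
    asc <- .mhg_rank_stat(r, N, groups)
    dsc <- .mhg_rank_stat(N + 1 - r, N, groups_rev)
    p_asc <- mhg_exact_pvalue(asc$stat, N, B)
    p_dsc <- mhg_exact_pvalue(dsc$stat, N, B)
    negative <- p_asc <= p_dsc
    tibble::tibble(
      gene = gene, n_guides = as.integer(B),
      gi_score = median(delta$delta[r]),
      mhg_stat = if (negative) asc$stat else dsc$stat,
      pvalue = min(1, 2 * min(p_asc, p_dsc)),
      direction = if (negative) "negative" else "positive")
  })
  dplyr::bind_rows(res)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1,
#' in input order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Vector of p-values in `(0, 1]`.
#' @return Vector of q-values, elementwise `>= pvalues`.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1))
    stop("bh_adjust: p-values must lie in (0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Tiered hit calling
#'
#' `tier2` requires `qvalue < fdr_threshold` and `|gi_score| > gi_tier2`;
#' `tier1` requires `qvalue < fdr_threshold` and `|gi_score| > gi_tier1`;
#' everything else (including untested genes) is `none`.  Thresholds
#' compare the magnitude of the GI score; the signed score is kept.
#'
#' @param results Gene tibble with `gi_score` and `qvalue` populated.
#' @param config A [pipeline_config()].
#' @return `results` with a `tier` column (`none`/`tier1`/`tier2`).
#' @export
classify_hits <- function(results, config = pipeline_config()) {
  stopifnot(all(c("gi_score", "qvalue") %in% names(results)))
  sig <- !is.na(results$qvalue) & results$qvalue < config$fdr_threshold
  mag <- abs(results$gi_score)
  tier <- rep("none", nrow(results))
  tier[sig & !is.na(mag) & mag > config$gi_tier1] <- "tier1"
  tier[sig & !is.na(mag) & mag > config$gi_tier2] <- "tier2"
  results$tier <- tier
  results
}
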