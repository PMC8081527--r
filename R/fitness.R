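# Guide-level fitness: sample-size normalization, replicate pooling,
# coverage filtering, log2 fold-change with +1 pseudocounts, and
# centring on the median of non-targeting control guides.

#' Pipeline thresholds and options
#'
#' @param min_norm_reads Guides with fewer than this many normalized reads
#'   in the pooled start timepoint of a background fail the coverage
#'   filter there (strict `<`; the default 100 keeps a guide at exactly
#'   100 normalized reads).
#' @param fdr_threshold FDR gate for hit calling.
#' @param gi_tier1,gi_tier2 Absolute GI-score thresholds for the two hit
#'   tiers (strict `>`).
#' @param normalization_target `"mean_depth"` scales every column to the
#'   mean column total, keeping values on a read-count-like scale so the
#'   read-count filter threshold stays meaningful; `"per_million"` scales
#'   to 1e6.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_norm_reads = 100, fdr_threshold = 0.05,
                            gi_tier1 = 1, gi_tier2 = 2,
                            normalization_target = c("mean_depth",
                                                     "per_million")) {
  normalization_target <- match.arg(normalization_target)
  stopifnot(min_norm_reads >= 0, fdr_threshold > 0, fdr_threshold < 1,
            gi_tier1 >= 0, gi_tier1 <= gi_tier2)
  structure(list(min_norm_reads = as.numeric(min_norm_reads),
                 fdr_threshold = as.numeric(fdr_threshold),
                 gi_tier1 = as.numeric(gi_tier1),
                 gi_tier2 = as.numeric(gi_tier2),
                 normalization_target = normalization_target),
            class = "pipeline_config")
}

#' Normalize by sample size and pool replicates
#'
#' Each raw column is scaled to the normalization target (sample-size
#' normalization), replicate columns of the same (background, timepoint)
#' are summed to increase depth, and the pooled columns are normalized by
#' sample size once more.  The result has one column per
#' (background, timepoint) and equal column totals.
#'
#' @param raw Raw-stage [count_table()].
#' @param config A [pipeline_config()].
#' @return Normalized-stage [count_table()] with columns
#'   `<background>_<timepoint>` (replicate set to `NA`).
#' @export
normalize_and_pool <- function(raw, config = pipeline_config()) {
  stopifnot(inherits(raw, "count_table"))
  if (raw$stage != "raw")
    stop("normalize_and_pool: expected a raw-stage count table",
         call. = FALSE)
  totals <- colSums(raw$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero) > 0)
    stop("normalize_and_pool: sample '", zero[1], "' has zero total reads",
         call. = FALSE)
  target1 <- if (config$normalization_target == "per_million") 1e6 else
    mean(totals)
  norm1 <- sweep(raw$counts, 2, totals / target1, "/")

  meta <- raw$samples
  groups <- expand.grid(timepoint = .timepoints, background = .backgrounds,
                        stringsAsFactors = FALSE)
  groups <- groups[, c("background", "timepoint")]
  keep <- logical(nrow(groups))
  pooled <- matrix(0, nrow = nrow(norm1), ncol = nrow(groups),
                   dimnames = list(rownames(norm1),
                                   paste(groups$background, groups$timepoint,
                                         sep = "_")))
  for (i in seq_len(nrow(groups))) {
    idx <- which(meta$background == groups$background[i] &
                   meta$timepoint == groups$timepoint[i])
    keep[i] <- length(idx) > 0
    if (keep[i])
      pooled[, i] <- rowSums(norm1[, idx, drop = FALSE])
  }
  pooled <- pooled[, keep, drop = FALSE]
  groups <- groups[keep, , drop = FALSE]

  totals2 <- colSums(pooled)
  target2 <- if (config$normalization_target == "per_million") 1e6 else
    mean(totals2)
  norm2 <- sweep(pooled, 2, totals2 / target2, "/")

  samples <- tibble::tibble(sample_id = colnames(norm2),
                            background = groups$background,
                            timepoint = groups$timepoint,
                            replicate = NA_integer_)
  count_table(norm2, samples, stage = "normalized")
}

.norm_column <- function(norm, background, timepoint) {
  idx <- which(norm$samples$background == background &
                 norm$samples$timepoint == timepoint)
  if (length(idx) != 1)
    stop("expected one pooled column for (", background, ", ", timepoint,
         ")", call. = FALSE)
  norm$counts[, idx]
}

#' Coverage filter on initial timepoints
#'
#' A guide fails in a background when its pooled, renormalized read count
#' at the start timepoint is strictly below `min_norm_reads`.
#'
#' @param norm Normalized, pooled [count_table()] from
#'   [normalize_and_pool()].
#' @param config A [pipeline_config()].
#' @return Tibble `guide_id`, `background`, `passed_filter`.
#' @export
filter_guides <- function(norm, config = pipeline_config()) {
  stopifnot(inherits(norm, "count_table"), norm$stage == "normalized")
  backgrounds <- intersect(.backgrounds, unique(norm$samples$background))
  res <- lapply(backgrounds, function(bg) {
    start <- .norm_column(norm, bg, "start")
    tibble::tibble(guide_id = rownames(norm$counts), background = bg,
                   passed_filter = unname(start >= config$min_norm_reads))
  })
  dplyr::bind_rows(res)
}

#' Per-guide log2 fold-change
#'
#' For each background, `log2fc_raw = log2((norm_end + 1) /
#' (norm_start + 1))`; the +1 pseudocounts keep dropouts finite.
#'
#' @param norm Normalized, pooled [count_table()].
#' @return Tibble `guide_id`, `background`, `norm_start`, `norm_end`,
#'   `log2fc_raw`.
#' @export
guide_log2fc <- function(norm) {
  stopifnot(inherits(norm, "count_table"), norm$stage == "normalized")
  backgrounds <- intersect(.backgrounds, unique(norm$samples$background))
  res <- lapply(backgrounds, function(bg) {
    start <- .norm_column(norm, bg, "start")
    end <- .norm_column(norm, bg, "end")
    tibble::tibble(guide_id = rownames(norm$counts), background = bg,
                   norm_start = unname(start), norm_end = unname(end),
                   log2fc_raw = unname(log2((end + 1) / (start + 1))))
  })
  dplyr::bind_rows(res)
}

#' Centre log2 fold-changes on non-targeting controls
#'
#' Per background, subtracts the median raw log2FC of the non-targeting
#' control guides that pass the coverage filter, anchoring neutral fitness
#' at 0.  The even-size median is the mean of the two middle values.
#'
#' @param fitness Tibble from [guide_log2fc()] joined with a
#'   `passed_filter` column (see [filter_guides()]).
#' @param annotation Guide annotation tibble.
#' @return `fitness` with an added `log2fc_centered` column.
#' @export
center_on_controls <- function(fitness, annotation) {
  stopifnot(all(c("guide_id", "background", "log2fc_raw",
                  "passed_filter") %in% names(fitness)))
  ctrl_ids <- annotation$guide_id[annotation$is_control]
  out <- fitness
  out$log2fc_centered <- NA_real_
  for (bg in unique(fitness$background)) {
    in_bg <- fitness$background == bg
    ctrl <- in_bg & fitness$guide_id %in% ctrl_ids & fitness$passed_filter
    if (!any(ctrl))
      stop("center_on_controls: no non-targeting control guides pass the ",
           "filter in background '", bg, "'", call. = FALSE)
    med <- median(fitness$log2fc_raw[ctrl])
    out$log2fc_centered[in_bg] <- fitness$log2fc_raw[in_bg] - med
  }
  out
}

#' Raw counts to centred per-guide fitness
#'
#' Convenience composition: [normalize_and_pool()], [guide_log2fc()],
#' [filter_guides()], [center_on_controls()].
#'
#' @param raw Raw-stage [count_table()].
#' @param annotation Guide annotation tibble.
#' @param config A [pipeline_config()].
#' @return Fitness tibble with columns `guide_id`, `background`,
#'   `norm_start`, `norm_end`, `log2fc_raw`, `log2fc_centered`,
#'   `passed_filter`.
#' @export
compute_fitness <- function(raw, annotation, config = pipeline_config()) {
  norm <- normalize_and_pool(raw, config)
  fit <- guide_log2fc(norm)
  filt <- filter_guides(norm, config)
  fit <- dplyr::left_join(fit, filt, by = c("guide_id", "background"))
  fit <- center_on_controls(fit, annotation)
  fit[, c("guide_id", "background", "norm_start", "norm_end",
          "log2fc_raw", "log2fc_centered", "passed_filter")]
}

#' Write a per-guide fitness table
#'
#' @param fitness Fitness tibble from [compute_fitness()].
#' @param path Output TSV path.
#' @export
write_fitness_table <- function(fitness, path) {
  out <- data.frame(guide_id = fitness$guide_id,
                    background = fitness$background,
                    norm_start = .fmt_num(fitness$norm_start),
                    norm_end = .fmt_num(fitness$norm_end),
                    log2fc_raw = .fmt_num(fitness$log2fc_raw),
                    log2fc_centered = .fmt_num(fitness$log2fc_centered),
                    passed_filter = as.integer(fitness$passed_filter))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}
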