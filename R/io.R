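# Tabular I/O: guide annotation, sample metadata, count tables and
# gene-level results.  All files are header-first TSV, UTF-8, '.' decimal
# separator, no quoting.  Missing cells are an error, never silently zero.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, comment.char = "")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(what, ": missing required column(s) ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
}

#' Read a guide annotation table
#'
#' Reads the TSV mapping each guide to its target gene or marking it as a
#' non-targeting control.  Columns: `guide_id`, `target_gene`,
#' `is_control` (0/1).  `target_gene` must be empty exactly when
#' `is_control` is 1: a guide either targets one gene or is a control,
#' never both, never neither.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `guide_id` (character, unique),
#'   `target_gene` (character, `NA` for controls) and `is_control`
#'   (logical), in file order.
#' @export
read_guide_annotation <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("guide_id", "target_gene", "is_control"),
                   "guide annotation")
  if (nrow(df) == 0) stop("guide annotation: no records", call. = FALSE)
  if (!all(df$is_control %in% c("0", "1")))
    stop("guide annotation: is_control must be 0 or 1", call. = FALSE)
  is_control <- df$is_control == "1"
  target <- df$target_gene
  target[target == ""] <- NA_character_

  dup <- unique(df$guide_id[duplicated(df$guide_id)])
  if (length(dup) > 0)
    stop("guide annotation: duplicate guide_id ",
         paste0("'", dup, "'", collapse = ", "), call. = FALSE)
  # line numbers are 1-based file lines (header is line 1)
  bad_both <- which(!is.na(target) & is_control)
  if (length(bad_both) > 0)
    stop("guide annotation: line ", bad_both[1] + 1,
         ": guide '", df$guide_id[bad_both[1]],
         "' has both a target gene and the control flag", call. = FALSE)
  bad_neither <- which(is.na(target) & !is_control)
  if (length(bad_neither) > 0)
    stop("guide annotation: line ", bad_neither[1] + 1,
         ": guide '", df$guide_id[bad_neither[1]],
         "' has neither a target gene nor the control flag", call. = FALSE)

  tibble::tibble(guide_id = df$guide_id, target_gene = target,
                 is_control = is_control)
}

#' Write a guide annotation table
#'
#' @param annotation Tibble as returned by [read_guide_annotation()].
#' @param path Output TSV path.
#' @export
write_guide_annotation <- function(annotation, path) {
  out <- data.frame(
    guide_id = annotation$guide_id,
    target_gene = ifelse(is.na(annotation$target_gene), "",
                         annotation$target_gene),
    is_control = as.integer(annotation$is_control)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Read screen sample metadata
#'
#' Columns: `sample_id`, `background` (`reference`/`mutant`), `timepoint`
#' (`start`/`end`), `replicate` (positive integer).  The
#' (background, timepoint, replicate) triples must be unique and every
#' background present must have at least one start and one end sample.
#'
#' @param path Path to the sample metadata TSV.
#' @return A tibble with one row per sample, in file order.
#' @export
read_sample_meta <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("sample_id", "background", "timepoint", "replicate"),
                   "sample metadata")
  if (nrow(df) == 0) stop("sample metadata: no records", call. = FALSE)
  if (!all(df$background %in% .backgrounds))
    stop("sample metadata: background must be one of ",
         paste(.backgrounds, collapse = ", "), call. = FALSE)
  if (!all(df$timepoint %in% .timepoints))
    stop("sample metadata: timepoint must be one of ",
         paste(.timepoints, collapse = ", "), call. = FALSE)
  rep_num <- suppressWarnings(as.numeric(df$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num)))
    stop("sample metadata: replicate must be a positive integer",
         call. = FALSE)
  dup <- duplicated(df[c("background", "timepoint", "replicate")])
  if (any(dup))
    stop("sample metadata: duplicate (background, timepoint, replicate) ",
         "triple for sample '", df$sample_id[which(dup)[1]], "'",
         call. = FALSE)
  dup_id <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup_id) > 0)
    stop("sample metadata: duplicate sample_id '", dup_id[1], "'",
         call. = FALSE)
  for (bg in unique(df$background)) {
    tps <- df$timepoint[df$background == bg]
    if (!all(.timepoints %in% tps))
      stop("sample metadata: background '", bg,
           "' must have at least one start and one end sample",
           call. = FALSE)
  }
  tibble::tibble(sample_id = df$sample_id, background = df$background,
                 timepoint = df$timepoint, replicate = as.integer(rep_num))
}

#' @rdname read_sample_meta
#' @param samples Tibble of sample metadata.
#' @export
write_sample_meta <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

#' Construct a screen count table
#'
#' Light S3 container pairing a guides-by-samples count matrix with its
#' sample metadata and a processing stage tag.
#'
#' @param counts Numeric matrix, rows named by guide id, columns by
#'   sample id.  Raw-stage values must be nonnegative integers.
#' @param samples Sample metadata tibble (one row per column of `counts`,
#'   same order).
#' @param stage `"raw"` or `"normalized"`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, samples, stage = c("raw", "normalized")) {
  stage <- match.arg(stage)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("count_table: counts must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_table: counts must have guide and sample names",
         call. = FALSE)
  if (nrow(samples) != ncol(counts))
    stop("count_table: one metadata row per sample column required",
         call. = FALSE)
  if (!identical(colnames(counts), samples$sample_id))
    stop("count_table: column order must match sample metadata order",
         call. = FALSE)
  if (any(counts < 0))
    stop("count_table: negative counts", call. = FALSE)
  if (stage == "raw" && any(counts != round(counts)))
    stop("count_table: raw counts must be integers", call. = FALSE)
  structure(list(counts = counts, samples = samples, stage = stage),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " guides x ", ncol(x$counts),
      " samples, stage=", x$stage, "\n", sep = "")
  invisible(x)
}

#' Read a raw sgRNA count table
#'
#' First column `guide_id`, remaining columns named by sample id; every
#' sample column must appear in `samples`.  Values must be nonnegative
#' integers; a malformed cell is reported with its guide and sample.
#' Guides not covered by `annotation` (when given) are retained but listed
#' in the `unannotated` attribute: they are never part of any gene's guide
#' set and never controls.
#'
#' @param path Path to the count TSV.
#' @param samples Sample metadata tibble (see [read_sample_meta()]).
#' @param annotation Optional guide annotation used only to flag
#'   unannotated guides.
#' @return A raw-stage [count_table()] with attribute `unannotated`
#'   (character vector of guide ids absent from the annotation).
#' @export
read_count_table <- function(path, samples, annotation = NULL) {
  df <- .read_tsv(path)
  if (names(df)[1] != "guide_id")
    stop("count table: first column must be guide_id", call. = FALSE)
  if (ncol(df) < 2) stop("count table: no sample columns", call. = FALSE)
  sample_cols <- names(df)[-1]
  unknown <- setdiff(sample_cols, samples$sample_id)
  if (length(unknown) > 0)
    stop("count table: sample column '", unknown[1],
         "' absent from sample metadata", call. = FALSE)
  dup <- unique(df$guide_id[duplicated(df$guide_id)])
  if (length(dup) > 0)
    stop("count table: duplicate guide_id '", dup[1], "'", call. = FALSE)

  mat <- matrix(NA_real_, nrow = nrow(df), ncol = length(sample_cols),
                dimnames = list(df$guide_id, sample_cols))
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0)
      stop("count table: invalid raw count '", df[[j + 1]][bad[1]],
           "' at guide '", df$guide_id[bad[1]], "', sample '",
           sample_cols[j], "' (must be a nonnegative integer)",
           call. = FALSE)
    mat[, j] <- v
  }
  meta <- samples[match(sample_cols, samples$sample_id), , drop = FALSE]
  ct <- count_table(mat, meta, stage = "raw")
  unannotated <- character(0)
  if (!is.null(annotation))
    unannotated <- setdiff(rownames(mat), annotation$guide_id)
  attr(ct, "unannotated") <- unannotated
  ct
}

#' Write a count table
#'
#' @param ct A [count_table()].
#' @param path Output TSV path.
#' @export
write_count_table <- function(ct, path) {
  vals <- ct$counts
  chr <- if (ct$stage == "raw") {
    format(vals, scientific = FALSE, trim = TRUE)
  } else {
    matrix(.fmt_num(vals), nrow = nrow(vals), dimnames = dimnames(vals))
  }
  out <- cbind(guide_id = rownames(vals), as.data.frame(chr))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}

# 12 significant digits: round-trips all pipeline quantities losslessly at
# the precision the result files promise
.fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Write gene-level interaction results
#'
#' Emits the per-gene TSV with columns `gene`, `n_guides`, `gi_score`,
#' `mhg_stat`, `pvalue`, `qvalue`, `direction`, `tier`, sorted by qvalue
#' ascending then |gi_score| descending (untested genes, with absent
#' statistics, last).  Numbers are written with 12 significant digits and
#' round-trip losslessly through [read_gene_results()].
#'
#' @param results Gene interaction tibble (see [score_genes()]).
#' @param path Output TSV path.
#' @export
write_gene_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0)
    stop("write_gene_results: results must be non-empty", call. = FALSE)
  ord <- order(results$qvalue, -abs(results$gi_score), results$gene,
               na.last = TRUE, method = "radix")
  r <- results[ord, , drop = FALSE]
  lines <- paste(
    r$gene,
    ifelse(is.na(r$n_guides), "NA", as.character(r$n_guides)),
    .fmt_num(r$gi_score),
    .fmt_num(r$mhg_stat),
    .fmt_num(r$pvalue),
    .fmt_num(r$qvalue),
    ifelse(is.na(r$direction), "NA", r$direction),
    r$tier,
    sep = "\t"
  )
  header <- paste(c("gene", "n_guides", "gi_score", "mhg_stat", "pvalue",
                    "qvalue", "direction", "tier"), collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con)
  invisible(NULL)
}

#' @rdname write_gene_results
#' @export
read_gene_results <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("gene", "n_guides", "gi_score", "mhg_stat",
                         "pvalue", "qvalue", "direction", "tier"),
                   "gene results")
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  tibble::tibble(
    gene = df$gene,
    n_guides = as.integer(num(df$n_guides)),
    gi_score = num(df$gi_score),
    mhg_stat = num(df$mhg_stat),
    pvalue = num(df$pvalue),
    qvalue = num(df$qvalue),
    direction = ifelse(df$direction == "NA", NA_character_, df$direction),
    tier = df$tier
  )
}
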