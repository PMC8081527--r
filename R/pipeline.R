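# End-to-end orchestration: counts (real or simulated) -> fitness ->
# ranked differences -> gene scores -> FDR -> tiers, with a run manifest
# recording resolved settings and per-stage row counts.

.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(stage, ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full interaction-scoring pipeline
#'
#' Accepts either a [sim_config()] (fully synthetic end-to-end run) or a
#' named list of input paths (`counts`, `samples`, `guides`).  Executes
#' normalization and pooling, coverage filtering, log2FC computation,
#' control centring, per-guide differencing, gene scoring, BH adjustment
#' and tier classification.  Stage errors are re-raised with the stage
#' name prefixed.
#'
#' @param inputs A `sim_config`, or `list(counts =, samples =, guides =)`
#'   of TSV paths.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes
#'   `gene_results.tsv`, `fitness.tsv`, `excluded_guides.tsv` and
#'   `manifest.json` there.
#' @param quiet Suppress per-stage progress messages.
#' @return List with `results` (gene tibble incl. `qvalue`, `tier`),
#'   `manifest`, `fitness`, `delta`, `excluded`, `annotation` and, for
#'   synthetic runs, `truth`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  truth <- NULL
  digests <- NULL
  sim_cfg <- NULL

  if (inherits(inputs, "sim_config")) {
    sim_cfg <- inputs
    sim <- .with_stage("simulate", simulate_paired_screens(inputs))
    annotation <- sim$annotation
    raw <- sim$counts
    truth <- sim$truth
    say("simulate: ", nrow(raw$counts), " guides x ", ncol(raw$counts),
        " samples (seed ", inputs$seed, ")")
  } else {
    stopifnot(is.list(inputs),
              all(c("counts", "samples", "guides") %in% names(inputs)))
    annotation <- .with_stage("read_guides",
                              read_guide_annotation(inputs$guides))
    samples <- .with_stage("read_samples", read_sample_meta(inputs$samples))
    raw <- .with_stage("read_counts",
                       read_count_table(inputs$counts, samples, annotation))
    paths <- unlist(inputs[c("counts", "samples", "guides")])
    digests <- as.list(stats::setNames(unname(tools::md5sum(paths)),
                                       names(paths)))
    say("read: ", nrow(raw$counts), " guides x ", ncol(raw$counts),
        " samples")
  }

  norm <- .with_stage("normalize_and_pool", normalize_and_pool(raw, config))
  fit <- .with_stage("guide_log2fc", guide_log2fc(norm))
  filt <- .with_stage("filter_guides", filter_guides(norm, config))
  fit <- dplyr::left_join(fit, filt, by = c("guide_id", "background"))
  fit <- .with_stage("center_on_controls", center_on_controls(fit, annotation))
  passed <- vapply(.backgrounds, function(bg)
    sum(fit$passed_filter[fit$background == bg]), integer(1))
  say("fitness: passed filter reference=", passed[["reference"]],
      " mutant=", passed[["mutant"]])

  gd <- .with_stage("guide_delta", guide_delta(fit))
  say("delta: ", nrow(gd$delta), " guides ranked, ",
      nrow(gd$excluded), " excluded")
  res <- .with_stage("score_genes", score_genes(gd$delta, annotation, config))
  tested <- !is.na(res$pvalue)
  res$qvalue <- NA_real_
  res$qvalue[tested] <- .with_stage("bh_adjust", bh_adjust(res$pvalue[tested]))
  res <- .with_stage("classify_hits", classify_hits(res, config))
  n_t2 <- sum(res$tier == "tier2")
  n_t1p <- sum(res$tier %in% c("tier1", "tier2"))
  say("genes: ", sum(tested), " tested, ", n_t1p, " hits (",
      n_t2, " tier2)")

  manifest <- list(
    package_version = as.character(utils::packageVersion("crisprigi")),
    pipeline_config = unclass(config),
    sim_config = if (!is.null(sim_cfg)) unclass(sim_cfg) else NULL,
    input_md5 = digests,
    seed = if (!is.null(sim_cfg)) sim_cfg$seed else NULL,
    counts = list(
      guides_read = nrow(raw$counts),
      samples_read = ncol(raw$counts),
      guides_passed_reference = unname(passed[["reference"]]),
      guides_passed_mutant = unname(passed[["mutant"]]),
      guides_ranked = nrow(gd$delta),
      guides_excluded = nrow(gd$excluded),
      genes_in_annotation = length(unique(
        annotation$target_gene[!annotation$is_control])),
      genes_tested = sum(tested),
      hits_tier1_or_tier2 = n_t1p,
      hits_tier2 = n_t2
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_results(res, file.path(out_dir, "gene_results.tsv"))
    write_fitness_table(fit, file.path(out_dir, "fitness.tsv"))
    utils::write.table(as.data.frame(gd$excluded),
                       file.path(out_dir, "excluded_guides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }

  list(results = res, manifest = manifest, fitness = fit,
       delta = gd$delta, excluded = gd$excluded,
       annotation = annotation, truth = truth)
}
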