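# Synthetic paired-screen generator.
#
# Emulates a genome-wide CRISPRi library screened in two isogenic
# backgrounds: uniform initial plasmid abundances, deterministic
# exponential competition over a fixed number of generations, and
# multinomial sequencing sampling at both timepoints.  All randomness
# flows from the config seed; per-sample sub-seeds are derived with a
# counter so results do not depend on sample processing order.

#' Configuration for a synthetic paired screen
#'
#' Defaults describe a genome-scale screen: five sgRNAs per gene, ~17
#' generations of induced competitive growth, two replicates per
#' background, and deep sequencing at 10^4 expected reads per guide.
#' Per-generation fitness effects `s` are 0 for a neutral majority of
#' genes and `-|N(0, fitness_sd)|` for the rest; a planted subset of
#' genes additionally receives an interaction effect `delta_effect` in the
#' mutant background only.  Guide efficacy scales the gene effect
#' linearly, modelling partial knockdown.
#'
#' @param n_genes Number of targeted genes.
#' @param guides_per_gene Guides per gene.
#' @param n_controls Number of non-targeting control guides.
#' @param generations Generations of competitive growth between the start
#'   and end timepoints.
#' @param replicates Replicate cultures per background.
#' @param depth_per_sample Expected sequencing reads per guide in each
#'   sample; the multinomial size is `depth_per_sample * n_guides`.
#' @param fitness_sd Scale (per generation) of background fitness effects
#'   of deleterious genes.
#' @param frac_deleterious Fraction of genes with a nonzero background
#'   fitness effect.
#' @param frac_interacting Fraction of genes with a planted genetic
#'   interaction.
#' @param delta_effect Per-generation interaction effect added to the
#'   mutant background for interacting genes (negative = synthetic
#'   sickness).
#' @param efficacy_range Range (low, high) of per-guide knockdown
#'   efficacies, drawn uniformly.
#' @param seed Master seed; every downstream draw derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, guides_per_gene = 5,
                       n_controls = 100, generations = 17,
                       replicates = 2, depth_per_sample = 10000,
                       fitness_sd = 0.1, frac_deleterious = 0.3,
                       frac_interacting = 0.05, delta_effect = -0.15,
                       efficacy_range = c(0.6, 1), seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              guides_per_gene = as.integer(guides_per_gene),
              n_controls = as.integer(n_controls),
              generations = as.numeric(generations),
              replicates = as.integer(replicates),
              depth_per_sample = as.integer(depth_per_sample),
              fitness_sd = as.numeric(fitness_sd),
              frac_deleterious = as.numeric(frac_deleterious),
              frac_interacting = as.numeric(frac_interacting),
              delta_effect = as.numeric(delta_effect),
              efficacy_range = as.numeric(efficacy_range),
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1, cfg$guides_per_gene >= 1, cfg$n_controls >= 0,
            cfg$generations >= 0, cfg$replicates >= 1,
            cfg$depth_per_sample >= 1, cfg$fitness_sd >= 0,
            cfg$frac_deleterious >= 0, cfg$frac_deleterious <= 1,
            cfg$frac_interacting >= 0, cfg$frac_interacting <= 1,
            length(cfg$efficacy_range) == 2,
            cfg$efficacy_range[1] >= 0, cfg$efficacy_range[2] <= 1,
            cfg$efficacy_range[1] <= cfg$efficacy_range[2])
  class(cfg) <- "sim_config"
  cfg
}

# counter-based sub-seed derivation: deterministic, order-independent,
# stays inside 32-bit integer range
.derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + counter * 9749) %% 2147483647L)
}

#' Build a synthetic guide library with planted ground truth
#'
#' @param config A [sim_config()].
#' @return A list with `annotation` (guide annotation tibble) and `truth`,
#'   an object of class `sim_truth` holding per-gene effects
#'   (`genes`: gene, s_ref, s_mut, delta, interacting) and per-guide
#'   efficacies (`guides`: guide_id, gene, efficacy, is_control).
#' @export
build_synthetic_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.derive_seed(config$seed, 1L))
  ng <- config$n_genes
  gw <- max(4L, nchar(as.character(ng)))
  genes <- sprintf("gene%0*d", gw, seq_len(ng))

  deleterious <- runif(ng) < config$frac_deleterious
  s_ref <- ifelse(deleterious, -abs(rnorm(ng, 0, config$fitness_sd)), 0)
  n_int <- floor(config$frac_interacting * ng)
  interacting <- rep(FALSE, ng)
  if (n_int > 0) interacting[sample.int(ng, n_int)] <- TRUE
  delta <- ifelse(interacting, config$delta_effect, 0)
  s_mut <- s_ref + delta

  gpg <- config$guides_per_gene
  target_gene <- rep(genes, each = gpg)
  guide_id <- paste0(target_gene, "_g", rep(seq_len(gpg), times = ng))
  efficacy <- runif(ng * gpg, config$efficacy_range[1],
                    config$efficacy_range[2])
  if (config$n_controls > 0) {
    cw <- max(4L, nchar(as.character(config$n_controls)))
    ctrl_id <- sprintf("ctrl%0*d", cw, seq_len(config$n_controls))
  } else ctrl_id <- character(0)

  all_ids <- c(guide_id, ctrl_id)
  all_genes <- c(target_gene, rep(NA_character_, length(ctrl_id)))
  all_ctrl <- c(rep(FALSE, length(guide_id)), rep(TRUE, length(ctrl_id)))
  annotation <- tibble::tibble(guide_id = all_ids, target_gene = all_genes,
                               is_control = all_ctrl)
  truth <- structure(list(
    genes = tibble::tibble(gene = genes, s_ref = s_ref, s_mut = s_mut,
                           delta = delta, interacting = interacting),
    guides = tibble::tibble(
      guide_id = annotation$guide_id,
      gene = annotation$target_gene,
      efficacy = c(efficacy, rep(NA_real_, length(ctrl_id))),
      is_control = annotation$is_control),
    seed = config$seed
  ), class = "sim_truth")
  list(annotation = annotation, truth = truth)
}

#' Deterministic competitive growth of the guide pool
#'
#' Relative abundance after `generations` doublings of the unperturbed
#' population: `a_i` proportional to `2^(generations * w_i)` from uniform
#' initial abundances, where `w_i = s_gene(background) * efficacy_i` for targeting
#' guides and 0 for non-targeting controls.
#'
#' @param truth A `sim_truth` from [build_synthetic_library()].
#' @param background `"reference"` or `"mutant"`.
#' @param generations Number of growth generations (0 returns the initial
#'   uniform abundances).
#' @return Named numeric vector of relative abundances summing to 1.
#' @export
simulate_growth <- function(truth, background, generations) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(background) != 1 || !background %in% .backgrounds)
    stop("simulate_growth: unknown background '", background,
         "' (must be 'reference' or 'mutant')", call. = FALSE)
  g <- truth$guides
  s_col <- if (background == "reference") "s_ref" else "s_mut"
  s_gene <- truth$genes[[s_col]][match(g$gene, truth$genes$gene)]
  w <- ifelse(g$is_control, 0, s_gene * g$efficacy)
  a <- 2^(generations * w)
  a <- a / sum(a)
  names(a) <- g$guide_id
  a
}

#' Multinomial sequencing of a guide pool
#'
#' One multinomial draw of `depth * length(abundance)` reads over the
#' abundance vector, modelling quantitative sequencing of the plasmid
#' pool.
#'
#' @param abundance Named nonnegative vector summing to 1 (tolerance
#'   1e-9).
#' @param depth Expected reads per guide.
#' @param seed Seed for this draw.
#' @return Named integer vector of read counts.
#' @export
sample_sequencing <- function(abundance, depth, seed) {
  if (any(abundance < 0) || abs(sum(abundance) - 1) > 1e-9)
    stop("sample_sequencing: abundances must be nonnegative and sum to 1",
         call. = FALSE)
  stopifnot(depth >= 1)
  size <- round(depth * length(abundance))
  if (size > .Machine$integer.max)
    stop("sample_sequencing: requested depth exceeds integer read count",
         call. = FALSE)
  set.seed(seed)
  counts <- as.integer(rmultinom(1, size = size, prob = abundance))
  names(counts) <- names(abundance)
  counts
}

#' Simulate a pair of CRISPRi screens with known ground truth
#'
#' Generates the full paired design: reference and mutant backgrounds,
#' start and end timepoints, `replicates` cultures each.  Start samples
#' are sequenced from the uniform initial abundances, end samples from the
#' abundances after [simulate_growth()].  Each sample gets its own
#' counter-derived sub-seed, so the output is bitwise reproducible from
#' `config$seed` alone.
#'
#' @param config A [sim_config()].
#' @return List with `annotation`, `counts` (raw-stage [count_table()]
#'   with `2 * 2 * replicates` samples) and `truth`.
#' @export
simulate_paired_screens <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lib <- build_synthetic_library(config)
  truth <- lib$truth
  a0 <- simulate_growth(truth, "reference", 0)

  grid <- expand.grid(replicate = seq_len(config$replicates),
                      timepoint = .timepoints, background = .backgrounds,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("background", "timepoint", "replicate")]
  grid$sample_id <- sprintf("%s_%s_r%d",
                            ifelse(grid$background == "reference",
                                   "ref", "mut"),
                            grid$timepoint, grid$replicate)
  abund <- list(
    reference = simulate_growth(truth, "reference", config$generations),
    mutant = simulate_growth(truth, "mutant", config$generations)
  )
  mat <- matrix(0L, nrow = length(a0), ncol = nrow(grid),
                dimnames = list(names(a0), grid$sample_id))
  for (i in seq_len(nrow(grid))) {
    a <- if (grid$timepoint[i] == "start") a0 else abund[[grid$background[i]]]
    mat[, i] <- sample_sequencing(a, config$depth_per_sample,
                                  .derive_seed(config$seed, 100L + i))
  }
  samples <- tibble::tibble(sample_id = grid$sample_id,
                            background = grid$background,
                            timepoint = grid$timepoint,
                            replicate = as.integer(grid$replicate))
  list(annotation = lib$annotation,
       counts = count_table(mat, samples, stage = "raw"),
       truth = truth)
}

#' Write simulation ground truth
#'
#' @param truth A `sim_truth`.
#' @param path Output TSV path (`gene  s_ref  s_mut  delta  interacting`).
#' @export
write_sim_truth <- function(truth, path) {
  g <- truth$genes
  out <- data.frame(gene = g$gene, s_ref = .fmt_num(g$s_ref),
                    s_mut = .fmt_num(g$s_mut), delta = .fmt_num(g$delta),
                    interacting = as.integer(g$interacting))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(NULL)
}
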