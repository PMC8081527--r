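test_that("normalization preserves proportions through pooling", {
  mat <- matrix(c(10, 30, 20, 60), nrow = 2,
                dimnames = list(c("g1", "g2"), NULL))
  # two replicate start columns with equal proportions plus a token end
  mat2 <- cbind(mat, end = c(1, 1))
  ct <- make_counts(mat2, background = rep("reference", 3),
                    timepoint = c("start", "start", "end"),
                    replicate = c(1L, 2L, 1L))
  cfg <- pipeline_config(normalization_target = "per_million")
  norm <- normalize_and_pool(ct, cfg)
  start <- norm$counts[, "reference_start"]
  expect_equal(unname(start / sum(start)), c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(norm$stage, "normalized")
})

test_that("pooling a single replicate is the identity", {
  mat <- matrix(c(5, 15, 40, 10), nrow = 2,
                dimnames = list(c("g1", "g2"), NULL))
  ct <- make_counts(mat, background = rep("reference", 2),
                    timepoint = c("start", "end"), replicate = c(1L, 1L))
  cfg <- pipeline_config(normalization_target = "per_million")
  norm <- normalize_and_pool(ct, cfg)
  expect_equal(unname(norm$counts[, "reference_start"]),
               c(5, 15) / 20 * 1e6, tolerance = 1e-12)
})

test_that("pooling identical replicate columns equals using one of them", {
  mat1 <- matrix(c(5, 15, 40, 10), nrow = 2,
                 dimnames = list(c("g1", "g2"), NULL))
  one <- make_counts(mat1, background = rep("reference", 2),
                     timepoint = c("start", "end"), replicate = c(1L, 1L))
  mat2 <- mat1[, c(1, 1, 2, 2)]
  two <- make_counts(mat2, background = rep("reference", 4),
                     timepoint = c("start", "start", "end", "end"),
                     replicate = c(1L, 2L, 1L, 2L))
  cfg <- pipeline_config(normalization_target = "per_million")
  expect_equal(normalize_and_pool(two, cfg)$counts,
               normalize_and_pool(one, cfg)$counts, tolerance = 1e-12)
})

test_that("normalized column sums are equal", {
  set.seed(2)
  mat <- matrix(rpois(40, 50), nrow = 5)
  rownames(mat) <- sprintf("g%d", 1:5)
  ct <- make_counts(mat, background = rep(c("reference", "mutant"), each = 4),
                    timepoint = rep(c("start", "start", "end", "end"), 2),
                    replicate = rep(c(1L, 2L), 4))
  for (target in c("mean_depth", "per_million")) {
    norm <- normalize_and_pool(ct, pipeline_config(
      normalization_target = target))
    sums <- colSums(norm$counts)
    expect_lt(diff(range(sums)) / mean(sums), 1e-9)
  }
})

test_that("a sample with zero total reads is a named data error", {
  mat <- matrix(c(1, 2, 0, 0, 3, 4), nrow = 2,
                dimnames = list(c("g1", "g2"), NULL))
  ct <- make_counts(mat, background = rep("reference", 3),
                    timepoint = c("start", "start", "end"),
                    replicate = c(1L, 2L, 1L))
  expect_error(normalize_and_pool(ct), "ref_start_r2")
})

test_that("log2 fold-change applies the +1 pseudocount formula", {
  norm <- make_norm(ref_start = c(1, 0, 127), ref_end = c(7, 0, 0))
  fit <- guide_log2fc(norm)
  expect_equal(fit$log2fc_raw, c(2, 0, -7), tolerance = 1e-12)
  expect_equal(fit$norm_start, c(1, 0, 127))
  expect_equal(fit$norm_end, c(7, 0, 0))
})

test_that("scaling a raw sample column leaves log2FC unchanged", {
  set.seed(5)
  mat <- matrix(rpois(24, 200) + 1, nrow = 6)
  rownames(mat) <- sprintf("g%d", 1:6)
  bg <- rep("reference", 4); tp <- c("start", "start", "end", "end")
  ct1 <- make_counts(mat, bg, tp, rep(c(1L, 2L), 2))
  mat2 <- mat; mat2[, 3] <- mat2[, 3] * 9
  ct2 <- make_counts(mat2, bg, tp, rep(c(1L, 2L), 2))
  # a fixed target absorbs the factor exactly; the mean-depth target also
  # absorbs it in the ratio but shifts the absolute scale feeding the +1
  # pseudocount, so it is only asymptotically invariant
  cfg <- pipeline_config(normalization_target = "per_million")
  f1 <- guide_log2fc(normalize_and_pool(ct1, cfg))
  f2 <- guide_log2fc(normalize_and_pool(ct2, cfg))
  expect_equal(f2$log2fc_raw, f1$log2fc_raw, tolerance = 1e-12)
  g1 <- guide_log2fc(normalize_and_pool(ct1))
  g2 <- guide_log2fc(normalize_and_pool(ct2))
  expect_equal(g2$log2fc_raw, g1$log2fc_raw, tolerance = 5e-2)
})

test_that("the coverage filter is strict at the threshold", {
  norm <- make_norm(ref_start = c(99.99, 100, 0, 250),
                    ref_end = c(1, 1, 1, 1))
  filt <- filter_guides(norm, pipeline_config(min_norm_reads = 100))
  expect_equal(filt$passed_filter, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("centring subtracts the filtered-control median per background", {
  # controls with raw log2FC {-0.2, 0.1, 0.4}: subtract the median 0.1
  start <- rep(1000, 5)
  end <- (start + 1) * 2^c(1.5, -0.2, 0.1, 0.4, -3) - 1
  norm <- make_norm(start, end, ids = c("g1", "c1", "c2", "c3", "g2"))
  ann <- make_annotation(c(g1 = "geneA", g2 = "geneB"),
                         c("c1", "c2", "c3"))
  fit <- guide_log2fc(norm)
  fit$passed_filter <- TRUE
  cen <- center_on_controls(fit, ann)
  expect_equal(cen$log2fc_centered, cen$log2fc_raw - 0.1,
               tolerance = 1e-12)
  ctrl <- cen$log2fc_centered[cen$guide_id %in% c("c1", "c2", "c3")]
  expect_equal(median(ctrl), 0, tolerance = 1e-12)
})

test_that("centring handles single and even-sized control sets", {
  start <- rep(1000, 3)
  end1 <- (start + 1) * 2^c(1, 0.7, 2) - 1
  norm <- make_norm(start, end1, ids = c("g1", "c1", "g2"))
  ann <- make_annotation(c(g1 = "geneA", g2 = "geneB"), "c1")
  fit <- guide_log2fc(norm); fit$passed_filter <- TRUE
  cen <- center_on_controls(fit, ann)
  expect_equal(cen$log2fc_centered, cen$log2fc_raw - 0.7,
               tolerance = 1e-12)

  # even number of controls {0, 1}: shift by the mean of the middle pair
  end2 <- (start + 1) * 2^c(0, 1, 2) - 1
  norm2 <- make_norm(start, end2, ids = c("c1", "c2", "g1"))
  ann2 <- make_annotation(c(g1 = "geneA"), c("c1", "c2"))
  fit2 <- guide_log2fc(norm2); fit2$passed_filter <- TRUE
  cen2 <- center_on_controls(fit2, ann2)
  expect_equal(cen2$log2fc_centered, cen2$log2fc_raw - 0.5,
               tolerance = 1e-12)
})

test_that("centring only uses controls that pass the filter", {
  start <- rep(1000, 3)
  end <- (start + 1) * 2^c(0, 5, 1) - 1
  norm <- make_norm(start, end, ids = c("c1", "c2", "g1"))
  ann <- make_annotation(c(g1 = "geneA"), c("c1", "c2"))
  fit <- guide_log2fc(norm)
  fit$passed_filter <- c(TRUE, FALSE, TRUE)  # c2 fails
  cen <- center_on_controls(fit, ann)
  expect_equal(cen$log2fc_centered, cen$log2fc_raw - 0,
               tolerance = 1e-12)
  fit$passed_filter <- c(FALSE, FALSE, TRUE)
  expect_error(center_on_controls(fit, ann), "reference")
})

test_that("simulated screens recover generations * s * efficacy", {
  cfg <- sim_config(n_genes = 100, n_controls = 30,
                    depth_per_sample = 1e4, frac_interacting = 0,
                    seed = 31)
  sim <- simulate_paired_screens(cfg)
  fit <- compute_fitness(sim$counts, sim$annotation)
  ref <- fit[fit$background == "reference", ]
  g <- sim$truth$guides[match(ref$guide_id, sim$truth$guides$guide_id), ]
  gene_mean <- tapply(ref$log2fc_centered[!g$is_control],
                      g$gene[!g$is_control], mean)
  eff_mean <- tapply(g$efficacy[!g$is_control], g$gene[!g$is_control],
                     mean)
  tr <- sim$truth$genes
  expected <- 17 * tr$s_ref[match(names(gene_mean), tr$gene)] *
    eff_mean[names(gene_mean)]
  expect_lt(max(abs(gene_mean - expected)), 0.1)
})
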