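fitness_row <- function(guide_id, background, centered, passed = TRUE) {
  tibble::tibble(guide_id = guide_id, background = background,
                 log2fc_centered = centered, passed_filter = passed)
}

test_that("guide deltas subtract reference from mutant and rank ascending", {
  fit <- dplyr::bind_rows(
    fitness_row(c("g1", "g2", "g3"), "reference", c(-1.0, 0.5, 0.0)),
    fitness_row(c("g1", "g2", "g3"), "mutant", c(-3.0, 1.0, 0.0)))
  gd <- guide_delta(fit)
  d <- gd$delta
  expect_equal(d$guide_id[d$rank], d$guide_id)  # sorted table
  expect_equal(d$delta[d$guide_id == "g1"], -2.0)
  expect_equal(d$rank, seq_len(3))
  expect_true(all(diff(d$delta) >= 0))
  expect_equal(nrow(gd$excluded), 0)
})

test_that("deltas {0.5, -2, 0} rank as {3, 1, 2}", {
  fit <- dplyr::bind_rows(
    fitness_row(c("g1", "g2", "g3"), "reference", c(0, 0, 0)),
    fitness_row(c("g1", "g2", "g3"), "mutant", c(0.5, -2.0, 0.0)))
  d <- guide_delta(fit)$delta
  expect_equal(d$rank[match(c("g1", "g2", "g3"), d$guide_id)],
               c(3L, 1L, 2L))
})

test_that("guides failing a filter or missing a background are excluded", {
  fit <- dplyr::bind_rows(
    fitness_row(c("g1", "g2", "g3"), "reference", c(0, 0, 0),
                passed = c(TRUE, FALSE, TRUE)),
    fitness_row(c("g1", "g2", "g4"), "mutant", c(-1, 0, 0)))
  gd <- guide_delta(fit)
  expect_equal(sort(gd$delta$guide_id), "g1")
  ex <- gd$excluded
  expect_equal(ex$reason[ex$guide_id == "g2"], "failed_filter_reference")
  expect_equal(ex$reason[ex$guide_id == "g3"], "missing_in_mutant")
  expect_equal(ex$reason[ex$guide_id == "g4"], "missing_in_reference")
})

test_that("tied deltas share a group and break deterministically by id", {
  fit <- dplyr::bind_rows(
    fitness_row(c("a2", "a1", "b1"), "reference", c(0, 0, 0)),
    fitness_row(c("a2", "a1", "b1"), "mutant", c(0.5, 0.5, -1)))
  d <- guide_delta(fit)$delta
  expect_equal(d$guide_id, c("b1", "a1", "a2"))
  expect_equal(d$group, c(1L, 2L, 2L))
})

test_that("gene scores take the median delta and calibrate both directions", {
  # one strongly depleted gene among neutral fillers
  genes <- c(sprintf("hit_g%d", 1:5), sprintf("filler%02d", 1:35))
  names(genes) <- genes
  ann <- make_annotation(setNames(
    c(rep("geneHit", 5), rep("geneF", 35)), genes))
  deltas <- c(-3.0, -2.5, -2.0, -1.5, -1.0, seq(0.01, 0.35, by = 0.01))
  delta <- tibble::tibble(guide_id = genes, delta = deltas)
  delta <- delta[order(delta$delta, delta$guide_id), ]
  delta$rank <- seq_len(nrow(delta))
  delta$group <- seq_len(nrow(delta))

  res <- score_genes(delta, ann, pipeline_config())
  hit <- res[res$gene == "geneHit", ]
  expect_equal(hit$gi_score, -2.0)
  expect_equal(hit$n_guides, 5L)
  expect_equal(hit$direction, "negative")
  # guides at ranks 1..5 of N=40: p is twice the one-direction exact value
  stat <- mhg_statistic(as.integer(seq_len(40) <= 5))$stat
  expect_equal(hit$pvalue, min(1, 2 * mhg_exact_pvalue(stat, 40, 5)),
               tolerance = 1e-12)
  expect_equal(hit$mhg_stat, stat, tolerance = 1e-12)
})

test_that("a fully tied delta table yields p-value 1 for every gene", {
  ann <- make_annotation(setNames(rep(c("geneA", "geneB"), each = 3),
                                  sprintf("g%d", 1:6)))
  delta <- tibble::tibble(guide_id = sprintf("g%d", 1:6), delta = 0,
                          rank = 1:6, group = 1L)
  res <- score_genes(delta, ann, pipeline_config())
  expect_true(all(res$pvalue == 1))
  expect_true(all(res$mhg_stat == 1))
})

test_that("one-direction exact doubling matches the permutation oracle", {
  set.seed(23)
  N <- 200
  labels <- integer(N); labels[sample.int(N, 5)] <- 1L
  stat <- mhg_statistic(labels)$stat
  p_exact <- mhg_exact_pvalue(stat, N, 5)
  pp <- permutation_pvalue(labels, n_perm = 2e4, seed = 77)
  expect_lt(abs(p_exact - pp$p), 4 * pp$mc_se)
})

test_that("genes without surviving guides are flagged, not scored", {
  ann <- make_annotation(c(g1 = "geneA", g2 = "geneB"))
  delta <- tibble::tibble(guide_id = "g1", delta = -1, rank = 1L,
                          group = 1L)
  res <- score_genes(delta, ann, pipeline_config())
  b <- res[res$gene == "geneB", ]
  expect_equal(b$n_guides, 0L)
  expect_true(is.na(b$pvalue))
  expect_true(is.na(b$gi_score))
})

test_that("swapping backgrounds negates scores and flips directions", {
  cfg <- sim_config(n_genes = 30, n_controls = 10, depth_per_sample = 2000,
                    frac_interacting = 0.1, seed = 13)
  sim <- simulate_paired_screens(cfg)
  swapped <- sim$counts
  swapped$samples$background <- c(reference = "mutant",
                                  mutant = "reference")[
                                    swapped$samples$background]
  pc <- pipeline_config()
  f1 <- compute_fitness(sim$counts, sim$annotation, pc)
  f2 <- compute_fitness(swapped, sim$annotation, pc)
  d1 <- guide_delta(f1)$delta
  d2 <- guide_delta(f2)$delta
  m <- match(d1$guide_id, d2$guide_id)
  expect_equal(d2$delta[m], -d1$delta, tolerance = 1e-12)
  r1 <- score_genes(d1, sim$annotation, pc)
  r2 <- score_genes(d2, sim$annotation, pc)
  m <- match(r1$gene, r2$gene)
  expect_equal(r2$gi_score[m], -r1$gi_score, tolerance = 1e-12)
  flip <- c(negative = "positive", positive = "negative")
  expect_equal(r2$direction[m], unname(flip[r1$direction]))
  expect_equal(r2$pvalue[m], r1$pvalue, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  # worked by hand: q_(i) = min_(j>=i) p_(j) * 4 / j -> all 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("hit tiers gate on FDR and GI magnitude", {
  res <- tibble::tibble(
    gene = sprintf("g%d", 1:6),
    gi_score = c(-2.5, -1.5, -3.0, 2.5, -2.0, -0.5),
    qvalue = c(0.01, 0.01, 0.2, 0.01, 0.01, 0.01))
  out <- classify_hits(res, pipeline_config())
  expect_equal(out$tier,
               c("tier2",  # q 0.01, |GI| 2.5
                 "tier1",  # q 0.01, |GI| 1.5
                 "none",   # fails the FDR gate
                 "tier2",  # suppressor side counts by magnitude
                 "tier1",  # |GI| exactly 2: strict threshold
                 "none"))  # |GI| below tier1
})
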