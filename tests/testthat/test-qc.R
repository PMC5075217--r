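# Quality control: threshold boundaries, homozygous-deletion masking,
# amplicon/site exclusion, irregular-sample detection, idempotence.

test_that("sample read filter applies the threshold boundary exactly", {
  panel <- make_panel(n_genes = 1, amps_per_gene = 2)
  counts <- cbind(low = c(7000L, 7999L),   # 14999 reads: out
                  edge = c(7000L, 8000L),  # 15000 reads: in
                  high = c(9000L, 9000L))
  rownames(counts) <- panel$id
  m <- coverage_matrix(panel, counts)
  res <- filter_samples_by_reads(m)
  expect_equal(res$failed_samples$sample, "low")
  expect_setequal(colnames(res$matrix$counts), c("edge", "high"))
})

test_that("removing every sample is fatal", {
  panel <- make_panel(n_genes = 1, amps_per_gene = 2)
  counts <- matrix(0L, 2, 3, dimnames = list(panel$id, c("a", "b", "c")))
  m <- coverage_matrix(panel, counts)
  expect_error(filter_samples_by_reads(m), "inspect")
})

test_that("homozygous-deletion calling applies the coverage-10 boundary", {
  panel <- make_panel(n_genes = 1, amps_per_gene = 1)
  counts <- matrix(c(0L, 9L, 10L, 500L), 1, 4,
                   dimnames = list(panel$id,
                                   c("zero", "nine", "ten", "wt")))
  m <- coverage_matrix(panel, counts)
  res <- call_homozygous_deletions(m)
  expect_setequal(res$homdel_cells$sample, c("zero", "nine"))
  expect_false(res$matrix$qc_mask[1, "zero"])
  expect_false(res$matrix$qc_mask[1, "nine"])
  expect_true(res$matrix$qc_mask[1, "ten"])
})

test_that("low-coverage amplicons are never homdel-eligible", {
  panel <- make_panel(n_genes = 1, amps_per_gene = 1)
  # mean coverage below 50: near-zero cells are low quality, not deletions
  counts <- matrix(c(0L, 5L, 8L, 9L), 1, 4,
                   dimnames = list(panel$id, sprintf("s%d", 1:4)))
  res <- call_homozygous_deletions(coverage_matrix(panel, counts))
  expect_equal(nrow(res$homdel_cells), 0L)
})

test_that("amplicon filter applies coverage and partner rules, excluding dead sites", {
  panel <- make_panel(n_genes = 1, amps_per_gene = 3)  # sites G1S1..G1S3
  counts <- matrix(c(49L, 500L, 700L), 3, 20,
                   dimnames = list(panel$id, sprintf("s%02d", 1:20)))
  m <- coverage_matrix(panel, counts)
  avail <- c(G1A1 = TRUE, G1A2 = FALSE, G1A3 = TRUE)
  res <- filter_amplicons(m, qc_thresholds(), avail)
  expect_true(any(grepl("low_mean_coverage", res$failed_amplicons$reason[
    res$failed_amplicons$amplicon == "G1A1"])))
  expect_true("no_partners" %in% res$failed_amplicons$reason[
    res$failed_amplicons$amplicon == "G1A2"])
  # single-amplicon sites G1S1 and G1S2 lose their only amplicon
  expect_setequal(res$excluded_sites, c("G1S1", "G1S2"))
  expect_true(all(!res$matrix$qc_mask[c("G1A1", "G1A2"), ]))
})

test_that("a cohort-conforming sample is never irregular", {
  panel <- make_panel(n_genes = 4, amps_per_gene = 4)
  m <- make_correlated_matrix(panel, n_samples = 25, depth = 800, seed = 13)
  irr <- detect_irregular_samples(m)
  expect_equal(nrow(irr), 0L)
})

test_that("distorting most genes makes a sample irregular; 2-gene panels never do", {
  set.seed(17)
  panel <- make_panel(n_genes = 4, amps_per_gene = 4)
  m <- make_correlated_matrix(panel, n_samples = 25, depth = 800, seed = 17)
  counts <- m$counts
  # distort the within-gene profile of 3 of 4 genes for one sample:
  # half of each gene's amplicons scaled x4
  for (g in 1:3) {
    rows <- which(panel$gene == sprintf("GENE%d", g))[1:2]
    counts[rows, 1] <- counts[rows, 1] * 4L
  }
  m2 <- coverage_matrix(panel, counts)
  irr <- detect_irregular_samples(m2)
  expect_true(colnames(counts)[1] %in% irr$sample)
  expect_gte(irr$n_failed_genes[irr$sample == colnames(counts)[1]], 3)

  # same distortion on a 2-gene panel: the n > 2 condition bars the rule
  panel2 <- make_panel(n_genes = 2, amps_per_gene = 4)
  m3 <- make_correlated_matrix(panel2, n_samples = 25, depth = 800, seed = 17)
  counts3 <- m3$counts
  for (g in 1:2) {
    rows <- which(panel2$gene == sprintf("GENE%d", g))[1:2]
    counts3[rows, 1] <- counts3[rows, 1] * 4L
  }
  irr2 <- detect_irregular_samples(coverage_matrix(panel2, counts3))
  expect_equal(nrow(irr2), 0L)
})

test_that("the full QC pass is idempotent", {
  sim <- default_sim(seed = 23, cnv_events = list(
    list(sample = 2, gene = "GENE1", sites = "GENE1_E01", multiplier = 0)))
  q1 <- run_qc(sim$matrix)
  q2 <- run_qc(q1$matrix)
  expect_identical(q2$matrix$qc_mask, q1$matrix$qc_mask)
  expect_identical(q2$matrix$counts, q1$matrix$counts)
})

test_that("masked cells never reach downstream estimators", {
  sim <- default_sim(seed = 29, cnv_events = list(
    list(sample = 5, gene = "GENE2", sites = "GENE2_E01", multiplier = 0)))
  q <- run_qc(sim$matrix)
  expect_gt(nrow(q$report$homdel_cells), 0)
  cfg <- unsupervised_config()
  res1 <- run_unsupervised(q$matrix, cfg)
  # poison masked cells with absurd values; results must not move
  poisoned <- q$matrix
  poisoned$counts[!poisoned$qc_mask] <- 10000000L
  res2 <- run_unsupervised(poisoned, cfg)
  expect_identical(res2$calls, res1$calls)
  expect_identical(res2$T, res1$T)
})

test_that("simulator output with no anomalies passes QC untouched", {
  sim <- default_sim(seed = 31)
  q <- run_qc(sim$matrix)
  expect_equal(nrow(q$report$failed_samples), 0L)
  expect_equal(nrow(q$report$failed_amplicons), 0L)
  expect_equal(length(q$report$excluded_sites), 0L)
  expect_equal(nrow(q$report$homdel_cells), 0L)
  expect_true(all(q$matrix$qc_mask))
})

test_that("QC thresholds load from a flat key=value config file", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# thresholds", "min_sample_reads=10000",
               "homdel_max_cov=5", "gene_alpha = 0.05"), path)
  th <- qc_thresholds_from_file(path)
  expect_equal(th$min_sample_reads, 10000)
  expect_equal(th$homdel_max_cov, 5)
  expect_equal(th$gene_alpha, 0.05)
  expect_equal(th$min_amplicon_mean_cov, 50)  # default retained
  writeLines("bogus_key=1", path)
  expect_error(qc_thresholds_from_file(path), "unknown config key")
  writeLines("min_sample_reads=abc", path)
  expect_error(qc_thresholds_from_file(path), "non-numeric")
})

test_that("null irregular-sample rate stays below the per-gene test level", {
  # the composite >n/2-genes rule is tested per gene at gene_alpha; with
  # correlated same-group amplicons inside a gene the chi-squared reference
  # is mildly anticonservative, so the guarantee is read at the per-gene
  # level: the fraction of samples flagged irregular on CNV-free data must
  # not exceed gene_alpha
  flagged <- 0; total <- 0
  for (i in 1:50) {
    sim <- default_sim(seed = 20000 + i)
    irr <- detect_irregular_samples(sim$matrix)
    flagged <- flagged + nrow(irr)
    total <- total + ncol(sim$matrix$counts)
  }
  expect_lte(flagged / total, qc_thresholds()$gene_alpha)
})
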