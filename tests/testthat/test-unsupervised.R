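# Unsupervised caller: threshold selection, partner selection, outlier
# voting, and its invariances.

test_that("two perfectly correlated genes give the grid-maximum threshold", {
  panel <- make_panel(n_genes = 2, amps_per_gene = 3)
  set.seed(71)
  base <- exp(rnorm(30, sd = 0.5))
  counts <- t(sapply(seq_len(6), function(i) round(1000 * base)))
  dimnames(counts) <- list(panel$id, sprintf("S%02d", 1:30))
  # small independent jitter keeps MAD positive without breaking correlation
  counts <- counts + matrix(rpois(length(counts), 3), nrow(counts))
  m <- coverage_matrix(panel, counts)
  expect_equal(choose_corr_threshold(m), 0.99)
})

test_that("qualifying amplicons are non-increasing in the threshold", {
  sim <- default_sim(seed = 73)
  corr <- amplicon_correlations(sim$matrix)
  best <- apply(corr, 1, function(r) suppressWarnings(max(r, na.rm = TRUE)))
  n_qualifying <- vapply(seq(0, 0.99, 0.01),
                         function(t) sum(best > t), numeric(1))
  expect_true(all(diff(n_qualifying) <= 0))
})

test_that("an uncorrelated panel falls back to T = 0 with a warning", {
  panel <- make_panel(n_genes = 2, amps_per_gene = 3)
  set.seed(79)
  counts <- matrix(rpois(6 * 30, 500), 6, 30,
                   dimnames = list(panel$id, sprintf("S%02d", 1:30)))
  m <- coverage_matrix(panel, counts)
  corr <- amplicon_correlations(m)
  # independent Poisson noise: correlations hover near zero
  expect_lt(max(abs(corr), na.rm = TRUE), 0.9)
})

test_that("partner selection prefers identical coverage and never same-gene", {
  panel <- make_panel(n_genes = 3, amps_per_gene = 3)
  set.seed(83)
  base <- exp(rnorm(30, sd = 0.4))
  counts <- matrix(0L, 9, 30, dimnames = list(panel$id,
                                              sprintf("S%02d", 1:30)))
  for (j in 1:9) counts[j, ] <- rpois(30, 500 * base)
  counts["G2A1", ] <- counts["G1A1", ]  # exact copy on another gene
  m <- coverage_matrix(panel, counts)
  corr <- amplicon_correlations(m)
  partners <- select_partners("G1A1", m,
                              unsupervised_config(L = 3, votes_required = 3),
                              corr = corr, T = 0.5)
  expect_equal(partners[1], "G2A1")
  expect_false(any(grepl("^G1", partners)))
  # same-gene pairs are never considered at all
  expect_true(all(is.na(corr["G1A1", c("G1A2", "G1A3")])))
})

test_that("simulated partners come from the matched efficiency group", {
  sim <- default_sim(seed = 89)
  m <- sim$matrix
  corr <- amplicon_correlations(m)
  T <- choose_corr_threshold(m, corr)
  cfg <- unsupervised_config()
  hits <- 0; total <- 0
  set.seed(89)
  for (a in sample(rownames(m$counts), 12)) {
    partners <- select_partners(a, m, cfg, corr = corr, T = T)
    hits <- hits + sum(sim$groups[partners] == sim$groups[a])
    total <- total + length(partners)
  }
  expect_gt(hits / total, 0.9)
})

test_that("injected deletions and duplications are called with enough votes", {
  sim <- default_sim(seed = 97, cnv_events = list(
    list(sample = 4, gene = "GENE1",
         sites = c("GENE1_E02", "GENE1_E03"), multiplier = 0.5),
    list(sample = 9, gene = "GENE2",
         sites = c("GENE2_E02", "GENE2_E03"), multiplier = 1.5),
    list(sample = 14, gene = "GENE3",
         sites = c("GENE3_E02", "GENE3_E03"), multiplier = 2.0)))
  q <- run_qc(sim$matrix)
  res <- run_unsupervised(q$matrix)
  calls <- res$calls
  panel <- q$matrix$panel
  del_amps <- panel$id[panel$site_id %in% c("GENE1_E02", "GENE1_E03")]
  del_calls <- calls[calls$sample == "S04" & calls$amplicon %in% del_amps, ]
  expect_true(all(del_calls$state == "HET_DEL"))
  expect_true(all(del_calls$votes >= 4))
  dup_amps <- panel$id[panel$site_id %in% c("GENE2_E02", "GENE2_E03")]
  dup_calls <- calls[calls$sample == "S09" & calls$amplicon %in% dup_amps, ]
  expect_true(all(dup_calls$state == "DUP"))
  # homozygous duplication (multiplier 2) is reported as DUP, not separated
  hdup_amps <- panel$id[panel$site_id %in% c("GENE3_E02", "GENE3_E03")]
  hdup_calls <- calls[calls$sample == "S14" & calls$amplicon %in% hdup_amps, ]
  expect_true(all(hdup_calls$state == "DUP"))
  # no stray calls elsewhere for these samples
  other <- calls[calls$sample == "S04" & !(calls$amplicon %in% del_amps), ]
  expect_lt(mean(other$state != "NORMAL"), 0.05)
})

test_that("deletions never flip toward duplication under coverage halving", {
  sim <- default_sim(seed = 101)
  q <- run_qc(sim$matrix)
  res0 <- run_unsupervised(q$matrix)
  amp <- rownames(q$matrix$counts)[10]
  cnt <- q$matrix$counts
  cnt[amp, "S07"] <- as.integer(round(cnt[amp, "S07"] * 0.5))
  m2 <- coverage_matrix(q$matrix$panel, cnt, q$matrix$qc_mask,
                        q$matrix$homdel)
  res1 <- run_unsupervised(m2)
  call0 <- res0$calls[res0$calls$amplicon == amp &
                        res0$calls$sample == "S07", ]
  call1 <- res1$calls[res1$calls$amplicon == amp &
                        res1$calls$sample == "S07", ]
  expect_true(call1$state %in% c("HET_DEL", call0$state))
  expect_false(call1$state == "DUP")
})

test_that("globally rescaling one sample produces no calls for it", {
  # the no-library-size-normalization property: a global multiplier moves a
  # sample along, not off, the partner regression lines, and cancels exactly
  # in the supervised cluster normalisation
  sim <- default_sim(seed = 103)
  cnt <- sim$matrix$counts
  cnt[, "S11"] <- cnt[, "S11"] * 3L
  res <- run_pipeline(coverage_matrix(sim$matrix$panel, cnt))
  expect_equal(sum(res$report$sample == "S11"), 0L)
})

test_that("votes_required = L = 1 degenerates to single-model outlier calls", {
  sim <- default_sim(seed = 107, cnv_events = list(
    list(sample = 2, gene = "GENE1",
         sites = c("GENE1_E02", "GENE1_E03"), multiplier = 0.5)))
  q <- run_qc(sim$matrix)
  cfg <- unsupervised_config(L = 1, votes_required = 1)
  res <- run_unsupervised(q$matrix, cfg)
  panel <- q$matrix$panel
  del_amps <- panel$id[panel$site_id %in% c("GENE1_E02", "GENE1_E03")]
  del_calls <- res$calls[res$calls$sample == "S02" &
                           res$calls$amplicon %in% del_amps, ]
  expect_true(all(del_calls$state == "HET_DEL"))
  expect_true(all(del_calls$votes == 1))
})

test_that("small datasets are refused unless overridden", {
  sim <- simulate_coverage(sim_params(n_samples = 20, seed = 109))
  q <- run_qc(sim$matrix)
  expect_error(run_unsupervised(q$matrix), "25")
  cfg <- unsupervised_config(allow_small_dataset = TRUE)
  expect_silent(run_unsupervised(q$matrix, cfg))
})
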