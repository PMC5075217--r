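# Supervised classifier: control/test split, clustering, normalisation,
# model fitting, site classification and iteration.

test_that("control/test split follows the any-outlier rule and the control floor", {
  samples <- sprintf("S%02d", 1:48)
  calls <- data.frame(
    amplicon = "A", sample = samples,
    state = c(rep("HET_DEL", 3), rep("NORMAL", 45)),
    votes = 0L, bayes_factor_K = NA_real_)
  sp <- split_control_test(samples, calls)
  expect_equal(length(sp$control), 45L)
  expect_setequal(sp$test, samples[1:3])

  calls$state <- c(rep("HET_DEL", 40), rep("NORMAL", 8))
  expect_error(split_control_test(samples, calls), "at least 20")

  # explicit control list takes precedence over the unsupervised split
  sp2 <- split_control_test(samples, calls, control_samples = samples[1:30])
  expect_equal(sp2$control, samples[1:30])
  expect_setequal(sp2$test, samples[31:48])
})

test_that("cluster estimator switches between Pearson and Sn-correlation", {
  # candX correlates with the target only through one shared outlier pair,
  # candY correlates cleanly: Pearson prefers candX, the robust estimator
  # prefers candY
  panel <- amplicon_panel(data.frame(
    chrom = c("chr1", "chr2", "chr3"), start = 100L, end = 200L,
    id = c("target", "candX", "candY"),
    gene = c("G1", "G2", "G3"), site_id = c("E1", "E2", "E3")))
  set.seed(113)
  n <- 21
  z <- rnorm(n, sd = 0.3)
  target <- round(400 * exp(z + rnorm(n, sd = 0.05)))
  candY <- round(400 * exp(z + rnorm(n, sd = 0.05)))
  candX <- round(400 * exp(rnorm(n, sd = 0.05)))
  target[1] <- 40000L; candX[1] <- 40000L  # shared gross outlier
  counts <- rbind(target = target, candX = candX, candY = candY)
  colnames(counts) <- sprintf("S%02d", 1:n)
  m <- coverage_matrix(panel, counts)
  cfg <- supervised_config(cluster_size_k = 1)
  # 21 controls > 20: Pearson, dominated by the outlier
  expect_equal(suppressWarnings(
    cluster_amplicons("target", m, colnames(counts), cfg)), "candX")
  # 20 controls: robust Sn-correlation resists the outlier
  expect_equal(suppressWarnings(
    cluster_amplicons("target", m, colnames(counts)[1:20], cfg)), "candY")
})

test_that("cluster normalisation is exact and library-size invariant", {
  panel <- make_panel(n_genes = 2, amps_per_gene = 2)
  counts <- matrix(c(100L, 100L, 100L, 100L,
                     50L, 100L, 100L, 200L), 4, 2,
                   dimnames = list(panel$id, c("s1", "s2")))
  m <- coverage_matrix(panel, counts)
  x <- normalize_amplicon("G1A1", c("G2A1", "G2A2"), m)
  expect_equal(unname(x["s1"]), 0)
  expect_equal(unname(x["s2"]), log(50) - mean(log(c(100, 200))))
  # doubling every count of a sample leaves x unchanged
  counts2 <- counts; counts2[, "s2"] <- counts2[, "s2"] * 2L
  x2 <- normalize_amplicon("G1A1", c("G2A1", "G2A2"),
                           coverage_matrix(panel, counts2))
  expect_equal(x2, x)
})

test_that("fit_models places the three hypotheses at the multiplier shifts", {
  set.seed(127)
  x <- rnorm(40, 0, 0.1)
  mdl <- fit_models("amp", x, supervised_config())
  expect_equal(mdl$het_del$location, mdl$normal$location + log(0.5))
  expect_equal(mdl$dup$location, mdl$normal$location + log(1.5))
  expect_equal(mdl$het_del$scale, mdl$normal$scale * sqrt(2))
  expect_equal(mdl$dup$scale, mdl$normal$scale * sqrt(2 / 3))
  expect_lt(abs(mdl$normal$location), 0.05)
  expect_lt(abs(mdl$normal$scale - 0.1), 0.03)
  # degenerate controls are excluded with a warning
  expect_warning(out <- fit_models("amp", rep(0.3, 40), supervised_config()),
                 "zero robust scale")
  expect_null(out)
})

test_that("variance corrections match log-Poisson simulation", {
  set.seed(131)
  lambda <- 1000
  v1 <- var(log(rpois(1e5, lambda)))
  vdel <- var(log(rpois(1e5, 0.5 * lambda)))
  vdup <- var(log(rpois(1e5, 1.5 * lambda)))
  expect_lt(abs(vdel / v1 - 2), 0.1)
  expect_lt(abs(vdup / v1 - 2 / 3), 0.05)
})

test_that("classify_site answers the three questions in order", {
  mdl <- list(
    structure(list(amplicon = "a1",
                   normal = list(location = 0, scale = 0.1),
                   het_del = list(location = log(0.5), scale = 0.1 * sqrt(2)),
                   dup = list(location = log(1.5), scale = 0.1 * sqrt(2 / 3))),
              class = "amplicon_models"),
    structure(list(amplicon = "a2",
                   normal = list(location = 0, scale = 0.1),
                   het_del = list(location = log(0.5), scale = 0.1 * sqrt(2)),
                   dup = list(location = log(1.5), scale = 0.1 * sqrt(2 / 3))),
              class = "amplicon_models"))
  # exactly on the normal locations: nothing suspicious
  res <- classify_site(c(0, 0), mdl, supervised_config(), expected_altered = 50)
  expect_length(res$suspicious_states, 0)
  expect_gt(res$p_normal, 0.99)
  # at the deletion locations: suspicious for HET_DEL with huge Bayes factor
  res <- classify_site(c(log(0.5), log(0.5)), mdl, supervised_config(),
                       expected_altered = 50)
  expect_equal(res$suspicious_states, "HET_DEL")
  expect_lt(res$p_normal, 1e-6)
  expect_gt(res$bf[["HET_DEL"]], 100)
  # at the duplication locations: suspicious for DUP
  res <- classify_site(c(log(1.5), log(1.5)), mdl, supervised_config(),
                       expected_altered = 50)
  expect_equal(res$suspicious_states, "DUP")
  expect_gt(res$bf[["DUP"]], 100)
})

test_that("run_supervised recovers injected events and grows the control set", {
  sim <- default_sim(seed = 137, cnv_events = list(
    list(sample = 6, gene = "GENE1",
         sites = c("GENE1_E02", "GENE1_E03"), multiplier = 0.5)))
  q <- run_qc(sim$matrix)
  un <- run_unsupervised(q$matrix)
  sup <- run_supervised(q$matrix, un$calls)
  hits <- sup$calls[sup$calls$state == "HET_DEL" &
                      sup$calls$sample == "S06", ]
  expect_setequal(hits$site_id, c("GENE1_E02", "GENE1_E03"))
  expect_true(all(hits$adj_p_normal <= 0.05))
  expect_true(all(hits$bayes_factor >= 100))
  # iteration only ever grows the control set
  expect_gte(length(sup$control), 47 - length(sup$test))
  expect_false("S06" %in% sup$control)
})

test_that("classify_site is deterministic", {
  sim <- default_sim(seed = 139, cnv_events = list(
    list(sample = 3, gene = "GENE2",
         sites = c("GENE2_E02", "GENE2_E03"), multiplier = 1.5)))
  q <- run_qc(sim$matrix)
  un <- run_unsupervised(q$matrix)
  s1 <- run_supervised(q$matrix, un$calls)
  s2 <- run_supervised(q$matrix, un$calls)
  expect_identical(s1$calls, s2$calls)
})
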