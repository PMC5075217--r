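# Input-data quality control: low-read sample filter, homozygous-deletion
# calling, amplicon coverage/partner filter, and irregular-sample detection
# via per-gene trimmed normalised Euclidean distance.

#' QC thresholds
#'
#' @param min_sample_reads Minimum total reads per sample (default 15000).
#' @param min_amplicon_mean_cov Minimum across-sample mean coverage per
#'   amplicon (default 50).
#' @param homdel_max_cov Coverage threshold for homozygous deletion: cells
#'   with count strictly below this value on an otherwise well-covered
#'   amplicon are called homozygous deletions (default 10).
#' @param trimmed_fraction Fraction of per-gene coordinates (smallest
#'   squared standardized deviations, rounded up) kept in the irregular-
#'   sample NED statistic (default 0.8).
#' @param gene_alpha Significance level of the per-gene chi-squared
#'   irregularity test (default 0.01).
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_reads = 15000,
                          min_amplicon_mean_cov = 50,
                          homdel_max_cov = 10,
                          trimmed_fraction = 0.8,
                          gene_alpha = 0.01) {
  stopifnot(min_sample_reads > 0, min_amplicon_mean_cov > 0,
            homdel_max_cov > 0, trimmed_fraction > 0, trimmed_fraction <= 1,
            gene_alpha > 0, gene_alpha < 1)
  structure(list(min_sample_reads = min_sample_reads,
                 min_amplicon_mean_cov = min_amplicon_mean_cov,
                 homdel_max_cov = homdel_max_cov,
                 trimmed_fraction = trimmed_fraction,
                 gene_alpha = gene_alpha),
            class = "qc_thresholds")
}

#' Read QC thresholds from a flat key=value file
#'
#' Lines of the form `key=value` (`#` comments and blank lines ignored);
#' keys are the arguments of [qc_thresholds()]. Missing keys keep their
#' defaults; unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A [qc_thresholds()].
#' @export
qc_thresholds_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  known <- names(formals(qc_thresholds))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (anyNA(vals)) stop("non-numeric config value for: ", keys[is.na(vals)][1])
  do.call(qc_thresholds, as.list(setNames(vals, keys)))
}

.empty_qc_report <- function() {
  structure(list(
    failed_samples = data.frame(sample = character(), reason = character(),
                                stringsAsFactors = FALSE),
    failed_amplicons = data.frame(amplicon = character(), reason = character(),
                                  stringsAsFactors = FALSE),
    excluded_sites = character(),
    homdel_cells = data.frame(amplicon = character(), sample = character(),
                              stringsAsFactors = FALSE),
    irregular_samples = data.frame(sample = character(),
                                   n_failed_genes = integer(),
                                   stringsAsFactors = FALSE)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0(
    "QC report: %d failed sample(s), %d failed amplicon(s), ",
    "%d excluded site(s), %d homozygous-deletion cell(s), ",
    "%d irregular sample(s)\n"),
    nrow(x$failed_samples), nrow(x$failed_amplicons),
    length(x$excluded_sites), nrow(x$homdel_cells),
    nrow(x$irregular_samples)))
  invisible(x)
}

#' Remove low-read samples
#'
#' Drops samples whose total read count is below `min_sample_reads`.
#'
#' @param matrix A [coverage_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with the filtered `matrix` and a `failed_samples` data frame.
#' @export
filter_samples_by_reads <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  totals <- colSums(matrix$counts)
  fail <- totals < thresholds$min_sample_reads
  if (all(fail)) {
    stop("all samples fall below the minimum read count (",
         thresholds$min_sample_reads, "); inspect the dataset")
  }
  failed <- data.frame(sample = colnames(matrix$counts)[fail],
                       reason = sprintf("low_reads(%d)", totals[fail]),
                       stringsAsFactors = FALSE)
  out <- coverage_matrix(matrix$panel,
                         matrix$counts[, !fail, drop = FALSE],
                         matrix$qc_mask[, !fail, drop = FALSE],
                         matrix$homdel[, !fail, drop = FALSE])
  list(matrix = out, failed_samples = failed)
}

#' Call homozygous deletions
#'
#' Cells with coverage strictly below `homdel_max_cov` on amplicons whose
#' across-sample mean coverage is at least `min_amplicon_mean_cov` are
#' homozygous deletions (zero template copies yield essentially zero reads).
#' Flagged cells are masked out of all downstream statistics.
#'
#' @inheritParams filter_samples_by_reads
#' @return List with the updated `matrix` (mask cleared on flagged cells)
#'   and a `homdel_cells` data frame (amplicon, sample).
#' @export
call_homozygous_deletions <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  means <- rowMeans(matrix$counts)
  eligible <- means >= thresholds$min_amplicon_mean_cov
  flag <- matrix$counts < thresholds$homdel_max_cov & eligible & matrix$qc_mask
  idx <- which(flag, arr.ind = TRUE)
  cells <- data.frame(amplicon = rownames(matrix$counts)[idx[, 1]],
                      sample = colnames(matrix$counts)[idx[, 2]],
                      stringsAsFactors = FALSE)
  mask <- matrix$qc_mask
  mask[flag] <- FALSE
  homdel <- matrix$homdel
  homdel[flag] <- TRUE
  list(matrix = coverage_matrix(matrix$panel, matrix$counts, mask, homdel),
       homdel_cells = cells)
}

#' Filter amplicons by coverage and partner availability
#'
#' An amplicon fails if its across-sample mean coverage is below
#' `min_amplicon_mean_cov` or if it lacks the correlating partners required
#' by the unsupervised caller. Sites whose amplicons all fail are excluded
#' from analysis in every sample.
#'
#' @inheritParams filter_samples_by_reads
#' @param partner_available Named logical vector over amplicon ids: `TRUE`
#'   when the unsupervised partner search found enough correlating
#'   amplicons. Defaults to all available (coverage-only filtering).
#' @return List with updated `matrix` (failed amplicons masked in all
#'   samples), `failed_amplicons` and `excluded_sites`.
#' @export
filter_amplicons <- function(matrix, thresholds = qc_thresholds(),
                             partner_available = NULL) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  ids <- rownames(matrix$counts)
  if (is.null(partner_available)) {
    partner_available <- setNames(rep(TRUE, length(ids)), ids)
  }
  means <- rowMeans(matrix$counts)
  low <- means < thresholds$min_amplicon_mean_cov
  no_partner <- !partner_available[ids] & !low
  failed <- rbind(
    data.frame(amplicon = ids[low],
               reason = sprintf("low_mean_coverage(%.1f)", means[low]),
               stringsAsFactors = FALSE),
    data.frame(amplicon = ids[no_partner],
               reason = rep("no_partners", sum(no_partner)),
               stringsAsFactors = FALSE)
  )
  mask <- matrix$qc_mask
  mask[low | no_partner, ] <- FALSE
  pass_any <- rowSums(mask) > 0
  sites <- panel_sites(matrix$panel)
  excluded <- names(sites)[vapply(sites, function(a) !any(pass_any[a]),
                                  logical(1))]
  if (length(excluded)) {
    mask[matrix$panel$site_id %in% excluded, ] <- FALSE
  }
  list(matrix = coverage_matrix(matrix$panel, matrix$counts, mask,
                                matrix$homdel),
       failed_amplicons = failed, excluded_sites = excluded)
}

# Per-gene trimmed NED statistic for one sample; returns NA when the gene
# cannot be tested for that sample.
.gene_ned_stat <- function(v, ref, s, trimmed_fraction) {
  z <- (v - ref)^2 / s^2
  keep <- ceiling(trimmed_fraction * length(z))
  sum(sort(z)[seq_len(keep)])
}

#' Detect irregular samples
#'
#' A sample is irregular when its per-gene normalised coverage profile
#' deviates from the cohort in more than half of the genes. Per gene,
#' coverages are normalised by the gene's total reads in that sample and
#' log-transformed; the reference profile is the per-amplicon
#' Hodges-Lehmann location and the scale the per-amplicon Sn across
#' samples. The test statistic is the trimmed squared normalised Euclidean
#' distance (smallest `trimmed_fraction` of squared standardized
#' coordinates, rounded up), compared against the upper `gene_alpha`
#' chi-squared quantile with the trimmed count as degrees of freedom.
#' The rule only applies when more than 2 genes are testable.
#'
#' @inheritParams filter_samples_by_reads
#' @return Data frame `irregular_samples` (sample, n_failed_genes) plus the
#'   per-sample gene failure counts as attribute `gene_failures`.
#' @export
detect_irregular_samples <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  panel <- matrix$panel
  samples <- colnames(matrix$counts)
  genes <- unique(panel$gene)
  fails <- matrix(FALSE, length(samples), length(genes),
                  dimnames = list(samples, genes))
  testable <- logical(length(genes)); names(testable) <- genes
  for (g in genes) {
    amp <- which(panel$gene == g & rowSums(matrix$qc_mask) > 0)
    if (length(amp) < 2) next
    # only samples with every gene amplicon unmasked are comparable
    ok_sample <- colSums(!matrix$qc_mask[amp, , drop = FALSE]) == 0
    if (sum(ok_sample) < 3) next
    testable[g] <- TRUE
    counts <- matrix$counts[amp, , drop = FALSE]
    counts[counts == 0] <- 0.5
    v <- log(sweep(counts, 2, colSums(counts), "/"))
    ref <- apply(v[, ok_sample, drop = FALSE], 1, hodges_lehmann)
    s <- apply(v[, ok_sample, drop = FALSE], 1, sn_scale)
    if (any(s == 0)) { testable[g] <- FALSE; next }
    m <- length(amp)
    df <- ceiling(thresholds$trimmed_fraction * m)
    crit <- qchisq(1 - thresholds$gene_alpha, df = df)
    for (i in which(ok_sample)) {
      stat <- .gene_ned_stat(v[, i], ref, s, thresholds$trimmed_fraction)
      fails[i, g] <- stat > crit
    }
  }
  n <- sum(testable)
  n_failed <- rowSums(fails[, testable, drop = FALSE])
  irregular <- if (n > 2) names(which(n_failed > n / 2)) else character(0)
  out <- data.frame(sample = irregular,
                    n_failed_genes = as.integer(n_failed[irregular]),
                    stringsAsFactors = FALSE)
  attr(out, "gene_failures") <- n_failed
  out
}

#' Run the full QC pass
#'
#' Order: low-read sample filter, homozygous-deletion calling, amplicon
#' coverage/partner filter (with site exclusion), irregular-sample removal.
#'
#' @inheritParams filter_samples_by_reads
#' @param partner_available Optional named logical vector over amplicon ids
#'   (see [filter_amplicons()]).
#' @return List with the QC'd `matrix` and a `qc_report`.
#' @export
run_qc <- function(matrix, thresholds = qc_thresholds(),
                   partner_available = NULL) {
  report <- .empty_qc_report()
  s <- filter_samples_by_reads(matrix, thresholds)
  report$failed_samples <- s$failed_samples
  h <- call_homozygous_deletions(s$matrix, thresholds)
  report$homdel_cells <- h$homdel_cells
  a <- filter_amplicons(h$matrix, thresholds, partner_available)
  report$failed_amplicons <- a$failed_amplicons
  report$excluded_sites <- a$excluded_sites
  irr <- detect_irregular_samples(a$matrix, thresholds)
  report$irregular_samples <- irr
  m <- a$matrix
  if (nrow(irr)) {
    keep <- setdiff(colnames(m$counts), irr$sample)
    if (length(keep) == 0) stop("all samples are irregular; inspect dataset")
    m <- coverage_matrix(m$panel, m$counts[, keep, drop = FALSE],
                         m$qc_mask[, keep, drop = FALSE],
                         m$homdel[, keep, drop = FALSE])
    report$failed_samples <- rbind(
      report$failed_samples,
      data.frame(sample = irr$sample, reason = "irregular",
                 stringsAsFactors = FALSE))
  }
  list(matrix = m, report = report)
}
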