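# Unsupervised zygosity caller: per-amplicon partner selection by
# Sn-correlation, one Theil-Sen model per partner, studentized-residual
# outlier detection, Bayes-factor confirmation and N-of-L voting.

#' Unsupervised caller configuration
#'
#' @param L Number of partner models per amplicon (default 5).
#' @param votes_required Models that must agree for a call (default 4).
#' @param corr_threshold Correlation threshold T; `NULL` (default) selects T
#'   automatically with [choose_corr_threshold()].
#' @param alpha_del One-sided significance level for deletion outliers
#'   (default 0.02).
#' @param alpha_dup One-sided significance level for duplication outliers
#'   (default 0.05).
#' @param max_cnv_frequency Assumed upper bound on the carrier fraction of
#'   any one CNV (default 0.20).
#' @param min_samples Minimum QC-passed samples required to call
#'   (default 25).
#' @param allow_small_dataset Set `TRUE` to override the `min_samples`
#'   refusal (default `FALSE`).
#' @return Object of class `unsupervised_config`.
#' @export
unsupervised_config <- function(L = 5, votes_required = 4,
                                corr_threshold = NULL,
                                alpha_del = 0.02, alpha_dup = 0.05,
                                max_cnv_frequency = 0.20,
                                min_samples = 25,
                                allow_small_dataset = FALSE) {
  stopifnot(L >= 1, votes_required >= 1, votes_required <= L,
            alpha_del > 0, alpha_del < 0.5,
            alpha_dup > 0, alpha_dup < 0.5,
            max_cnv_frequency > 0, max_cnv_frequency <= 1,
            min_samples >= 3)
  if (!is.null(corr_threshold)) {
    stopifnot(corr_threshold > 0, corr_threshold < 1)
  }
  structure(list(L = L, votes_required = votes_required,
                 corr_threshold = corr_threshold,
                 alpha_del = alpha_del, alpha_dup = alpha_dup,
                 max_cnv_frequency = max_cnv_frequency,
                 min_samples = min_samples,
                 allow_small_dataset = allow_small_dataset),
            class = "unsupervised_config")
}

# Log coverage with pseudo-count 0.5 for zero cells that passed QC.
.log_coverage <- function(matrix) {
  counts <- matrix$counts
  counts[counts == 0] <- 0.5
  log(counts)
}

#' Robust cross-gene correlation matrix
#'
#' Sn-correlation of log coverages for every cross-gene amplicon pair over
#' samples where both amplicons pass QC. Same-gene pairs (which could share
#' a CNV) and degenerate pairs (zero MAD, too few common samples) are `NA`.
#'
#' @param matrix A QC'd [coverage_matrix()].
#' @return Symmetric matrix of correlations, amplicon ids as dimnames.
#' @export
amplicon_correlations <- function(matrix) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  panel <- matrix$panel
  lc <- .log_coverage(matrix)
  n_amp <- nrow(lc)
  usable <- matrix$qc_mask
  cmat <- matrix(NA_real_, n_amp, n_amp,
                 dimnames = list(panel$id, panel$id))
  for (j in seq_len(n_amp - 1)) {
    for (k in (j + 1):n_amp) {
      if (panel$gene[j] == panel$gene[k]) next
      common <- usable[j, ] & usable[k, ]
      if (sum(common) < 3) next
      r <- tryCatch(sn_correlation(lc[j, common], lc[k, common]),
                    error = function(e) NA_real_)
      cmat[j, k] <- r
      cmat[k, j] <- r
    }
  }
  cmat
}

#' Choose the correlation threshold T
#'
#' The largest T on a 0.00-0.99 grid (step 0.01) such that every
#' non-excluded CNV site keeps at least one amplicon that would pass the
#' partner-availability quality check at T, i.e. with at least
#' `min_partners` cross-gene partners correlating above T. Falls back to 0
#' with a warning when no positive T qualifies.
#'
#' @param matrix A QC'd [coverage_matrix()].
#' @param corr Optional precomputed [amplicon_correlations()] matrix.
#' @param min_partners Partners an amplicon needs to pass QC (the caller's
#'   L; default 1).
#' @return Scalar threshold T.
#' @export
choose_corr_threshold <- function(matrix, corr = NULL, min_partners = 1) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  if (is.null(corr)) corr <- amplicon_correlations(matrix)
  panel <- matrix$panel
  active <- rowSums(matrix$qc_mask) > 0
  sites <- panel_sites(panel)
  sites <- lapply(sites, function(a) a[active[match(a, panel$id)]])
  sites <- sites[lengths(sites) > 0]
  if (length(sites) == 0) stop("no active sites after QC")
  # an amplicon passes at T iff its min_partners-th best correlation > T
  kth_best <- apply(corr, 1, function(r) {
    r <- sort(r[!is.na(r)], decreasing = TRUE)
    if (length(r) >= min_partners) r[min_partners] else -Inf
  })
  best_per_site <- vapply(sites, function(a) max(kth_best[a]), numeric(1))
  grid <- seq(0, 0.99, by = 0.01)
  ok <- vapply(grid, function(t) all(best_per_site > t), logical(1))
  if (!any(ok[-1])) {
    warning("no positive correlation threshold keeps all sites; using T = 0")
    return(0)
  }
  max(grid[ok])
}

#' Select partner amplicons
#'
#' The top-L candidates by Sn-correlation with the target amplicon, drawn
#' from genes other than the target's (so a shared CNV cannot corrupt the
#' predictor), all correlating above T. Ties break by correlation, then by
#' genomic distance (descending), then by amplicon id, so runs are
#' deterministic.
#'
#' @param amplicon_id Target amplicon id.
#' @param matrix A QC'd [coverage_matrix()].
#' @param config An [unsupervised_config()].
#' @param corr Precomputed [amplicon_correlations()] matrix.
#' @param T Correlation threshold.
#' @return Character vector of partner ids (may be shorter than L; then the
#'   amplicon is partnerless and should be QC-failed).
#' @export
select_partners <- function(amplicon_id, matrix, config = unsupervised_config(),
                            corr = NULL, T = NULL) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  if (is.null(corr)) corr <- amplicon_correlations(matrix)
  if (is.null(T)) T <- choose_corr_threshold(matrix, corr)
  panel <- matrix$panel
  r <- corr[amplicon_id, ]
  usable <- rowSums(matrix$qc_mask) > 0
  cand <- names(r)[!is.na(r) & r > T & usable[panel$id]]
  if (length(cand) == 0) return(character(0))
  j <- match(amplicon_id, panel$id)
  k <- match(cand, panel$id)
  dist <- ifelse(panel$chrom[k] == panel$chrom[j],
                 abs(panel$start[k] - panel$start[j]), Inf)
  ord <- order(-r[cand], -dist, cand)
  utils::head(cand[ord], config$L)
}

#' Call zygosity states for one amplicon
#'
#' For each of the L partners, fits a Theil-Sen regression of the target's
#' log coverage on the partner's over QC-passed samples. A sample supports
#' heterozygous deletion in one model when its studentized residual falls
#' below the lower Student-t critical value (level `alpha_del`, df = n - 2)
#' and the Bayes factor K against the model line shifted by log(0.5)
#' exceeds 1; duplication support is analogous (upper tail, `alpha_dup`,
#' shift log(1.5)). A state is called when at least `votes_required` of the
#' L models support it. Cells masked as homozygous deletions are reported
#' HOM_DEL with votes = L by convention.
#'
#' @inheritParams select_partners
#' @param partners Character vector of partner ids (from
#'   [select_partners()]).
#' @return Data frame with one row per sample: `amplicon`, `sample`,
#'   `state`, `votes`, `bayes_factor_K`.
#' @export
call_amplicon <- function(amplicon_id, partners, matrix,
                          config = unsupervised_config()) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  samples <- colnames(matrix$counts)
  n_s <- length(samples)
  lc <- .log_coverage(matrix)
  mask <- matrix$qc_mask
  homdel_mask <- .homdel_cells_of(matrix, amplicon_id)

  votes_del <- votes_dup <- integer(n_s)
  models_seen <- integer(n_s)
  k_del_best <- k_dup_best <- rep(0, n_s)

  y_all <- lc[amplicon_id, ]
  for (p in partners) {
    common <- mask[amplicon_id, ] & mask[p, ]
    n <- sum(common)
    if (n < max(3, if (config$allow_small_dataset) 3 else config$min_samples)) {
      if (n < config$min_samples && !config$allow_small_dataset) {
        stop("fewer than min_samples (", config$min_samples,
             ") QC-passed samples for amplicon ", amplicon_id,
             "; set allow_small_dataset = TRUE to override")
      }
      if (n < 3) next
    }
    x <- lc[p, common]; y <- y_all[common]
    fit <- tryCatch(theil_sen(x, y), error = function(e) NULL)
    if (is.null(fit) || fit$residual_scale <= 0) next
    r <- studentized_residuals(fit, x, y)
    fitted <- fit$slope * x + fit$intercept
    s <- fit$residual_scale
    k_del <- dnorm(y, fitted + log(0.5), s) / dnorm(y, fitted, s)
    k_dup <- dnorm(y, fitted + log(1.5), s) / dnorm(y, fitted, s)
    lo <- r < -qt(1 - config$alpha_del, df = fit$n - 2)
    hi <- r > qt(1 - config$alpha_dup, df = fit$n - 2)
    sup_del <- lo & k_del > 1
    sup_dup <- hi & k_dup > 1
    idx <- which(common)
    votes_del[idx] <- votes_del[idx] + sup_del
    votes_dup[idx] <- votes_dup[idx] + sup_dup
    models_seen[idx] <- models_seen[idx] + 1L
    k_del_best[idx] <- pmax(k_del_best[idx], k_del)
    k_dup_best[idx] <- pmax(k_dup_best[idx], k_dup)
  }

  state <- rep("NORMAL", n_s)
  votes <- integer(n_s)
  bf <- rep(NA_real_, n_s)
  del <- votes_del >= config$votes_required
  dup <- !del & votes_dup >= config$votes_required
  state[del] <- "HET_DEL"; votes[del] <- votes_del[del]; bf[del] <- k_del_best[del]
  state[dup] <- "DUP"; votes[dup] <- votes_dup[dup]; bf[dup] <- k_dup_best[dup]
  state[homdel_mask] <- "HOM_DEL"
  votes[homdel_mask] <- length(partners)
  bf[homdel_mask] <- NA_real_
  data.frame(amplicon = amplicon_id, sample = samples, state = state,
             votes = votes, bayes_factor_K = bf,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Cells of one amplicon flagged as homozygous deletions by the QC pass.
.homdel_cells_of <- function(matrix, amplicon_id) {
  matrix$homdel[amplicon_id, ]
}

#' Run the unsupervised caller over a QC'd matrix
#'
#' Computes the correlation matrix, chooses T (unless fixed in the config),
#' selects partners, masks partnerless amplicons, and calls every remaining
#' amplicon in every sample.
#'
#' @param matrix A QC'd [coverage_matrix()].
#' @param config An [unsupervised_config()].
#' @param corr Optional precomputed correlation matrix.
#' @return List: `calls` (per-amplicon data frame), `T`, `partners` (named
#'   list), `partnerless` (amplicon ids with fewer than L partners),
#'   `corr` (the correlation matrix).
#' @export
run_unsupervised <- function(matrix, config = unsupervised_config(),
                             corr = NULL) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  n_s <- ncol(matrix$counts)
  if (n_s < config$min_samples && !config$allow_small_dataset) {
    stop("dataset has ", n_s, " samples; at least ", config$min_samples,
         " are required (set allow_small_dataset = TRUE to override)")
  }
  if (is.null(corr)) corr <- amplicon_correlations(matrix)
  T <- if (is.null(config$corr_threshold)) {
    choose_corr_threshold(matrix, corr, config$L)
  } else config$corr_threshold
  active <- rownames(matrix$counts)[rowSums(matrix$qc_mask) > 0]
  partners <- lapply(setNames(active, active), select_partners,
                     matrix = matrix, config = config, corr = corr, T = T)
  partnerless <- names(partners)[lengths(partners) < config$L]
  callable <- setdiff(active, partnerless)
  calls <- do.call(rbind, lapply(callable, function(a) {
    call_amplicon(a, partners[[a]], matrix, config)
  }))
  if (is.null(calls)) {
    calls <- data.frame(amplicon = character(), sample = character(),
                        state = character(), votes = integer(),
                        bayes_factor_K = numeric(), stringsAsFactors = FALSE)
  }
  list(calls = calls, T = T, partners = partners,
       partnerless = partnerless, corr = corr)
}
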