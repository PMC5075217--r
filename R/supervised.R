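# Supervised site-level classifier: control/test split, cross-gene cluster
# normalisation, three copy-number models per amplicon, chi-squared
# admissibility, NED + Benjamini-Hochberg rejection of the normal model,
# Bayes-factor confirmation, and iterative control-set growth.

#' Supervised classifier configuration
#'
#' @param cluster_size_k Amplicons per normalisation cluster (default 5).
#' @param cluster_min_corr Minimum correlation for cluster membership
#'   (default 0.5): clusters are built from highly correlated amplicons and
#'   shrink rather than admit weak members, whose unrelated fluctuations
#'   would inflate the normalised statistic.
#' @param min_control_for_pearson Control-set size above which Pearson
#'   correlation replaces the robust Sn-correlation (default 20).
#' @param min_control_required Minimum control-set size (default 20).
#' @param admissibility_alpha_base Base significance level of the per-
#'   amplicon chi-squared admissibility test, divided by the expected number
#'   of altered amplicons (default 0.05).
#' @param fdr_level Benjamini-Hochberg FDR level for rejecting the normal
#'   model (default 0.05).
#' @param bayes_factor_threshold Bayes-factor threshold for a final call,
#'   assuming equal model priors (default 100).
#' @param max_iterations Maximum control-growth iterations (default 5).
#' @return Object of class `supervised_config`.
#' @export
supervised_config <- function(cluster_size_k = 5,
                              cluster_min_corr = 0.5,
                              min_control_for_pearson = 20,
                              min_control_required = 20,
                              admissibility_alpha_base = 0.05,
                              fdr_level = 0.05,
                              bayes_factor_threshold = 100,
                              max_iterations = 5) {
  stopifnot(cluster_size_k >= 1, cluster_min_corr >= 0, cluster_min_corr < 1,
            min_control_for_pearson >= 3,
            min_control_required >= 3,
            admissibility_alpha_base > 0, admissibility_alpha_base < 1,
            fdr_level > 0, fdr_level < 1,
            bayes_factor_threshold > 0, max_iterations >= 1)
  structure(list(cluster_size_k = cluster_size_k,
                 cluster_min_corr = cluster_min_corr,
                 min_control_for_pearson = min_control_for_pearson,
                 min_control_required = min_control_required,
                 admissibility_alpha_base = admissibility_alpha_base,
                 fdr_level = fdr_level,
                 bayes_factor_threshold = bayes_factor_threshold,
                 max_iterations = max_iterations),
            class = "supervised_config")
}

#' Split samples into control and test sets
#'
#' With an explicit control list, that list defines the control set. From
#' unsupervised output, any sample with at least one non-NORMAL amplicon
#' call is suspected of carrying a CNV and goes to the test set; all others
#' form the control set.
#'
#' @param samples Character vector of QC-passed sample ids.
#' @param unsupervised_calls Per-amplicon call data frame from
#'   [run_unsupervised()] (ignored when `control_samples` is given).
#' @param control_samples Optional explicit control sample ids.
#' @param config A [supervised_config()].
#' @return List with `control` and `test` character vectors.
#' @export
split_control_test <- function(samples, unsupervised_calls = NULL,
                               control_samples = NULL,
                               config = supervised_config()) {
  if (!is.null(control_samples)) {
    control <- intersect(samples, control_samples)
    test <- setdiff(samples, control)
  } else {
    if (is.null(unsupervised_calls)) {
      stop("either unsupervised_calls or control_samples must be supplied")
    }
    flagged <- unique(unsupervised_calls$sample[
      unsupervised_calls$state != "NORMAL"])
    test <- intersect(samples, flagged)
    control <- setdiff(samples, test)
  }
  if (length(control) < config$min_control_required) {
    stop("control set has ", length(control), " samples; at least ",
         config$min_control_required, " CNV-free samples are required - ",
         "supply an a-priori control list or enlarge the dataset")
  }
  list(control = control, test = test)
}

#' Build the normalisation cluster for one amplicon
#'
#' The `k` amplicons from other genes whose log coverages on the control
#' samples correlate best with the target's. Pearson correlation is used
#' when the control set is large enough (> `min_control_for_pearson`),
#' the robust Sn-correlation otherwise. Shrinks with a warning when fewer
#' than `k` candidates correlate above `cluster_min_corr`.
#'
#' @param amplicon_id Target amplicon id.
#' @param matrix A QC'd [coverage_matrix()].
#' @param control Control sample ids.
#' @param config A [supervised_config()].
#' @return Character vector of cluster amplicon ids (possibly < k).
#' @export
cluster_amplicons <- function(amplicon_id, matrix, control,
                              config = supervised_config()) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  panel <- matrix$panel
  lc <- .log_coverage(matrix)[, control, drop = FALSE]
  mask <- matrix$qc_mask[, control, drop = FALSE]
  j <- match(amplicon_id, panel$id)
  cand <- which(panel$gene != panel$gene[j] & rowSums(mask) > 0)
  use_pearson <- length(control) > config$min_control_for_pearson
  rs <- vapply(cand, function(k) {
    common <- mask[j, ] & mask[k, ]
    if (sum(common) < 3) return(NA_real_)
    if (use_pearson) {
      suppressWarnings(cor(lc[j, common], lc[k, common]))
    } else {
      tryCatch(sn_correlation(lc[j, common], lc[k, common]),
               error = function(e) NA_real_)
    }
  }, numeric(1))
  ok <- !is.na(rs) & rs > config$cluster_min_corr
  ids <- panel$id[cand[ok]]
  ord <- order(-rs[ok], ids)
  out <- utils::head(ids[ord], config$cluster_size_k)
  if (length(out) < config$cluster_size_k) {
    warning("cluster for amplicon ", amplicon_id, " shrank to ",
            length(out), " of ", config$cluster_size_k, " amplicons")
  }
  out
}

#' Cluster-normalised log coverage
#'
#' \eqn{x_j = \log cov(a_j) - mean_{k \in C} \log cov(a_{jk})}: the
#' amplicon's log coverage centred on the average log coverage of its
#' cluster of correlated amplicons from other genes. A global per-sample
#' scaling (library size) cancels exactly.
#'
#' A cluster cell can itself lie inside a CNV of the sample being
#' normalised (the different-gene rule only protects the target amplicon).
#' Cells listed in `exclude_cells` - QC-masked cells and cells the
#' unsupervised stage flagged non-NORMAL - contribute their reference
#' level (median log coverage over `ref_samples`) instead of their own
#' deviation, so a deletion elsewhere in the genome cannot masquerade as a
#' duplication here, and no level bias is introduced.
#'
#' @param amplicon_id Target amplicon id.
#' @param cluster Cluster amplicon ids.
#' @param matrix A [coverage_matrix()].
#' @param samples Sample ids to compute for (default: all).
#' @param exclude_cells Optional logical matrix (amplicon x sample): cells
#'   whose deviations must not enter the cluster term.
#' @param ref_samples Samples over which reference levels are taken
#'   (default: all).
#' @return Named numeric vector of x_j per sample (`NA` where the target
#'   cell is QC-masked or no cluster cell is usable).
#' @export
normalize_amplicon <- function(amplicon_id, cluster, matrix,
                               samples = colnames(matrix$counts),
                               exclude_cells = NULL,
                               ref_samples = colnames(matrix$counts)) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  if (length(cluster) == 0) stop("empty cluster for amplicon ", amplicon_id)
  lc <- .log_coverage(matrix)
  mask <- matrix$qc_mask
  drop <- !mask
  if (!is.null(exclude_cells)) drop <- drop | exclude_cells
  cl <- lc[cluster, samples, drop = FALSE]
  cl_drop <- drop[cluster, samples, drop = FALSE]
  if (any(cl_drop)) {
    ref <- apply(lc[cluster, ref_samples, drop = FALSE], 1, median)
    # cluster term = mean member level + mean deviation of CLEAN members:
    # excluded cells contribute no deviation, and the deviation average is
    # taken over the surviving members so the sample's shared condition
    # response is tracked at full strength
    dev <- cl - ref
    dev[cl_drop] <- 0
    n_clean <- colSums(!cl_drop)
    term <- mean(ref) + colSums(dev) / pmax(n_clean, 1)
    all_dropped <- n_clean == 0
  } else {
    term <- colMeans(cl)
    all_dropped <- rep(FALSE, length(samples))
  }
  x <- lc[amplicon_id, samples] - term
  x[!mask[amplicon_id, samples] | all_dropped] <- NA_real_
  x
}

#' Fit the three copy-number models for one amplicon
#'
#' Locations: the Hodges-Lehmann estimate of the control samples'
#' normalised log coverages, shifted by log(0.5) for heterozygous deletion
#' and log(1.5) for duplication. Scales: the Sn estimate on controls,
#' multiplied by sqrt(2) (deletion) and sqrt(2/3) (duplication) - the
#' delta-method corrections for the variance of log-transformed Poisson
#' coverage at half and 1.5 times the wild-type rate.
#'
#' @param amplicon_id Target amplicon id.
#' @param x_control Control samples' normalised values (NAs dropped).
#' @param config A [supervised_config()].
#' @return Object of class `amplicon_models`: list with `amplicon`,
#'   `normal`, `het_del`, `dup` (each `list(location, scale)`), or `NULL`
#'   when the scale degenerates to zero.
#' @export
fit_models <- function(amplicon_id, x_control,
                       config = supervised_config()) {
  x <- x_control[is.finite(x_control)]
  if (length(x) < config$min_control_required) {
    stop("amplicon ", amplicon_id, ": only ", length(x),
         " usable control values (need ", config$min_control_required, ")")
  }
  loc <- hodges_lehmann(x)
  s <- sn_scale(x)
  if (s <= 0) {
    warning("amplicon ", amplicon_id,
            " has zero robust scale on controls; excluded")
    return(NULL)
  }
  structure(list(
    amplicon = amplicon_id,
    normal = list(location = loc, scale = s),
    het_del = list(location = loc + log(0.5), scale = s * sqrt(2)),
    dup = list(location = loc + log(1.5), scale = s * sqrt(2 / 3))
  ), class = "amplicon_models")
}

#' Classify one CNV site in one test sample
#'
#' Three consecutive questions: (a) admissibility - could every amplicon of
#' the site have been produced by the deletion (or duplication) model?
#' Tested per amplicon with a chi-squared(1) statistic at level
#' `admissibility_alpha_base / expected_altered`; the site is "suspicious"
#' for a state only if all its amplicons are admissible under that state's
#' model. (b) is the normal model rejected? The squared normalised
#' Euclidean distance to the normal locations follows a chi-squared with
#' one degree of freedom per amplicon (diagonal covariance after cluster
#' normalisation); its p-value enters a Benjamini-Hochberg correction
#' across all suspicious pairs (done by the caller, so this function
#' returns the raw p). (c) is the CNV model the best explanation? The Bayes
#' factor multiplies per-amplicon normal-density ratios; the final call
#' requires it to reach `bayes_factor_threshold`.
#'
#' @param x Named numeric vector: the sample's normalised values for the
#'   site's modelled amplicons.
#' @param models List of `amplicon_models` for those amplicons (same order).
#' @param config A [supervised_config()].
#' @param expected_altered Expected number of altered amplicons (test-set
#'   amplicon count / 2, floored at 1).
#' @param pois_var_adjust Optional per-amplicon additions to the normal
#'   model's variance for this sample: the delta-method shot-noise term
#'   \eqn{1/\hat\mu_{ij} - q_j} that accounts for the sample's own expected
#'   depth differing from the control average (see the methods vignette).
#'   The deletion/duplication variance factors multiply the adjusted base
#'   variance.
#' @return List: `suspicious_states` (subset of HET_DEL/DUP), `p_normal`
#'   (raw upper-tail chi-squared p of NED^2), `bf` (named Bayes factors for
#'   the suspicious states), `n_amplicons`.
#' @export
classify_site <- function(x, models, config = supervised_config(),
                          expected_altered = 1, pois_var_adjust = NULL) {
  stopifnot(length(x) == length(models), length(x) >= 1)
  expected_altered <- max(1, expected_altered)
  alpha <- config$admissibility_alpha_base / expected_altered
  crit <- qchisq(1 - alpha, df = 1)
  loc_n <- vapply(models, function(m) m$normal$location, numeric(1))
  s_n <- vapply(models, function(m) m$normal$scale, numeric(1))
  if (!is.null(pois_var_adjust)) {
    adj <- ifelse(is.finite(pois_var_adjust), pois_var_adjust, 0)
    s_n <- sqrt(pmax(s_n^2 + adj, 0.25 * s_n^2))
  }
  suspicious <- character(0)
  bf <- c(HET_DEL = NA_real_, DUP = NA_real_)
  log_lik_normal <- sum(dnorm(x, loc_n, s_n, log = TRUE))
  for (state in c("HET_DEL", "DUP")) {
    key <- if (state == "HET_DEL") "het_del" else "dup"
    loc <- vapply(models, function(m) m[[key]]$location, numeric(1))
    s <- s_n * if (state == "HET_DEL") sqrt(2) else sqrt(2 / 3)
    z2 <- ((x - loc) / s)^2
    if (all(z2 <= crit)) {
      suspicious <- c(suspicious, state)
      bf[state] <- exp(sum(dnorm(x, loc, s, log = TRUE)) - log_lik_normal)
    }
  }
  d2 <- ned(x, loc_n, s_n)^2
  p_normal <- pchisq(d2, df = length(x), lower.tail = FALSE)
  list(suspicious_states = suspicious, p_normal = p_normal,
       bf = bf, n_amplicons = length(x))
}

# One full supervised pass over the current control/test split.
.supervised_pass <- function(matrix, control, test, config,
                             exclude_cells = NULL) {
  panel <- matrix$panel
  active <- rownames(matrix$counts)[rowSums(matrix$qc_mask) > 0]
  clusters <- lapply(setNames(active, active), function(a) {
    suppressWarnings(cluster_amplicons(a, matrix, control, config))
  })
  modelled <- character(0)
  models <- list()
  x_all <- list()
  pois_adj <- list()
  lc <- .log_coverage(matrix)
  for (a in active) {
    cl <- clusters[[a]]
    if (length(cl) == 0) next
    x <- normalize_amplicon(a, cl, matrix, exclude_cells = exclude_cells,
                            ref_samples = control)
    m <- tryCatch(fit_models(a, x[control], config), error = function(e) NULL)
    if (is.null(m)) next
    models[[a]] <- m
    x_all[[a]] <- x
    # delta-method shot-noise adjustment: x = log cov_j - mean_k log cov_k
    # carries Poisson variance 1/mu_j + sum_k (1/mu_k)/|C|^2 per cell; the
    # target's mu under the normal model is exp(location + cluster term),
    # the members' observed counts estimate theirs. The control-median part
    # q is already inside the fitted Sn scale.
    mu_hat <- exp(m$normal$location + (lc[a, ] - x))
    member_shot <- colSums(1 / pmax(matrix$counts[cl, , drop = FALSE],
                                    1)) / length(cl)^2
    v <- 1 / mu_hat + member_shot
    q <- median(v[control], na.rm = TRUE)
    pois_adj[[a]] <- v - q
    modelled <- c(modelled, a)
  }
  if (length(modelled) == 0 || length(test) == 0) {
    return(list(calls = .empty_site_calls(), modelled = modelled))
  }
  expected_altered <- max(1, length(test) * length(modelled) / 2)
  sites <- panel_sites(panel)
  rows <- list()
  for (site in names(sites)) {
    amp <- intersect(sites[[site]], modelled)
    if (length(amp) == 0) next
    for (smp in test) {
      x <- vapply(amp, function(a) x_all[[a]][smp], numeric(1))
      ok <- is.finite(x)
      if (!any(ok)) next
      adj <- vapply(amp[ok], function(a) pois_adj[[a]][smp], numeric(1))
      res <- classify_site(x[ok], models[amp[ok]], config, expected_altered,
                           pois_var_adjust = adj)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, site_id = site,
        gene = panel$gene[match(amp[1], panel$id)],
        suspicious = length(res$suspicious_states) > 0,
        states = paste(res$suspicious_states, collapse = ","),
        p_normal = res$p_normal,
        bf_het_del = res$bf[["HET_DEL"]], bf_dup = res$bf[["DUP"]],
        n_amplicons = res$n_amplicons, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(list(calls = .empty_site_calls(), modelled = modelled))
  # BH family: all suspicious (site, sample) pairs of this iteration
  tab$adj_p_normal <- NA_real_
  susp <- which(tab$suspicious)
  tab$adj_p_normal[susp] <- benjamini_hochberg(tab$p_normal[susp])
  tab$state <- "NORMAL"
  tab$bayes_factor <- NA_real_
  for (i in susp) {
    if (is.na(tab$adj_p_normal[i]) || tab$adj_p_normal[i] > config$fdr_level) next
    bfs <- c(HET_DEL = tab$bf_het_del[i], DUP = tab$bf_dup[i])
    bfs <- bfs[!is.na(bfs)]
    if (length(bfs) == 0) next
    best <- names(bfs)[which.max(bfs)]
    if (max(bfs) >= config$bayes_factor_threshold) {
      tab$state[i] <- best
      tab$bayes_factor[i] <- max(bfs)
    }
  }
  list(calls = tab, modelled = modelled)
}

.empty_site_calls <- function() {
  data.frame(sample = character(), site_id = character(), gene = character(),
             suspicious = logical(), states = character(),
             p_normal = numeric(), bf_het_del = numeric(), bf_dup = numeric(),
             n_amplicons = integer(), adj_p_normal = numeric(),
             state = character(), bayes_factor = numeric(),
             stringsAsFactors = FALSE)
}

#' Run the supervised classifier with iterative control growth
#'
#' Repeats the cluster / model / classify pass, moving test samples with
#' zero non-NORMAL site calls into the control set after each pass, until
#' no sample moves or `max_iterations` is reached. The control set only
#' ever grows.
#'
#' @param matrix A QC'd [coverage_matrix()].
#' @param unsupervised_calls Per-amplicon calls from [run_unsupervised()]
#'   (used for the initial split unless `control_samples` is given).
#' @param control_samples Optional explicit control sample ids.
#' @param config A [supervised_config()].
#' @return List: `calls` (site-level data frame from the final pass),
#'   `control`, `test`, `iterations`.
#' @export
run_supervised <- function(matrix, unsupervised_calls = NULL,
                           control_samples = NULL,
                           config = supervised_config()) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  samples <- colnames(matrix$counts)
  split <- split_control_test(samples, unsupervised_calls,
                              control_samples, config)
  control <- split$control
  test <- split$test
  # cluster-cell hygiene: cells the unsupervised stage called non-NORMAL
  # must not contribute deviations to other amplicons' cluster terms
  exclude <- matrix$homdel
  if (!is.null(unsupervised_calls) && nrow(unsupervised_calls)) {
    nn <- unsupervised_calls[unsupervised_calls$state != "NORMAL", ,
                             drop = FALSE]
    idx <- cbind(match(nn$amplicon, rownames(matrix$counts)),
                 match(nn$sample, colnames(matrix$counts)))
    idx <- idx[stats::complete.cases(idx), , drop = FALSE]
    exclude[idx] <- TRUE
  }
  iterations <- 0L
  calls <- .empty_site_calls()
  repeat {
    iterations <- iterations + 1L
    pass <- .supervised_pass(matrix, control, test, config, exclude)
    calls <- pass$calls
    if (length(test) == 0) break
    clean <- setdiff(test, unique(calls$sample[calls$state != "NORMAL"]))
    if (length(clean) == 0 || iterations >= config$max_iterations) break
    control <- c(control, clean)
    test <- setdiff(test, clean)
    if (length(test) == 0) break
  }
  list(calls = calls, control = control, test = test,
       iterations = iterations)
}
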