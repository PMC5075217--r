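# Pipeline orchestration: QC -> unsupervised caller -> control/test split ->
# supervised classifier -> iteration -> merged site-level report.

#' Pipeline configuration
#'
#' @param qc A [qc_thresholds()].
#' @param unsupervised An [unsupervised_config()].
#' @param supervised A [supervised_config()].
#' @param mode One of `"both"`, `"unsupervised_only"`, `"supervised_only"`.
#'   `"supervised_only"` requires an explicit control list.
#' @param control_samples Optional a-priori CNV-free control sample ids.
#' @param keep_single_site_dup Keep duplications confined to a single CNV
#'   site in the default report (default `FALSE`: they are emitted flagged
#'   `single_site_dup` but suppressed, because the normal and duplication
#'   models overlap too much for a one-site duplication to be reliable).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            unsupervised = unsupervised_config(),
                            supervised = supervised_config(),
                            mode = c("both", "unsupervised_only",
                                     "supervised_only"),
                            control_samples = NULL,
                            keep_single_site_dup = FALSE) {
  mode <- match.arg(mode)
  if (mode == "supervised_only" && is.null(control_samples)) {
    stop("supervised_only mode requires an explicit control_samples list")
  }
  structure(list(qc = qc, unsupervised = unsupervised,
                 supervised = supervised, mode = mode,
                 control_samples = control_samples,
                 keep_single_site_dup = keep_single_site_dup),
            class = "pipeline_config")
}

# Collapse consecutive same-state site calls (within sample and gene) into
# runs; returns the site-run report rows.
.merge_site_runs <- function(site_calls, panel, stage) {
  if (nrow(site_calls) == 0) return(.empty_report())
  site_order <- unique(panel$site_id)
  site_first <- vapply(split(seq_len(nrow(panel)), panel$site_id)[site_order],
                       min, integer(1))
  site_last <- vapply(split(seq_len(nrow(panel)), panel$site_id)[site_order],
                      max, integer(1))
  calls <- site_calls[site_calls$state != "NORMAL", , drop = FALSE]
  if (nrow(calls) == 0) return(.empty_report())
  calls$site_rank <- match(calls$site_id, site_order)
  calls <- calls[order(calls$sample, calls$site_rank), , drop = FALSE]
  out <- list()
  for (key in unique(paste(calls$sample, calls$gene, calls$state))) {
    sub <- calls[paste(calls$sample, calls$gene, calls$state) == key, ,
                 drop = FALSE]
    brk <- c(0, which(diff(sub$site_rank) != 1), nrow(sub))
    for (b in seq_len(length(brk) - 1)) {
      run <- sub[(brk[b] + 1):brk[b + 1], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        sample = run$sample[1], gene = run$gene[1],
        first_site = run$site_id[1],
        last_site = run$site_id[nrow(run)],
        state = run$state[1],
        n_sites = nrow(run),
        n_amplicons = sum(run$n_amplicons),
        first_amplicon = site_first[[run$site_id[1]]],
        last_amplicon = site_last[[run$site_id[nrow(run)]]],
        votes = if ("votes" %in% names(run)) max(run$votes) else NA_integer_,
        adj_p = if ("adj_p_normal" %in% names(run)) {
          suppressWarnings(min(run$adj_p_normal, na.rm = TRUE))
        } else NA_real_,
        bayes_factor = if ("bayes_factor" %in% names(run)) {
          suppressWarnings(max(run$bayes_factor, na.rm = TRUE))
        } else NA_real_,
        stage = stage, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.empty_report <- function() {
  data.frame(sample = character(), gene = character(),
             first_site = character(), last_site = character(),
             state = character(), n_sites = integer(),
             n_amplicons = integer(), first_amplicon = integer(),
             last_amplicon = integer(), votes = integer(),
             adj_p = numeric(), bayes_factor = numeric(),
             stage = character(), flag = character(),
             stringsAsFactors = FALSE)
}

# Site-level summary of unsupervised per-amplicon calls: a site gets a
# sample's state when the majority of its called amplicons agree (HOM_DEL
# outranks on presence).
.unsupervised_site_calls <- function(calls, panel) {
  if (nrow(calls) == 0) {
    return(data.frame(sample = character(), site_id = character(),
                      gene = character(), state = character(),
                      n_amplicons = integer(), votes = integer(),
                      stringsAsFactors = FALSE))
  }
  calls$site_id <- panel$site_id[match(calls$amplicon, panel$id)]
  calls$gene <- panel$gene[match(calls$amplicon, panel$id)]
  out <- list()
  for (key in unique(paste(calls$sample, calls$site_id))) {
    sub <- calls[paste(calls$sample, calls$site_id) == key, , drop = FALSE]
    non_normal <- sub[sub$state != "NORMAL", , drop = FALSE]
    state <- if (nrow(non_normal) == 0) {
      "NORMAL"
    } else if (any(non_normal$state == "HOM_DEL")) {
      "HOM_DEL"
    } else {
      names(sort(table(non_normal$state), decreasing = TRUE))[1]
    }
    n_called <- sum(sub$state == state & state != "NORMAL")
    out[[length(out) + 1L]] <- data.frame(
      sample = sub$sample[1], site_id = sub$site_id[1],
      gene = sub$gene[1], state = state,
      n_amplicons = if (state == "NORMAL") nrow(sub) else n_called,
      votes = max(sub$votes), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full CNV detection pipeline on one coverage matrix
#'
#' One coverage matrix is one sequencing run; runs are analysed separately.
#' Steps: quality control (with partner-availability feedback from the
#' unsupervised partner search), the unsupervised per-amplicon caller, the
#' control/test split, the supervised site classifier with iterative
#' control growth, and a merged site-run report. Deterministic given the
#' inputs and configuration.
#'
#' @param matrix A [coverage_matrix()] of raw counts.
#' @param config A [pipeline_config()].
#' @return Object of class `cnv_pipeline_result`: list with `report` (the
#'   default site-run report, single-site duplications suppressed),
#'   `full_report` (including flagged rows), `qc_report`, `T`,
#'   `amplicon_calls`, `site_calls_supervised`, `control`, `test`,
#'   `iterations`, `config`.
#' @export
run_pipeline <- function(matrix, config = pipeline_config()) {
  stopifnot(inherits(matrix, "coverage_matrix"),
            inherits(config, "pipeline_config"))
  # QC stage 1: read-count filter, homozygous deletions, coverage filter
  qc1 <- run_qc(matrix, config$qc)
  m <- qc1$matrix
  report <- qc1$report
  un <- NULL
  amp_calls <- data.frame()
  if (config$mode != "supervised_only") {
    # partner availability feeds back into amplicon QC
    corr <- amplicon_correlations(m)
    T <- if (is.null(config$unsupervised$corr_threshold)) {
      choose_corr_threshold(m, corr, config$unsupervised$L)
    } else config$unsupervised$corr_threshold
    active <- rownames(m$counts)[rowSums(m$qc_mask) > 0]
    partners <- lapply(setNames(active, active), select_partners,
                       matrix = m, config = config$unsupervised,
                       corr = corr, T = T)
    avail <- setNames(rep(FALSE, nrow(m$counts)), rownames(m$counts))
    avail[names(partners)] <- lengths(partners) >= config$unsupervised$L
    fa <- filter_amplicons(m, config$qc, avail)
    m <- fa$matrix
    report$failed_amplicons <- rbind(report$failed_amplicons,
                                     fa$failed_amplicons)
    report$excluded_sites <- union(report$excluded_sites, fa$excluded_sites)
    cfg_u <- config$unsupervised
    cfg_u$corr_threshold <- T
    un <- run_unsupervised(m, cfg_u, corr = corr)
    amp_calls <- un$calls
  } else {
    T <- NA_real_
  }
  sup <- NULL
  if (config$mode != "unsupervised_only") {
    sup <- run_supervised(
      m,
      unsupervised_calls = if (nrow(amp_calls)) amp_calls else NULL,
      control_samples = config$control_samples,
      config = config$supervised)
  }

  panel <- m$panel
  un_sites <- .unsupervised_site_calls(amp_calls, panel)
  rep_un <- .merge_site_runs(un_sites, panel, "unsupervised")
  rep_sup <- if (!is.null(sup)) {
    .merge_site_runs(sup$calls, panel, "supervised")
  } else .empty_report()

  full <- if (config$mode == "unsupervised_only") {
    rep_un
  } else if (config$mode == "supervised_only") {
    rep_sup
  } else {
    # supervised is the final arbiter for its test samples; unsupervised
    # contributes homozygous deletions and stage annotation
    hom <- rep_un[rep_un$state == "HOM_DEL", , drop = FALSE]
    both_key <- paste(rep_sup$sample, rep_sup$gene, rep_sup$first_site,
                      rep_sup$state)
    un_key <- paste(rep_un$sample, rep_un$gene, rep_un$first_site,
                    rep_un$state)
    rep_sup$stage[both_key %in% un_key] <- "both"
    rbind(rep_sup, hom)
  }
  if (nrow(full)) {
    full$flag <- ""
    single_dup <- full$state == "DUP" & full$n_sites == 1
    full$flag[single_dup] <- "single_site_dup"
    rownames(full) <- NULL
  } else {
    full <- .empty_report()
  }
  default_report <- if (config$keep_single_site_dup) full else {
    full[full$flag != "single_site_dup", , drop = FALSE]
  }
  structure(list(report = default_report, full_report = full,
                 qc_report = report, T = T,
                 amplicon_calls = amp_calls,
                 site_calls_supervised = if (!is.null(sup)) sup$calls else NULL,
                 control = if (!is.null(sup)) sup$control else NULL,
                 test = if (!is.null(sup)) sup$test else NULL,
                 iterations = if (!is.null(sup)) sup$iterations else NA_integer_,
                 config = config),
            class = "cnv_pipeline_result")
}

#' @export
print.cnv_pipeline_result <- function(x, ...) {
  cat(sprintf("CNV pipeline result (mode %s): %d call(s), T = %s\n",
              x$config$mode, nrow(x$report),
              if (is.na(x$T)) "-" else format(x$T)))
  if (nrow(x$report)) {
    print(as.data.frame(x$report[, c("sample", "gene", "first_site",
                                     "last_site", "state", "n_amplicons",
                                     "stage")]))
  }
  invisible(x)
}

#' Write the pipeline report to TSV
#'
#' Columns: sample, gene, first_site, last_site, state, n_sites,
#' n_amplicons, votes, adj_p, bayes_factor, stage, flag.
#'
#' @param result A `cnv_pipeline_result` (or a report data frame).
#' @param path Output path.
#' @param full Write the full report including suppressed flagged rows.
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(result, path, full = FALSE) {
  report <- if (inherits(result, "cnv_pipeline_result")) {
    if (full) result$full_report else result$report
  } else result
  cols <- c("sample", "gene", "first_site", "last_site", "state",
            "n_sites", "n_amplicons", "votes", "adj_p", "bayes_factor",
            "stage", "flag")
  cols <- intersect(cols, names(report))
  write.table(report[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
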