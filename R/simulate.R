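# Multiplex-PCR coverage simulator: exponential amplification with shared
# efficiency groups, per-sample condition shifts, Poisson read noise and
# injected CNVs with a machine-readable truth set.

#' Build a synthetic amplicon panel
#'
#' Genes on separate contigs, each covered by CNV sites (exons) of 1-5
#' amplicons, until roughly `n_amplicons` targets exist. Deterministic given
#' the seed.
#'
#' @param n_genes Number of genes (default 3).
#' @param n_amplicons Approximate total amplicons (default 130).
#' @param seed Integer seed.
#' @return An [amplicon_panel()].
#' @export
simulate_panel <- function(n_genes = 3, n_amplicons = 130, seed = 1) {
  set.seed(seed)
  per_gene <- diff(round(seq(0, n_amplicons, length.out = n_genes + 1)))
  rows <- list()
  for (g in seq_len(n_genes)) {
    gene <- sprintf("GENE%d", g)
    chrom <- sprintf("chr%d", g)
    n_amp <- per_gene[g]
    sizes <- integer(0)
    while (sum(sizes) < n_amp) {
      sizes <- c(sizes, sample(1:5, 1))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_amp)
    sizes <- sizes[sizes > 0]
    amp_i <- 0L
    for (e in seq_along(sizes)) {
      for (k in seq_len(sizes[e])) {
        amp_i <- amp_i + 1L
        start <- 1000L + (amp_i - 1L) * 300L
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = start, end = start + 150L,
          id = sprintf("%s_A%03d", gene, amp_i),
          gene = gene, site_id = sprintf("%s_E%02d", gene, e),
          stringsAsFactors = FALSE)
      }
    }
  }
  amplicon_panel(do.call(rbind, rows))
}

#' Simulation parameters
#'
#' Defaults emulate one sequencing run of the targeted panels the method is
#' designed for: 48 samples, ~130 amplicons in 3 genes, 25 PCR cycles,
#' per-amplicon mean depth spread over roughly 150-1080 reads, four
#' amplification-efficiency groups interleaved across genes (so every
#' amplicon has correlated partners on other genes), lognormal per-sample
#' condition factors shared within a group, and Poisson read noise.
#'
#' @param n_samples Number of samples (default 48).
#' @param panel An [amplicon_panel()]; default [simulate_panel()] with the
#'   same seed.
#' @param n_cycles PCR cycles c in the amplification law
#'   \eqn{N = N_0 (1+e)^c} (default 25).
#' @param target_depth Mean wild-type coverage per amplicon (default 400;
#'   per-amplicon means are drawn log-uniformly within a factor ~2.7 of it).
#' @param efficiency_groups Number of shared-behaviour groups (default 15).
#'   Each gene's amplicons are split into consecutive blocks, and block g of
#'   every gene belongs to group g, so each group spans all genes: an
#'   amplicon's strongest correlation partners sit on other genes, while any
#'   one gene holds only a few amplicons of the same group.
#' @param efficiency_range Range of group-centre efficiencies e (default
#'   c(0.45, 0.85)).
#' @param efficiency_spread Within-group half-width of per-amplicon
#'   efficiencies (default 0.02; tight, so log-log coverage slopes between
#'   group mates stay near 1 - the biochemical-similarity premise).
#' @param sample_condition_sd Log-scale SD of the per-sample, per-group
#'   condition factor (default 0.05).
#' @param overdispersion Negative-binomial overdispersion; 0 (default)
#'   means pure Poisson noise.
#' @param cnv_events List of events, each a list with `sample` (id or
#'   index), `gene`, `sites` (character vector of site_ids, contiguous
#'   within the gene) and `multiplier` (one of 0, 0.5, 1.5, 2).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_samples = 48, panel = NULL, n_cycles = 25,
                       target_depth = 400, efficiency_groups = 15,
                       efficiency_range = c(0.45, 0.85),
                       efficiency_spread = 0.02,
                       sample_condition_sd = 0.05,
                       overdispersion = 0,
                       cnv_events = list(), seed = 1) {
  stopifnot(n_samples >= 2, n_cycles >= 1, target_depth > 0,
            efficiency_groups >= 1, efficiency_spread >= 0,
            sample_condition_sd >= 0, overdispersion >= 0)
  if (is.null(panel)) panel <- simulate_panel(seed = seed)
  allowed <- c(0, 0.5, 1.5, 2)
  for (ev in cnv_events) {
    stopifnot(all(c("sample", "gene", "sites", "multiplier") %in% names(ev)))
    if (!ev$multiplier %in% allowed) {
      stop("CNV multiplier must be one of ", paste(allowed, collapse = ", "))
    }
    if (!all(ev$sites %in% panel$site_id[panel$gene == ev$gene])) {
      stop("CNV event sites must lie within gene ", ev$gene)
    }
  }
  # carrier fraction per site must respect the model's core assumption
  if (length(cnv_events)) {
    site_sample <- unique(do.call(rbind, lapply(cnv_events, function(ev) {
      data.frame(site = ev$sites, sample = as.character(ev$sample),
                 stringsAsFactors = FALSE)
    })))
    frac <- table(site_sample$site) / n_samples
    if (any(frac > 0.20)) {
      stop("per-site CNV carrier fraction exceeds the 20% model assumption")
    }
  }
  structure(list(n_samples = n_samples, panel = panel, n_cycles = n_cycles,
                 target_depth = target_depth,
                 efficiency_groups = efficiency_groups,
                 efficiency_range = efficiency_range,
                 efficiency_spread = efficiency_spread,
                 sample_condition_sd = sample_condition_sd,
                 overdispersion = overdispersion,
                 cnv_events = cnv_events, seed = seed),
            class = "sim_params")
}

#' Simulate a coverage matrix with truth set
#'
#' For amplicon j (efficiency group g) in sample i the expected coverage is
#' \eqn{\mu_{ij} = m_{ij} d_j (1+e_j f_{gi})^c / mean_i (1+e_j f_{gi})^c}:
#' the amplification law scaled to the amplicon's depth \eqn{d_j}, with
#' \eqn{m_{ij}} the CNV multiplier (1 for wild type), \eqn{e_j} the
#' amplicon efficiency and \eqn{f_{gi}} the shared sample-by-group
#' condition factor. Counts are Poisson around \eqn{\mu} (negative binomial
#' when overdispersion is on). Identical seed and parameters give identical
#' output.
#'
#' @param params A [sim_params()].
#' @return List: `matrix` (a [coverage_matrix()]), `truth` (data frame with
#'   one row per event: sample, gene, first/last site, multiplier, amplicon
#'   span as panel row indices, n_amplicons), and `groups` (the efficiency
#'   group of each amplicon).
#' @export
simulate_coverage <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  panel <- params$panel
  n_amp <- nrow(panel)
  n_s <- params$n_samples
  samples <- sprintf("S%02d", seq_len(n_s))

  # per gene, consecutive blocks; block g of every gene shares group g.
  # blocks hold >= 3 amplicons (leftovers merge into the last block) so
  # every group supplies enough cross-gene partners
  group <- integer(n_amp)
  for (gene in unique(panel$gene)) {
    idx <- which(panel$gene == gene)
    size <- max(3, ceiling(length(idx) / params$efficiency_groups))
    n_blocks <- max(1, length(idx) %/% size)
    group[idx] <- pmin(ceiling(seq_along(idx) / size), n_blocks)
  }
  n_groups <- max(group)
  centre <- runif(n_groups,
                  params$efficiency_range[1], params$efficiency_range[2])
  e <- centre[group] + runif(n_amp, -params$efficiency_spread,
                             params$efficiency_spread)
  depth <- params$target_depth * exp(runif(n_amp, -1, 1))
  f <- matrix(exp(rnorm(n_groups * n_s, sd = params$sample_condition_sd)),
              n_groups, n_s)

  resp <- (1 + outer(e, rep(1, n_s)) * f[group, , drop = FALSE])^params$n_cycles
  resp <- resp / rowMeans(resp)
  mu <- depth * resp

  mult <- matrix(1, n_amp, n_s, dimnames = list(panel$id, samples))
  truth <- list()
  for (ev in params$cnv_events) {
    smp <- if (is.numeric(ev$sample)) samples[ev$sample] else as.character(ev$sample)
    amp_rows <- which(panel$site_id %in% ev$sites)
    mult[amp_rows, smp] <- ev$multiplier
    truth[[length(truth) + 1L]] <- data.frame(
      sample = smp, gene = ev$gene,
      first_site = ev$sites[1], last_site = ev$sites[length(ev$sites)],
      multiplier = ev$multiplier,
      first_amplicon = min(amp_rows), last_amplicon = max(amp_rows),
      n_amplicons = length(amp_rows), stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    sample = character(), gene = character(), first_site = character(),
    last_site = character(), multiplier = numeric(),
    first_amplicon = integer(), last_amplicon = integer(),
    n_amplicons = integer(), stringsAsFactors = FALSE)

  mu <- mu * mult
  if (any(mu[mult == 1] < 1)) {
    stop("parameters give expected wild-type coverage below 1 read; ",
         "increase target_depth or reduce spread")
  }
  counts <- if (params$overdispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / params$overdispersion),
           n_amp, n_s)
  } else {
    matrix(rpois(length(mu), mu), n_amp, n_s)
  }
  dimnames(counts) <- list(panel$id, samples)
  list(matrix = coverage_matrix(panel, counts), truth = truth,
       groups = setNames(group, panel$id))
}

#' Draw a random CNV event list
#'
#' Helper to build carrier events for power studies: each carrier sample
#' receives one event in a random gene over a contiguous run of sites
#' totalling between `min_amplicons` and `max_amplicons` amplicons.
#' Duplication events are drawn over at least two sites (single-site
#' duplications are outside the caller's reporting scope); deletions may
#' cover a single site.
#'
#' @param panel An [amplicon_panel()].
#' @param carriers Sample indices to receive events.
#' @param multipliers Multipliers to sample from (default c(0.5, 1.5)).
#' @param min_amplicons,max_amplicons Bounds on event size in amplicons.
#' @return List of event lists suitable for [sim_params()].
#' @export
draw_cnv_events <- function(panel, carriers, multipliers = c(0.5, 1.5),
                            min_amplicons = 2, max_amplicons = 10) {
  site_tab <- unique(panel[, c("gene", "site_id")])
  site_sizes <- table(panel$site_id)
  events <- list()
  for (smp in carriers) {
    repeat {
      mult <- sample(multipliers, 1)
      gene <- sample(unique(site_tab$gene), 1)
      sites <- site_tab$site_id[site_tab$gene == gene]
      start <- sample(seq_along(sites), 1)
      need_sites <- if (mult > 1) 2 else 1
      max_len <- length(sites) - start + 1
      if (max_len < need_sites) next
      for (len in need_sites:max_len) {
        run <- sites[start:(start + len - 1)]
        n_amp <- sum(site_sizes[run])
        if (n_amp >= min_amplicons && n_amp <= max_amplicons) {
          events[[length(events) + 1L]] <- list(
            sample = smp, gene = gene, sites = run, multiplier = mult)
          break
        }
        if (n_amp > max_amplicons) break
      }
      if (length(events) && identical(events[[length(events)]]$sample, smp)) break
    }
  }
  events
}

# Wilson 95% score interval for a proportion.
.wilson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Score calls against a truth set
#'
#' A true event is detected (TP) when a call in the same sample and gene
#' with the matching direction (deletion vs duplication) overlaps at least
#' 50\% of the event's amplicon span; otherwise it is missed (FN). Calls
#' that match no true event that way are false positives. Specificity is
#' sample-level: the fraction of event-free samples with no call. Note the
#' convention: sensitivity is reported as TP / (TP + FN); "proportion of
#' true positives among all positive results" would instead be the
#' positive predictive value, which is also reported.
#'
#' @param calls Data frame with columns `sample`, `gene`, `state`,
#'   `first_amplicon`, `last_amplicon` (panel row indices), as produced by
#'   [run_pipeline()]'s report.
#' @param truth Truth data frame from [simulate_coverage()].
#' @param n_samples Total number of samples in the run.
#' @return List: `sensitivity`, `specificity`, `ppv`, counts (`tp`, `fn`,
#'   `fp`, `tn`), Wilson 95\% intervals, and a per-length breakdown data
#'   frame (`by_length`).
#' @export
score_calls <- function(calls, truth, n_samples) {
  del_states <- c("HET_DEL", "HOM_DEL")
  direction <- function(state, mult) {
    (state %in% del_states & mult < 1) | (state == "DUP" & mult > 1)
  }
  tp <- 0L; fn <- 0L
  detected <- logical(nrow(truth))
  call_used <- rep(FALSE, nrow(calls))
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      ev <- truth[i, ]
      span <- ev$last_amplicon - ev$first_amplicon + 1
      if (nrow(calls)) {
        for (k in seq_len(nrow(calls))) {
          cl <- calls[k, ]
          if (cl$sample != ev$sample || cl$gene != ev$gene) next
          if (!direction(cl$state, ev$multiplier)) next
          ov <- min(cl$last_amplicon, ev$last_amplicon) -
            max(cl$first_amplicon, ev$first_amplicon) + 1
          if (ov / span >= 0.5) {
            detected[i] <- TRUE
            call_used[k] <- TRUE
          }
        }
      }
    }
    tp <- sum(detected)
    fn <- sum(!detected)
  }
  fp <- sum(!call_used)
  carrier_samples <- unique(truth$sample)
  neg_samples <- n_samples - length(carrier_samples)
  fp_samples <- length(setdiff(unique(calls$sample[!call_used]),
                               carrier_samples))
  tn <- neg_samples - fp_samples
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (neg_samples > 0) tn / neg_samples else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  by_length <- if (nrow(truth)) {
    len <- truth$n_amplicons
    stats::aggregate(detected, by = list(n_amplicons = len),
                     FUN = function(d) c(detected = sum(d), total = length(d)))
  } else NULL
  list(sensitivity = sens, specificity = spec, ppv = ppv,
       tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity_ci = .wilson(tp, tp + fn),
       specificity_ci = .wilson(tn, neg_samples),
       by_length = by_length)
}
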