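# Shared fixtures built in code: small panels, coverage matrices with known
# structure, and SAM files for the read counter.

make_panel <- function(n_genes = 2, amps_per_gene = 3, sites_per_gene = NULL) {
  rows <- list()
  for (g in seq_len(n_genes)) {
    for (a in seq_len(amps_per_gene)) {
      site <- if (is.null(sites_per_gene)) a else
        ceiling(a / (amps_per_gene / sites_per_gene))
      start <- 100 * a
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sprintf("chr%d", g), start = start, end = start + 80,
        id = sprintf("G%dA%d", g, a), gene = sprintf("GENE%d", g),
        site_id = sprintf("G%dS%d", g, site),
        stringsAsFactors = FALSE)
    }
  }
  amplicon_panel(do.call(rbind, rows))
}

# Coverage matrix with multiplicative sample effects plus Poisson noise so
# cross-gene amplicons correlate strongly (one shared efficiency group).
make_correlated_matrix <- function(panel, n_samples = 30, depth = 1000,
                                   seed = 42) {
  set.seed(seed)
  f <- exp(rnorm(n_samples, sd = 0.3))
  mu <- outer(rep(depth, nrow(panel)), f)
  counts <- matrix(rpois(length(mu), mu), nrow(mu),
                   dimnames = list(panel$id, sprintf("S%02d", 1:n_samples)))
  coverage_matrix(panel, counts)
}

# Write a SAM file; reads is a data.frame(qname, flag, rname, pos, cigar).
write_sam <- function(path, chrom_lengths, reads) {
  con <- file(path, "w")
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (chrom in names(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_lengths[[chrom]]), con)
  }
  if (nrow(reads)) {
    reads <- reads[order(reads$rname, reads$pos), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                       reads$qname, reads$flag, reads$rname, reads$pos,
                       reads$cigar), con)
  }
  close(con)
  path
}

default_sim <- function(seed, cnv_events = list(), ...) {
  simulate_coverage(sim_params(seed = seed, cnv_events = cnv_events, ...))
}
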