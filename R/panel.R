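# Target-panel definitions: ordered amplicons with gene and CNV-site (exon)
# annotation. Coordinates are 0-based half-open (BED convention) throughout.

#' Construct an amplicon panel
#'
#' An amplicon panel is the coordinate system of all calls: an ordered set of
#' PCR target regions, each annotated with the gene and the CNV site (exon)
#' it covers. Sites are the exon-level units over which CNVs are reported;
#' within a gene they must form contiguous runs of amplicons.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `id`, `gene`,
#'   `site_id`. Coordinates 0-based half-open.
#' @return Object of class `amplicon_panel` (a validated, sorted data frame).
#' @export
amplicon_panel <- function(df) {
  required <- c("chrom", "start", "end", "id", "gene", "site_id")
  if (!all(required %in% names(df))) {
    stop("panel must have columns: ", paste(required, collapse = ", "))
  }
  df <- df[required]
  df$chrom <- as.character(df$chrom)
  df$id <- as.character(df$id)
  df$gene <- as.character(df$gene)
  df$site_id <- as.character(df$site_id)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df) == 0) stop("panel is empty")
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    stop("invalid interval (start >= end) for amplicon(s): ",
         paste(df$id[bad], collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate amplicon id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (any(!nzchar(df$gene)) || any(!nzchar(df$site_id))) {
    stop("every amplicon must have a non-empty gene and site_id")
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  # sites must be contiguous runs within one gene
  site_gene <- tapply(df$gene, df$site_id, function(g) length(unique(g)))
  if (any(site_gene > 1)) {
    stop("site_id spanning multiple genes: ",
         paste(names(site_gene)[site_gene > 1], collapse = ", "))
  }
  runs <- rle(df$site_id)
  if (anyDuplicated(runs$values)) {
    stop("site_id must label a contiguous run of amplicons: ",
         paste(unique(runs$values[duplicated(runs$values)]), collapse = ", "))
  }
  class(df) <- c("amplicon_panel", "data.frame")
  df
}

#' Read a panel definition file
#'
#' Six tab-separated columns without header: chrom, start, end, amplicon id,
#' gene, site_id; BED coordinate convention (0-based half-open).
#'
#' @param path Path to the panel file.
#' @return An [amplicon_panel()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("panel file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 6)) {
    stop("malformed panel line ", which(nfield != 6)[1],
         ": expected 6 tab-separated columns, got ", nfield[nfield != 6][1])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed panel line ", which(is.na(start) | is.na(end))[1],
         ": non-integer coordinate")
  }
  bad <- which(!(start < end))
  if (length(bad)) {
    stop("malformed panel line ", bad[1], ": start >= end")
  }
  amplicon_panel(data.frame(
    chrom = m[, 1], start = start, end = end,
    id = m[, 4], gene = m[, 5], site_id = m[, 6],
    stringsAsFactors = FALSE
  ))
}

#' Write a panel definition file
#'
#' @param panel An [amplicon_panel()].
#' @param path Output path (6-column tab-separated, no header).
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "amplicon_panel"))
  write.table(as.data.frame(panel)[, c("chrom", "start", "end", "id",
                                       "gene", "site_id")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Site map of a panel
#'
#' @param panel An [amplicon_panel()].
#' @return Named list mapping each site_id (in panel order) to the amplicon
#'   ids it contains.
#' @export
panel_sites <- function(panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  ids <- split(panel$id, factor(panel$site_id, levels = unique(panel$site_id)))
  lapply(ids, as.character)
}

#' Genes of a panel
#' @param panel An [amplicon_panel()].
#' @return Character vector of gene names in panel order.
#' @export
panel_genes <- function(panel) {
  stopifnot(inherits(panel, "amplicon_panel"))
  unique(panel$gene)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("Amplicon panel: %d amplicons, %d genes, %d CNV sites\n",
              nrow(x), length(unique(x$gene)), length(unique(x$site_id))))
  NextMethod()
}
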