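# Coverage matrices: amplicon x sample integer read counts with a QC mask,
# built from aligned reads or from TSV, written back losslessly.

#' Construct a coverage matrix
#'
#' @param panel An [amplicon_panel()].
#' @param counts Integer matrix, amplicons (rows, named by amplicon id) by
#'   samples (columns, named by sample id); all counts >= 0.
#' @param qc_mask Logical matrix of the same shape (`TRUE` = cell usable);
#'   defaults to all `TRUE`.
#' @param homdel Logical matrix of the same shape flagging cells called as
#'   homozygous deletions by QC; defaults to all `FALSE`.
#' @return Object of class `coverage_matrix`: list with `panel`, `samples`,
#'   `counts`, `qc_mask`, `homdel`.
#' @export
coverage_matrix <- function(panel, counts, qc_mask = NULL, homdel = NULL) {
  stopifnot(inherits(panel, "amplicon_panel"))
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- panel$id
  if (nrow(counts) != nrow(panel) || !identical(rownames(counts), panel$id)) {
    stop("counts rows must match the panel's amplicon ids (in panel order)")
  }
  if (is.null(colnames(counts))) {
    stop("counts must have sample ids as column names")
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(qc_mask)) {
    qc_mask <- matrix(TRUE, nrow(counts), ncol(counts),
                      dimnames = dimnames(counts))
  }
  qc_mask <- as.matrix(qc_mask)
  if (!identical(dim(qc_mask), dim(counts))) {
    stop("qc_mask must have the same shape as counts")
  }
  dimnames(qc_mask) <- dimnames(counts)
  if (is.null(homdel)) {
    homdel <- matrix(FALSE, nrow(counts), ncol(counts),
                     dimnames = dimnames(counts))
  }
  homdel <- as.matrix(homdel)
  if (!identical(dim(homdel), dim(counts))) {
    stop("homdel must have the same shape as counts")
  }
  dimnames(homdel) <- dimnames(counts)
  structure(list(panel = panel, samples = colnames(counts),
                 counts = counts, qc_mask = qc_mask, homdel = homdel),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf(
    "Coverage matrix: %d amplicons x %d samples (%.1f%% cells QC-passed)\n",
    nrow(x$counts), ncol(x$counts), 100 * mean(x$qc_mask)))
  invisible(x)
}

#' Read a coverage TSV
#'
#' Tab-separated, amplicons as rows (first column = amplicon id), samples as
#' columns (header row = sample ids). Amplicon ids must match the panel
#' exactly (any order; rows are reordered to panel order).
#'
#' @param path Path to the TSV.
#' @param panel An [amplicon_panel()].
#' @return A [coverage_matrix()].
#' @export
load_coverage_tsv <- function(path, panel) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("coverage TSV needs an id column and >= 1 sample")
  ids <- as.character(df[[1]])
  unknown <- setdiff(ids, panel$id)
  if (length(unknown)) {
    stop("unknown amplicon id(s) in coverage TSV: ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(panel$id, ids)
  if (length(missing)) {
    stop("coverage TSV is missing amplicon id(s): ",
         paste(missing, collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m != round(m))) {
    bad <- which(!is.finite(m) | m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer coverage at amplicon '%s', sample '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative coverage at amplicon '%s', sample '%s'",
                 ids[bad[1]], colnames(m)[bad[2]]))
  }
  rownames(m) <- ids
  m <- m[panel$id, , drop = FALSE]
  coverage_matrix(panel, m)
}

#' Write a coverage TSV
#'
#' @param matrix A [coverage_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coverage_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "coverage_matrix"))
  df <- data.frame(amplicon_id = rownames(matrix$counts),
                   matrix$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Reference-space width of a CIGAR string (M/D/N/=/X consume reference).
.cigar_ref_width <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(tokens) {
    op <- substring(tokens, nchar(tokens))
    len <- as.integer(substring(tokens, 1, nchar(tokens) - 1))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

# Assign each read span to the amplicon with maximal overlap (ties to the
# leftmost amplicon). Spans and amplicons are 0-based half-open.
.assign_reads <- function(read_start, read_end, amp_start, amp_end) {
  n_amp <- length(amp_start)
  assigned <- integer(length(read_start))
  for (r in seq_along(read_start)) {
    ov <- pmin(read_end[r], amp_end) - pmax(read_start[r], amp_start)
    best <- max(ov)
    assigned[r] <- if (best > 0) which.max(ov == best) else NA_integer_
  }
  assigned
}

#' Count reads per amplicon from alignments
#'
#' Counts primary, mapped, non-duplicate reads per amplicon and sample. Each
#' read is assigned to the single amplicon whose interval has the largest
#' overlap with the read's aligned reference span; ties go to the leftmost
#' amplicon. Secondary, supplementary and duplicate alignments are skipped;
#' strand is ignored (amplicons are double-stranded PCR products). SAM
#' 1-based positions are converted to the panel's 0-based half-open system.
#'
#' SAM inputs are converted to sorted, indexed BAM on the fly.
#'
#' @param panel An [amplicon_panel()].
#' @param alignments Named character vector or list of SAM/BAM paths, one per
#'   sample; names are the sample ids.
#' @return A [coverage_matrix()].
#' @export
count_reads <- function(panel, alignments) {
  stopifnot(inherits(panel, "amplicon_panel"))
  paths <- unlist(alignments)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("alignments must be named by sample id")
  }
  counts <- matrix(0L, nrow(panel), length(paths),
                   dimnames = list(panel$id, names(paths)))
  for (s in seq_along(paths)) {
    path <- paths[s]
    if (!file.exists(path)) stop("alignment file not found: ", path)
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = TRUE)
    } else {
      bam <- path
      if (!file.exists(paste0(bam, ".bai")) &&
          !file.exists(sub("\\.bam$", ".bai", bam))) {
        stop("missing index for BAM: ", bam)
      }
    }
    header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    absent <- setdiff(unique(panel$chrom), names(header))
    if (length(absent)) {
      stop("panel contig(s) absent from alignment header of '", path,
           "': ", paste(absent, collapse = ", "))
    }
    flags <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE)
    param <- Rsamtools::ScanBamParam(
      flag = flags, what = c("rname", "pos", "cigar"))
    rec <- Rsamtools::scanBam(bam, param = param)[[1]]
    keep <- !is.na(rec$pos) & !is.na(rec$cigar)
    if (!any(keep)) next
    rname <- as.character(rec$rname)[keep]
    start0 <- rec$pos[keep] - 1L  # SAM is 1-based
    end0 <- start0 + .cigar_ref_width(rec$cigar[keep])
    for (chrom in unique(panel$chrom)) {
      amp_idx <- which(panel$chrom == chrom)
      on_chrom <- which(rname == chrom)
      if (!length(on_chrom) || !length(amp_idx)) next
      assigned <- .assign_reads(start0[on_chrom], end0[on_chrom],
                                panel$start[amp_idx], panel$end[amp_idx])
      tab <- table(factor(assigned, levels = seq_along(amp_idx)))
      counts[amp_idx, s] <- counts[amp_idx, s] + as.integer(tab)
    }
  }
  coverage_matrix(panel, counts)
}
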