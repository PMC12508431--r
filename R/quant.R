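## Signal quantification over enhancer loci: overlap counting, rpk, the
## low-signal exclusion rules (30 rpk ChIP / 10 rpk eRNA), condition fold
## changes, and tornado-style binned signal matrices.
##
## A SignalTable is an S3 object:
##   values        |loci| x |samples| matrix of rpk
##   assay         "chip" or "rna"
##   normalization "spike", "depth" or "none"
##   threshold     low-signal rpk threshold once filtering has been applied
##   excluded      locus ids removed by the filter

.default_rpk_threshold <- c(chip = 30, rna = 10)

#' Count target-genome reads overlapping each locus
#'
#' A read is counted for a locus when the two half-open intervals share at
#' least one base (strand-agnostic); half-open abutment does not count.
#'
#' @param reads a `ReadSet` (only target-genome reads are counted) or a
#'   `GRanges` of reads.
#' @param loci `GRanges` of enhancer loci.
#' @return Integer vector of counts, one per locus.
#' @export
count_reads_in_loci <- function(reads, loci) {
  gr <- if (inherits(reads, "ReadSet")) .target_reads(reads) else reads
  GenomicRanges::countOverlaps(loci, gr, ignore.strand = TRUE)
}

#' Reads per kilobase
#'
#' @param count overlapping read count.
#' @param locus_width locus width in bases (must be > 0).
#' @return `count / (locus_width / 1000)`.
#' @export
rpk <- function(count, locus_width) {
  if (any(locus_width <= 0)) .stopf("locus_width must be > 0")
  count / (locus_width / 1000)
}

#' Build a locus x sample rpk signal table
#'
#' When `norm` is supplied, each sample is first downsampled by its
#' normalization fraction (see [compute_norm_factors()]); values are then
#' `rpk(overlapping reads, locus width)` per locus and sample.
#'
#' @param samples list of `ReadSet` objects with unique sample ids.
#' @param loci `GRanges` of enhancer loci.
#' @param norm optional `data.frame` from [compute_norm_factors()].
#' @param assay `"chip"` or `"rna"`; controls the default low-signal
#'   threshold used downstream.
#' @param seed RNG seed for normalization downsampling.
#' @return A `SignalTable`.
#' @export
build_signal_table <- function(samples, loci, norm = NULL,
                               assay = c("chip", "rna"), seed = 1) {
  assay <- match.arg(assay)
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) {
    .stopf("duplicate sample id: '%s'", ids[duplicated(ids)][1])
  }
  if (!is.null(norm)) samples <- apply_norm_factors(samples, norm, seed = seed)
  w <- GenomicRanges::width(loci)
  values <- vapply(samples, function(rs) {
    rpk(count_reads_in_loci(rs, loci), w)
  }, numeric(length(loci)))
  values <- matrix(values, nrow = length(loci), ncol = length(samples),
                   dimnames = list(loci$locus_id, ids))
  structure(list(values = values, assay = assay,
                 normalization = if (is.null(norm)) "none" else norm$mode[1],
                 threshold = NA_real_, excluded = character()),
            class = "SignalTable")
}

#' @export
print.SignalTable <- function(x, ...) {
  cat(sprintf("SignalTable (%s): %d loci x %d samples, normalization=%s%s\n",
              x$assay, nrow(x$values), ncol(x$values), x$normalization,
              if (is.na(x$threshold)) ""
              else sprintf(", filtered at %g rpk (%d excluded)",
                           x$threshold, length(x$excluded))))
  invisible(x)
}

.check_samples_present <- function(table, ids) {
  miss <- setdiff(ids, colnames(table$values))
  if (length(miss)) .stopf("unknown sample id: '%s'", miss[1])
  invisible(TRUE)
}

#' Exclude loci with low signal in both compared samples
#'
#' A locus is retained iff its rpk in the control OR the treatment sample is
#' at or above the threshold; loci below threshold in both are excluded.
#' Retained loci keep their raw (unthresholded) values. Default thresholds:
#' 30 rpk for ChIP, 10 rpk for eRNA (lower because of the low signal
#' expectation of enhancer transcription).
#'
#' @param table a `SignalTable`.
#' @param control,treatment sample ids to compare.
#' @param threshold rpk threshold; defaults by assay (30 chip / 10 rna).
#' @return A filtered `SignalTable`; excluded locus ids are recorded in
#'   `$excluded` and the threshold in `$threshold`.
#' @export
filter_low_signal <- function(table, control, treatment, threshold = NULL) {
  stopifnot(inherits(table, "SignalTable"))
  .check_samples_present(table, c(control, treatment))
  if (is.null(threshold)) threshold <- .default_rpk_threshold[[table$assay]]
  keep <- table$values[, control] >= threshold |
    table$values[, treatment] >= threshold
  out <- table
  out$values <- table$values[keep, , drop = FALSE]
  out$threshold <- threshold
  out$excluded <- rownames(table$values)[!keep]
  out
}

#' Per-locus log2 fold change between two samples
#'
#' `log2fc = log2((rpk_treatment + pc) / (rpk_control + pc))` with
#' pseudocount `pc`. Loci failing the low-signal filter are reported with
#' `passed_filter = FALSE` and no fold change. If `table` has already been
#' filtered its recorded threshold is reused; otherwise the assay default
#' applies.
#'
#' @param table a `SignalTable`.
#' @param control,treatment sample ids.
#' @param pseudocount rpk pseudocount (default 1.0; must be >= 0).
#' @param threshold optional rpk threshold override.
#' @return `data.frame` with columns `locus_id`, `rpk_control`,
#'   `rpk_treatment`, `log2fc`, `passed_filter`.
#' @export
fold_change <- function(table, control, treatment, pseudocount = 1,
                        threshold = NULL) {
  stopifnot(inherits(table, "SignalTable"))
  .check_samples_present(table, c(control, treatment))
  if (pseudocount < 0) .stopf("pseudocount must be non-negative")
  if (is.null(threshold)) {
    threshold <- if (!is.na(table$threshold)) table$threshold
    else .default_rpk_threshold[[table$assay]]
  }
  ctrl <- table$values[, control]
  trt <- table$values[, treatment]
  passed <- ctrl >= threshold | trt >= threshold
  lfc <- ifelse(passed,
                log2((trt + pseudocount) / (ctrl + pseudocount)),
                NA_real_)
  data.frame(locus_id = rownames(table$values),
             rpk_control = unname(ctrl), rpk_treatment = unname(trt),
             log2fc = unname(lfc), passed_filter = unname(passed),
             stringsAsFactors = FALSE)
}

#' Tornado-style binned signal matrix around locus anchors
#'
#' For each locus, a window of +/- `window` bases around the anchor is split
#' into bins of `bin` bases; each entry is the number of target reads
#' overlapping that bin, scaled to reads per 10 million by the sample's total
#' target read count. Bins extending past the chromosome start are clipped
#' and report 0.
#'
#' @param reads a `ReadSet`.
#' @param loci `GRanges` of enhancer loci (anchors define window centers).
#' @param window half-window width in bases (default 3000).
#' @param bin bin width in bases (default 50); `2 * window` must be divisible
#'   by `bin`.
#' @return Numeric matrix (loci x bins) with locus ids as row names; bin
#'   columns are labelled by their 0-based offset from the anchor.
#' @export
signal_matrix <- function(reads, loci, window = 3000, bin = 50) {
  stopifnot(inherits(reads, "ReadSet"))
  if ((2 * window) %% bin != 0) .stopf("2 * window must be divisible by bin")
  target <- .target_reads(reads)
  total <- length(target)
  k <- as.integer(2 * window / bin)
  offsets <- seq(-window, window - bin, by = bin)
  anchor <- rep(loci$anchor, each = k)
  chrom <- rep(.chr(loci), each = k)
  bs <- anchor + rep(offsets, times = length(loci))      # 0-based bin start
  be <- bs + bin
  valid <- be > 0
  bs <- pmax(bs, 0)
  counts <- numeric(length(bs))
  if (any(valid) && total > 0) {
    bins_gr <- GenomicRanges::GRanges(chrom[valid],
                                      IRanges::IRanges(bs[valid] + 1, be[valid]))
    counts[valid] <- GenomicRanges::countOverlaps(bins_gr, target,
                                                  ignore.strand = TRUE)
  }
  m <- matrix(if (total > 0) per_10M_scale(counts, total) else counts,
              nrow = length(loci), ncol = k, byrow = TRUE,
              dimnames = list(loci$locus_id, as.character(offsets)))
  m
}

#' Write a SignalTable as headered TSV
#' @param table a `SignalTable`.
#' @param path output path.
#' @param header extra named character vector of comment-header fields.
#' @export
write_signal_table <- function(table, path, header = character()) {
  meta <- c(assay = table$assay, normalization = table$normalization,
            threshold = if (is.na(table$threshold)) "none"
            else format(table$threshold), header)
  df <- data.frame(locus_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path, meta)
}
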