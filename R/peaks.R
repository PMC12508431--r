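## narrowPeak ingestion, enhancer-overlap fractions, and factor-vs-anchor
## peak intensity correlation.

#' Read an ENCODE narrowPeak file
#'
#' Requires the 10-column MACS2 narrowPeak layout. `"."` name/strand fields
#' and a `-1` summit offset map to `NA`.
#'
#' @param path narrowPeak file.
#' @return `GRanges` with metadata columns `name`, `score`, `signalValue`,
#'   `pValue`, `qValue` (both on the -log10 scale) and `summit_offset`.
#' @export
read_narrowpeak <- function(path) {
  parsed <- .read_bed_lines(path)
  nfield <- lengths(parsed$fields)
  if (any(nfield != 10)) {
    i <- which(nfield != 10)[1]
    .stopf("%s line %d: narrowPeak requires 10 columns, got %d",
           path, parsed$lineno[i], nfield[i])
  }
  .parse_bed_coords(parsed$fields, parsed$lineno, path)
  f <- function(j) vapply(parsed$fields, `[`, character(1), j)
  num <- function(j) as.numeric(f(j))
  chrom <- f(1); start <- num(2); end <- num(3)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  name <- f(4); name[name == "."] <- NA_character_
  strand <- f(6); strand[strand == "."] <- NA_character_
  summit <- num(10)
  if (any(!is.na(summit) & summit >= 0 & summit >= end - start)) {
    .stopf("%s: summit offset not smaller than peak width", path)
  }
  summit[summit < 0] <- NA_real_
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = name, score = num(5), peak_strand = strand,
    signalValue = num(7), pValue = num(8), qValue = num(9),
    summit_offset = summit)
  gr
}

#' Write peaks as a narrowPeak file
#' @param peaks `GRanges` as returned by [read_narrowpeak()].
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(
    chrom = .chr(peaks),
    start = GenomicRanges::start(peaks) - 1,
    end = GenomicRanges::end(peaks),
    name = ifelse(is.na(peaks$name), ".", peaks$name),
    score = peaks$score,
    strand = ifelse(is.na(peaks$peak_strand), ".", peaks$peak_strand),
    signalValue = peaks$signalValue,
    pValue = peaks$pValue,
    qValue = peaks$qValue,
    summit = ifelse(is.na(peaks$summit_offset), -1, peaks$summit_offset)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fraction of enhancer loci overlapped by a peak set
#'
#' A locus counts as overlapped when at least one peak shares at least one
#' base with its (half-open) interval.
#'
#' @param loci `GRanges` of enhancer loci.
#' @param peaks `GRanges` of peaks (e.g. from [read_narrowpeak()]).
#' @param factor label for the peak set (antibody/factor name).
#' @return List with `summary` (`data.frame`: `factor`, `n_enhancers`,
#'   `n_overlapped`, `fraction`) and `overlapped` (named logical per locus).
#' @export
overlap_fraction <- function(loci, peaks, factor = "peaks") {
  hit <- IRanges::overlapsAny(loci, peaks, ignore.strand = TRUE)
  names(hit) <- loci$locus_id
  n <- length(loci)
  list(summary = data.frame(factor = factor, n_enhancers = n,
                            n_overlapped = sum(hit),
                            fraction = if (n > 0) sum(hit) / n else NA_real_,
                            stringsAsFactors = FALSE),
       overlapped = hit)
}

#' Squared Pearson correlation of per-locus intensities for two factors
#'
#' Correlates the rpk columns of two samples in a `SignalTable`, optionally
#' after a `log2(x + 1)` transform (default, since raw ChIP intensities are
#' heavy-tailed), and returns the squared Pearson correlation.
#'
#' @param table a `SignalTable` whose columns include both factors.
#' @param factor_a,factor_b sample ids to correlate.
#' @param log_transform apply `log2(x + 1)` before correlating (default TRUE).
#' @return List with `r_squared`, `n`, `log_transform`, and `pairs`
#'   (`data.frame` of the per-locus transformed value pairs).
#' @export
intensity_correlation <- function(table, factor_a, factor_b,
                                  log_transform = TRUE) {
  stopifnot(inherits(table, "SignalTable"))
  .check_samples_present(table, c(factor_a, factor_b))
  x <- table$values[, factor_a]
  y <- table$values[, factor_b]
  if (length(x) < 3) .stopf("need at least 3 loci for correlation")
  if (log_transform) {
    x <- log2(x + 1)
    y <- log2(y + 1)
  }
  r2 <- pearson_r2(x, y)
  list(r_squared = r2, n = length(x), log_transform = log_transform,
       pairs = data.frame(locus_id = rownames(table$values),
                          a = unname(x), b = unname(y),
                          stringsAsFactors = FALSE))
}

#' Write per-locus overlap flags as BED6+1
#' @param loci `GRanges` of enhancer loci.
#' @param overlapped named logical vector from [overlap_fraction()].
#' @param path output path.
#' @export
write_overlap_flags <- function(loci, overlapped, path) {
  df <- data.frame(
    chrom = .chr(loci),
    start = GenomicRanges::start(loci) - 1,
    end = GenomicRanges::end(loci),
    name = loci$locus_id,
    score = 0L,
    strand = ".",
    overlapped = as.integer(overlapped[loci$locus_id])
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
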