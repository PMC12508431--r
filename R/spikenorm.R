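## Exogenous spike-in (ChIP-Rx) normalization: per-sample target/spike read
## counting, normalization factors, and seeded Bernoulli read downsampling.
##
## A ReadSet is an S3 object: list(sample_id, reads) where reads is a GRanges
## with a 'genome' metadata column ("target" or "spike") and an optional
## 'read_name' column used to keep paired-end mates together.

#' Construct a ReadSet from read intervals
#'
#' @param sample_id sample identifier.
#' @param chrom chromosome names of the reads.
#' @param start,end 0-based half-open read coordinates.
#' @param spike_prefix chromosome-name prefix identifying the spike-in
#'   (exogenous reference) genome; default `"dm6_"`.
#' @param genome optional explicit per-read tag, `"target"` or `"spike"`;
#'   overrides prefix matching.
#' @param read_name optional read names (mate pairing key for downsampling).
#' @return An object of class `ReadSet`.
#' @export
read_set <- function(sample_id, chrom, start, end, spike_prefix = "dm6_",
                     genome = NULL, read_name = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0 | start >= end)) .stopf("invalid read interval")
  if (is.null(genome)) {
    genome <- ifelse(startsWith(chrom, spike_prefix), "spike", "target")
  } else {
    genome <- as.character(genome)
    if (!all(genome %in% c("target", "spike"))) {
      .stopf("genome tags must be 'target' or 'spike'")
    }
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  gr$genome <- genome
  if (!is.null(read_name)) gr$read_name <- as.character(read_name)
  structure(list(sample_id = as.character(sample_id), reads = gr),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  n <- count_by_genome(x)
  cat(sprintf("ReadSet '%s': %d target reads, %d spike reads\n",
              x$sample_id, n[["target"]], n[["spike"]]))
  invisible(x)
}

.target_reads <- function(rs) rs$reads[rs$reads$genome == "target"]
.spike_reads <- function(rs) rs$reads[rs$reads$genome == "spike"]

#' Read a simplified reads-as-BED file into a ReadSet
#'
#' One read per line, columns chrom/start/end (0-based half-open); an
#' optional fourth column carries the read name.
#'
#' @inheritParams read_set
#' @param path BED3(+1) file of read intervals.
#' @return A `ReadSet`.
#' @export
read_reads_bed <- function(path, sample_id, spike_prefix = "dm6_") {
  parsed <- .read_bed_lines(path)
  .parse_bed_coords(parsed$fields, parsed$lineno, path)
  chrom <- vapply(parsed$fields, `[`, character(1), 1L)
  start <- as.numeric(vapply(parsed$fields, `[`, character(1), 2L))
  end <- as.numeric(vapply(parsed$fields, `[`, character(1), 3L))
  name <- vapply(parsed$fields, function(f)
    if (length(f) >= 4) f[4] else NA_character_, character(1))
  read_set(sample_id, chrom, start, end, spike_prefix = spike_prefix,
           read_name = if (all(is.na(name))) NULL else name)
}

## CIGAR reference-consumed length (M/D/N/=/X ops)
.cigar_ref_len <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.numeric(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read mapped primary alignments from a SAM text file into a ReadSet
#'
#' Unmapped (0x4), secondary (0x100), supplementary (0x800) and duplicate
#' (0x400) records are skipped; an optional MAPQ filter is applied. The read
#' interval is the CIGAR reference span from POS. Read names are retained so
#' paired-end mates are kept or dropped together during downsampling.
#'
#' @param path SAM file (text).
#' @param sample_id sample identifier.
#' @param spike_prefix chromosome prefix identifying spike-in reads.
#' @param mapq_min minimum MAPQ (default 0 = keep all mapped).
#' @return A `ReadSet`.
#' @export
read_reads_sam <- function(path, sample_id, spike_prefix = "dm6_",
                           mapq_min = 0) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) .stopf("no alignment records in %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 11
  if (any(short)) .stopf("%s: malformed SAM record (fewer than 11 fields)", path)
  qname <- vapply(fields, `[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[`, character(1), 2L))
  rname <- vapply(fields, `[`, character(1), 3L)
  pos <- as.numeric(vapply(fields, `[`, character(1), 4L))
  mapq <- as.integer(vapply(fields, `[`, character(1), 5L))
  cigar <- vapply(fields, `[`, character(1), 6L)
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x400L) == 0L & bitwAnd(flag, 0x800L) == 0L &
    rname != "*" & mapq >= mapq_min
  if (!any(keep)) .stopf("no usable alignments in %s", path)
  len <- .cigar_ref_len(cigar[keep])
  len[len == 0] <- 1
  read_set(sample_id, rname[keep], pos[keep] - 1, pos[keep] - 1 + len,
           spike_prefix = spike_prefix, read_name = qname[keep])
}

#' Count target-genome and spike-in reads in a ReadSet
#'
#' @param readset a `ReadSet`.
#' @return Named numeric vector `c(target = H, spike = S)`;
#'   `H + S` equals the total read count.
#' @export
count_by_genome <- function(readset) {
  stopifnot(inherits(readset, "ReadSet"))
  g <- readset$reads$genome
  c(target = sum(g == "target"), spike = sum(g == "spike"))
}

#' Compute spike-in (or depth) normalization factors
#'
#' In `"spike"` mode the downsampling fraction is `f_s = min(S) / S_s`, which
#' equalizes the per-spike-read scale across samples while only ever removing
#' reads (one sample keeps `f = 1`). In `"depth"` mode `f_s = min(H) / H_s`.
#' The per-million-spike scale `gamma_s = 1e6 / S_s` is always reported.
#'
#' @param samples list of `ReadSet` objects (a comparison group; >= 2).
#' @param mode `"spike"` (exogenous reference) or `"depth"` (read depth).
#' @return `data.frame` with columns `sample`, `H`, `S`, `gamma`, `f`, `mode`.
#' @export
compute_norm_factors <- function(samples, mode = c("spike", "depth")) {
  mode <- match.arg(mode)
  stopifnot(is.list(samples), length(samples) >= 2,
            all(vapply(samples, inherits, logical(1), "ReadSet")))
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) .stopf("duplicate sample id: '%s'",
                                 ids[duplicated(ids)][1])
  counts <- t(vapply(samples, count_by_genome, numeric(2)))
  H <- counts[, "target"]
  S <- counts[, "spike"]
  if (mode == "spike" && any(S == 0)) {
    .stopf("sample '%s' has zero spike-in reads; spike normalization undefined",
           ids[S == 0][1])
  }
  if (mode == "depth" && any(H == 0)) {
    .stopf("sample '%s' has zero target reads; depth normalization undefined",
           ids[H == 0][1])
  }
  f <- if (mode == "spike") min(S) / S else min(H) / H
  gamma <- ifelse(S > 0, 1e6 / S, NA_real_)
  data.frame(sample = ids, H = unname(H), S = unname(S),
             gamma = unname(gamma), f = unname(f), mode = mode,
             stringsAsFactors = FALSE)
}

#' Downsample target-genome reads of a ReadSet
#'
#' Each target read is independently retained with probability `fraction`
#' (seeded Bernoulli); when read names are present, records sharing a name
#' (paired-end mates) are kept or dropped together. Spike-in reads are
#' bookkeeping, not signal, and are retained unchanged. Output is
#' bit-reproducible for a fixed `(readset, fraction, seed)`.
#'
#' @param readset a `ReadSet`.
#' @param fraction retention probability in `[0, 1]`.
#' @param seed RNG seed (integer).
#' @return The downsampled `ReadSet`.
#' @export
downsample_reads <- function(readset, fraction, seed = 1) {
  stopifnot(inherits(readset, "ReadSet"))
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    .stopf("fraction must be a single value in [0, 1]")
  }
  is_target <- readset$reads$genome == "target"
  if (fraction == 1 || !any(is_target)) return(readset)
  target <- readset$reads[is_target]
  keep <- .with_seed(seed, function() {
    if (!is.null(target$read_name)) {
      nm <- target$read_name
      u <- unique(nm)
      kept_names <- u[runif(length(u)) < fraction]
      nm %in% kept_names
    } else {
      runif(length(target)) < fraction
    }
  })
  out <- readset
  out$reads <- c(target[keep], .spike_reads(readset))
  out
}

#' Apply normalization factors to a list of ReadSets by downsampling
#'
#' @param samples list of `ReadSet` objects.
#' @param norm `data.frame` from [compute_norm_factors()].
#' @param seed base RNG seed; sample `i` uses `seed + i - 1`.
#' @return List of downsampled `ReadSet` objects, in input order.
#' @export
apply_norm_factors <- function(samples, norm, seed = 1) {
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  miss <- setdiff(ids, norm$sample)
  if (length(miss)) .stopf("no normalization factor for sample '%s'", miss[1])
  f <- norm$f[match(ids, norm$sample)]
  lapply(seq_along(samples), function(i) {
    downsample_reads(samples[[i]], f[i], seed = seed + i - 1)
  })
}

#' Scale a count to reads per 10 million
#'
#' @param count read count.
#' @param total_reads library size (must be > 0).
#' @return `count * 1e7 / total_reads`.
#' @export
per_10M_scale <- function(count, total_reads) {
  if (any(total_reads <= 0)) .stopf("total_reads must be > 0")
  count * 1e7 / total_reads
}

#' Write normalization factors as TSV
#' @param norm `data.frame` from [compute_norm_factors()].
#' @param path output path.
#' @param header optional named character vector of comment-header fields.
#' @export
write_norm_factors <- function(norm, path, header = character()) {
  .write_tsv(norm, path, header)
}
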