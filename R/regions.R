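## Enhancer locus ingestion, minimum-width extension, and nearest-TSS linkage.
##
## Loci are held as a GRanges with metadata columns:
##   locus_id      unique identifier (BED column 4 or "chrom:start-end")
##   anchor        0-based position of the functional center (binding-site
##                 summit); defaults to the interval midpoint
##   linked_gene   gene assigned by nearest-TSS linkage (NA until linked)
##   link_distance |TSS - anchor| for the linked gene (NA until linked)
##
## All user-facing coordinates are 0-based half-open (BED convention); the
## GRanges holds the equivalent 1-based closed interval, so half-open
## abutment maps exactly onto countOverlaps() semantics.

#' Construct a set of enhancer loci
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open coordinates.
#' @param id unique locus identifiers; defaults to `"chrom:start-end"`.
#' @param anchor 0-based anchor positions (e.g. the anchoring factor's peak
#'   summit). Defaults to the interval midpoint `floor((start + end) / 2)`.
#'   Must satisfy `start <= anchor < end`.
#' @param chrom_sizes optional named integer vector of chromosome lengths;
#'   when supplied, intervals beyond the chromosome end are an error.
#' @return A `GRanges` with metadata columns `locus_id`, `anchor`,
#'   `linked_gene`, `link_distance`.
#' @export
enhancer_loci <- function(chrom, start, end, id = NULL, anchor = NULL,
                          chrom_sizes = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n) {
    .stopf("chrom, start, end must have equal length")
  }
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | start >= end)
  if (length(bad)) {
    .stopf("invalid interval at position %d: [%s, %s)",
           bad[1], format(start[bad[1]]), format(end[bad[1]]))
  }
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, start, end)
  id <- as.character(id)
  if (anyDuplicated(id)) {
    .stopf("duplicate locus id: '%s'", id[duplicated(id)][1])
  }
  if (is.null(anchor)) anchor <- floor((start + end) / 2)
  anchor <- as.numeric(anchor)
  bad <- which(anchor < start | anchor >= end)
  if (length(bad)) {
    .stopf("anchor outside interval for locus '%s'", id[bad[1]])
  }
  if (!is.null(chrom_sizes)) {
    .check_within_chrom(chrom, end, chrom_sizes, id)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_id = id,
    anchor = anchor,
    linked_gene = NA_character_,
    link_distance = rep(NA_real_, n)
  )
  gr
}

.check_within_chrom <- function(chrom, end, chrom_sizes, id) {
  known <- chrom %in% names(chrom_sizes)
  if (!all(known)) {
    .stopf("chromosome '%s' absent from chrom_sizes", chrom[!known][1])
  }
  over <- end > unname(chrom_sizes[chrom])
  if (any(over)) {
    .stopf("locus '%s' extends beyond the end of %s",
           id[over][1], chrom[over][1])
  }
  invisible(TRUE)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with columns chromosome name and length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) .stopf("chrom.sizes file needs two columns: %s", path)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Write chromosome sizes as a two-column TSV
#' @param chrom_sizes named numeric vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## split a BED-like text file into fields, skipping track/browser/# lines;
## returns list(fields = list of character vectors, lineno = original line no)
.read_bed_lines <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(lines)
  lines <- lines[!skip]
  lineno <- lineno[!skip]
  list(fields = strsplit(lines, "\t", fixed = TRUE), lineno = lineno)
}

.parse_bed_coords <- function(fields, lineno, path, min_fields = 3L) {
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < min_fields) {
      .stopf("%s line %d: expected >= %d tab-separated fields, got %d",
             path, lineno[i], min_fields, length(f))
    }
    if (!.is_int_string(f[2]) || !.is_int_string(f[3])) {
      .stopf("%s line %d: non-integer coordinates '%s', '%s'",
             path, lineno[i], f[2], f[3])
    }
    if (as.numeric(f[2]) >= as.numeric(f[3]) || as.numeric(f[2]) < 0) {
      .stopf("%s line %d: invalid interval [%s, %s)",
             path, lineno[i], f[2], f[3])
    }
  }
  invisible(TRUE)
}

#' Read enhancer loci from a BED3/BED4/BED6 file
#'
#' Track and browser lines are skipped. Column 4, when present and not ".",
#' becomes the locus id; otherwise ids default to `"chrom:start-end"`. The
#' anchor defaults to the interval midpoint. Input order is preserved.
#'
#' @param path BED file (tab-separated, no header).
#' @param chrom_sizes optional named vector of chromosome lengths used to
#'   validate intervals.
#' @return A `GRanges` of enhancer loci (see [enhancer_loci()]).
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  parsed <- .read_bed_lines(path)
  .parse_bed_coords(parsed$fields, parsed$lineno, path)
  chrom <- vapply(parsed$fields, `[`, character(1), 1L)
  start <- as.numeric(vapply(parsed$fields, `[`, character(1), 2L))
  end <- as.numeric(vapply(parsed$fields, `[`, character(1), 3L))
  name <- vapply(parsed$fields, function(f) {
    if (length(f) >= 4 && nzchar(f[4]) && f[4] != ".") f[4] else NA_character_
  }, character(1))
  id <- ifelse(is.na(name), sprintf("%s:%d-%d", chrom, start, end), name)
  enhancer_loci(chrom, start, end, id = id, chrom_sizes = chrom_sizes)
}

#' Extend loci to a minimum width
#'
#' Loci narrower than `min_width` are padded: `floor(deficit / 2)` bases on
#' the left and `ceiling(deficit / 2)` on the right, so the anchor stays
#' inside the interval. If clipping at position 0 or at the chromosome end
#' truncates one side, the lost bases are moved to the other side, so the
#' output width equals `min_width` exactly whenever the chromosome permits.
#' Loci already at least `min_width` wide are returned unchanged; anchors are
#' never moved.
#'
#' @param loci `GRanges` from [enhancer_loci()] / [read_bed()].
#' @param min_width minimum locus width in bases (default 600).
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   right-edge clipping; a chromosome shorter than `min_width` is an error.
#' @return `GRanges` with every width `>= min_width`.
#' @export
extend_to_min_width <- function(loci, min_width = 600, chrom_sizes = NULL) {
  if (!.is_count(min_width) || min_width <= 0) {
    .stopf("min_width must be a positive integer")
  }
  s <- GenomicRanges::start(loci) - 1   # 0-based
  e <- GenomicRanges::end(loci)
  w <- e - s
  deficit <- pmax(min_width - w, 0)
  short <- deficit > 0
  if (!any(short)) return(loci)

  chrom <- .chr(loci)
  if (!is.null(chrom_sizes)) {
    len <- unname(chrom_sizes[chrom])
    if (anyNA(len[short])) {
      .stopf("chromosome '%s' absent from chrom_sizes",
             chrom[short][is.na(len[short])][1])
    }
    too_short <- short & len < min_width
    if (any(too_short)) {
      .stopf("chromosome %s (length %d) is shorter than min_width %d (locus '%s')",
             chrom[too_short][1], len[too_short][1], min_width,
             loci$locus_id[too_short][1])
    }
  }

  ns <- ifelse(short, s - floor(deficit / 2), s)
  ne <- ifelse(short, e + ceiling(deficit / 2), e)
  ## left clip: move lost bases to the right
  clip <- pmax(0 - ns, 0)
  ns <- ns + clip
  ne <- ne + clip
  ## right clip against chromosome end: move lost bases back to the left
  if (!is.null(chrom_sizes)) {
    len <- unname(chrom_sizes[chrom])
    clip <- ifelse(short, pmax(ne - len, 0), 0)
    ne <- ne - clip
    ns <- pmax(ns - clip, 0)
  }
  out <- loci
  GenomicRanges::ranges(out) <- IRanges::IRanges(ns + 1, ne)
  out
}

#' Read a TSS annotation from a BED6 file
#'
#' The transcription start site is `start` for `+` strand records and
#' `end - 1` for `-` strand records (0-based). Column 4 is the gene id.
#'
#' @param path BED6 file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  parsed <- .read_bed_lines(path)
  .parse_bed_coords(parsed$fields, parsed$lineno, path, min_fields = 6L)
  chrom <- vapply(parsed$fields, `[`, character(1), 1L)
  start <- as.numeric(vapply(parsed$fields, `[`, character(1), 2L))
  end <- as.numeric(vapply(parsed$fields, `[`, character(1), 3L))
  gene <- vapply(parsed$fields, `[`, character(1), 4L)
  strand <- vapply(parsed$fields, `[`, character(1), 6L)
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    .stopf("%s line %d: strand must be '+' or '-', got '%s'",
           path, parsed$lineno[bad][1], strand[bad][1])
  }
  if (anyDuplicated(gene)) {
    .stopf("duplicate gene_id in TSS annotation: '%s'",
           gene[duplicated(gene)][1])
  }
  data.frame(gene_id = gene, chrom = chrom,
             tss = ifelse(strand == "+", start, end - 1),
             strand = strand, stringsAsFactors = FALSE)
}

#' Link each locus to the gene with the nearest TSS
#'
#' Distance is point-to-point between the locus anchor and the TSS, on the
#' same chromosome. Ties are broken by lexicographically smallest gene id.
#' Loci on chromosomes with no TSS are returned unlinked with a warning.
#'
#' @param loci `GRanges` of enhancer loci.
#' @param tss `data.frame` as returned by [read_tss_bed()] (columns
#'   `gene_id`, `chrom`, `tss`).
#' @return `loci` with `linked_gene` and `link_distance` filled in.
#' @export
link_to_nearest_tss <- function(loci, tss) {
  stopifnot(is.data.frame(tss),
            all(c("gene_id", "chrom", "tss") %in% names(tss)))
  chrom <- .chr(loci)
  anchor <- loci$anchor
  gene <- rep(NA_character_, length(loci))
  dist <- rep(NA_real_, length(loci))
  by_chrom <- split(tss[, c("gene_id", "tss")], tss$chrom)
  for (i in seq_along(loci)) {
    cand <- by_chrom[[chrom[i]]]
    if (is.null(cand) || nrow(cand) == 0) next
    d <- abs(cand$tss - anchor[i])
    best <- which(d == min(d))
    if (length(best) > 1) {
      best <- best[order(cand$gene_id[best])][1]  # tie: smallest gene id
    }
    gene[i] <- cand$gene_id[best]
    dist[i] <- d[best]
  }
  if (anyNA(gene)) {
    .warnf("%d locus/loci on chromosomes with no TSS left unlinked",
           sum(is.na(gene)))
  }
  out <- loci
  out$linked_gene <- gene
  out$link_distance <- dist
  out
}

#' Write loci as BED6+2 (id, score, strand, linked gene, distance)
#' @param loci `GRanges` of enhancer loci.
#' @param path output path.
#' @export
write_loci_bed <- function(loci, path) {
  df <- data.frame(
    chrom = .chr(loci),
    start = GenomicRanges::start(loci) - 1,
    end = GenomicRanges::end(loci),
    name = loci$locus_id,
    score = 0L,
    strand = ".",
    linked_gene = ifelse(is.na(loci$linked_gene), ".", loci$linked_gene),
    distance = ifelse(is.na(loci$link_distance), -1, loci$link_distance)
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
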