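## Degron-sensitivity classification: differential-expression tables are
## intersected with enhancer-gene links to call sensitive genes and their
## enhancers, plus exact set-overlap summaries.

#' Read a differential-expression table
#'
#' Headered TSV with configurable column names. Rows with missing adjusted p
#' are retained but can never be called significant.
#'
#' @param path TSV file.
#' @param gene_col,lfc_col,padj_col column names (defaults `gene`,
#'   `log2FoldChange`, `padj`).
#' @return `data.frame` with columns `gene`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path, gene_col = "gene",
                          lfc_col = "log2FoldChange", padj_col = "padj") {
  df <- .read_tsv(path, colClasses = "character")
  need <- c(gene_col, lfc_col, padj_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("%s: missing column '%s'", path, miss[1])
  gene <- df[[gene_col]]
  if (anyDuplicated(gene)) {
    .stopf("%s: duplicate gene id '%s'", path, gene[duplicated(gene)][1])
  }
  parse_num <- function(x, what) {
    x[x %in% c("NA", "")] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad)) {
      .stopf("%s line %d: unparseable %s '%s'", path, bad[1] + 1, what, x[bad[1]])
    }
    out
  }
  lfc <- parse_num(df[[lfc_col]], "log2 fold change")
  padj <- parse_num(df[[padj_col]], "adjusted p")
  if (any(padj < 0 | padj > 1, na.rm = TRUE)) {
    .stopf("%s: adjusted p outside [0, 1]", path)
  }
  data.frame(gene = gene, log2fc = lfc, padj = padj, stringsAsFactors = FALSE)
}

#' Call downregulated genes from a DE table
#'
#' Both thresholds are strict, matching the convention
#' log2FC < -0.5 and FDR < 0.05: a gene is called iff
#' `log2fc < lfc_max` AND `padj < fdr_max`. Missing `padj` never qualifies.
#'
#' @param de `data.frame` from [read_de_table()] (columns `gene`, `log2fc`,
#'   `padj`; a raw `log2FoldChange` column is also accepted).
#' @param lfc_max log2 fold-change threshold (default -0.5).
#' @param fdr_max adjusted-p threshold (default 0.05).
#' @return Character vector of downregulated gene ids.
#' @export
call_downregulated <- function(de, lfc_max = -0.5, fdr_max = 0.05) {
  stopifnot(is.finite(lfc_max), is.finite(fdr_max))
  lfc <- if (!is.null(de$log2fc)) de$log2fc else de$log2FoldChange
  if (is.null(lfc) || is.null(de$padj) || is.null(de$gene)) {
    .stopf("DE table needs columns gene, log2fc/log2FoldChange, padj")
  }
  hit <- !is.na(lfc) & lfc < lfc_max & !is.na(de$padj) & de$padj < fdr_max
  de$gene[hit]
}

#' Call sensitive genes and enhancers for one degron system
#'
#' Sensitive genes are the downregulated genes that are linked to at least
#' one enhancer; sensitive enhancers are every locus whose linked gene is
#' sensitive (a gene with multiple enhancers marks all of them). Unlinked
#' loci are skipped with a warning.
#'
#' @param loci `GRanges` of enhancer loci with `linked_gene` set
#'   (see [link_to_nearest_tss()]).
#' @param down_genes character vector of downregulated gene ids.
#' @param system label for the degron system.
#' @return An object of class `SensitivityCall`: list with `system`,
#'   `down_genes`, `sensitive_genes`, `sensitive_enhancers`.
#' @export
call_sensitive <- function(loci, down_genes, system = "degrader") {
  linked <- loci$linked_gene
  if (anyNA(linked)) {
    .warnf("%d unlinked locus/loci skipped in sensitivity call",
           sum(is.na(linked)))
  }
  down_genes <- unique(as.character(down_genes))
  sensitive_genes <- sort(intersect(down_genes, linked[!is.na(linked)]))
  sensitive_enh <- loci$locus_id[!is.na(linked) & linked %in% sensitive_genes]
  out <- structure(list(system = system,
                        down_genes = down_genes,
                        sensitive_genes = sensitive_genes,
                        sensitive_enhancers = sensitive_enh),
                   class = "SensitivityCall")
  ## containment invariants, asserted on every output
  stopifnot(all(out$sensitive_genes %in% out$down_genes),
            all(linked[match(out$sensitive_enhancers, loci$locus_id)] %in%
                  out$sensitive_genes))
  out
}

#' @export
print.SensitivityCall <- function(x, ...) {
  cat(sprintf("SensitivityCall '%s': %d downregulated genes, %d sensitive genes, %d sensitive enhancers\n",
              x$system, length(x$down_genes), length(x$sensitive_genes),
              length(x$sensitive_enhancers)))
  invisible(x)
}

#' Exact overlap between two id sets
#'
#' @param a,b character vectors (treated as sets).
#' @return List with `n_a`, `n_b`, `n_intersect`, `pct_a`, `pct_b`
#'   (percentages of each set covered by the intersection; percentages are
#'   not rounded).
#' @export
set_overlap <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  i <- length(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_intersect = i,
       pct_a = if (length(a)) 100 * i / length(a) else 0,
       pct_b = if (length(b)) 100 * i / length(b) else 0)
}

#' Write a SensitivityCall as two TSVs plus a JSON summary
#'
#' @param call a `SensitivityCall`.
#' @param loci the linked loci used for the call.
#' @param dir output directory (created if needed).
#' @param header named character vector of comment-header fields.
#' @return Paths of the written files, invisibly.
#' @export
write_sensitivity_call <- function(call, loci, dir, header = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes_path <- file.path(dir, sprintf("%s_sensitive_genes.tsv", call$system))
  enh_path <- file.path(dir, sprintf("%s_sensitive_enhancers.tsv", call$system))
  .write_tsv(data.frame(gene = call$sensitive_genes), genes_path, header)
  idx <- match(call$sensitive_enhancers, loci$locus_id)
  .write_tsv(data.frame(locus_id = call$sensitive_enhancers,
                        chrom = .chr(loci)[idx],
                        start = GenomicRanges::start(loci)[idx] - 1,
                        end = GenomicRanges::end(loci)[idx],
                        linked_gene = loci$linked_gene[idx]),
             enh_path, header)
  summary_path <- file.path(dir, sprintf("%s_summary.json", call$system))
  jsonlite::write_json(
    list(system = call$system,
         n_down_genes = length(call$down_genes),
         n_sensitive_genes = length(call$sensitive_genes),
         n_sensitive_enhancers = length(call$sensitive_enhancers)),
    summary_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(genes_path, enh_path, summary_path))
}
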