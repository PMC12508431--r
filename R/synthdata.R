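## Fully synthetic fixtures with known ground truth for every pipeline
## stage: annotation (loci, TSS, chrom sizes), spike-in-mixed read sets with
## planted enrichment and depletion at a sensitive subset, differential-
## expression tables, narrowPeak sets with planted coverage, and
## dose-response grids.
##
## The generator is deterministic per seed (R's default Mersenne-Twister via
## set.seed, integer-grid coordinates) and every planted quantity is
## recoverable by the corresponding pipeline stage.

#' Simulation configuration
#'
#' Defaults emulate a degron ChIP-Rx study design: spike-in chromatin mixed
#' at a 1:4 (spike : target cells) ratio so roughly 20 percent of reads map
#' to the exogenous genome, single-end 75 nt reads, strong enrichment at a
#' fixed enhancer set, and a sensitive subset whose enhancer signal is halved
#' in the treatment (degraded) condition and whose genes carry a planted
#' log2FC around -1.5 in the DE table.
#'
#' @param seed master RNG seed.
#' @param n_enhancers number of enhancer loci.
#' @param width_range min/max locus width in bases.
#' @param target_chrom,target_length the (single) target chromosome.
#' @param spike_chrom,spike_length the spike-in chromosome; its name must
#'   begin with `spike_prefix`.
#' @param spike_prefix chromosome-name prefix identifying spike-in reads.
#' @param background_density background read density, reads per kilobase.
#' @param enrichment ChIP enrichment factor at enhancer loci (extra reads at
#'   a locus have mean `density * enrichment * width`).
#' @param rna_enrichment eRNA enrichment factor at enhancer loci (lower:
#'   enhancer transcription is weak relative to ChIP signal).
#' @param sensitive_fraction fraction of loci planted as degron-sensitive.
#' @param depletion multiplier on enhancer signal at sensitive loci in the
#'   treatment condition (0.5 = halved).
#' @param mix_ratio spike : target cell mixing ratio (0.25 = 1:4).
#' @param depth_jitter per-sample relative jitter of overall yield/depth
#'   (target and spike scale together, as IP efficiency and sequencing depth
#'   do); spike read counts therefore jitter by about this fraction.
#' @param read_length read length in bases.
#' @param de_effect mean/sd of planted log2 fold change at sensitive genes.
#' @param de_null_sd sd of null-gene log2 fold change (mean 0).
#' @param peak_coverage named fractions of loci covered per simulated factor.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1,
                       n_enhancers = 200,
                       width_range = c(300, 900),
                       target_chrom = "chr1",
                       target_length = n_enhancers * 1e5,
                       spike_chrom = "dm6_chr2L",
                       spike_length = 2e6,
                       spike_prefix = "dm6_",
                       background_density = 2,
                       enrichment = 50,
                       rna_enrichment = 10,
                       sensitive_fraction = 0.15,
                       depletion = 0.5,
                       mix_ratio = 0.25,
                       depth_jitter = 0.2,
                       read_length = 75,
                       de_effect = c(mean = -1.5, sd = 0.3),
                       de_null_sd = 0.2,
                       peak_coverage = c(p300 = 0.86, CBP = 0.94,
                                         MLL4 = 0.25, UTX = 0.16)) {
  cfg <- list(seed = seed, n_enhancers = n_enhancers,
              width_range = width_range, target_chrom = target_chrom,
              target_length = target_length, spike_chrom = spike_chrom,
              spike_length = spike_length, spike_prefix = spike_prefix,
              background_density = background_density,
              enrichment = enrichment, rna_enrichment = rna_enrichment,
              sensitive_fraction = sensitive_fraction,
              depletion = depletion, mix_ratio = mix_ratio,
              depth_jitter = depth_jitter, read_length = read_length,
              de_effect = de_effect, de_null_sd = de_null_sd,
              peak_coverage = peak_coverage)
  stopifnot(n_enhancers >= 2, width_range[1] > 0,
            width_range[1] <= width_range[2],
            background_density > 0, enrichment > 0,
            sensitive_fraction >= 0, sensitive_fraction <= 1,
            depletion >= 0, depletion <= 1,
            mix_ratio > 0, depth_jitter >= 0, depth_jitter < 1,
            startsWith(spike_chrom, spike_prefix))
  structure(cfg, class = "SimConfig")
}

## per-slot layout parameters; errors when the chromosome cannot hold the
## requested loci with planted-linkage guarantees
.sim_layout <- function(cfg) {
  slot <- floor(cfg$target_length / cfg$n_enhancers)
  if (slot < 24000 || slot < 2 * cfg$width_range[2]) {
    .stopf("infeasible packing: %d loci need a target chromosome of at least %d bases",
           cfg$n_enhancers, cfg$n_enhancers * max(24000, 2 * cfg$width_range[2]))
  }
  omax <- min(10000, floor(slot / 8))      # anchor offset from slot center
  dmax <- min(20000, floor(slot / 4) - 1000)  # TSS distance from anchor
  list(slot = slot, omax = omax, dmin = 5000, dmax = dmax)
}

#' Generate a synthetic annotation with planted enhancer-gene links
#'
#' Places non-overlapping loci in evenly spaced slots on the target
#' chromosome; each locus gets one designated gene whose TSS is 5-20 kb from
#' the anchor and is, by construction, the nearest TSS to that anchor, plus
#' decoy TSSs between slots. A `sensitive_fraction` subset of loci (and
#' their genes) is designated degron-sensitive.
#'
#' @param cfg a `SimConfig`.
#' @return A list of class `SimAnnotation`: `loci` (`GRanges`), `tss`
#'   (`data.frame`), `chrom_sizes`, `gene_map` (named locus id -> gene id),
#'   `sensitive_enhancers`, `sensitive_genes`, `config`.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  lay <- .sim_layout(cfg)
  n <- cfg$n_enhancers
  ann <- .with_seed(cfg$seed, function() {
    w <- sample(seq(cfg$width_range[1], cfg$width_range[2]), n, replace = TRUE)
    center <- (seq_len(n) - 1) * lay$slot + floor(lay$slot / 2)
    offset <- round(runif(n, -lay$omax, lay$omax))
    mid <- center + offset
    start <- mid - floor(w / 2)
    end <- start + w
    ids <- sprintf("E%04d", seq_len(n))
    genes <- sprintf("G%04d", seq_len(n))
    sign <- sample(c(-1, 1), n, replace = TRUE)
    mag <- round(runif(n, lay$dmin, lay$dmax))
    anchor <- floor((start + end) / 2)
    tss_pos <- anchor + sign * mag
    strand <- sample(c("+", "-"), n, replace = TRUE)
    n_decoy <- n - 1
    decoy_pos <- seq_len(n_decoy) * lay$slot + round(runif(n_decoy, -2000, 2000))
    tss <- data.frame(
      gene_id = c(genes, sprintf("D%04d", seq_len(n_decoy))),
      chrom = cfg$target_chrom,
      tss = c(tss_pos, decoy_pos),
      strand = c(strand, sample(c("+", "-"), n_decoy, replace = TRUE)),
      stringsAsFactors = FALSE)
    sensitive_idx <- sort(sample(n, round(cfg$sensitive_fraction * n)))
    list(w = w, start = start, end = end, ids = ids, genes = genes,
         tss = tss, sensitive_idx = sensitive_idx)
  })
  chrom_sizes <- setNames(c(cfg$target_length, cfg$spike_length),
                          c(cfg$target_chrom, cfg$spike_chrom))
  loci <- enhancer_loci(rep(cfg$target_chrom, n), ann$start, ann$end,
                        id = ann$ids, chrom_sizes = chrom_sizes)
  structure(list(loci = loci, tss = ann$tss, chrom_sizes = chrom_sizes,
                 gene_map = setNames(ann$genes, ann$ids),
                 sensitive_enhancers = ann$ids[ann$sensitive_idx],
                 sensitive_genes = ann$genes[ann$sensitive_idx],
                 config = cfg),
            class = "SimAnnotation")
}

#' Simulate a spike-in-mixed read set for one sample
#'
#' Background reads are uniform over the target chromosome at the configured
#' density; each enhancer locus receives additional Poisson reads with mean
#' `density * enrichment * width`, multiplied by the depletion factor at
#' sensitive loci in the treatment condition. A per-sample depth/efficiency
#' factor (uniform in `1 +/- depth_jitter`) scales every expected count;
#' spike-chromosome reads are then drawn with expected count
#' `mix_ratio * target reads`, so the expected spike share matches the
#' mixing design while spike counts jitter between samples.
#'
#' @param cfg a `SimConfig`.
#' @param ann a `SimAnnotation` from [generate_annotation()].
#' @param condition `"control"` or `"treatment"`.
#' @param sample_id sample identifier.
#' @param seed RNG seed for this sample (default derives from the config
#'   seed; pass distinct seeds for distinct samples).
#' @param enrichment enrichment factor (default `cfg$enrichment`; use
#'   `cfg$rna_enrichment` for eRNA libraries).
#' @return A `ReadSet`; the planted truth (depth factor, expected spike
#'   share) is attached as `$sim`.
#' @export
simulate_reads <- function(cfg, ann, condition = c("control", "treatment"),
                           sample_id, seed = cfg$seed,
                           enrichment = cfg$enrichment) {
  stopifnot(inherits(cfg, "SimConfig"), inherits(ann, "SimAnnotation"))
  condition <- match.arg(condition)
  rl <- cfg$read_length
  loci <- ann$loci
  sens <- loci$locus_id %in% ann$sensitive_enhancers
  out <- .with_seed(seed, function() {
    d <- runif(1, 1 - cfg$depth_jitter, 1 + cfg$depth_jitter)
    ## background, uniform over the target chromosome
    n_bg <- rpois(1, cfg$background_density * cfg$target_length / 1000 * d)
    bg_start <- floor(runif(n_bg, 0, cfg$target_length - rl))
    ## planted enhancer reads: any start in [locus_start - rl + 1, end - 1]
    ## overlaps the locus by >= 1 bp
    lam <- cfg$background_density * enrichment *
      GenomicRanges::width(loci) / 1000 * d
    if (condition == "treatment") lam[sens] <- lam[sens] * cfg$depletion
    n_enh <- rpois(length(loci), lam)
    s0 <- GenomicRanges::start(loci) - 1
    e0 <- GenomicRanges::end(loci)
    enh_start <- unlist(lapply(seq_along(loci), function(i) {
      if (n_enh[i] == 0) return(numeric(0))
      pmax(floor(runif(n_enh[i], s0[i] - rl + 1, e0[i] - 1)), 0)
    }), use.names = FALSE)
    n_target <- n_bg + length(enh_start)
    ## spike chromatin is constant per cell: its expected yield follows the
    ## sample's depth/efficiency factor and the *undepleted* target
    ## expectation, never the treatment's signal loss -- that decoupling is
    ## what makes exogenous normalization informative
    lam0 <- cfg$background_density * cfg$target_length / 1000 * d + sum(
      cfg$background_density * enrichment * GenomicRanges::width(loci) / 1000 * d)
    n_spike <- rpois(1, cfg$mix_ratio * lam0)
    spike_start <- floor(runif(n_spike, 0, cfg$spike_length - rl))
    list(d = d,
         chrom = c(rep(cfg$target_chrom, n_target),
                   rep(cfg$spike_chrom, n_spike)),
         start = c(bg_start, enh_start, spike_start))
  })
  rs <- read_set(sample_id, out$chrom, out$start, out$start + rl,
                 spike_prefix = cfg$spike_prefix)
  rs$sim <- list(condition = condition, depth_factor = out$d,
                 expected_spike_share = cfg$mix_ratio / (1 + cfg$mix_ratio))
  rs
}

#' Simulate a differential-expression table with planted sensitive genes
#'
#' Sensitive genes draw `log2fc ~ Normal(de_effect)` and
#' `padj = 10^-Uniform(3, 8)`; all other genes (the remaining locus-linked
#' genes and the decoy genes) draw `log2fc ~ Normal(0, de_null_sd)` and
#' `padj ~ Uniform(0.2, 1)`, so a -0.5 / 0.05 cut recovers exactly the
#' planted set in expectation.
#'
#' @param cfg a `SimConfig`.
#' @param ann a `SimAnnotation`.
#' @param seed RNG seed (default `cfg$seed`).
#' @return `data.frame` with columns `gene`, `log2FoldChange`, `padj`.
#' @export
simulate_de_table <- function(cfg, ann, seed = cfg$seed) {
  stopifnot(inherits(ann, "SimAnnotation"))
  genes <- ann$tss$gene_id
  sens <- genes %in% ann$sensitive_genes
  .with_seed(seed, function() {
    lfc <- rnorm(length(genes), 0, cfg$de_null_sd)
    padj <- runif(length(genes), 0.2, 1)
    lfc[sens] <- rnorm(sum(sens), cfg$de_effect[["mean"]],
                       cfg$de_effect[["sd"]])
    padj[sens] <- 10^-runif(sum(sens), 3, 8)
    data.frame(gene = genes, log2FoldChange = lfc, padj = padj,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a narrowPeak set covering a planted fraction of loci
#'
#' Peaks are placed on a uniformly chosen `round(coverage * n)` subset of
#' loci (centered on the anchor, so each covered locus overlaps exactly its
#' peak) plus decoy peaks between slots that never overlap any locus, so
#' [overlap_fraction()] recovers the planted coverage exactly.
#'
#' @param cfg a `SimConfig`.
#' @param ann a `SimAnnotation`.
#' @param factor factor label (also used in peak names).
#' @param coverage fraction of loci to cover; defaults to
#'   `cfg$peak_coverage[factor]`.
#' @param seed RNG seed (default `cfg$seed`).
#' @return `GRanges` in narrowPeak layout (see [read_narrowpeak()]).
#' @export
simulate_peaks <- function(cfg, ann, factor = "p300",
                           coverage = cfg$peak_coverage[[factor]],
                           seed = cfg$seed) {
  stopifnot(inherits(ann, "SimAnnotation"),
            coverage >= 0, coverage <= 1)
  lay <- .sim_layout(cfg)
  n <- cfg$n_enhancers
  loci <- ann$loci
  p <- .with_seed(seed, function() {
    n_cov <- round(coverage * n)
    covered <- sort(sample(n, n_cov))
    w <- round(runif(n_cov, 200, 400))
    anchor <- loci$anchor[covered]
    start <- anchor - floor(w / 2)
    n_decoy <- max(1, round(n / 4))
    db <- sample(n - 1, min(n_decoy, n - 1))
    d_start <- db * lay$slot + round(runif(length(db), -2000, 2000))
    sv <- exp(rnorm(n_cov + length(db), 2, 0.5))
    list(chrom = rep(cfg$target_chrom, n_cov + length(db)),
         start = c(start, d_start), end = c(start + w, d_start + 300),
         name = c(sprintf("%s_peak_%04d", factor, covered),
                  sprintf("%s_decoy_%04d", factor, seq_along(db))),
         signal = sv,
         summit = c(anchor - start, rep(150, length(db))))
  })
  gr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1, p$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = p$name, score = pmin(round(p$signal * 100), 1000),
    peak_strand = NA_character_, signalValue = p$signal,
    pValue = round(p$signal * 2, 3), qValue = round(p$signal, 3),
    summit_offset = p$summit)
  gr
}

#' Simulate a dose-response inhibition grid
#'
#' Single-agent inhibitions follow a Hill-type curve
#' `E(d) = d / (d + ic50)`; combinations equal the Bliss independence
#' expectation plus `synergy / 100` (so [bliss_synergy()] recovers `synergy`
#' as the score) plus optional Gaussian noise, clipped into `[0, 1]`.
#'
#' @param doses_a,doses_b dose vectors (0 margins added automatically).
#' @param ic50_a,ic50_b half-maximal doses.
#' @param synergy planted synergy score in percentage points (default 0 =
#'   exact Bliss independence).
#' @param noise_sd Gaussian noise sd on the combination wells (default 0).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return Numeric matrix with dose dimnames including the 0 margins.
#' @export
simulate_dose_grid <- function(doses_a = c(0.25, 0.5, 1, 2),
                               doses_b = c(0.25, 0.5, 1, 2),
                               ic50_a = 1, ic50_b = 1,
                               synergy = 0, noise_sd = 0, seed = 1) {
  da <- sort(unique(c(0, doses_a)))
  db <- sort(unique(c(0, doses_b)))
  ea <- da / (da + ic50_a)
  eb <- db / (db + ic50_b)
  grid <- outer(ea, eb, function(a, b) a + b - a * b) + synergy / 100
  grid[, db == 0] <- matrix(ea, ncol = sum(db == 0))
  grid[da == 0, ] <- matrix(eb, nrow = sum(da == 0), byrow = TRUE)
  if (noise_sd > 0) {
    noise <- .with_seed(seed, function()
      matrix(rnorm(length(grid), 0, noise_sd), nrow = nrow(grid)))
    noise[da == 0, ] <- 0
    noise[, db == 0] <- 0
    grid <- grid + noise
  }
  grid <- pmin(pmax(grid, 0), 1)
  dimnames(grid) <- list(format(da, trim = TRUE, scientific = FALSE),
                         format(db, trim = TRUE, scientific = FALSE))
  grid
}

#' Write the synthetic annotation and ground truth to a directory
#'
#' Emits `loci.bed`, `tss.bed`, `chrom.sizes` and a JSON ground-truth
#' manifest (sensitive enhancer and gene ids, locus-gene map).
#'
#' @param ann a `SimAnnotation`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "SimAnnotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_loci_bed(ann$loci, file.path(dir, "loci.bed"))
  tss <- ann$tss
  tss_df <- data.frame(chrom = tss$chrom,
                       start = ifelse(tss$strand == "+", tss$tss, tss$tss),
                       end = ifelse(tss$strand == "+", tss$tss + 1, tss$tss + 1),
                       name = tss$gene_id, score = 0L, strand = tss$strand)
  ## BED6 TSS dialect: tss = start for "+", end - 1 for "-"; a 1 bp interval
  ## at the TSS satisfies both conventions
  write.table(tss_df, file.path(dir, "tss.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_chrom_sizes(ann$chrom_sizes, file.path(dir, "chrom.sizes"))
  jsonlite::write_json(
    list(sensitive_enhancers = ann$sensitive_enhancers,
         sensitive_genes = ann$sensitive_genes,
         gene_map = as.list(ann$gene_map)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write a ReadSet as a reads-as-BED file
#' @param readset a `ReadSet`.
#' @param path output path.
#' @export
write_reads_bed <- function(readset, path) {
  gr <- readset$reads
  df <- data.frame(chrom = .chr(gr),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$read_name)) df$name <- gr$read_name
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a ReadSet as a minimal SAM text file
#'
#' Emits an @HD/@SQ header (from `chrom_sizes`) and one single-end primary
#' alignment per read (FLAG 0, MAPQ 60, full-match CIGAR).
#'
#' @param readset a `ReadSet`.
#' @param chrom_sizes named vector of chromosome lengths for the header.
#' @param path output path.
#' @export
write_reads_sam <- function(readset, chrom_sizes, path) {
  gr <- readset$reads
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                     as.integer(chrom_sizes)), con)
  nm <- if (!is.null(gr$read_name)) gr$read_name
  else sprintf("r%07d", seq_along(gr))
  w <- GenomicRanges::width(gr)
  writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                     nm, .chr(gr), GenomicRanges::start(gr), w), con)
  invisible(path)
}

#' Write a DE table as TSV
#' @param de `data.frame` with columns `gene`, `log2FoldChange`, `padj`.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  .write_tsv(de, path)
}
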