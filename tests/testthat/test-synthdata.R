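cfg_small <- function(seed = 11, ...) {
  sim_config(seed = seed, n_enhancers = 60, ...)
}

test_that("the generator is deterministic per seed", {
  a <- generate_annotation(cfg_small())
  b <- generate_annotation(cfg_small())
  expect_identical(a$tss, b$tss)
  expect_identical(GenomicRanges::ranges(a$loci), GenomicRanges::ranges(b$loci))
  expect_identical(a$sensitive_enhancers, b$sensitive_enhancers)
  r1 <- simulate_reads(cfg_small(), a, "control", "s", seed = 5)
  r2 <- simulate_reads(cfg_small(), a, "control", "s", seed = 5)
  expect_identical(r1$reads, r2$reads)
  expect_false(identical(
    r1$reads, simulate_reads(cfg_small(), a, "control", "s", seed = 6)$reads))
  expect_identical(simulate_de_table(cfg_small(), a),
                   simulate_de_table(cfg_small(), a))
})

test_that("annotation plants disjoint loci whose designated TSS is nearest", {
  cfg <- cfg_small()
  ann <- generate_annotation(cfg)
  expect_length(ann$loci, 60)
  expect_true(all(GenomicRanges::width(ann$loci) >= cfg$width_range[1]))
  ## disjoint even after extension to 600 bp
  ext <- extend_to_min_width(ann$loci, 600, ann$chrom_sizes)
  hits <- GenomicRanges::countOverlaps(ext, ext)
  expect_true(all(hits == 1))
  ## linkage recovers the planted locus -> gene map exactly
  linked <- link_to_nearest_tss(ext, ann$tss)
  expect_identical(setNames(linked$linked_gene, linked$locus_id),
                   ann$gene_map)
  expect_error(generate_annotation(sim_config(n_enhancers = 1000,
                                              target_length = 1e6)),
               "infeasible")
})

test_that("simulated spike share tracks the 1:4 mixing design", {
  cfg <- cfg_small(depth_jitter = 0)
  ann <- generate_annotation(cfg)
  rs <- simulate_reads(cfg, ann, "control", "s", seed = 2)
  n <- count_by_genome(rs)
  share <- n[["spike"]] / sum(n)
  expect_equal(share, 0.2, tolerance = 0.05)
})

test_that("treatment depletion halves enhancer reads at sensitive loci", {
  cfg <- cfg_small(depth_jitter = 0)
  ann <- generate_annotation(cfg)
  ctrl <- simulate_reads(cfg, ann, "control", "c", seed = 3)
  trt <- simulate_reads(cfg, ann, "treatment", "t", seed = 4)
  sens <- ann$loci$locus_id %in% ann$sensitive_enhancers
  cc <- count_reads_in_loci(ctrl, ann$loci)
  tc <- count_reads_in_loci(trt, ann$loci)
  ## expected ratio (bg + 0.5 * enr) / (bg + enr) ~ 0.51 at enrichment 50
  expect_equal(sum(tc[sens]) / sum(cc[sens]), 0.51, tolerance = 0.08)
  expect_equal(sum(tc[!sens]) / sum(cc[!sens]), 1, tolerance = 0.08)
})

test_that("planted DE structure is recovered by the default thresholds", {
  cfg <- cfg_small()
  ann <- generate_annotation(cfg)
  de <- simulate_de_table(cfg, ann, seed = 9)
  expect_equal(nrow(de), nrow(ann$tss))
  down <- call_downregulated(de)
  ## null genes essentially never pass (padj >= 0.2 by construction)
  null_called <- setdiff(down, ann$sensitive_genes)
  expect_length(null_called, 0)
  expect_gte(length(intersect(down, ann$sensitive_genes)),
             0.9 * length(ann$sensitive_genes))
})

test_that("peak simulation plants an exact coverage fraction", {
  cfg <- sim_config(seed = 13, n_enhancers = 200)
  ann <- generate_annotation(cfg)
  peaks <- simulate_peaks(cfg, ann, "p300", coverage = 0.86, seed = 14)
  res <- overlap_fraction(ann$loci, peaks, "p300")
  expect_identical(res$summary$n_overlapped, 172L)
  none <- simulate_peaks(cfg, ann, "x", coverage = 0, seed = 15)
  expect_equal(overlap_fraction(ann$loci, none)$summary$fraction, 0)
  decoys <- none  # coverage 0 emits decoys only
  expect_false(any(IRanges::overlapsAny(ann$loci, decoys)))
})

test_that("fixtures round-trip through their writers", {
  cfg <- cfg_small()
  ann <- generate_annotation(cfg)
  dir <- withr::local_tempdir()
  write_annotation(ann, dir)
  loci <- read_bed(file.path(dir, "loci.bed"),
                   read_chrom_sizes(file.path(dir, "chrom.sizes")))
  expect_equal(length(loci), length(ann$loci))
  expect_identical(loci$locus_id, ann$loci$locus_id)
  tss <- read_tss_bed(file.path(dir, "tss.bed"))
  expect_setequal(tss$gene_id, ann$tss$gene_id)

  rs <- simulate_reads(cfg, ann, "control", "s", seed = 6)
  bed <- file.path(dir, "reads.bed")
  write_reads_bed(rs, bed)
  back <- read_reads_bed(bed, "s")
  expect_equal(unname(count_by_genome(back)), unname(count_by_genome(rs)))

  sam <- file.path(dir, "reads.sam")
  write_reads_sam(rs, ann$chrom_sizes, sam)
  back_sam <- read_reads_sam(sam, "s")
  expect_equal(unname(count_by_genome(back_sam)), unname(count_by_genome(rs)))

  de <- simulate_de_table(cfg, ann, seed = 7)
  de_path <- file.path(dir, "de.tsv")
  write_de_table(de, de_path)
  expect_identical(read_de_table(de_path)$gene, de$gene)

  pk <- simulate_peaks(cfg, ann, "p300", seed = 8)
  np <- file.path(dir, "p300.narrowPeak")
  write_narrowpeak(pk, np)
  back_pk <- read_narrowpeak(np)
  expect_equal(length(back_pk), length(pk))
  expect_equal(GenomicRanges::start(back_pk), GenomicRanges::start(pk))
})
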