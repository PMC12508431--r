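test_that("read_bed parses BED3/BED4 with midpoint anchors and preserves order", {
  path <- withr::local_tempfile(lines = c(
    "track name=enh",
    "chr1\t100\t700\tE1",
    "chr1\t2000\t2500",
    "chr2\t50\t950\tE3"))
  loci <- read_bed(path)
  expect_length(loci, 3)
  expect_identical(loci$locus_id, c("E1", "chr1:2000-2500", "E3"))
  expect_equal(GenomicRanges::start(loci)[1] - 1, 100)
  expect_equal(GenomicRanges::end(loci)[1], 700)
  expect_equal(loci$anchor, c(400, 2250, 500))
})

test_that("read_bed rejects malformed coordinates with the line number", {
  path <- withr::local_tempfile(lines = c("chr1\t100\t700\tE1",
                                          "chr1\t700\t100\tE2"))
  expect_error(read_bed(path), "line 2")
  path2 <- withr::local_tempfile(lines = "chr1\tabc\t700")
  expect_error(read_bed(path2), "non-integer")
  path3 <- withr::local_tempfile(lines = "chr1\t100")
  expect_error(read_bed(path3), ">= 3")
})

test_that("read_bed validates against chromosome sizes and duplicate ids", {
  path <- withr::local_tempfile(lines = "chr1\t100\t700\tE1")
  expect_error(read_bed(path, chrom_sizes = c(chr1 = 500)), "beyond the end")
  expect_silent(read_bed(path, chrom_sizes = c(chr1 = 700)))
  dup <- withr::local_tempfile(lines = c("chr1\t1\t10\tE1", "chr1\t20\t30\tE1"))
  expect_error(read_bed(dup), "duplicate locus id")
})

test_that("extension pads short loci symmetrically and clips at edges", {
  loci <- enhancer_loci("chr1", c(1000, 0, 1000), c(1400, 100, 2601),
                        id = c("A", "B", "C"))
  out <- extend_to_min_width(loci, 600)
  # deficit 200 split 100/100
  expect_equal(GenomicRanges::start(out)[1] - 1, 900)
  expect_equal(GenomicRanges::end(out)[1], 1500)
  # left clip at 0 moves the deficit right
  expect_equal(GenomicRanges::start(out)[2] - 1, 0)
  expect_equal(GenomicRanges::end(out)[2], 600)
  # width 1601 already sufficient: unchanged
  expect_equal(GenomicRanges::start(out)[3] - 1, 1000)
  expect_equal(GenomicRanges::end(out)[3], 2601)
  # anchors never move
  expect_equal(out$anchor, loci$anchor)
})

test_that("extension clips at the chromosome end, moving lost bases left", {
  loci <- enhancer_loci("chr1", 900, 980)
  out <- extend_to_min_width(loci, 600, chrom_sizes = c(chr1 = 1000))
  expect_equal(GenomicRanges::end(out), 1000)
  expect_equal(GenomicRanges::width(out), 600)
  expect_error(extend_to_min_width(loci, 600, chrom_sizes = c(chr1 = 500)),
               "shorter than min_width")
})

test_that("extension is idempotent and conserves max(width, min_width)", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 30
    s <- floor(runif(n, 5000, 5e5))
    w <- sample(50:1500, n, replace = TRUE)
    loci <- enhancer_loci(rep("chr1", n), s, s + w,
                          id = sprintf("L%d", seq_len(n)))
    once <- extend_to_min_width(loci, 600)
    twice <- extend_to_min_width(once, 600)
    expect_identical(GenomicRanges::ranges(once), GenomicRanges::ranges(twice))
    expect_equal(GenomicRanges::width(once), pmax(w, 600))
  }
})

test_that("nearest-TSS linkage follows distance and the lexicographic tie rule", {
  loci <- enhancer_loci(c("chr1", "chr1", "chr3"),
                        c(5700, 9700, 100), c(6300, 10300, 700),
                        id = c("E1", "E2", "E3"))
  tss <- data.frame(
    gene_id = c("GENEA", "GENEB", "Z", "A"),
    chrom = c("chr1", "chr1", "chr1", "chr1"),
    tss = c(5000, 20000, 9000, 11000),
    strand = "+", stringsAsFactors = FALSE)
  expect_warning(out <- link_to_nearest_tss(loci, tss), "no TSS")
  expect_identical(out$linked_gene[1], "GENEA")
  expect_equal(out$link_distance[1], 1000)
  # E2 anchor 10000: Z and A both at distance 1000 -> lexicographic "A"
  expect_identical(out$linked_gene[2], "A")
  expect_true(is.na(out$linked_gene[3]))
})

test_that("linkage matches a brute-force all-pairs scan on random sets", {
  set.seed(7)
  for (rep in 1:25) {
    n_loci <- sample(1:50, 1)
    n_tss <- sample(1:50, 1)
    chroms <- c("chr1", "chr2")
    s <- floor(runif(n_loci, 0, 1e6))
    loci <- enhancer_loci(sample(chroms, n_loci, replace = TRUE),
                          s, s + 500, id = sprintf("L%d", seq_len(n_loci)))
    tss <- data.frame(gene_id = sprintf("g%02d", sample(99, n_tss)),
                      chrom = sample(chroms, n_tss, replace = TRUE),
                      tss = floor(runif(n_tss, 0, 1e6)),
                      strand = "+", stringsAsFactors = FALSE)
    out <- suppressWarnings(link_to_nearest_tss(loci, tss))
    expected <- vapply(seq_along(loci), function(i) {
      oracle_nearest_gene(loci$anchor[i],
                          as.character(GenomicRanges::seqnames(loci))[i], tss)
    }, character(1))
    expect_identical(out$linked_gene, expected)
  }
})

test_that("TSS BED6 reader places the TSS by strand", {
  path <- withr::local_tempfile(lines = c(
    "chr1\t1000\t1200\tGP\t0\t+",
    "chr1\t3000\t3400\tGM\t0\t-"))
  tss <- read_tss_bed(path)
  expect_equal(tss$tss, c(1000, 3399))
  expect_error(read_tss_bed(withr::local_tempfile(
    lines = "chr1\t1\t2\tG\t0\t*")), "strand")
})
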