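test_that("overlap counting is >= 1 bp and half-open", {
  locus <- enhancer_loci("chr1", 150, 700, id = "L")
  expect_equal(count_reads_in_loci(make_reads(100, len = 100), locus), 1)
  expect_equal(count_reads_in_loci(make_reads(700, len = 100), locus), 0)
  inside <- make_reads(c(200, 300, 400), len = 50)
  expect_equal(count_reads_in_loci(inside, locus), 3)
})

test_that("overlap counting matches the per-base brute-force oracle", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(10:100, 1)
    rs <- floor(runif(n, 0, 9800))
    re <- rs + sample(1:150, n, replace = TRUE)
    k <- sample(1:10, 1)
    ls <- floor(runif(k, 0, 9400))
    le <- pmin(ls + sample(50:500, k, replace = TRUE), 10000)
    loci <- enhancer_loci(rep("chr1", k), ls, le, id = sprintf("L%d", 1:k))
    reads <- read_set("s", rep("chr1", n), rs, re)
    counts <- count_reads_in_loci(reads, loci)
    for (j in seq_len(k)) {
      expect_equal(counts[j],
                   oracle_count_overlaps(rs, re, ls[j], le[j], 10000))
    }
  }
})

test_that("rpk is count per kilobase and additive over disjoint read sets", {
  expect_equal(rpk(300, 600), 500)
  expect_equal(rpk(0, 600), 0)
  expect_equal(rpk(50, 2500), 20)
  expect_error(rpk(1, 0), "> 0")
  locus <- enhancer_loci("chr1", 0, 1000)
  a <- make_reads(c(10, 20, 30), len = 40)
  b <- make_reads(c(500, 600), len = 40)
  merged <- make_reads(c(10, 20, 30, 500, 600), len = 40)
  expect_equal(rpk(count_reads_in_loci(merged, locus), 1000),
               rpk(count_reads_in_loci(a, locus), 1000) +
                 rpk(count_reads_in_loci(b, locus), 1000))
})

test_that("signal tables hold rpk per locus and sample", {
  locus <- enhancer_loci("chr1", 1000, 1600, id = "L1")
  zero <- enhancer_loci("chr1", 9000, 9600, id = "L0")
  loci <- c(locus, zero)
  s1 <- make_reads(seq(1000, 1590, by = 10), len = 10, sample_id = "a") # 60 reads
  s2 <- make_reads(c(1100, 1200), len = 10, sample_id = "b")
  tbl <- build_signal_table(list(s1, s2), loci, assay = "chip")
  expect_equal(tbl$values["L1", "a"], 100)
  expect_equal(unname(tbl$values["L0", ]), c(0, 0))
  # permuting samples permutes columns only
  tbl2 <- build_signal_table(list(s2, s1), loci, assay = "chip")
  expect_equal(tbl2$values[, c("a", "b")], tbl$values[, c("a", "b")])
  s1b <- s1; s1b$sample_id <- "b"
  expect_error(build_signal_table(list(s1b, s2), loci), "duplicate sample")
})

test_that("the low-signal filter retains loci above threshold in either sample", {
  loci <- enhancer_loci("chr1", c(0, 1000, 2000) * 10, c(600, 10600, 20600),
                        id = c("A", "B", "C"))
  tbl <- structure(list(
    values = matrix(c(25, 25, 40, 28, 35, 10), nrow = 3,
                    dimnames = list(c("A", "B", "C"), c("ctrl", "trt"))),
    assay = "chip", normalization = "none",
    threshold = NA_real_, excluded = character()), class = "SignalTable")
  out <- filter_low_signal(tbl, "ctrl", "trt", threshold = 30)
  expect_identical(rownames(out$values), c("B", "C"))
  expect_identical(out$excluded, "A")
  # rna default threshold 10
  tbl$assay <- "rna"
  tbl$values[] <- c(5, 25, 40, 8, 35, 10)
  out_rna <- filter_low_signal(tbl, "ctrl", "trt")
  expect_false("A" %in% rownames(out_rna$values))
  expect_equal(out_rna$threshold, 10)
  expect_error(filter_low_signal(tbl, "ctrl", "nope"), "unknown sample")
})

test_that("raising the threshold never grows the retained set", {
  set.seed(5)
  vals <- matrix(runif(200, 0, 60), ncol = 2,
                 dimnames = list(sprintf("L%03d", 1:100), c("c", "t")))
  tbl <- structure(list(values = vals, assay = "chip", normalization = "none",
                        threshold = NA_real_, excluded = character()),
                   class = "SignalTable")
  prev <- rownames(vals)
  for (thr in c(0, 10, 20, 30, 40, 70)) {
    kept <- rownames(filter_low_signal(tbl, "c", "t", threshold = thr)$values)
    expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("fold change uses the rpk pseudocount and flags filtered loci", {
  vals <- matrix(c(100, 100, 0, 100, 50, 0), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("ctrl", "trt")))
  tbl <- structure(list(values = vals, assay = "chip", normalization = "none",
                        threshold = NA_real_, excluded = character()),
                   class = "SignalTable")
  fc <- fold_change(tbl, "ctrl", "trt", pseudocount = 1, threshold = 30)
  expect_equal(fc$log2fc[1], 0)
  expect_equal(fc$log2fc[2], log2(51 / 101))
  expect_false(fc$passed_filter[3])
  expect_true(is.na(fc$log2fc[3]))
  expect_true(all(is.finite(fc$log2fc[fc$passed_filter])))
  expect_error(fold_change(tbl, "ctrl", "trt", pseudocount = -1), "non-negative")
})

test_that("tornado matrices bin a +/- window around the anchor", {
  loci <- enhancer_loci("chr1", 10000, 10600, id = "L")  # anchor 10300
  # one read per bin position: equal signal in every bin
  starts <- seq(10300 - 3000, 10300 + 3000 - 50, by = 50)
  rs <- make_reads(starts, len = 50)
  m <- signal_matrix(rs, loci, window = 3000, bin = 50)
  expect_equal(ncol(m), 120)
  expect_true(all(m == m[1, 1]))
  # single read at the anchor: only the central bins are nonzero
  one <- make_reads(10300, len = 75)
  m1 <- signal_matrix(one, loci, window = 3000, bin = 50)
  nonzero <- which(m1[1, ] > 0)
  expect_true(all(colnames(m1)[nonzero] %in% c("0", "50")))
  # window past the chromosome start: clipped bins report 0
  early <- enhancer_loci("chr1", 0, 600, id = "E")  # anchor 300, window from -2700
  m2 <- signal_matrix(make_reads(100, len = 75), early,
                      window = 3000, bin = 50)
  expect_equal(ncol(m2), 120)
  expect_true(all(m2[1, as.numeric(colnames(m2)) < -300] == 0))
  expect_error(signal_matrix(one, loci, window = 3000, bin = 70), "divisible")
})
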