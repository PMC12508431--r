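## Independent brute-force oracles and small fixture builders used across
## the suite. These deliberately avoid the code paths they check.

## per-base scan: number of reads sharing >= 1 bp with the half-open locus
## [locus_start, locus_end); all coordinates 0-based, bounded by max_pos
oracle_count_overlaps <- function(read_start, read_end,
                                  locus_start, locus_end, max_pos) {
  ind <- integer(max_pos)
  ind[(locus_start + 1):locus_end] <- 1L
  cs <- c(0, cumsum(ind))
  sum(cs[read_end + 1] - cs[read_start + 1] > 0)
}

## all-pairs overlap booleans for loci vs peaks (0-based half-open)
oracle_overlap_any <- function(ls, le, ps, pe) {
  vapply(seq_along(ls), function(i) {
    any(pmax(ls[i], ps) < pmin(le[i], pe))
  }, logical(1))
}

## exhaustive-enumeration two-sided Mann-Whitney p for tieless samples
oracle_mwu_exact_p <- function(x, y) {
  n <- length(x)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * length(y) / 2
  assign_u <- combn(length(vals), n, function(idx) {
    sum(r[idx]) - n * (n + 1) / 2
  })
  mean(abs(assign_u - mu) >= abs(u_obs - mu))
}

## nearest-TSS assignment by all-pairs distance scan with the documented
## tie rule (lexicographically smallest gene id)
oracle_nearest_gene <- function(anchor, chrom, tss_df) {
  cand <- tss_df[tss_df$chrom == chrom, ]
  if (nrow(cand) == 0) return(NA_character_)
  d <- abs(cand$tss - anchor)
  best <- cand$gene_id[d == min(d)]
  sort(best)[1]
}

## minimal ReadSet on one target chromosome from 0-based starts
make_reads <- function(start, len = 75, chrom = "chr1", sample_id = "s") {
  read_set(sample_id, rep(chrom, length(start)), start, start + len)
}

## ReadSet with a given number of target and spike reads
make_mixed_reads <- function(n_target, n_spike, sample_id = "s") {
  read_set(sample_id,
           c(rep("chr1", n_target), rep("dm6_chr2L", n_spike)),
           c(seq_len(n_target), seq_len(n_spike)) * 10,
           c(seq_len(n_target), seq_len(n_spike)) * 10 + 75)
}
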