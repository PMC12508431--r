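---
title: "Methods: spike-in normalized enhancer quantification and sensitivity classification"
author: "enhancerx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-in normalized enhancer quantification and sensitivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerx)
```

# The analysis model

enhancerx analyzes a *fixed* set of enhancer loci — regions defined by the
binding of an anchoring factor such as a fusion oncoprotein — across
conditions of a degradation (degron) or inhibitor experiment. Nothing in the
package calls peaks or fits expression models; it consumes loci, aligned
reads, MACS2 narrowPeak files and differential-expression (DE) tables, and
produces normalized per-locus signal, fold changes, classifications and
group statistics. This vignette explains each method, the tunable
parameters, the synthetic data model used for validation, and the design
choices made where the conventions of the field leave room.

## Coordinates and locus preparation

All user-facing coordinates are 0-based half-open (BED convention);
internally loci live in `GRanges` (1-based closed), and the conversion is
exact, so "a read abutting a locus end does not overlap it" holds under
`countOverlaps()` semantics.

Each locus carries an **anchor**: the functional center (the anchoring
factor's peak summit when known, otherwise the interval midpoint). Three
operations prepare loci:

* `read_bed()` ingests BED3/4/6, preserving order, defaulting ids to
  `chrom:start-end` and validating coordinates against an optional
  `chrom.sizes` map. Malformed lines are hard errors naming the line —
  silently skipping records would bias every downstream fraction.
* `extend_to_min_width()` pads loci narrower than `min_width` (default
  **600 bp**) to exactly `min_width`: `floor(deficit/2)` bases left,
  `ceiling(deficit/2)` right, with bases lost to a chromosome edge moved to
  the other side. The default reflects the practice of widening very short
  called regions so occupancy around the binding site is assessed on a
  comparable footprint; anchors are never moved, and extension is idempotent.
* `link_to_nearest_tss()` assigns each locus the gene whose TSS minimizes
  `|TSS − anchor|` on the same chromosome. Distance is point-to-point from
  the anchor because the anchor is the defined functional center of the
  locus. Ties — e.g. bidirectional promoters equidistant from the anchor —
  are broken by lexicographically smallest gene id: an arbitrary but
  *documented and deterministic* convention, preferable to an
  implementation-order accident. Loci on chromosomes without any TSS are
  returned unlinked with a warning rather than erroring, so a partial
  annotation degrades gracefully.

## Spike-in (ChIP-Rx) normalization

When exogenous reference chromatin is mixed into every sample at a fixed
cell ratio (the generator's default emulates 1:4 spike:target cells), the
spike-in read count `S_s` is proportional to the sample's overall
depth/IP-efficiency, while the target count `H_s` is additionally
proportional to true per-cell occupancy. Scaling samples to a common
per-spike-read depth therefore preserves genuine global occupancy changes —
the reason to use spike-ins at all.

`compute_norm_factors()` realizes this as **downsampling only**:

* spike mode: `f_s = min_t(S_t) / S_s`
* depth mode: `f_s = min_t(H_t) / H_s`
* `gamma_s = 10^6 / S_s` (per-million-spike scale) is always reported.

Downsampling by `f_s` never upsamples, leaves exactly one sample intact, and
is equivalent to equalizing `gamma_s` across samples. `downsample_reads()`
retains each target read independently with probability `f` (per-read
Bernoulli from R's seeded Mersenne-Twister — the simplest contract that is
bit-reproducible given a seed, chosen over hash-of-read-name schemes).
Records sharing a read name (paired-end mates) are kept or dropped together.
Spike reads are bookkeeping, not signal, and pass through unchanged.

Normalization is computed within a user-declared comparison group (a
control and its treatments); the package does not guess batch structure.

## Signal quantification and filtering

`build_signal_table()` produces a locus × sample matrix of
**rpk** — overlapping read count divided by locus length in kb — using ≥1 bp
strand-agnostic overlap. Counting is strand-agnostic because ribo-depleted
eRNA libraries do not warrant a strandedness assumption, and each alignment
record counts once at its mapped interval (no fragment-length extension).
rpk always uses the post-extension locus width, so the quantity is
consistent for loci that were widened.

The **low-signal exclusion rule** drops a locus only when *both* compared
samples fall below the threshold: 30 rpk for ChIP, 10 rpk for eRNA (lower
because enhancer transcription is intrinsically weak). The OR-retention form
matters: a locus that collapses from strong signal to zero is precisely the
biology of interest and must not be filtered. Retained loci keep raw,
unthresholded values.

`fold_change()` reports `log2((rpk_trt + pc) / (rpk_ctrl + pc))` with a
pseudocount of **1 rpk**. The pseudocount keeps the fold change finite for
loci that pass the OR-filter with one zero side; 1 rpk is small against the
30/10 thresholds, so it attenuates only values already near the detection
floor.

`signal_matrix()` emits tornado-plot input: per-10-million-read counts in
`2W/b` bins (default W = 3000, b = 50, i.e. 120 bins) over ±W around each
anchor. Bins clipped at the chromosome start report zero. The package emits
the matrix only; heatmap rendering is left to the caller.

## Peak overlap and intensity correlation

`overlap_fraction()` marks a locus overlapped when ≥1 narrowPeak shares ≥1
base with it and reports `n_overlapped / n_enhancers` per factor.
`intensity_correlation()` correlates two samples' per-locus rpk and returns
squared Pearson r. "Peak intensity" is deliberately realized as rpk from the
same SignalTable machinery rather than MACS2 `signalValue`, so the
correlation is defined at every locus (including those without a called
peak for one factor) and both factors are measured identically; the
narrowPeak `signalValue` remains available to callers who prefer it. A
`log2(x + 1)` transform is applied by default because raw ChIP intensities
are heavy-tailed; exactly linear relationships are therefore only R² = 1
with `log_transform = FALSE`, and every output records which transform was
used.

## Sensitivity classification

`call_downregulated()` applies **strict** inequalities `log2FC < −0.5` and
`FDR < 0.05` — printed thresholds with strict signs are honored exactly, so
a gene at the boundary is excluded; missing adjusted p never qualifies.
`call_sensitive()` intersects downregulated genes with the enhancer-gene
links: a gene linked to several enhancers marks *all* of them sensitive.
Containment invariants (sensitive genes ⊆ downregulated genes; sensitive
enhancers' genes ⊆ sensitive genes) are asserted on every call.
`set_overlap()` reports intersections with percentages of *both* sets, so
either denominator convention in a figure can be matched.

The DE table is an input: negative-binomial modeling belongs to DESeq2 and
is out of scope here.

## Group tests and synergy

`mann_whitney_u()` and `kruskal_wallis()` wrap the reference implementations
in the stats package with a fixed small-sample policy: exact enumeration
when the combined sample size is ≤12 with no ties, otherwise the tie- and
continuity-corrected normal approximation. The test suite cross-checks the
exact path against an independent `combn()` enumeration oracle and verifies
type-I error calibration (rejection rate in [0.04, 0.06] at α = 0.05 under
the null, n = 50 per group). Tests are two-sided by default. The pipeline
tests *groups* of loci once per comparison, so no multiple-testing
correction is built in; `bh_fdr()` is provided for callers who add
per-feature tests.

`bliss_synergy()` scores a dose-response grid against Bliss independence
`E_a + E_b − E_a·E_b`, in percentage points
(`score = 100 × (observed − expected)`, the SynergyFinder convention, under
which scores between 0 and 10 read as additive-to-weak synergy). Both the
per-dose-pair score matrix and the grid mean are returned, since published
summaries use either. Inhibition values outside [0, 1] are errors unless
`clip = TRUE`.

## The synthetic data model

The generator plants every quantity the pipeline estimates:

* **Annotation** — `n_enhancers` (default 200) non-overlapping loci of
  300–900 bp in evenly spaced slots on one target chromosome; each locus's
  designated gene gets a TSS 5–20 kb from the anchor that is *provably* the
  nearest TSS (slot geometry bounds every competing distance), plus decoy
  TSSs between slots. A `sensitive_fraction` (default 0.15, matching the
  minority-subset design of degron studies) is designated sensitive.
* **Reads** — uniform background at `background_density` (2 reads/kb) plus
  Poisson extra reads at each locus with mean
  `density × enrichment × width` (enrichment 50 for ChIP, 10 for eRNA, about
  60 and 12 expected extra reads per 600 bp locus), multiplied by
  `depletion` (0.5) at sensitive loci in the treatment. Reads are single-end
  75 nt on an integer grid. A per-sample depth/efficiency factor, uniform in
  1 ± `depth_jitter` (0.2), scales all expected counts. Spike reads are
  emitted on a dedicated prefixed chromosome with expectation
  `mix_ratio × (undepleted target expectation × depth factor)`:
  spike chromatin is constant per cell, so its yield follows sample depth
  but *not* the treatment's signal loss — the premise that makes exogenous
  normalization informative.
* **DE tables** — sensitive genes draw `log2FC ~ N(−1.5, 0.3)` and
  `padj = 10^−U(3, 8)`; null genes draw `N(0, 0.2)` with
  `padj ~ U(0.2, 1)`, so the −0.5/0.05 cut has essentially zero false-
  positive probability by construction and recovery failures indicate real
  pipeline defects.
* **Peaks** — placed on exactly `round(coverage × n)` loci, centered on
  anchors, plus decoys that cannot overlap any locus, so overlap fractions
  recover the planted coverage exactly. Default coverages (0.86, 0.94,
  0.25, 0.16 across four simulated factors) span the strong-to-weak range
  seen for enhancer co-factors.
* **Dose grids** — Hill-type single agents `E(d) = d/(d + IC50)` with
  combinations equal to Bliss independence plus a planted synergy offset.

What the generator does **not** emulate: sequence content (no FASTA/FASTQ,
no mappability or GC structure), fragment-size distributions, duplicate
reads, overdispersion beyond Poisson, chromatin-state correlation between
neighboring loci, and liftover/assembly issues. Passing tests therefore
demonstrate the correctness of the *analysis arithmetic* — normalization,
counting, filtering, classification, statistics — not robustness to
alignment artifacts, which are upstream of this package's contract.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit seed and runs inside a
  save/restore of the session RNG; identical inputs and seed are
  bit-reproducible, and `run_pipeline()` reruns are byte-identical
  (verified by MD5 in the tests).
* The pipeline derives stage seeds as fixed offsets from the master seed,
  so stage functions called individually with those seeds compose to the
  same tables as the driver.
* Degenerate inputs are defined, not accidental: empty read sets count
  zero; a Kruskal–Wallis on all-identical observations returns H = 0,
  p = 1; zero-variance columns make correlation an error rather than NaN;
  zero spike reads make spike normalization an error.
* Tie-breaks (TSS linkage) and boundary cases (strict DE thresholds,
  half-open abutment) are documented conventions tested explicitly.
* Config files are flat key-value YAML; unknown keys are errors, which
  catches threshold typos that would otherwise silently revert defaults.

## Validation problem sizes

The shipped tests run the oracle-equivalence checks on 1000 random small
instances (≤100 reads × ≤10 loci; ≤200 peaks × ≤50 loci), the
normalization-recovery check on three samples of roughly a million target
reads each (retained-count CV < 2%), the planted fold-change recovery on
400 loci with 200 depleted (medians within ±0.15 of −1 and 0 after the
30/10 rpk filters), the end-to-end classification on the default 200-locus
design (precision and recall ≥ 0.95), and the Mann–Whitney calibration on
2000 null replicates. These sizes were chosen so the full suite completes
in about two minutes while every estimate it checks has standard error well
inside the asserted tolerance.

## Known limitations

* eRNA fold-change recovery is biased toward zero at weak enrichment:
  with enrichment 10 over background 2, a true halving appears as about
  −0.8 log2FC after background dilution and the pseudocount. This mirrors
  real eRNA analyses (low counts compress fold changes) and is why the
  planted-recovery validation uses ChIP-scale enrichment.
* Nearest-TSS linkage is a proximity heuristic; enhancers skipping their
  nearest promoter are mis-assigned by construction, and no
  chromatin-contact information is consulted.
* Spike normalization assumes the mixing ratio is actually constant across
  samples; a pipetting error in the mix is indistinguishable from a global
  occupancy change, and the package cannot detect it.
* The SAM reader handles plain single- or paired-end primary alignments
  (FLAG/MAPQ filtering, CIGAR reference span) and is intended for modest
  files and fixtures; BAM-scale inputs should be converted or summarized
  upstream.
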