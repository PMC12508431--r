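# enhancerx

Enhancer-centric analysis of spike-in-normalized ChIP-seq (ChIP-Rx) and
enhancer-RNA (eRNA) data around fusion-protein degradation experiments.

## The problem

Oncogenic fusion transcription factors such as EWS::FLI1 create de novo
enhancers whose activity can be probed by acutely degrading the fusion
protein (degron systems) and measuring what happens to chromatin occupancy,
enhancer transcription, and target-gene expression. Analyses of this kind
revolve around a *fixed set of enhancer loci* and repeatedly need the same
machinery:

* **Locus preparation** — BED ingestion, extension of short loci to a minimum
  width (default 600 bp) around the fusion-protein binding site, and linkage
  of each enhancer to its nearest promoter (TSS), which defines the
  enhancer's putative target gene.
* **Spike-in (ChIP-Rx) normalization** — when exogenous reference chromatin
  (e.g. *Drosophila* S2, mixed at 1:4 spike:target cells) is included, each
  sample's target reads are downsampled by `f_s = min(S) / S_s`, where `S_s`
  is the sample's spike-in read count, so every sample is scaled to a common
  per-spike-read depth. Global occupancy loss then survives normalization
  instead of being washed out.
* **Signal quantification** — reads per kilobase (rpk) over each locus,
  low-signal exclusion (a locus is dropped only when *both* compared samples
  are below 30 rpk for ChIP or 10 rpk for eRNA), per-locus
  `log2((rpk_trt + 1) / (rpk_ctrl + 1))` fold changes, and binned
  (tornado-style) signal matrices over ±3 kb windows around the binding-site
  anchor.
* **Sensitivity classification** — genes with `log2FC < -0.5` and
  `FDR < 0.05` in an externally produced differential-expression table,
  intersected with the enhancer-gene links: a *sensitive* gene is a
  downregulated gene linked to an enhancer, and every enhancer linked to a
  sensitive gene is a *sensitive* enhancer.
* **Peak and statistics support** — narrowPeak overlap fractions, peak
  intensity correlation (R²), Mann–Whitney U and Kruskal–Wallis group tests,
  Benjamini–Hochberg adjustment, and Bliss-independence drug synergy scores
  (`score = 100 × (observed − (E_a + E_b − E_a·E_b))`).

Because real degron datasets are large, the package ships a fully synthetic
generator (`sim_config()`, `generate_annotation()`, `simulate_reads()`,
`simulate_de_table()`, `simulate_peaks()`, `simulate_dose_grid()`) that
plants known enrichment, depletion, mixing ratios, DE structure and peak
coverage, so every stage is testable end-to-end with no downloads.

## Worked example

A complete in-memory run on synthetic data (see `run_pipeline()` for the
one-call version that also writes TSV outputs):

```r
library(enhancerx)

cfg <- sim_config(seed = 1, n_enhancers = 200)   # 15% planted sensitive loci
ann <- generate_annotation(cfg)
ctrl <- simulate_reads(cfg, ann, "control",   "chip_control",   seed = 102)
trt  <- simulate_reads(cfg, ann, "treatment", "chip_treatment", seed = 103)

norm <- compute_norm_factors(list(ctrl, trt), mode = "spike")
norm
#>           sample     H     S    gamma         f  mode
#> 1   chip_control 53811 13508 74.03020 0.8517915 spike
#> 2 chip_treatment 45161 11506 86.91118 1.0000000 spike

loci <- link_to_nearest_tss(
  extend_to_min_width(ann$loci, 600, ann$chrom_sizes), ann$tss)
tbl <- build_signal_table(list(ctrl, trt), loci, norm = norm,
                          assay = "chip", seed = 104)
fc <- fold_change(tbl, "chip_control", "chip_treatment")
sens <- fc$locus_id %in% ann$sensitive_enhancers
median(fc$log2fc[sens & fc$passed_filter])    # -0.86 (planted halving)
median(fc$log2fc[!sens & fc$passed_filter])   # -0.04 (stable background)

de <- simulate_de_table(cfg, ann, seed = 105)
call_sensitive(loci, call_downregulated(de), system = "demo")
#> SensitivityCall 'demo': 30 downregulated genes, 30 sensitive genes,
#>   30 sensitive enhancers

mann_whitney_u(fc$log2fc[sens & fc$passed_filter],
               fc$log2fc[!sens & fc$passed_filter])
#> Mann-Whitney U (normal approximation): statistic = 153, p = 2.41111e-16
#>   (n = 30/170, two-sided)
```

The control sample keeps `f = 0.85` of its target reads (it has the deeper
spike library); after normalization the planted 50% treatment depletion at
sensitive enhancers appears as a median log2FC near −1 while the untouched
loci sit near 0, and the sensitivity call recovers all 30 planted
gene/enhancer pairs.

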