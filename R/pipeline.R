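## Deterministic pipeline driver: one flat config, staged execution
## (simulate/ingest -> normalize -> quantify -> filter -> fold change ->
## classify -> peak overlap/correlation -> group tests), reproducibility
## metadata embedded in every output.

#' Default run configuration
#'
#' A flat named list of every pipeline setting. With `synthetic = TRUE`
#' (default) all inputs are generated by the synthetic module; otherwise the
#' `loci` / `tss` / `chrom_sizes` / `reads_*` / `peaks` / `de_table` path
#' entries are read from disk (reads as `.sam` or reads-as-BED).
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return Named list of class `RunConfig`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    synthetic = TRUE,
    normalization = "spike",      # chip normalization: spike | depth | none
    spike_prefix = "dm6_",
    ## fixed analysis constants
    min_width = 600,
    chip_rpk = 30,
    rna_rpk = 10,
    lfc = -0.5,
    fdr = 0.05,
    window = 3000,
    bin = 50,
    pseudocount = 1,
    ## synthetic design
    n_enhancers = 200,
    sensitive_fraction = 0.15,
    depletion = 0.5,
    enrichment = 50,
    rna_enrichment = 10,
    background_density = 2,
    mix_ratio = 0.25,
    depth_jitter = 0.2,
    ## file inputs (non-synthetic mode)
    loci = NULL,
    tss = NULL,
    chrom_sizes = NULL,
    reads_chip_control = NULL,
    reads_chip_treatment = NULL,
    reads_rna_control = NULL,
    reads_rna_treatment = NULL,
    peaks = NULL,
    de_table = NULL
  ), class = "RunConfig")
}

#' Read a run configuration from a flat YAML file
#'
#' Unknown keys are errors (this catches threshold typos); keys left out
#' take their defaults.
#'
#' @param path YAML file with a flat key-value mapping.
#' @return A validated `RunConfig`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (!is.list(user)) .stopf("config must be a flat key-value mapping: %s", path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    .stopf("unknown config key: '%s'", unknown[1])
  }
  cfg[names(user)] <- user
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param config a `RunConfig` list.
#' @return The config, invisibly usable, after checks; errors describe the
#'   offending key.
#' @export
validate_run_config <- function(config) {
  ref <- default_run_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) .stopf("unknown config key: '%s'", unknown[1])
  num_keys <- c("seed", "min_width", "chip_rpk", "rna_rpk", "lfc", "fdr",
                "window", "bin", "pseudocount", "n_enhancers",
                "sensitive_fraction", "depletion", "enrichment",
                "rna_enrichment", "background_density", "mix_ratio",
                "depth_jitter")
  for (k in num_keys) {
    if (!is.numeric(config[[k]]) || length(config[[k]]) != 1 ||
        !is.finite(config[[k]])) {
      .stopf("config key '%s' must be a single finite number", k)
    }
  }
  if (!config$normalization %in% c("spike", "depth", "none")) {
    .stopf("config key 'normalization' must be spike, depth or none")
  }
  if (!isTRUE(config$synthetic) && !isFALSE(config$synthetic)) {
    .stopf("config key 'synthetic' must be TRUE or FALSE")
  }
  if (!config$synthetic) {
    for (k in c("loci", "tss", "chrom_sizes")) {
      if (is.null(config[[k]])) .stopf("config key '%s' is required when synthetic = FALSE", k)
      if (!file.exists(config[[k]])) .stopf("config key '%s': file not found: %s", k, config[[k]])
    }
    pairs <- list(c("reads_chip_treatment", "reads_chip_control"),
                  c("reads_rna_treatment", "reads_rna_control"))
    for (p in pairs) {
      if (!is.null(config[[p[1]]]) && is.null(config[[p[2]]])) {
        .stopf("config key '%s' is set but its control '%s' is missing",
               p[1], p[2])
      }
    }
    for (k in c("reads_chip_control", "reads_chip_treatment",
                "reads_rna_control", "reads_rna_treatment",
                "peaks", "de_table")) {
      if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
        .stopf("config key '%s': file not found: %s", k, config[[k]])
      }
    }
  }
  structure(config, class = "RunConfig")
}

#' Deterministic hash of a run configuration
#'
#' MD5 of the canonical `key=value` serialization; embedded in every output
#' header so results can be traced to their exact settings.
#'
#' @param config a `RunConfig`.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  keys <- sort(names(config))
  vals <- vapply(config[keys], function(v) {
    if (is.null(v)) "NULL" else paste(format(v, digits = 15), collapse = ",")
  }, character(1))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste0(keys, "=", vals), tmp)
  unname(md5sum(tmp))
}

.read_reads_any <- function(path, sample_id, spike_prefix) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    read_reads_sam(path, sample_id, spike_prefix = spike_prefix)
  } else {
    read_reads_bed(path, sample_id, spike_prefix = spike_prefix)
  }
}

#' Run the full enhancer analysis pipeline
#'
#' Executes the stages in order -- simulate/ingest, normalize, quantify,
#' low-signal filter, fold change, sensitivity classification, peak overlap
#' and intensity correlation, group tests -- and writes TSV/JSON outputs to
#' `out_dir`. Every output embeds the config hash, seed and package version;
#' rerunning with an identical config reproduces byte-identical outputs.
#'
#' @param config a `RunConfig` (see [default_run_config()],
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results: `loci`,
#'   `norm`, `chip_table`, `rna_table`, `chip_fc`, `rna_fc`, `call`,
#'   `overlaps`, `correlation`, `tests`, `summary`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  hdr <- c(config_hash = config_hash(config),
           seed = format(seed),
           enhancerx_version = as.character(utils::packageVersion("enhancerx")))

  ## ---- stage: simulate / ingest -------------------------------------
  ann <- NULL
  if (config$synthetic) {
    cfg <- sim_config(seed = seed,
                      n_enhancers = config$n_enhancers,
                      sensitive_fraction = config$sensitive_fraction,
                      depletion = config$depletion,
                      enrichment = config$enrichment,
                      rna_enrichment = config$rna_enrichment,
                      background_density = config$background_density,
                      mix_ratio = config$mix_ratio,
                      depth_jitter = config$depth_jitter,
                      spike_prefix = config$spike_prefix)
    ann <- generate_annotation(cfg)
    loci0 <- ann$loci
    tss <- ann$tss
    chrom_sizes <- ann$chrom_sizes
    chip <- list(
      simulate_reads(cfg, ann, "control", "chip_control", seed = seed + 101),
      simulate_reads(cfg, ann, "treatment", "chip_treatment", seed = seed + 102))
    rna <- list(
      simulate_reads(cfg, ann, "control", "rna_control", seed = seed + 103,
                     enrichment = cfg$rna_enrichment),
      simulate_reads(cfg, ann, "treatment", "rna_treatment", seed = seed + 104,
                     enrichment = cfg$rna_enrichment))
    cofactor <- simulate_reads(cfg, ann, "control", "cofactor_chip",
                               seed = seed + 105)
    de <- simulate_de_table(cfg, ann, seed = seed + 106)
    peak_sets <- lapply(seq_along(cfg$peak_coverage), function(i) {
      simulate_peaks(cfg, ann, names(cfg$peak_coverage)[i],
                     seed = seed + 110 + i)
    })
    names(peak_sets) <- names(cfg$peak_coverage)
    write_annotation(ann, out_dir)
  } else {
    chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
    loci0 <- read_bed(config$loci, chrom_sizes)
    tss <- read_tss_bed(config$tss)
    chip <- rna <- NULL
    if (!is.null(config$reads_chip_control)) {
      chip <- list(
        .read_reads_any(config$reads_chip_control, "chip_control",
                        config$spike_prefix),
        .read_reads_any(config$reads_chip_treatment, "chip_treatment",
                        config$spike_prefix))
    }
    if (!is.null(config$reads_rna_control)) {
      rna <- list(
        .read_reads_any(config$reads_rna_control, "rna_control",
                        config$spike_prefix),
        .read_reads_any(config$reads_rna_treatment, "rna_treatment",
                        config$spike_prefix))
    }
    cofactor <- NULL
    de <- if (!is.null(config$de_table)) read_de_table(config$de_table)
    peak_sets <- if (!is.null(config$peaks)) {
      list(peaks = read_narrowpeak(config$peaks))
    }
  }

  ## ---- stage: regions (extend + link) -------------------------------
  loci <- extend_to_min_width(loci0, config$min_width, chrom_sizes)
  loci <- link_to_nearest_tss(loci, tss)
  write_loci_bed(loci, file.path(out_dir, "loci_linked.bed"))

  ## ---- stage: normalize ---------------------------------------------
  norm <- NULL
  if (!is.null(chip) && config$normalization != "none") {
    norm <- compute_norm_factors(chip, mode = config$normalization)
    write_norm_factors(norm, file.path(out_dir, "norm_factors.tsv"), hdr)
  }

  ## ---- stage: quantify / filter / fold change -----------------------
  chip_table <- rna_table <- chip_fc <- rna_fc <- NULL
  if (!is.null(chip)) {
    chip_table <- build_signal_table(chip, loci, norm = norm, assay = "chip",
                                     seed = seed + 201)
    write_signal_table(chip_table, file.path(out_dir, "chip_signal.tsv"), hdr)
    chip_fc <- fold_change(chip_table, "chip_control", "chip_treatment",
                           pseudocount = config$pseudocount,
                           threshold = config$chip_rpk)
    .write_tsv(chip_fc, file.path(out_dir, "chip_fold_change.tsv"),
               c(hdr, threshold_rpk = format(config$chip_rpk),
                 pseudocount = format(config$pseudocount)))
    tornado <- signal_matrix(chip[[1]], loci, window = config$window,
                             bin = config$bin)
    .write_tsv(data.frame(locus_id = rownames(tornado), tornado,
                          check.names = FALSE),
               file.path(out_dir, "chip_tornado_matrix.tsv"), hdr)
  }
  if (!is.null(rna)) {
    rna_norm <- compute_norm_factors(rna, mode = "depth")
    rna_table <- build_signal_table(rna, loci, norm = rna_norm, assay = "rna",
                                    seed = seed + 202)
    write_signal_table(rna_table, file.path(out_dir, "rna_signal.tsv"), hdr)
    rna_fc <- fold_change(rna_table, "rna_control", "rna_treatment",
                          pseudocount = config$pseudocount,
                          threshold = config$rna_rpk)
    .write_tsv(rna_fc, file.path(out_dir, "rna_fold_change.tsv"),
               c(hdr, threshold_rpk = format(config$rna_rpk),
                 pseudocount = format(config$pseudocount)))
  }

  ## ---- stage: classify ----------------------------------------------
  call <- NULL
  if (!is.null(de)) {
    down <- call_downregulated(de, lfc_max = config$lfc, fdr_max = config$fdr)
    call <- suppressWarnings(call_sensitive(loci, down, system = "degron"))
    write_sensitivity_call(call, loci, out_dir, hdr)
  }

  ## ---- stage: peak overlap + intensity correlation ------------------
  overlaps <- correlation <- NULL
  if (!is.null(peak_sets)) {
    ov <- lapply(names(peak_sets), function(f) {
      overlap_fraction(loci, peak_sets[[f]], factor = f)
    })
    overlaps <- do.call(rbind, lapply(ov, `[[`, "summary"))
    .write_tsv(overlaps, file.path(out_dir, "peak_overlaps.tsv"), hdr)
  }
  if (!is.null(chip) && !is.null(cofactor)) {
    pair_table <- build_signal_table(c(chip[1], list(cofactor)), loci,
                                     assay = "chip")
    correlation <- intensity_correlation(pair_table, "chip_control",
                                         "cofactor_chip")
    .write_tsv(data.frame(factor_a = "chip_control",
                          factor_b = "cofactor_chip",
                          r_squared = correlation$r_squared,
                          n = correlation$n,
                          log_transform = correlation$log_transform),
               file.path(out_dir, "intensity_correlation.tsv"), hdr)
  }

  ## ---- stage: group tests -------------------------------------------
  tests <- list()
  if (!is.null(chip_fc) && !is.null(call)) {
    sens <- chip_fc$locus_id %in% call$sensitive_enhancers
    ok <- chip_fc$passed_filter
    if (any(sens & ok) && any(!sens & ok)) {
      tests$chip_rpk_sensitive <- mann_whitney_u(
        chip_table$values[sens & ok, "chip_treatment"],
        chip_table$values[sens & ok, "chip_control"])
      tests$chip_lfc_sensitive_vs_other <- kruskal_wallis(
        list(other = chip_fc$log2fc[!sens & ok],
             sensitive = chip_fc$log2fc[sens & ok]))
    }
  }
  if (!is.null(rna_fc) && !is.null(call)) {
    sens <- rna_fc$locus_id %in% call$sensitive_enhancers
    ok <- rna_fc$passed_filter
    if (any(sens & ok) && any(!sens & ok)) {
      tests$erna_lfc_sensitive_vs_other <- kruskal_wallis(
        list(other = rna_fc$log2fc[!sens & ok],
             sensitive = rna_fc$log2fc[sens & ok]))
    }
  }
  if (length(tests)) {
    .write_tsv(data.frame(
      comparison = names(tests),
      method = vapply(tests, `[[`, character(1), "method"),
      statistic = vapply(tests, `[[`, numeric(1), "statistic"),
      p_value = vapply(tests, `[[`, numeric(1), "p_value")),
      file.path(out_dir, "group_tests.tsv"), hdr)
  }

  ## ---- summary -------------------------------------------------------
  summary <- list(config_hash = unname(hdr[["config_hash"]]),
                  seed = seed,
                  n_loci = length(loci))
  if (!is.null(call)) {
    summary$n_down_genes <- length(call$down_genes)
    summary$n_sensitive_genes <- length(call$sensitive_genes)
    summary$n_sensitive_enhancers <- length(call$sensitive_enhancers)
  }
  if (!is.null(ann) && !is.null(call)) {
    tp <- length(intersect(call$sensitive_enhancers, ann$sensitive_enhancers))
    summary$sensitivity_precision <-
      if (length(call$sensitive_enhancers)) tp / length(call$sensitive_enhancers) else NA
    summary$sensitivity_recall <-
      if (length(ann$sensitive_enhancers)) tp / length(ann$sensitive_enhancers) else NA
  }
  if (!is.null(overlaps)) {
    summary$peak_overlap_fraction <- as.list(
      setNames(overlaps$fraction, overlaps$factor))
  }
  if (!is.null(correlation)) summary$cofactor_r_squared <- correlation$r_squared
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(config = config, loci = loci, norm = norm,
                 chip_table = chip_table, rna_table = rna_table,
                 chip_fc = chip_fc, rna_fc = rna_fc, call = call,
                 overlaps = overlaps, correlation = correlation,
                 tests = tests, summary = summary, annotation = ann))
}
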