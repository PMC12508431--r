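## internal helpers shared across modules

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

## Run `fn()` with a locally seeded RNG, restoring the caller's RNG state.
## All stochastic operations in the package go through this so that a given
## (input, seed) pair is bit-reproducible and never perturbs the session RNG.
.with_seed <- function(seed, fn) {
  if (!.is_count(seed) || seed >= 2^31) {
    .stopf("seed must be a single non-negative integer < 2^31, got %s",
           deparse(seed))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

## strictly-integer coordinate strings ("-" not allowed mid-token)
.is_int_string <- function(x) grepl("^-?[0-9]+$", x)

## chromosome name of a GRanges as plain character
.chr <- function(gr) as.character(GenomicRanges::seqnames(gr))

## Write a data.frame as TSV with optional "# key: value" comment header.
## Used by every module writer so outputs are byte-stable across reruns.
.write_tsv <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) {
    writeLines(paste0("# ", names(header), ": ", unname(header)), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}
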