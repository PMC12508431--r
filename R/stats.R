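## Nonparametric group tests and Bliss drug-synergy scoring.
##
## The rank tests delegate to the reference routines in the stats package;
## the wrappers fix the small-sample policy (exact enumeration only for
## combined n <= 12 with no ties, otherwise the tie- and continuity-corrected
## normal approximation) and return a uniform TestResult structure.

.test_result <- function(statistic, p_value, method, n, two_sided = TRUE) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, n = n, two_sided = two_sided),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %g (n = %s, %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n, collapse = "/"),
              if (x$two_sided) "two-sided" else "one-sided"))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from midranks. The p value uses exact enumeration when the
#' combined sample size is at most 12 and there are no ties, and otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param two_sided two-sided test (default TRUE).
#' @return A `TestResult` with the U statistic for `x` relative to `y`.
#' @export
mann_whitney_u <- function(x, y, two_sided = TRUE) {
  if (!length(x) || !length(y)) .stopf("both samples must be non-empty")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))                       # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (nx + ny) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y,
                alternative = if (two_sided) "two.sided" else "less",
                exact = exact, correct = TRUE)
  )
  .test_result(u, min(wt$p.value, 1),
               if (exact) "Mann-Whitney U (exact)"
               else "Mann-Whitney U (normal approximation)",
               c(nx, ny), two_sided)
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with tie correction; p from the chi-squared distribution with
#' k - 1 degrees of freedom. When every observation is identical the test is
#' degenerate and `H = 0`, `p = 1` is returned.
#'
#' @param groups list of numeric samples (>= 2 groups, each non-empty).
#' @return A `TestResult`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) .stopf("all groups must be non-empty")
  all_obs <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  if (length(unique(all_obs)) == 1) {
    return(.test_result(0, 1, "Kruskal-Wallis", n))
  }
  kt <- kruskal.test(groups)
  .test_result(kt$statistic, kt$p.value, "Kruskal-Wallis", n)
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return R-squared in `[0, 1]`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 3) .stopf("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    .stopf("correlation undefined: zero variance in one of the inputs")
  }
  cor(x, y)^2
}

#' Bliss synergy scores for a dose-response grid
#'
#' The grid holds observed fractional inhibitions in `[0, 1]` indexed by
#' (dose of drug A, dose of drug B), including the single-agent margins at
#' dose 0. For every combination the Bliss independence expectation is
#' `E_a + E_b - E_a * E_b`; the synergy score is
#' `(observed - expected) * 100` (percentage points, the SynergyFinder
#' convention), and the mean score over all dose pairs is also reported.
#'
#' @param grid numeric matrix; rownames are doses of drug A and colnames
#'   doses of drug B, each including `"0"`.
#' @param clip clip inhibitions into `[0, 1]` instead of erroring (default
#'   FALSE).
#' @return List with `scores` (matrix over the nonzero dose pairs),
#'   `mean_score`, and `expected` (the Bliss expectation matrix).
#' @export
bliss_synergy <- function(grid, clip = FALSE) {
  stopifnot(is.matrix(grid), !is.null(rownames(grid)), !is.null(colnames(grid)))
  da <- suppressWarnings(as.numeric(rownames(grid)))
  db <- suppressWarnings(as.numeric(colnames(grid)))
  if (anyNA(da) || anyNA(db)) .stopf("grid dimnames must be numeric doses")
  if (!any(da == 0) || !any(db == 0)) {
    .stopf("grid must include single-agent margins at dose 0")
  }
  if (any(grid < 0 | grid > 1)) {
    if (clip) grid <- pmin(pmax(grid, 0), 1)
    else .stopf("inhibition values must lie in [0, 1] (set clip = TRUE to clip)")
  }
  ia <- which(da > 0)
  ib <- which(db > 0)
  e_a <- grid[ia, which(db == 0)[1]]
  e_b <- grid[which(da == 0)[1], ib]
  expected <- outer(e_a, e_b, function(a, b) a + b - a * b)
  obs <- grid[ia, ib, drop = FALSE]
  scores <- (obs - expected) * 100
  dimnames(scores) <- list(rownames(grid)[ia], colnames(grid)[ib])
  dimnames(expected) <- dimnames(scores)
  list(scores = scores, mean_score = mean(scores), expected = expected)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment; a convenience for per-feature
#' testing layered on top of the pipeline (the pipeline itself tests groups
#' of loci once per comparison).
#'
#' @param pvalues numeric vector of p values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    .stopf("p values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Read a dose grid from TSV (dose labels in first row and column)
#' @param path TSV file.
#' @return Numeric matrix with dose dimnames.
#' @export
read_dose_grid <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   row.names = 1, comment.char = "#")
  as.matrix(df)
}

#' Write a dose grid as TSV
#' @param grid numeric matrix with dose dimnames.
#' @param path output path.
#' @export
write_dose_grid <- function(grid, path) {
  df <- data.frame(dose_a = rownames(grid), grid, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
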