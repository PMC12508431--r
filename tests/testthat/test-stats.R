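test_that("Mann-Whitney exact p matches exhaustive enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)   # 2 of the C(6,3)=20 assignments as extreme
  expect_match(res$method, "exact")
  set.seed(21)
  for (rep in 1:40) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    if (nx + ny > 12) next
    v <- sample(1000, nx + ny)   # tieless
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mwu_exact_p(x, y))
  }
})

test_that("Mann-Whitney is symmetric in its arguments", {
  set.seed(4)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_equal(b$statistic, length(x) * length(y) - a$statistic)
  ident <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_gte(ident$p_value, 0.99)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("exact and normal-approximation Mann-Whitney p agree closely", {
  set.seed(31)
  worst <- 0
  for (rep in 1:300) {
    v <- sample(1e6, 12)
    x <- v[1:6]; y <- v[7:12]
    p_exact <- mann_whitney_u(x, y)$p_value
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    worst <- max(worst, abs(p_exact - wt$p.value))
  }
  expect_lt(worst, 0.03)
})

test_that("Kruskal-Wallis handles ties, degenerate input, and known H", {
  ident <- kruskal_wallis(list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  # H = 12/(N(N+1)) * sum n_i (rbar_i - (N+1)/2)^2 = 7.2 for 1:3, 4:6, 7:9
  res <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(res$statistic, 7.2)
  expect_error(kruskal_wallis(list(1:3)), "2")
  expect_error(kruskal_wallis(list(1:3, numeric())), "non-empty")
})

test_that("two-group Kruskal-Wallis tracks the Mann-Whitney approximation", {
  set.seed(77)
  for (rep in 1:30) {
    x <- rnorm(25); y <- rnorm(25, runif(1, -1, 1))
    p_kw <- kruskal_wallis(list(x, y))$p_value
    p_mwu <- mann_whitney_u(x, y)$p_value
    expect_lt(abs(p_kw - p_mwu), 0.02)
  }
})

test_that("pearson_r2 validates its input", {
  expect_equal(pearson_r2(1:10, 2 * (1:10)), 1)
  expect_equal(pearson_r2(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.36)
  expect_error(pearson_r2(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r2(1:2, 1:2), "at least 3")
})

bliss_grid <- function(obs = NULL) {
  g <- matrix(c(0, 0.5, 0.5, 0.75), 2, 2,
              dimnames = list(c("0", "1"), c("0", "1")))
  if (!is.null(obs)) g["1", "1"] <- obs
  g
}

test_that("Bliss scores are observed minus independence, in points", {
  expect_equal(unname(bliss_synergy(bliss_grid(0.75))$scores[1, 1]), 0)
  expect_equal(unname(bliss_synergy(bliss_grid(0.85))$scores[1, 1]), 10)
  expect_equal(unname(bliss_synergy(bliss_grid(0.70))$scores[1, 1]), -5)
  # any grid equal to the independence surface scores 0 everywhere
  g <- simulate_dose_grid(synergy = 0)
  s <- bliss_synergy(g)
  expect_true(all(abs(s$scores) < 1e-12))
  expect_equal(s$mean_score, 0)
})

test_that("Bliss input validation catches bad grids", {
  g <- bliss_grid(1.2)
  expect_error(bliss_synergy(g), "\\[0, 1\\]")
  clipped <- bliss_synergy(g, clip = TRUE)
  expect_equal(unname(clipped$scores[1, 1]), 25)  # clipped to 1.0
  nomargin <- matrix(0.5, 2, 2, dimnames = list(c("1", "2"), c("1", "2")))
  expect_error(bliss_synergy(nomargin), "dose 0")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone after sorting
})

test_that("dose grids round-trip through TSV", {
  g <- simulate_dose_grid(synergy = 5)
  path <- withr::local_tempfile()
  write_dose_grid(g, path)
  back <- read_dose_grid(path)
  expect_equal(unname(back), unname(g), tolerance = 1e-12)
  expect_equal(bliss_synergy(back)$mean_score, 5, tolerance = 1e-9)
})
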