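make_matrix <- function(values, m, n) {
  matrix(values, m, n, dimnames = list(sprintf("s%02d", seq_len(m)),
                                       sprintf("g%02d", seq_len(n))))
}

test_that("drop_missing_genes removes exactly the genes with missing cells", {
  m <- make_matrix(rnorm(9), 3, 3)
  expect_equal(drop_missing_genes(m), m)
  m[2, "g02"] <- NA
  out <- drop_missing_genes(m)
  expect_equal(colnames(out), c("g01", "g03"))
  expect_equal(nrow(out), 3L)

  big <- withr::with_seed(11, make_matrix(rnorm(20 * 50), 20, 50))
  holes <- withr::with_seed(12, sample(50, 10))
  for (j in holes) big[sample(20, 1), j] <- NA
  expect_equal(ncol(drop_missing_genes(big)), 40L)

  all_na <- make_matrix(NA_real_, 2, 2)
  expect_error(drop_missing_genes(all_na), "all 2 genes")
})

test_that("select_top_genes ranks by variance or an external score", {
  m <- make_matrix(0, 4, 5)
  for (j in 1:5) m[, j] <- (5 - j) * c(-1, 1, -1, 1)  # variances desc by j
  vars <- apply(m, 2, var)
  expect_equal(unname(vars), sort(unname(vars), decreasing = TRUE))
  expect_equal(colnames(select_top_genes(m, 2)), c("g01", "g02"))
  # all genes kept but reordered by score
  expect_equal(colnames(select_top_genes(m, 5)), colnames(m))
  # external ranking overrides variance
  rk <- setNames(1:5, colnames(m))  # reverses the variance order
  expect_equal(colnames(select_top_genes(m, 1, rk)), "g05")
  expect_error(select_top_genes(m, 1, rk[-1]), "missing scores.*g01")
  expect_error(select_top_genes(m, 6), "exceeds")
})

test_that("zscore discretization flags outliers and passes through binaries", {
  one_out <- make_matrix(c(0, 0, 0, 0, 10), 5, 1)
  b <- discretize(one_out, discretization_spec("zscore", 1.5, "both"))
  expect_equal(unname(b[, 1]), c(0L, 0L, 0L, 0L, 1L))
  # already-binary matrix passes through under a fixed 0.5 cut
  tb <- toy_matrix() * 1.0
  expect_equal(discretize(tb, discretization_spec("fixed", 0.5, "up")),
               toy_matrix())
  # constant gene: all zero plus warning
  const <- make_matrix(c(1, 1, 1, 1, rnorm(4)), 4, 2)
  expect_warning(bc <- discretize(const, discretization_spec("zscore")),
                 "constant gene")
  expect_equal(unname(bc[, 1]), rep(0L, 4))
})

test_that("each method marks the documented samples", {
  x <- make_matrix(c(1, 2, 3, 4, 100, -50, 5, 6, 7, 8), 10, 1)
  # mean_sd: mean 8.6, sd ~ 36.5 -> only the extremes pass 1 sd
  b <- discretize(x, discretization_spec("mean_sd", 1, "both"))
  expect_equal(which(b[, 1] == 1L), c(s05 = 5L, s06 = 6L))
  # fixed, both: |value| > 7
  b <- discretize(x, discretization_spec("fixed", 7, "both"))
  expect_equal(unname(b[, 1]), as.integer(abs(x[, 1]) > 7))
  # quantile 0.2 strict: below the 20% and above the 80% empirical quantile
  q <- quantile(x[, 1], c(0.2, 0.8), names = FALSE)
  b <- discretize(x, discretization_spec("quantile", 0.2, "both"))
  expect_equal(unname(b[, 1]), as.integer(x[, 1] < q[1] | x[, 1] > q[2]))
  # top_fraction 0.2 of 10 samples: the 2 largest |value - median|
  b <- discretize(x, discretization_spec("top_fraction", 0.2, "both"))
  expect_equal(sum(b), 2)
  expect_equal(which(b[, 1] == 1L), c(s05 = 5L, s06 = 6L))
})

test_that("direction=up OR direction=down equals direction=both, all methods", {
  m <- withr::with_seed(5, make_matrix(rnorm(30 * 6), 30, 6))
  for (method in c("zscore", "quantile", "top_fraction", "mean_sd", "fixed")) {
    thr <- switch(method, zscore = 1.5, mean_sd = 1.5,
                  quantile = 0.1, top_fraction = 0.1, fixed = 1)
    both <- discretize(m, discretization_spec(method, thr, "both"))
    up <- discretize(m, discretization_spec(method, thr, "up"))
    down <- discretize(m, discretization_spec(method, thr, "down"))
    expect_equal(pmax(up, down), both, info = method)
    expect_equal(sum(up * down), 0, info = method)  # sides are disjoint
  }
})

test_that("discretization commutes with gene permutation", {
  m <- withr::with_seed(6, make_matrix(rnorm(20 * 8), 20, 8))
  perm <- withr::with_seed(7, sample(8))
  spec <- discretization_spec("quantile", 0.15, "both")
  expect_equal(discretize(m[, perm], spec), discretize(m, spec)[, perm])
})

test_that("top_fraction hits the requested fraction within one sample", {
  m <- withr::with_seed(8, make_matrix(rnorm(40 * 5), 40, 5))
  for (f in c(0.05, 0.1, 0.25)) {
    b <- discretize(m, discretization_spec("top_fraction", f, "both"))
    expect_true(all(abs(colSums(b) - f * 40) <= 1))
  }
})

test_that("invalid discretization specs are rejected", {
  expect_error(discretization_spec("zscore", -1), "positive")
  expect_error(discretization_spec("quantile", 0.7), "0, 0.5")
  expect_error(discretization_spec("top_fraction", 0), "0, 0.5")
  m <- make_matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(discretize(m, discretization_spec("zscore")), "missing values")
})
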