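test_that("sample partition matches the worked example and edge cases", {
  b <- toy_matrix()
  p <- partition_samples("NEK2", "CDKN3", b)
  expect_equal(p$both_one, c("TCGA-2H-A9GF-01", "TCGA-2H-A9GH-01",
                             "TCGA-2H-A9GI-01"))
  expect_equal(p$both_zero, c("TCGA-2H-A9GG-01", "TCGA-2H-A9GJ-01"))
  expect_equal(p$inconsistent, character(0))
  expect_setequal(c(p$both_one, p$both_zero, p$inconsistent), rownames(b))

  ones <- matrix(1L, 4, 2, dimnames = list(paste0("s", 1:4), c("A", "C")))
  p <- partition_samples("A", "C", ones)
  expect_equal(p$both_one, paste0("s", 1:4))
  expect_length(p$inconsistent, 0L)
  comp <- cbind(A = c(1L, 0L, 1L, 0L), C = c(0L, 1L, 0L, 1L))
  rownames(comp) <- paste0("s", 1:4)
  expect_equal(partition_samples("A", "C", comp)$inconsistent, paste0("s", 1:4))
  expect_error(partition_samples("A", "nope", comp), "nope")
})

test_that("correlation p-values match the closed-form t-test and clamp", {
  # perfect correlation clamps to the 1e-300 floor
  expect_equal(correlation_pvalue(1:5, 2 * (1:5)), 1e-300)
  # degenerate sizes and constant vectors return 1
  expect_equal(correlation_pvalue(c(1, 2), c(3, 4)), 1)
  expect_equal(correlation_pvalue(rep(1, 5), rnorm(5)), 1)
  expect_error(correlation_pvalue(1:4, 1:5), "same length")
  # independent closed form: t = r * sqrt((n-2)/(1-r^2)), two-sided on n-2 df
  x <- c(1, 2, 3, 4, 5, 6); y <- c(2, 1, 4, 3, 6, 5)
  r <- cor(x, y)
  t_stat <- r * sqrt((6 - 2) / (1 - r^2))
  expect_equal(correlation_pvalue(x, y),
               2 * pt(abs(t_stat), df = 4, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("lamda3 equals an independent transcription of its formula", {
  for (seed in 1:30) {
    mats <- random_cont_bin(30, 8, seed)
    genes <- colnames(mats$cont)
    pairs <- expand.grid(a = genes[1:4], c = genes[5:8],
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(pairs))) {
      got <- lamda3_score(pairs$a[i], pairs$c[i], mats$cont, mats$bin)$value
      want <- oracle_lamda3(pairs$a[i], pairs$c[i], mats$cont, mats$bin)
      expect_equal(got, want, tolerance = 1e-10,
                   info = sprintf("seed %d pair %s=>%s", seed,
                                  pairs$a[i], pairs$c[i]))
    }
  }
})

test_that("numerator equal to the background median gives exactly 1", {
  # background genes are copies of C, so every background p equals the
  # rule-pair p in both partitions and the ratio is 1 by construction
  m <- 40
  withr::with_seed(301, {
    a_vals <- rnorm(m); c_vals <- 0.6 * a_vals + rnorm(m, sd = 0.5)
  })
  cont <- cbind(A = a_vals, C = c_vals, B1 = c_vals, B2 = c_vals,
                B3 = c_vals, B4 = c_vals)
  rownames(cont) <- sprintf("s%02d", 1:m)
  bin <- matrix(0L, m, 6, dimnames = dimnames(cont))
  bin[1:20, ] <- 1L  # both-one = s01-s20, both-zero = s21-s40
  bd <- lamda3_score("A", "C", cont, bin)
  expect_identical(bd$value, 1)
  expect_equal(bd$p2_bg, bd$p2_ac)
  expect_equal(bd$p0_bg, bd$p0_ac)
})

test_that("degenerate partitions and flat backgrounds return NA", {
  # toy matrix as continuous input: both_zero has 2 < 3 samples
  tb <- toy_matrix()
  expect_true(is.na(lamda3_score("NEK2", "CDKN3", tb * 1.0, tb)$value))
  # both background medians 1 (constant background) -> zero denominator
  m <- 12
  cont <- cbind(A = rnorm(m), C = rnorm(m), B1 = rep(1, m), B2 = rep(2, m))
  rownames(cont) <- sprintf("s%02d", 1:m)
  bin <- matrix(0L, m, 4, dimnames = dimnames(cont))
  bin[1:6, c("A", "C")] <- 1L
  expect_true(is.na(lamda3_score("A", "C", cont, bin)$value))
  # no background gene at all
  two <- cont[, c("A", "C")]
  expect_true(is.na(lamda3_score("A", "C", two, bin[, c("A", "C")])$value))
})

test_that("lamda3 is invariant to sample order and per-gene rescaling", {
  sim <- generate_single_omics(m = 50, n = 10, seed = 77)
  base <- lamda3_score("A1", "C1", sim$continuous, sim$binary)$value
  perm <- withr::with_seed(78, sample(nrow(sim$continuous)))
  expect_equal(lamda3_score("A1", "C1", sim$continuous[perm, ],
                            sim$binary[perm, ])$value,
               base, tolerance = 1e-12)
  scaled <- sweep(sim$continuous, 2, seq_len(ncol(sim$continuous)), `*`)
  expect_equal(lamda3_score("A1", "C1", scaled, sim$binary)$value,
               base, tolerance = 1e-10)
})

test_that("multi-gene rules aggregate pairwise scores by the median", {
  sim <- generate_single_omics(m = 60, n = 12, planted = 2, seed = 55)
  with2 <- lamda3_score(c("A1", "A2"), "C1", sim$continuous, sim$binary)
  p1 <- lamda3_score("A1", "C1", sim$continuous, sim$binary)$value
  p2 <- lamda3_score("A2", "C1", sim$continuous, sim$binary)$value
  expect_equal(with2$value, median(c(p1, p2)), tolerance = 1e-12)
  expect_equal(with2$n_pairs, 2L)
})

test_that("wcs reduces to support under unit weights and scales by weights", {
  b <- toy_matrix()
  rules <- mine_rules(b, 0.6, 0.8)
  for (i in seq_len(nrow(rules))) {
    expect_equal(wcs_score(rules$lhs[[i]], rules$rhs[[i]], b),
                 rules$support[i], tolerance = 1e-12)
  }
  w <- c(NEK2 = 1.0, CDKN3 = 0.5)
  expect_equal(wcs_score("NEK2", "CDKN3", b, w), 0.6 * 0.75)
  # zero-support rule (never emitted by the miner, direct call) scores 0
  disj <- cbind(P = c(1L, 1L, 0L, 0L), Q = c(0L, 0L, 1L, 1L))
  rownames(disj) <- paste0("s", 1:4)
  expect_equal(wcs_score("P", "Q", disj), 0)
  expect_error(wcs_score("NEK2", "CDKN3", b, c(NEK2 = 1)), "missing weight")
  # rank weights: top gene 1, linear decay to 1/n
  rw <- rank_weights(c("a", "b", "c", "d"))
  expect_equal(unname(rw), c(4, 3, 2, 1) / 4)
})

test_that("rank_rules orders by the measure with NA last and fixed ties", {
  rules <- rule_set(list("A", "B", "C"), list("X", "Y", "Z"),
                    support = c(0.5, 0.4, 0.6),
                    confidence = 1, lift = c(2, 3, 1))
  rules$lamda3 <- c(2.0, NA, 1.1)
  top2 <- rank_rules(rules, "lamda3", 2)
  expect_equal(unlist(top2$lhs), c("A", "C"))
  # ties on the measure fall back to lift desc then support desc
  tied <- rule_set(list("A", "B", "C"), list("X", "Y", "Z"),
                   support = c(0.4, 0.4, 0.6), confidence = 1,
                   lift = c(1, 3, 3))
  ranked <- rank_rules(tied, "support", 3)
  expect_equal(unlist(ranked$lhs), c("C", "B", "A"))
  expect_equal(nrow(rank_rules(tied, "support", 1)), 1L)
  # worked example: all 12 rules tie on support; order is the documented one
  b <- toy_matrix()
  rules12 <- mine_rules(b, 0.6, 0.8, max_rhs = 2)
  ranked12 <- rank_rules(rules12, "support", 20)
  expect_equal(nrow(ranked12), 12L)
  lhs_key <- vapply(ranked12$lhs, paste, "", collapse = ",")
  rhs_key <- vapply(ranked12$rhs, paste, "", collapse = ",")
  expect_equal(order(lhs_key, rhs_key), seq_len(12L))
})

test_that("score_rules fills both measures for a mined rule set", {
  sim <- generate_single_omics(m = 60, n = 10, seed = 8)
  rules <- score_rules(mine_rules(sim$binary, 0.3, 0.8),
                       sim$continuous, sim$binary)
  expect_true(all(!is.na(rules$wcs)))
  expect_equal(rules$wcs, rules$support, tolerance = 1e-12)
  expect_true(any(!is.na(rules$lamda3)))
})
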