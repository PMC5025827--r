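test_that("Fisher's exact test reproduces the worked tables", {
  expect_equal(signif(fisher_exact_2x2(25, 3389, 22, 5700), 3), 0.0332)
  expect_equal(signif(fisher_exact_2x2(25, 10, 22, 89), 2), 3.9e-8)
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_2x2(10, 90, 10, 90), 1)
})

test_that("Fisher test is symmetric and validates input", {
  set.seed(4)
  for (i in 1:10) {
    t <- sample(1:30, 4, replace = TRUE)
    p <- fisher_exact_2x2(t[1], t[2], t[3], t[4])
    expect_equal(fisher_exact_2x2(t[3], t[4], t[1], t[2]), p)  # row swap
    expect_equal(fisher_exact_2x2(t[2], t[1], t[4], t[3]), p)  # col swap
    expect_equal(p, stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "negative")
  expect_warning(fisher_exact_2x2(0, 0, 3, 4), "degenerate")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.123), 0.123)
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))
  expect_equal(bh_qvalues(numeric(0)), numeric(0))
  # monotone: raising one p never lowers any q
  p <- c(0.001, 0.01, 0.2, 0.5)
  q1 <- bh_qvalues(p)
  p2 <- p; p2[2] <- 0.05
  expect_true(all(bh_qvalues(p2) >= q1 - 1e-12))
})

test_that("bootstrap majority test behaves at the extremes and is seeded", {
  taxa <- c("t1", "t2")
  tok <- cbind(matrix("1", 2, 5), matrix("0", 2, 5))
  rownames(tok) <- taxa
  m <- character_matrix(tok, type = rep(c("morphological", "molecular"),
                                        each = 5),
                        alphabet = c("0", "1"))
  # units: one unit comparing mean state index; morph all "1" >> mol all "0"
  analysis <- function(mm) {
    mean(mm$state[1, mm$type == "morphological"]) <
      mean(mm$state[1, mm$type == "molecular"])
  }
  r <- bootstrap_majority_test(m, analysis, B = 50, seed = 1)
  expect_equal(r$P, 0)
  expect_error(bootstrap_majority_test(m, analysis, B = 0), "B must be")
  b1 <- bootstrap_majority_test(m, analysis, B = 1, seed = 5)
  expect_true(b1$P %in% c(0, 1))
  # identically distributed types: P has mean 0.5 by exchangeability
  # (for any one data realisation the bootstrap replicates correlate
  # through the data, so average over independent realisations)
  analysis2 <- function(mm) {
    im <- mm$type == "morphological"
    mean(mm$state[1, im]) < mean(mm$state[1, !im])
  }
  set.seed(42)
  ps <- replicate(12, {
    tok2 <- matrix(sample(c("0", "1"), 2 * 400, replace = TRUE), 2, 400)
    rownames(tok2) <- taxa
    m2 <- character_matrix(tok2, type = rep(c("morphological", "molecular"),
                                            200), alphabet = c("0", "1"))
    bootstrap_majority_test(m2, analysis2, B = 60,
                            seed = sample.int(1e6, 1))$P
  })
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)
  # bit-reproducible under a fixed seed
  tokr <- matrix(sample(c("0", "1"), 2 * 100, replace = TRUE), 2, 100)
  rownames(tokr) <- taxa
  mr <- character_matrix(tokr, type = rep(c("morphological", "molecular"), 50),
                         alphabet = c("0", "1"))
  r2 <- bootstrap_majority_test(mr, analysis2, B = 100, seed = 2)
  r3 <- bootstrap_majority_test(mr, analysis2, B = 100, seed = 2)
  expect_identical(r2$P, r3$P)
})

test_that("Mann-Whitney wrapper: paired and unpaired behaviour", {
  x <- c(1.2, 3.1, 2.2, 5.5, 4.1)
  expect_warning(p <- mann_whitney(x, x, paired = TRUE), "zero")
  expect_equal(p, 1)
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50) + 3
  expect_lt(mann_whitney(a, b), 0.01)
  expect_lt(mann_whitney(a, b, paired = TRUE), 0.01)
  # exact small-sample case against brute-force rank enumeration
  xs <- c(1.1, 2.3, 3.9, 10.2)
  ys <- c(3.1, 4.5, 5.2, 6.6)
  ranks <- rank(c(xs, ys))
  u_obs <- sum(ranks[1:4]) - 4 * 5 / 2
  all_u <- apply(utils::combn(8, 4), 2, function(ix)
    sum(rank(c(xs, ys))[ix]) - 4 * 5 / 2)
  p_exact <- mean(abs(all_u - 8) >= abs(u_obs - 8))  # 8 = n1*n2/2
  expect_equal(mann_whitney(xs, ys), p_exact)
})

test_that("partial correlation matches residual regression", {
  set.seed(10)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200); z <- rnorm(200)
  expect_equal(partial_correlation(x, y, z), cor(x, y), tolerance = 0.1)
  # fixed 6-point vectors: compare to correlating the z-residuals
  x6 <- c(1, 2, 3, 4, 5, 7); y6 <- c(2, 1, 4, 3, 7, 8); z6 <- c(1, 1, 2, 3, 5, 8)
  rx <- resid(lm(x6 ~ z6)); ry <- resid(lm(y6 ~ z6))
  expect_equal(partial_correlation(x6, y6, z6), cor(rx, ry),
               tolerance = 1e-12)
  expect_warning(out <- partial_correlation(x6, y6, y6), "collinear")
  expect_true(is.na(out))
  expect_warning(partial_correlation(rep(1, 5), y6[1:5], z6[1:5]), "variance")
})
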