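# brute-force oracle: enumerate all sign assignments of the nonzero
# differences, two-sided p = 2 * min(tail probabilities), capped at 1
wilcoxon_oracle <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  if (!length(d)) return(1)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% rk
  p_lo <- mean(Ws <= W + 1e-9)
  p_hi <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

test_that("exact signed-rank p-values match printed anchors", {
  # 8 pairs, all shifted the same way: 2/2^8
  expect_equal(wilcoxon_exact(1:8, 1:8 + 1), 0.0078125)
  expect_equal(signif(wilcoxon_exact(1:8, 1:8 + 1), 3), 0.00781)
  # direction does not matter for the two-sided value
  expect_equal(wilcoxon_exact(1:8 + 1, 1:8), 0.0078125)
  # a single pair cannot be extreme two-sided
  expect_equal(wilcoxon_exact(1, 2), 1)
  # all-zero differences: degenerate, p = 1
  p0 <- wilcoxon_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(as.numeric(p0), 1)
  expect_true(isTRUE(attr(p0, "degenerate")))
})

test_that("exact signed-rank equals brute-force enumeration", {
  # a mixed-sign case
  b <- rep(0, 8)
  a <- c(1, 2, 3, 4, 5, 6, 7, -8)
  expect_equal(wilcoxon_exact(b, a), wilcoxon_oracle(b, a))

  # property: random integer differences with ties and zeros, n <= 10
  set.seed(123)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    d <- sample(-4:4, n, replace = TRUE)
    expect_equal(as.numeric(wilcoxon_exact(rep(0, n), d)),
                 wilcoxon_oracle(rep(0, n), d),
                 info = paste("d =", paste(d, collapse = ",")))
  }

  # tie-free case agrees with the stock exact test
  set.seed(5)
  x <- rnorm(9)
  y <- rnorm(9)
  expect_equal(wilcoxon_exact(x, y),
               stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value)
})

test_that("BH adjustment reproduces the published cohort table", {
  p <- c(0.0391, 0.742, 1, 0.945, 0.641, 0.844, 0.109, 0.00781, 0.945,
         0.547, 0.00781)
  fdr <- bh_adjust(p)
  expect_equal(round(fdr[p == 0.00781], 3), c(0.043, 0.043))
  expect_equal(round(fdr[p == 0.0391], 3), 0.143)
  # step-up oracle, written out directly
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(fdr[o], pmin(adj, 1))
  # dominance and range
  expect_true(all(fdr >= p))
  expect_true(all(fdr <= 1))
  # all-equal p-values are unchanged
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("receptor-change Delta matches the worked example and its sign law", {
  expect_equal(round(delta_receptor(0.005, 0.011), 2), -0.55)
  expect_equal(delta_receptor(0.004, 0.008), -0.5)
  expect_equal(delta_receptor(0.01, 0.01), 0)
  # sign: negative iff the dissociation constant increased
  set.seed(9)
  b <- runif(50, 1e-4, 1)
  a <- runif(50, 1e-4, 1)
  expect_equal(delta_receptor(b, a) < 0, a > b)
  expect_error(delta_receptor(0, 0.01), "> 0")
})

test_that("cohort summary handles null and extremal cases", {
  set.seed(2)
  tab <- as.data.frame(matrix(abs(rnorm(8 * 3, 5)), 8, 3))
  colnames(tab) <- c("V_1", "K1_prime", "G_max")
  rownames(tab) <- sprintf("S%02d", 1:8)

  s0 <- summarize_cohort(tab, tab)
  expect_true(all(s0$comparison$p == 1))
  expect_equal(s0$delta$av_delta, 0)
  expect_equal(s0$delta$delta_of_means, 0)

  # all K1_prime increased: reduces to the extremal signed-rank case
  tab2 <- tab
  tab2$K1_prime <- tab$K1_prime * 2.18
  s1 <- summarize_cohort(tab, tab2)
  expect_equal(s1$comparison$p[s1$comparison$parameter == "K1_prime"],
               0.0078125)
  expect_equal(s1$delta$av_delta, 1 / 2.18 - 1, tolerance = 1e-12)

  # misaligned tables are refused
  tab3 <- tab[-1, ]
  expect_error(summarize_cohort(tab, tab3), "aligned")
})
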