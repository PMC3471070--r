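# Statistical kernels against independent oracles (base R and brute force).

test_that("spearman reproduces hand-computed and limiting values", {
  x <- c(1, 2, 3, 4)
  expect_equal(spearman(x, c(2, 4, 6, 9))$rho, 1)
  expect_equal(spearman(x, -c(1, 3, 5, 10))$rho, -1)
  # d^2 sum = 2: rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(spearman(x, c(1, 3, 2, 4))$rho, 0.8)
  deg <- spearman(c(1, 1, 1), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$rho))
})

test_that("spearman agrees with cor / cor.test for all n <= 6 cases tried", {
  with_seed <- tractem:::with_seed
  cases <- with_seed(5, {
    lapply(1:20, function(i) {
      n <- sample(4:6, 1)
      list(x = sample(20, n), y = sample(20, n))    # untied
    })
  })
  for (cs in cases) {
    got <- spearman(cs$x, cs$y)
    expect_equal(got$rho, cor(cs$x, cs$y, method = "spearman"))
    oracle <- suppressWarnings(
      cor.test(cs$x, cs$y, method = "spearman", exact = TRUE))
    expect_equal(got$p, unname(oracle$p.value), tolerance = 1e-12)
    expect_identical(got$method, "exact")
  }
  # tied data: rho must still match cor()'s average-rank definition
  tied <- with_seed(6, lapply(1:10, function(i) {
    n <- sample(4:6, 1)
    list(x = sample(3, n, TRUE), y = sample(4, n, TRUE))
  }))
  for (cs in tied) {
    if (length(unique(cs$x)) < 2 || length(unique(cs$y)) < 2) next
    expect_equal(spearman(cs$x, cs$y)$rho,
                 cor(cs$x, cs$y, method = "spearman"))
  }
})

test_that("permutation p for larger n tracks the exact/approx answers", {
  with_seed <- tractem:::with_seed
  xy <- with_seed(8, list(x = rnorm(15), y = rnorm(15)))
  got <- spearman(xy$x, xy$y, n_perm = 20000L, rng_seed = 3)
  expect_identical(got$method, "permutation")
  oracle <- suppressWarnings(cor.test(xy$x, xy$y, method = "spearman"))
  expect_lt(abs(got$p - oracle$p.value), 0.03)
  # strongly correlated data: small p both ways
  got2 <- spearman(1:15, (1:15) + rnorm(15, sd = 0.1), rng_seed = 3)
  expect_lt(got2$p, 0.001)
})

test_that("rank-sum: exact enumeration oracle, boundary and tie handling", {
  # (1,2,3) vs (4,5,6): the most extreme of C(6,3)=20 assignments
  got <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(got$statistic, 6)
  expect_equal(got$p, 1 / 20)
  # identical multisets: two-sided p = 1 at the inclusive boundary
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2), c(1, 2, 2))$p, 1)
  # brute-force bitmask oracle on random small inputs, with and without ties
  with_seed <- tractem:::with_seed
  cases <- with_seed(9, lapply(1:15, function(i) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    list(a = sample(8, na, TRUE), b = sample(8, nb, TRUE))
  }))
  for (cs in cases) {
    got <- wilcoxon_rank_sum(cs$a, cs$b, alternative = "greater")
    n <- length(cs$a) + length(cs$b)
    r <- rank(c(cs$a, cs$b))
    Ws <- numeric(0)
    for (bits in 0:(2^n - 1)) {           # independent enumeration
      sel <- which(bitwAnd(bits, 2^(0:(n - 1))) > 0)
      if (length(sel) == length(cs$a)) Ws <- c(Ws, sum(r[sel]))
    }
    expect_equal(got$p, mean(Ws >= got$statistic - 1e-9))
  }
})

test_that("rank-sum agrees with wilcox.test and shifts shrink p", {
  with_seed <- tractem:::with_seed
  ab <- with_seed(10, list(a = rnorm(8), b = rnorm(9)))
  got <- wilcoxon_rank_sum(ab$a, ab$b)
  na <- length(ab$a)
  oracle <- wilcox.test(ab$a, ab$b, exact = TRUE)
  expect_equal(got$statistic - na * (na + 1) / 2, unname(oracle$statistic))
  expect_equal(got$p, oracle$p.value, tolerance = 1e-12)
  base <- with_seed(11, rnorm(10))
  ps <- vapply(c(0.5, 1.5, 3), function(shift) {
    wilcoxon_rank_sum(base + shift, base, alternative = "greater")$p
  }, 0)
  expect_true(all(diff(ps) < 0))
  # large-sample normal branch stays close to wilcox.test's approximation
  big <- with_seed(12, list(a = rnorm(25), b = rnorm(30, 0.5)))
  gotn <- wilcoxon_rank_sum(big$a, big$b)
  expect_identical(gotn$method, "normal")
  on <- wilcox.test(big$a, big$b, exact = FALSE, correct = TRUE)
  expect_equal(gotn$p, on$p.value, tolerance = 1e-6)
})

test_that("signed-rank test matches wilcox.test paired exact p-values", {
  with_seed <- tractem:::with_seed
  xy <- with_seed(13, list(x = rnorm(10), y = rnorm(10, 0.8)))
  got <- wilcoxon_signed_rank(xy$x, xy$y)
  oracle <- wilcox.test(xy$x, xy$y, paired = TRUE, exact = TRUE)
  expect_equal(got$statistic, unname(oracle$statistic))
  expect_equal(got$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))$p, 1)
})

test_that("Holm adjustment matches p.adjust", {
  with_seed <- tractem:::with_seed
  p <- with_seed(14, runif(7)^2)
  expect_equal(holm_adjust(p), p.adjust(p, "holm"))
})
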