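# Nonparametric statistical kernels: Spearman rank correlation with
# permutation significance, Wilcoxon rank-sum with exact enumeration for
# small samples, and the paired Wilcoxon signed-rank test.  Implemented
# in-package so small-sample p-values are exact and auditable; base R's
# cor()/wilcox.test() serve as independent oracles in the test suite only.

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with permutation significance
#'
#' Average ranks for ties; rho is the Pearson correlation of the rank
#' vectors.  The p-value is exact (all n! permutations of y) for n <= 7,
#' otherwise estimated from seeded random permutations with the add-one
#' correction (1 + #extreme)/(1 + n_perm).  The t-approximation p-value is
#' reported alongside.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @param n_perm random permutations when exact enumeration is not used
#'   (default 10000).
#' @param rng_seed seed for the permutation draw.
#' @return list(rho, p, p_approx, method, n); \code{rho} and p are NA (with
#'   \code{degenerate = TRUE}) for constant input.
#' @export
spearman <- function(x, y, alternative = c("two.sided", "greater", "less"),
                     n_perm = 10000L, rng_seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, p_approx = NA_real_,
                method = "degenerate", n = n, degenerate = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(perm_ry) {
    rxc <- rx - mean(rx)
    ryc <- perm_ry - mean(ry)
    sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
  }
  rho <- rho_of(ry)
  tail_p <- function(stats, obs) {
    eps <- 1e-12
    switch(alternative,
           two.sided = mean(abs(stats) >= abs(obs) - eps),
           greater = mean(stats >= obs - eps),
           less = mean(stats <= obs + eps))
  }
  if (n <= 7L) {
    pm <- all_perms(n)
    stats <- apply(pm, 1, function(ix) rho_of(ry[ix]))
    p <- tail_p(stats, rho)
    method <- "exact"
  } else {
    stats <- with_seed(rng_seed, {
      vapply(seq_len(n_perm), function(i) rho_of(sample(ry)), 0)
    })
    eps <- 1e-12
    k <- switch(alternative,
                two.sided = sum(abs(stats) >= abs(rho) - eps),
                greater = sum(stats >= rho - eps),
                less = sum(stats <= rho + eps))
    p <- (1 + k) / (1 + n_perm)
    method <- "permutation"
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p_ap <- switch(alternative,
                 two.sided = 2 * pt(-abs(tstat), n - 2),
                 greater = pt(tstat, n - 2, lower.tail = FALSE),
                 less = pt(tstat, n - 2))
  list(rho = rho, p = p, p_approx = min(p_ap, 1), method = method, n = n,
       degenerate = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' Statistic: sum of the pooled ranks (average ranks for ties) of the first
#' sample.  For groups of at most 10 each, the p-value is exact by full
#' enumeration of all C(n, n_a) rank assignments (ties handled naturally);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.  Boundary convention: permutations exactly as extreme
#' as the observed statistic are included, so two identical samples give a
#' two-sided p of 1.
#'
#' @param a,b numeric vectors (non-empty).
#' @param alternative "two.sided" (default), "greater" or "less" (location
#'   of \code{a} relative to \code{b}).
#' @return list(statistic = rank-sum of a, p, method, n_a, n_b).
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  eps <- 1e-9
  if (max(na, nb) <= 10L) {
    sets <- combn(n, na)
    Ws <- colSums(matrix(r[sets], nrow = na))
    p_le <- mean(Ws <= W + eps)
    p_ge <- mean(Ws >= W - eps)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "exact"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- na * nb / 12 * ((n + 1) - tie_term)
    z_ge <- (W - mu - 0.5) / sqrt(v)
    z_le <- (W - mu + 0.5) / sqrt(v)
    p_ge <- pnorm(z_ge, lower.tail = FALSE)
    p_le <- pnorm(z_le)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge, less = p_le)
    method <- "normal"
  }
  list(statistic = W, p = p, method = method, n_a = na, n_b = nb)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; V is the sum of the ranks of the positive
#' differences (ranks of |d|, average ties).  Exact by enumeration of all
#' 2^m sign assignments for m <= 12 retained pairs, else normal
#' approximation with tie correction.
#'
#' @param x,y paired numeric vectors (y defaults to zeros: one-sample test).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list(statistic = V, p, method, n_effective).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    return(list(statistic = 0, p = 1, method = "degenerate", n_effective = 0L))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  eps <- 1e-9
  if (m <= 12L) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    Vs <- as.numeric(signs %*% r)
    p_le <- mean(Vs <= V + eps)
    p_ge <- mean(Vs >= V - eps)
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    v <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    p_ge <- pnorm((V - mu - 0.5) / sqrt(v), lower.tail = FALSE)
    p_le <- pnorm((V - mu + 0.5) / sqrt(v))
    method <- "normal"
  }
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_le, p_ge)),
              greater = p_ge, less = p_le)
  list(statistic = V, p = p, method = method, n_effective = m)
}

#' Holm step-down adjustment of p-values
#' @param p numeric vector of raw p-values.
#' @export
holm_adjust <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}
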