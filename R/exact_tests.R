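#' Exact Mann-Whitney U test
#'
#' U counts the (x, y) pairs with `x > y` (ties count one half). Without
#' ties and for `n1 + n2 <= 30` the p-value is exact, computed from the
#' null distribution of U built by the standard count recursion
#' (dynamic-programming convolution over rank assignments); otherwise a
#' normal approximation with midranks and tie correction is used. The
#' two-sided p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric samples.
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return List `U`, `p`, `n1`, `n2`, `exact`.
#' @export
mann_whitney_exact <- function(x, y,
                               alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("empty sample")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 + n2 <= 30) {
    pmf <- mw_null_pmf(n1, n2)
    cdf <- cumsum(pmf)
    pl <- cdf[U + 1]
    pg <- 1 - if (U >= 1) cdf[U] else 0
    p <- switch(alternative,
                two_sided = min(1, 2 * min(pl, pg)),
                greater = pg, less = pl)
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    nt <- table(c(x, y))
    n <- n1 + n2
    sig <- sqrt(n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1))))
    z <- (U - mu) / sig
    p <- switch(alternative,
                two_sided = min(1, 2 * stats::pnorm(-abs(z))),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    exact <- FALSE
  }
  list(U = U, p = p, n1 = n1, n2 = n2, exact = exact)
}

# null pmf of U for sample sizes (m, n) without ties, by lattice-path DP:
# placing the m + n values in increasing order, a y placed while i x's have
# already been placed is exceeded by the remaining m - i x's, so
# c(i, j, u) = c(i-1, j, u) + c(i, j-1, u - (m - i)); result c(m, n, .)
# normalized by choose(m + n, m)
mw_null_pmf <- function(m, n) {
  len <- m * n + 1
  f <- matrix(0, nrow = n + 1, ncol = len)  # row j+1: vector over u, current i
  f[1, 1] <- 1
  for (j in seq_len(n)) {           # i = 0: each y adds m
    f[j + 1, ] <- c(rep(0, min(m, len)), f[j, ])[seq_len(len)]
  }
  for (i in seq_len(m)) {
    g <- matrix(0, nrow = n + 1, ncol = len)
    g[1, 1] <- 1                    # j = 0: U = 0 regardless of i
    add <- m - i                    # each y placed now adds m - i
    for (j in seq_len(n)) {
      shifted <- c(rep(0, min(add, len)), g[j, ])[seq_len(len)]
      g[j + 1, ] <- f[j + 1, ] + shifted
    }
    f <- g
  }
  f[n + 1, ] / choose(m + n, m)
}

#' Exact Wilcoxon signed-rank test
#'
#' W is the sum of the ranks of positive differences after dropping zero
#' differences (their count is returned). Without ties among `|d|` and for
#' `n <= 20` the p-value is exact via the subset-sum null distribution of W
#' (generating-polynomial convolution over the 2^n sign patterns);
#' otherwise a normal approximation with tie correction is used.
#'
#' @param x,y paired samples (equal length); or `y = NULL` to test the
#'   differences `x` against zero.
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return List `W`, `p`, `n` (non-zero differences), `n_zero`, `exact`.
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL,
                                       alternative = c("two_sided", "greater",
                                                       "less")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    x - y
  }
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate input: all differences zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 20) {
    pmf <- wsr_null_pmf(n)
    cdf <- cumsum(pmf)
    pl <- cdf[W + 1]
    pg <- 1 - if (W >= 1) cdf[W] else 0
    p <- switch(alternative,
                two_sided = min(1, 2 * min(pl, pg)),
                greater = pg, less = pl)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(tie_tab^3 - tie_tab) / 48)
    z <- (W - mu) / sig
    p <- switch(alternative,
                two_sided = min(1, 2 * stats::pnorm(-abs(z))),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    exact <- FALSE
  }
  list(W = W, p = p, n = n, n_zero = n_zero, exact = exact)
}

# null pmf of W for n untied ranks: convolution of (1 + z^k)/2 over k = 1..n
wsr_null_pmf <- function(n) {
  tmax <- n * (n + 1) / 2
  f <- numeric(tmax + 1)
  f[1] <- 1
  for (k in seq_len(n)) {
    g <- f
    g[(k + 1):(tmax + 1)] <- g[(k + 1):(tmax + 1)] + f[1:(tmax + 1 - k)]
    f <- g
  }
  f / 2^n
}

#' Rank-biserial correlation from a U or W statistic
#'
#' Mann-Whitney: `r = 2U/(n1 n2) - 1`. Wilcoxon signed-rank:
#' `r = (2W - T)/T` with `T = n(n+1)/2`.
#'
#' @param statistic the U or W value.
#' @param n1,n2 group sizes (Mann-Whitney) or `n1 = n` pairs (Wilcoxon).
#' @param kind `"mann_whitney"` or `"wilcoxon"`.
#' @return r in [-1, 1].
#' @export
rank_biserial <- function(statistic, n1, n2 = NULL,
                          kind = c("mann_whitney", "wilcoxon")) {
  kind <- match.arg(kind)
  if (kind == "mann_whitney") {
    if (is.null(n2)) stop("n2 required for mann_whitney")
    if (statistic < 0 || statistic > n1 * n2) stop("U out of range")
    2 * statistic / (n1 * n2) - 1
  } else {
    tot <- n1 * (n1 + 1) / 2
    if (statistic < 0 || statistic > tot) stop("W out of range")
    (2 * statistic - tot) / tot
  }
}

#' Percentile-bootstrap confidence interval for the rank-biserial r
#'
#' Resamples participants (independently within each group for
#' Mann-Whitney; pairs for Wilcoxon), recomputes the rank-biserial
#' correlation, and takes percentile bounds, clipped to [-1, 1].
#'
#' @param x,y the two samples (paired for `"wilcoxon"`).
#' @param kind `"mann_whitney"` or `"wilcoxon"`.
#' @param level confidence level.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return List `estimate`, `lower`, `upper`, `level`, `n_boot`.
#' @export
rb_confidence_interval <- function(x, y, kind = c("mann_whitney", "wilcoxon"),
                                   level = 0.95, n_boot = 10000, seed = 1L) {
  kind <- match.arg(kind)
  if (min(length(x), length(y)) < 4)
    warning("fewer than 4 observations per group: interval will be wide")
  rb_of <- function(xx, yy) {
    if (kind == "mann_whitney") {
      r <- rank(c(xx, yy))
      U <- sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
      rank_biserial(U, length(xx), length(yy), "mann_whitney")
    } else {
      d <- xx - yy
      d <- d[d != 0]
      if (length(d) == 0L) return(0)
      W <- sum(rank(abs(d))[d > 0])
      rank_biserial(W, length(d), kind = "wilcoxon")
    }
  }
  est <- rb_of(x, y)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    if (kind == "mann_whitney") {
      rb_of(sample(x, replace = TRUE), sample(y, replace = TRUE))
    } else {
      idx <- sample(length(x), replace = TRUE)
      rb_of(x[idx], y[idx])
    }
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(estimate = est, lower = max(-1, q[1]), upper = min(1, q[2]),
       level = level, n_boot = n_boot)
}

#' Partial eta squared from an F statistic
#'
#' @param F_value F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom (> 0).
#' @return `F*df1 / (F*df1 + df2)`, in [0, 1].
#' @export
partial_eta_sq <- function(F_value, df1, df2) {
  if (any(df1 <= 0) || any(df2 <= 0)) stop("degrees of freedom must be positive")
  if (any(F_value < 0)) stop("F must be non-negative")
  F_value * df1 / (F_value * df1 + df2)
}
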