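#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. For small samples
#' (combined n <= 20 by default) the exact permutation distribution of U is
#' enumerated — including under ties, via midranks — and the two-sided
#' p-value is the probability of a |U - n1*n2/2| deviation at least as large
#' as observed. Larger samples use the normal approximation with the tie
#' correction and (optionally) a continuity correction.
#'
#' @param x,y numeric samples.
#' @param exact force exact enumeration (`TRUE`), the normal approximation
#'   (`FALSE`), or decide by combined sample size (`NULL`, the default:
#'   exact when `length(x) + length(y) <= 20`).
#' @param correct continuity correction in the normal approximation.
#' @return List with `statistic` (U for `x`), `p`, and `method`.
#' @export
mann_whitney_test <- function(x, y, exact = NULL, correct = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) {
    stop("samples must be finite", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (is.null(exact)) exact <- n <= 20
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  if (exact) {
    combos <- utils::combn(n, nx)
    rsums <- colSums(matrix(r[combos], nrow = nx))
    Udist <- rsums - nx * (nx + 1) / 2
    dev <- abs(U - mu)
    p <- mean(abs(Udist - mu) >= dev - 1e-9)
    return(list(statistic = U, p = p, method = "exact"))
  }

  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    # all observations identical
    return(list(statistic = U, p = 1, method = "normal"))
  }
  z <- U - mu
  if (correct) z <- sign(z) * max(abs(z) - 0.5, 0)
  p <- min(2 * stats::pnorm(-abs(z) / sqrt(sigma2)), 1)
  list(statistic = U, p = p, method = "normal")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled sample points of the absolute
#' difference between the two ECDFs; the two-sided p-value comes from the
#' asymptotic Kolmogorov distribution at effective size
#' `n_a * n_b / (n_a + n_b)` (or from exact enumeration with
#' `exact = TRUE`, suitable for small tie-free samples).
#'
#' @param a,b numeric samples (degrees, in this package's use).
#' @param exact passed to [stats::ks.test()].
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' every admissible table whose probability does not exceed that of the
#' observed table (probability-mass ordering, the common two-sided
#' convention).
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @return List with `p` and `odds_ratio` (sample odds ratio, `NA` when a
#'   margin cell chain makes it undefined).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) {
    stop("`tab` must be a 2x2 matrix", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n2); hi <- min(m, k)
  support <- lo:hi
  pr <- stats::dhyper(support, m, n2, k)
  pobs <- stats::dhyper(tab[1, 1], m, n2, k)
  p <- sum(pr[pr <= pobs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p = min(p, 1), odds_ratio = or)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expectations from the margins,
#' `df = (r - 1)(c - 1)`, upper-tail chi-square p-value. No continuity
#' correction by default (flag provided).
#'
#' @param tab r x c matrix of nonnegative counts (r, c >= 2).
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("`tab` must be at least 2x2", call. = FALSE)
  }
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  zero <- which(expected == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    stop(sprintf("expected count is 0 in cell (%d, %d)",
                 zero[1, 1], zero[1, 2]), call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = expected)
}
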