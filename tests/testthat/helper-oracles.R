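# Independent brute-force oracles, kept deliberately naive and separate from
# the implementations they check.

# Longest circular supra-threshold run + trapezoid AUC + midpoint, by direct
# scan over every possible start index.
oracle_crescent <- function(v, threshold) {
  n <- length(v)
  supra <- v > threshold
  if (!any(supra)) {
    return(list(coverage = 0, auc = 0, position = NA_real_))
  }
  if (all(supra)) {
    a <- v - threshold
    auc <- 0
    for (i in seq_len(n)) auc <- auc + (a[i] + a[ifelse(i == n, 1, i + 1)]) / 2
    return(list(coverage = 100, auc = auc,
                position = (which.max(v) - 1) * (100 / n)))
  }
  best_len <- 0; best_start <- NA_integer_
  for (start in seq_len(n)) {
    if (!supra[start]) next
    prev <- ifelse(start == 1, n, start - 1)
    if (supra[prev]) next  # not a run head
    len <- 0
    i <- start
    while (supra[i]) {
      len <- len + 1
      i <- ifelse(i == n, 1, i + 1)
    }
    if (len > best_len) { best_len <- len; best_start <- start }
  }
  spacing <- 100 / n
  coverage <- (best_len - 1) * spacing
  if (best_len < 2) return(list(coverage = 0, auc = 0, position = NA_real_))
  auc <- 0
  i <- best_start
  for (k in seq_len(best_len - 1)) {
    j <- ifelse(i == n, 1, i + 1)
    auc <- auc + ((v[i] - threshold) + (v[j] - threshold)) / 2
    i <- j
  }
  position <- ((best_start - 1) * spacing + coverage / 2) %% 100
  list(coverage = coverage, auc = auc, position = position)
}

# Two-sample KS D by exhaustive evaluation at every pooled point.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}

# Fisher two-sided p by enumerating every table with the observed margins,
# probabilities via binomial coefficients.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(support, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(N, c1))
  }, numeric(1))
  pobs <- prob[support == tab[1, 1]]
  sum(prob[prob <= pobs * (1 + 1e-7)])
}

# Monte-Carlo permutation p for the two-sided Mann-Whitney (handles ties).
oracle_mw_mc <- function(x, y, n_perm = 20000) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  U <- U_of(seq_len(nx))
  mu <- nx * (n - nx) / 2
  dev <- abs(U - mu)
  hits <- vapply(seq_len(n_perm), function(i) {
    abs(U_of(sample.int(n, nx)) - mu) >= dev - 1e-9
  }, logical(1))
  mean(hits)
}

# Count-based ECDF oracle.
oracle_ecdf <- function(angles) {
  u <- sort(unique(angles))
  frac <- numeric(length(u))
  for (i in seq_along(u)) {
    cnt <- 0
    for (a in angles) if (a <= u[i]) cnt <- cnt + 1
    frac[i] <- cnt / length(angles)
  }
  data.frame(angle = u, cum_fraction = frac)
}

# Exact two-sided 99% binomial CI bounds for a parameter p at size n.
binom_ci99 <- function(p, n) {
  k <- 0:n
  cdf <- pbinom(k, n, p)
  lo <- k[which(cdf > 0.005)[1]]
  hi <- k[which(cdf >= 0.995)[1]]
  c(lo, hi) / n
}

# Random linescan profile (background already subtracted), with supra- and
# sub-threshold structure.
random_profile <- function(n = 100) {
  v <- runif(n, 0, 15)
  n_blobs <- sample(0:3, 1)
  for (b in seq_len(n_blobs)) {
    start <- sample(n, 1)
    len <- sample(3:35, 1)
    idx <- ((start - 1 + 0:(len - 1)) %% n) + 1
    v[idx] <- v[idx] + runif(1, 10, 80)
  }
  linescan_profile(v, background = 0, background_subtracted = TRUE)
}
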