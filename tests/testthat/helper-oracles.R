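# Independent reference computations used to cross-check the statistical
# layer. Everything here is written from the textbook formulas with plain
# loops, deliberately avoiding the code paths (and base-R functions) the
# implementation uses.

oracle_kw_h <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  offset <- 0
  ssq <- 0
  for (g in groups) {
    rg <- r[(offset + 1):(offset + length(g))]
    ssq <- ssq + sum(rg)^2 / length(g)
    offset <- offset + length(g)
  }
  h <- 12 / (N * (N + 1)) * ssq - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / corr
}

oracle_dunn <- function(groups, bonferroni_m = choose(length(groups), 2)) {
  values <- unlist(groups, use.names = FALSE)
  N <- length(values)
  r <- rank(values)
  k <- length(groups)
  rbar <- numeric(k); n <- numeric(k)
  offset <- 0
  for (i in seq_len(k)) {
    n[i] <- length(groups[[i]])
    rbar[i] <- mean(r[(offset + 1):(offset + n[i])])
    offset <- offset + n[i]
  }
  ties <- table(values)
  sig2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    z <- (rbar[i] - rbar[j]) / sqrt(sig2 * (1 / n[i] + 1 / n[j]))
    p <- 2 * pnorm(-abs(z))
    out <- rbind(out, data.frame(i = i, j = j, z = z, p_raw = p,
                                 p_adj = min(1, p * bonferroni_m)))
  }
  out
}

oracle_welch_t <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_welch_anova <- function(groups) {
  k <- length(groups)
  n <- sapply(groups, length)
  m <- sapply(groups, mean)
  v <- sapply(groups, function(g) sum((g - mean(g))^2) / (length(g) - 1))
  w <- n / v
  mw <- sum(w * m) / sum(w)
  A <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  W <- A / B
  df2 <- (k^2 - 1) / (3 * lam)
  list(W = W, df1 = k - 1, df2 = df2, p = pf(W, k - 1, df2, lower.tail = FALSE))
}

oracle_brown_forsythe <- function(groups) {
  k <- length(groups)
  n <- sapply(groups, length)
  m <- sapply(groups, mean)
  v <- sapply(groups, function(g) sum((g - mean(g))^2) / (length(g) - 1))
  N <- sum(n)
  grand <- sum(n * m) / N
  f <- sum(n * (m - grand)^2) / sum((1 - n / N) * v)
  c_i <- (1 - n / N) * v / sum((1 - n / N) * v)
  df2 <- 1 / sum(c_i^2 / (n - 1))
  list(F = f, df1 = k - 1, df2 = df2, p = pf(f, k - 1, df2, lower.tail = FALSE))
}

oracle_ks_d <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  d <- 0
  for (x in pts) {
    d <- max(d, abs(mean(a <= x) - mean(b <= x)))
  }
  d
}

# exact two-sample KS p by enumerating all group assignments (no ties):
# only the ranks matter, so assignments are enumerated over the sorted
# pooled positions
oracle_ks_p_exact <- function(a, b) {
  n <- length(a); m <- length(b)
  d_obs <- oracle_ks_d(a, b)
  idx <- combn(n + m, n)
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    memb <- logical(n + m)
    memb[idx[, j]] <- TRUE
    d <- max(abs(cumsum(memb) / n - cumsum(!memb) / m))
    if (d >= d_obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(idx)
}

# ROUT flags recomputed independently: the robust centre is found by
# direct minimisation of the Lorentzian objective (optimize), alternating
# with the percentile scale update; then per-point t ratios and an
# explicit prefix-by-prefix FDR scan.
oracle_rout <- function(values, Q = 1) {
  n <- length(values)
  rsd <- function(res) unname(quantile(abs(res), 0.6827, type = 7)) * n / (n - 1)
  c0 <- median(values)
  s <- rsd(values - c0)
  if (s == 0) return(logical(n))
  for (it in 1:200) {
    obj <- function(cc) sum(log(1 + ((values - cc) / s)^2))
    c1 <- optimize(obj, range(values))$minimum
    s1 <- rsd(values - c1)
    done <- abs(c1 - c0) < 1e-12 * max(1, abs(c0))
    c0 <- c1
    if (s1 > 0) s <- s1
    if (done) break
  }
  res <- values - c0
  if (all(res == 0)) return(logical(n))
  t <- abs(res) / s
  p <- 2 * pt(-t, df = n - 1)
  ord <- order(p)
  flags <- logical(n)
  last <- 0
  for (i in seq_len(n)) {
    if (p[ord[i]] <= (Q / 100) * i / n) last <- i
  }
  if (last > 0) flags[ord[1:last]] <- TRUE
  flags
}
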