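# Independent brute-force oracles. Each recomputes a statistic from its
# definition with straight-line code (explicit loops, full enumeration),
# sharing no code path with the package implementation.

# U statistic by explicit pair counting.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) u <- u + 1
    else if (xi == yj) u <- u + 0.5
  }
  u
}

# Exact two-sided Mann-Whitney p by enumerating every C(n1+n2, n1)
# assignment of the pooled values to the first group.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- oracle_u(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) oracle_u(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided Fisher p by explicit enumeration of every table with the
# observed margins, using factorial-based hypergeometric probabilities.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  prob_a <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(0)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
        lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(c) - lfactorial(d))
  }
  a_obs <- tab[1, 1]
  p_obs <- prob_a(a_obs)
  total <- 0
  for (a in 0:min(r1, c1)) {
    p <- prob_a(a)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  min(total, 1)
}

# Step-up BH from the definition: sort ascending, take running minima of
# p_(j) * n / j from the top, return in input order.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, sorted[i] * n / i)
    adj[i] <- running
  }
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# Straight-line TMM: per-sample loop recomputing M, A, weights and the
# trim-and-weight average from the stated formulas.
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  libs <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    uq[j] <- stats::quantile(counts[, j], 0.75) / libs[j]
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    M <- c(); A <- c(); w <- c()
    for (i in seq_len(nrow(counts))) {
      x <- counts[i, j]; xr <- counts[i, ref]
      if (x > 0 && xr > 0) {
        px <- x / libs[j]; pr <- xr / libs[ref]
        M <- c(M, log2(px / pr))
        A <- c(A, 0.5 * log2(px * pr))
        w <- c(w, (libs[j] - x) / (libs[j] * x) + (libs[ref] - xr) / (libs[ref] * xr))
      }
    }
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rm <- rank(M); ra <- rank(A)
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      if (rm[i] >= lo_m && rm[i] <= hi_m && ra[i] >= lo_a && ra[i] <= hi_a) {
        num <- num + M[i] / w[i]
        den <- den + 1 / w[i]
      }
    }
    f[j] <- if (den == 0) 1 else 2^(num / den)
  }
  f / exp(mean(log(f)))
}

# Straight-line RLE median-of-ratios.
oracle_rle <- function(counts) {
  libs <- colSums(counts)
  allpos <- apply(counts, 1, function(r) all(r > 0))
  gm <- numeric(sum(allpos))
  sub <- counts[allpos, , drop = FALSE]
  for (i in seq_len(nrow(sub))) gm[i] <- exp(mean(log(sub[i, ])))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    f[j] <- stats::median(sub[, j] / gm) / libs[j]
  f / exp(mean(log(f)))
}

# Mid-rank Spearman from sums, ranks built by explicit comparison counts.
oracle_spearman_r <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Small random count matrix helper.
rand_counts <- function(nr, nc, mu = 100, size = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnbinom(nr * nc, mu = mu, size = size) + 1L, nr, nc,
         dimnames = list(sprintf("m%02d", seq_len(nr)), sprintf("s%02d", seq_len(nc))))
}
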