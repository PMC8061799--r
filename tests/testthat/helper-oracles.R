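# Brute-force oracles, independent of the package's vectorised formulas:
# everything here enumerates pairs explicitly.

# mean pairwise mismatch fraction per usable site, averaged over usable sites
oracle_pi <- function(calls) {
  per_site <- apply(calls, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    mm <- 0
    np <- 0
    for (i in seq_len(length(v) - 1)) {
      for (j in seq(i + 1, length(v))) {
        np <- np + 1
        if (v[i] != v[j]) mm <- mm + 1
      }
    }
    mm / np
  })
  usable <- !is.na(per_site)
  if (!any(usable)) return(NA_real_)
  sum(per_site[usable]) / sum(usable)
}

# total pairwise mismatch fraction (sum over usable sites) and S, for Tajima
oracle_pi_total_S <- function(calls) {
  tot <- 0
  S <- 0L
  ns <- integer()
  for (s in seq_len(ncol(calls))) {
    v <- calls[, s]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    ns <- c(ns, length(v))
    mm <- 0
    np <- 0
    for (i in seq_len(length(v) - 1)) {
      for (j in seq(i + 1, length(v))) {
        np <- np + 1
        if (v[i] != v[j]) mm <- mm + 1
      }
    }
    tot <- tot + mm / np
    if (length(unique(v)) > 1) S <- S + 1L
  }
  list(pi_total = tot, S = S, n_mean = mean(ns))
}

# textbook Tajima's D from pi_total, S and sample size
oracle_tajima <- function(calls) {
  z <- oracle_pi_total_S(calls)
  if (z$S == 0) return(NA_real_)
  n <- as.integer(round(z$n_mean))
  if (n < 3) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  v <- e1 * z$S + e2 * z$S * (z$S - 1)
  if (v <= 0) return(NA_real_)
  (z$pi_total - z$S / a1) / sqrt(v)
}

# mean cross-class mismatch fraction per usable site
oracle_dxy <- function(callsA, callsB) {
  per_site <- vapply(seq_len(ncol(callsA)), function(s) {
    a <- callsA[, s]; a <- a[!is.na(a)]
    b <- callsB[, s]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) return(NA_real_)
    mm <- 0
    for (x in a) for (y in b) if (x != y) mm <- mm + 1
    mm / (length(a) * length(b))
  }, numeric(1))
  usable <- !is.na(per_site)
  if (!any(usable)) return(NA_real_)
  sum(per_site[usable]) / sum(usable)
}

# r^2 between two haploid 0/1 site vectors via D^2/(p1 q1 p2 q2)
oracle_r2 <- function(v1, v2) {
  ok <- !is.na(v1) & !is.na(v2)
  v1 <- v1[ok]; v2 <- v2[ok]
  p1 <- mean(v1); p2 <- mean(v2)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  p11 <- mean(v1 == 1 & v2 == 1)
  D <- p11 - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

# nested least-squares LOD via explicit normal equations
oracle_lod <- function(y, cofactor, dosage) {
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  X0 <- cbind(1, cofactor)
  X1 <- cbind(X0, dosage)
  (length(y) / 2) * log10(rss(X0) / rss(X1))
}
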