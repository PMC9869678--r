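# Independent brute-force oracles. These deliberately use different
# algorithms / code paths than the package implementations they check.

# KCC via the identity with the mean pairwise Spearman correlation:
# W = ((m - 1) * mean_rho_spearman + 1) / m   (exact when no ties)
oracle_kcc_spearman <- function(series) {
  m <- ncol(series)
  rs <- stats::cor(apply(series, 2, rank))
  mean_rho <- mean(rs[upper.tri(rs)])
  ((m - 1) * mean_rho + 1) / m
}

# naive O(n^2) DFT amplitude spectrum (no fft())
oracle_dft_amp <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  sapply(k, function(kk) {
    w <- -2 * pi * kk * (0:(n - 1)) / n
    Mod(sum(x * complex(real = cos(w), imaginary = sin(w))))
  })
}

oracle_falff <- function(x, TR, low = c(0.01, 0.08)) {
  n <- length(x)
  amp <- oracle_dft_amp(x)
  f <- (0:(n - 1)) / (n * TR)
  f[f > 1 / (2 * TR)] <- f[f > 1 / (2 * TR)] - 1 / TR
  pos <- f > 0
  sum(amp[pos & f >= low[1] & f <= low[2]]) / sum(amp[pos])
}

# explicit O(V^2) correlation loops
oracle_dc <- function(Y, thr = 0.25) {
  V <- ncol(Y)
  out <- numeric(V)
  for (i in seq_len(V)) for (j in seq_len(V)) {
    if (i == j) next
    r <- suppressWarnings(stats::cor(Y[, i], Y[, j]))
    if (!is.na(r) && r > thr) out[i] <- out[i] + r
  }
  out
}

oracle_fcs <- function(Y, r0 = 0.2) {
  V <- ncol(Y)
  out <- numeric(V)
  for (i in seq_len(V)) for (j in seq_len(V)) {
    if (i == j) next
    r <- suppressWarnings(stats::cor(Y[, i], Y[, j]))
    if (!is.na(r) && r > r0) out[i] <- out[i] + atanh(min(r, 1 - 1e-7))
  }
  out / (V - 1)
}

# hat-matrix residuals through an explicit pseudo-inverse
oracle_ols_resid <- function(X, Y) {
  H <- X %*% solve(crossprod(X)) %*% t(X)
  Y - H %*% Y
}

# textbook pooled two-sample t
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# connected-component labelling by iterative min-label relaxation
oracle_label <- function(bin, connectivity = 26) {
  s <- dim(bin)
  lab <- array(0, s)
  lab[bin] <- seq_len(sum(bin))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  repeat {
    changed <- FALSE
    for (v in which(bin)) {
      ci <- arrayInd(v, s)
      for (o in seq_len(nrow(off))) {
        nb <- ci + off[o, ]
        if (any(nb < 1) || any(nb > s)) next
        w <- nb[1] + (nb[2] - 1) * s[1] + (nb[3] - 1) * s[1] * s[2]
        if (bin[w] && lab[w] < lab[v]) { lab[v] <- lab[w]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  # canonical relabel 1..k in first-appearance order
  u <- unique(lab[lab > 0])
  out <- array(0L, s)
  for (i in seq_along(u)) out[lab == u[i]] <- i
  out
}

# same-partition check for two labelings
same_partition <- function(a, b) {
  fa <- a[a > 0 | b > 0]; fb <- b[a > 0 | b > 0]
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(fa)) == length(unique(fb))
}
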