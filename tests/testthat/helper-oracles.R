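# Independent brute-force oracles, deliberately written with different
# algebra than the package implementations.

# canonical correlations as roots of the generalized eigenproblem
# det(Rxy Ryy^-1 Ryx - r^2 Rxx) = 0, via a plain (non-symmetric) eigensolve
cca_oracle <- function(X, Y) {
  X <- scale(X); Y <- scale(Y)
  Rxx <- cor(X); Ryy <- cor(Y); Rxy <- cor(X, Y)
  M <- solve(Rxx) %*% Rxy %*% solve(Ryy) %*% t(Rxy)
  ev <- eigen(M, only.values = TRUE)$values
  ev <- sort(pmax(Re(ev), 0), decreasing = TRUE)
  sqrt(ev[seq_len(min(ncol(X), ncol(Y)))])
}

# direct double-loop Gi* evaluation from bin coordinates and values
gi_oracle <- function(x_km, y_km, x, band_km) {
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; s1 <- 0; s2 <- 0
    for (j in seq_len(n)) {
      w <- as.numeric(sqrt((x_km[i] - x_km[j])^2 +
                           (y_km[i] - y_km[j])^2) <= band_km)
      num <- num + w * x[j]
      s1 <- s1 + w
      s2 <- s2 + w^2
    }
    den <- S * sqrt((n * s2 - s1^2) / (n - 1))
    z[i] <- if (S == 0 || den == 0) 0 else (num - xbar * s1) / den
  }
  z
}

# containment scan: value of the cell whose half-open intervals hold the
# point, checked cell by cell
extract_oracle <- function(grid, lon, lat) {
  out <- rep(NA_real_, length(lon))
  for (k in seq_along(lon)) {
    for (r in seq_len(grid$n_rows)) {
      top <- grid$north - (r - 1) * grid$cell_size
      bot <- grid$north - r * grid$cell_size
      if (!(lat[k] <= top && lat[k] > bot)) next
      for (c in seq_len(grid$n_cols)) {
        w <- grid$west + (c - 1) * grid$cell_size
        if (lon[k] >= w && lon[k] < w + grid$cell_size) {
          out[k] <- grid$values[r, c]
          break
        }
      }
      break
    }
  }
  out
}

# 99% multinomial acceptance envelope: each class count within the exact
# binomial [0.005, 0.995] quantiles
in_multinomial_envelope <- function(counts, n, probs) {
  lo <- qbinom(0.005, n, probs)
  hi <- qbinom(0.995, n, probs)
  all(counts >= lo & counts <= hi)
}
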