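#' Standardize a block of variables
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1.
#'
#' @param X numeric matrix or data.frame.
#' @return matrix with standardized columns.
#' @export
standardize <- function(X) {
  X <- env_values(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop_ecogeo("zero-variance column: ",
                paste(colnames(X)[sds == 0 | is.na(sds)], collapse = ", "))
  scale(X, center = TRUE, scale = sds)
}

# symmetric inverse square root via eigendecomposition with an eigenvalue
# floor; also reports the smallest raw eigenvalue so callers can detect
# rank deficiency
inv_sqrt_sym <- function(R, floor = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  list(m = e$vectors %*% diag(1 / sqrt(pmax(e$values, floor)),
                              nrow = length(e$values)) %*% t(e$vectors),
       min_ev = min(e$values))
}

# canonical correlations and weights from block correlation matrices:
# SVD of Rxx^(-1/2) Rxy Ryy^(-1/2)
cca_core <- function(Rxx, Rxy, Ryy, ridge = 0, ev_floor = 1e-10) {
  if (ridge > 0) {
    Rxx <- Rxx + diag(ridge, nrow(Rxx))
    Ryy <- Ryy + diag(ridge, nrow(Ryy))
  }
  ix <- inv_sqrt_sym(Rxx, ev_floor)
  iy <- inv_sqrt_sym(Ryy, ev_floor)
  if (ridge == 0 && (ix$min_ev < ev_floor || iy$min_ev < ev_floor))
    stop_ecogeo("a block correlation matrix is numerically singular ",
                "(smallest eigenvalue < ", ev_floor,
                "); supply a small ridge > 0")
  K <- ix$m %*% Rxy %*% iy$m
  s <- min(nrow(Rxx), nrow(Ryy))
  sv <- svd(K, nu = s, nv = s)
  r <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  list(r = r, A = ix$m %*% sv$u, B = iy$m %*% sv$v)
}

#' Canonical correlation analysis between two variable blocks
#'
#' Correlation-based CCA between a climate block `X` and a soil block `Y`:
#' canonical correlations and weights come from the singular value
#' decomposition of `Rxx^(-1/2) Rxy Ryy^(-1/2)`, with symmetric inverse
#' square roots computed by eigendecomposition (eigenvalue floor `1e-10`).
#' Loadings are correlations of each original variable with its own block's
#' canonical scores; cross-loadings with the opposite block's scores. Signs
#' are made deterministic by orienting each X variate so that its
#' largest-|loading| variable loads positively, and each Y variate so that
#' the canonical pair correlates positively.
#'
#' @param X,Y numeric matrices/data.frames of the two blocks (same rows).
#' @param ridge nonnegative scalar added to the block correlation diagonals
#'   when a block is numerically singular (default 0: singularity is an
#'   error advising a ridge).
#' @param standardized set `TRUE` if `X`/`Y` are already standardized.
#' @return object of class `"cca_result"` with elements `cor` (canonical
#'   correlations, descending), `eigenvalues` (`r^2/(1-r^2)`), `proportions`
#'   (percent of `sum(eigenvalues)`), `xcoef`/`ycoef` (weights for
#'   standardized variables), `xload`/`yload` (loadings),
#'   `xcross`/`ycross` (cross-loadings), `scores_x`/`scores_y`, `tests`
#'   (sequential Bartlett chi-square tests, see [wilks_tests()]), and
#'   `n`, `p`, `q`, `ridge`.
#' @seealso [eigen_proportions()], [wilks_tests()]
#' @export
fit_cca <- function(X, Y, ridge = 0, standardized = FALSE) {
  Xs <- if (standardized) env_values(X) else standardize(X)
  Ys <- if (standardized) env_values(Y) else standardize(Y)
  stopifnot(nrow(Xs) == nrow(Ys), ridge >= 0)
  n <- nrow(Xs); p <- ncol(Xs); q <- ncol(Ys)
  if (n <= p + q)
    warning("n (", n, ") is not greater than p + q (", p + q,
            "); canonical correlations will be unstable")
  Rxx <- stats::cor(Xs); Ryy <- stats::cor(Ys); Rxy <- stats::cor(Xs, Ys)
  core <- cca_core(Rxx, Rxy, Ryy, ridge = ridge)
  r <- core$r; A <- core$A; B <- core$B
  s <- length(r)
  sx <- Xs %*% A; sy <- Ys %*% B
  xload <- stats::cor(Xs, sx)
  # deterministic orientation: anchor on the X block's dominant loading,
  # then keep each canonical pair positively correlated
  for (k in seq_len(s)) {
    anchor <- which.max(abs(xload[, k]))
    if (xload[anchor, k] < 0) {
      A[, k] <- -A[, k]; sx[, k] <- -sx[, k]; xload[, k] <- -xload[, k]
    }
    if (stats::cor(sx[, k], sy[, k]) < 0) {
      B[, k] <- -B[, k]; sy[, k] <- -sy[, k]
    }
  }
  yload <- stats::cor(Ys, sy)
  xcross <- stats::cor(Xs, sy)   # climate variables vs soil variates
  ycross <- stats::cor(Ys, sx)   # soil variables vs climate variates
  ax <- paste0("CLIMATE", seq_len(s)); ay <- paste0("SOIL", seq_len(s))
  dimnames(A) <- list(colnames(Xs), ax); dimnames(B) <- list(colnames(Ys), ay)
  colnames(xload) <- ax; colnames(yload) <- ay
  colnames(xcross) <- ay; colnames(ycross) <- ax
  colnames(sx) <- ax; colnames(sy) <- ay
  lam <- r^2 / (1 - r^2)
  structure(list(cor = r, eigenvalues = lam,
                 proportions = if (all(r < 1)) eigen_proportions(r) else
                   rep(NA_real_, s),
                 xcoef = A, ycoef = B, xload = xload, yload = yload,
                 xcross = xcross, ycross = ycross,
                 scores_x = sx, scores_y = sy,
                 tests = wilks_tests(r, n, p, q),
                 n = n, p = p, q = q, ridge = ridge),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, digits = 4, ...) {
  cat(sprintf("Canonical correlation analysis: n = %d, p = %d, q = %d\n",
              x$n, x$p, x$q))
  tab <- data.frame(cor = x$cor, eigenvalue = x$eigenvalues,
                    proportion_pct = x$proportions,
                    wilks = x$tests$lambda, chisq = x$tests$chisq,
                    df = x$tests$df, p_value = x$tests$p_value)
  print(round(tab, digits))
  invisible(x)
}

#' Eigenvalue proportions of canonical correlations
#'
#' Converts canonical correlations to eigenvalues
#' `lambda_k = r_k^2 / (1 - r_k^2)` and expresses each as a percentage of
#' their sum — the "percent of variation explained" convention attached to
#' successive canonical pairs.
#'
#' @param r canonical correlations, sorted descending, each in `[0, 1)`.
#' @return numeric vector of percentages summing to 100.
#' @export
#' @examples
#' eigen_proportions(c(0.8, 0.6))  # 75.97, 24.03
eigen_proportions <- function(r) {
  stopifnot(is.numeric(r), length(r) >= 1)
  if (any(r < 0 | r > 1)) stop_ecogeo("canonical correlations must be in [0, 1]")
  if (any(r == 1)) stop_ecogeo("r = 1 gives an infinite eigenvalue")
  if (any(diff(r) > 1e-12))
    stop_ecogeo("canonical correlations must be sorted descending")
  lam <- r^2 / (1 - r^2)
  100 * lam / sum(lam)
}

#' Sequential Bartlett tests of canonical correlations
#'
#' For each k, tests that canonical correlations k..s are all zero:
#' `Lambda_k = prod_{i>=k} (1 - r_i^2)`, Bartlett's chi-square
#' `-(n - 1 - (p + q + 1)/2) * log(Lambda_k)` on
#' `(p - k + 1)(q - k + 1)` degrees of freedom, upper-tail p-value.
#'
#' @param r canonical correlations (descending).
#' @param n number of observations.
#' @param p,q block widths.
#' @return data.frame with columns `k`, `lambda`, `chisq`, `df`, `p_value`.
#' @export
wilks_tests <- function(r, n, p, q) {
  s <- length(r)
  lambda <- rev(cumprod(rev(1 - r^2)))
  mult <- n - 1 - (p + q + 1) / 2
  chisq <- -mult * log(lambda)
  df <- (p - seq_len(s) + 1) * (q - seq_len(s) + 1)
  data.frame(k = seq_len(s), lambda = lambda, chisq = chisq, df = df,
             p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}
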