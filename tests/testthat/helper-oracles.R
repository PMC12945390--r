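# Independent oracles used to cross-check the package's linear algebra.
# These deliberately avoid the code paths they verify.

# variance along each direction by an explicit per-direction loop
oracle_variance_loop <- function(directions, prepared) {
  vapply(seq_len(ncol(directions)), function(k) {
    u <- directions[, k]
    sum(vapply(seq_len(ncol(prepared)), function(s)
      sum(u * prepared[, s])^2, numeric(1)))
  }, numeric(1))
}

# eigenvalues of the unit-by-unit second-moment matrix via SVD of the data
oracle_eigenvalues_svd <- function(prepared) {
  d <- svd(prepared, nu = 0, nv = 0)$d
  ev <- numeric(nrow(prepared))
  ev[seq_along(d)] <- d^2
  ev
}

# trapezoidal AUC written out longhand
oracle_auc_trapz <- function(per_pc, total) {
  cf <- cumsum(per_pc) / total
  k <- length(per_pc)
  area <- 0
  prev <- 0
  for (i in seq_len(k)) {
    area <- area + (prev + cf[i]) / 2 * (1 / k)
    prev <- cf[i]
  }
  area
}

# two-sample KS statistic from first principles (sup of ECDF differences)
oracle_ks_statistic <- function(x, y) {
  grid <- sort(c(x, y))
  fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(fx - fy))
}

# spatial autocorrelation of a map at integer bin shifts (direct sums)
oracle_autocorr <- function(m, max_shift) {
  nx <- nrow(m); ny <- ncol(m)
  mu <- mean(m); mc <- m - mu
  out <- matrix(NA_real_, 2 * max_shift + 1, 2 * max_shift + 1)
  for (dx in -max_shift:max_shift) {
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    for (dy in -max_shift:max_shift) {
      ys <- max(1, 1 - dy):min(ny, ny - dy)
      a <- mc[xs, ys]; b <- mc[xs + dx, ys + dy]
      out[dx + max_shift + 1, dy + max_shift + 1] <-
        sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }
  }
  out
}
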