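#' Principal components of a population activity matrix
#'
#' Eigendecomposition of the `n_units x n_units` second-moment matrix of the
#' prepared activity (uncentered, covariance or correlation structure
#' depending on `scaling_mode`). The returned directions are patterns across
#' units ("cell assemblies"); eigenvalues give the activity variance each
#' pattern carries, in prepared-data sum-of-squares units.
#'
#' The full basis (`K = n_units`) is returned unless `truncate` is given.
#' Eigenvalues below `1e-12` times the largest are clipped to zero; the
#' ordering among exactly tied eigenvalues is solver-dependent, which does
#' not affect any downstream variance partial sums.
#'
#' @param A An `activity_matrix`.
#' @param scaling_mode Passed to [prepare_matrix()].
#' @param truncate Optional number of leading components to keep.
#' @return An object of class `"pc_basis"`: list with `directions`
#'   (`n_units x K`, orthonormal columns), `eigenvalues` (length `K`,
#'   non-increasing, `>= 0`) and `scaling_mode`.
#' @examples
#' b <- compute_pcs(activity_matrix(matrix(rnorm(40), 4, 10)), "centered")
#' b$eigenvalues
#' @export
compute_pcs <- function(A, scaling_mode = c("raw", "centered", "zscored"),
                        truncate = NULL) {
  scaling_mode <- match.arg(scaling_mode)
  ap <- prepare_matrix(A, scaling_mode)
  sm <- tcrossprod(ap)
  e <- eigen(sm, symmetric = TRUE)
  ev <- e$values
  ev[ev < max(ev[1], 0) * 1e-12] <- 0
  k <- if (is.null(truncate)) nrow(ap) else min(as.integer(truncate), nrow(ap))
  basis <- list(directions = e$vectors[, seq_len(k), drop = FALSE],
                eigenvalues = ev[seq_len(k)],
                scaling_mode = scaling_mode)
  class(basis) <- "pc_basis"
  basis
}

#' @export
print.pc_basis <- function(x, ...) {
  cat("PC basis:", nrow(x$directions), "units,", ncol(x$directions),
      "components (", x$scaling_mode, "scaling )\n")
  invisible(x)
}

#' Variance of an activity matrix along a set of directions
#'
#' For each basis direction `u_k`, computes the summed squared projections of
#' the prepared states onto `u_k` — the activity variance the direction
#' explains. With a complete orthonormal basis these sum to the matrix's
#' total sum of squares.
#'
#' @param basis A `pc_basis` (from [compute_pcs()] or
#'   [random_orthonormal_basis()]).
#' @param A An `activity_matrix` over the same units.
#' @param scaling_mode Preparation applied to `A`; should match the basis.
#' @return A partial `"generalization_curve"`: list with `per_pc_variance`
#'   (length `K`) and `total_variance`. Complete it with
#'   [auc_from_variance()].
#' @export
variance_along <- function(A, basis,
                           scaling_mode = c("raw", "centered", "zscored")) {
  scaling_mode <- match.arg(scaling_mode)
  if (!inherits(basis, "pc_basis")) stop("basis must be a 'pc_basis'")
  ap <- prepare_matrix(A, scaling_mode)
  if (nrow(basis$directions) != nrow(ap))
    stop("dimension mismatch: basis has ", nrow(basis$directions),
         " units, activity matrix has ", nrow(ap))
  proj <- crossprod(basis$directions, ap)   # K x n_states
  curve <- list(per_pc_variance = rowSums(proj^2),
                total_variance = sum(ap^2))
  class(curve) <- "generalization_curve"
  curve
}

#' Complete a generalization curve: cumulative fraction and AUC
#'
#' Normalizes the per-direction variances by the total variance, forms the
#' cumulative curve (prefixed with an origin point at 0), and integrates it
#' by the trapezoidal rule over the component index rescaled to `[0, 1]`.
#' With this discretization a perfectly uniform variance profile — the
#' expectation under random directions — gives an AUC of exactly 0.5, and
#' variance concentrated on the first component gives `1 - 1/(2K)`.
#'
#' @param curve A partial `generalization_curve` from [variance_along()].
#' @return The completed `generalization_curve`, with fields
#'   `cumulative_fraction` (length `K + 1`, first element 0) and `auc`.
#' @export
auc_from_variance <- function(curve) {
  if (!inherits(curve, "generalization_curve"))
    stop("curve must be a 'generalization_curve'")
  if (!is.finite(curve$total_variance) || curve$total_variance <= 0)
    stop("degenerate input: total_variance must be positive, got ",
         curve$total_variance)
  v <- curve$per_pc_variance
  k <- length(v)
  cf <- c(0, cumsum(v) / curve$total_variance)
  curve$cumulative_fraction <- cf
  curve$auc <- sum((cf[-1L] + cf[-(k + 1L)]) / 2) / k
  curve
}

#' @export
print.generalization_curve <- function(x, ...) {
  cat("Generalization curve over", length(x$per_pc_variance), "components")
  if (!is.null(x$auc)) cat("; AUC =", format(x$auc, digits = 4))
  cat("\n")
  invisible(x)
}

#' Subspace generalization between two tasks
#'
#' The package's central measure: project task 2's activity onto the
#' principal components of task 1 and take the area under the normalized
#' cumulative variance-explained curve. High AUC means the directions that
#' dominate task 1 also explain task 2 — a shared low-dimensional subspace.
#' Chance level (random directions) is 0.5.
#'
#' @param A1,A2 `activity_matrix` objects over the same ordered unit set.
#' @param scaling_mode Per-unit preparation, see [prepare_matrix()]. Use
#'   `"zscored"` for firing-rate-map pipelines (correlation structure) and
#'   `"raw"` for beta-matrix pipelines.
#' @param symmetrize If `TRUE`, average the AUC of `A2` on `A1`'s PCs with
#'   the AUC of `A1` on `A2`'s PCs.
#' @param truncate Optional basis truncation (default full basis).
#' @return A single AUC in `(0, 1]`, with attribute `"directions"` holding
#'   the one-way AUCs `c(a1_to_a2, a2_to_a1)` (second entry `NA` when
#'   `symmetrize = FALSE`).
#' @examples
#' a <- activity_matrix(matrix(rnorm(200), 10, 20))
#' subspace_generalization(a, a, "zscored")   # self-projection ceiling
#' @export
subspace_generalization <- function(A1, A2,
                                    scaling_mode = c("raw", "centered", "zscored"),
                                    symmetrize = TRUE, truncate = NULL) {
  scaling_mode <- match.arg(scaling_mode)
  a1 <- as_activity_matrix(A1)
  a2 <- as_activity_matrix(A2)
  check_matched_units(a1, a2)
  auc12 <- auc_from_variance(variance_along(
    a2, compute_pcs(a1, scaling_mode, truncate), scaling_mode))$auc
  auc21 <- NA_real_
  if (symmetrize) {
    auc21 <- auc_from_variance(variance_along(
      a1, compute_pcs(a2, scaling_mode, truncate), scaling_mode))$auc
  }
  out <- if (symmetrize) (auc12 + auc21) / 2 else auc12
  attr(out, "directions") <- c(auc12, auc21)
  out
}

#' Within-vs-across AUC difference
#'
#' The generalization statistic used throughout the inference machinery:
#' the within-task baseline AUC minus the across-task AUC. Near zero means
#' the second task is explained as well as the first explains itself (full
#' generalization); large positive values mean the subspace does not carry
#' over (e.g. place-cell remapping).
#'
#' @inheritParams subspace_generalization
#' @param within One of `"self"` (each task projected on its own PCs — the
#'   ceiling) or `"splithalf"` (odd/even state split: PCs from one half,
#'   projection of the other).
#' @return Numeric scalar, `auc_within - auc_across` (symmetrized averages
#'   of both directions when `symmetrize = TRUE`).
#' @export
auc_difference <- function(A1, A2,
                           scaling_mode = c("raw", "centered", "zscored"),
                           symmetrize = TRUE, within = c("self", "splithalf")) {
  scaling_mode <- match.arg(scaling_mode)
  within <- match.arg(within)
  a1 <- as_activity_matrix(A1)
  a2 <- as_activity_matrix(A2)
  check_matched_units(a1, a2)
  self_auc <- function(a) {
    if (within == "self")
      return(auc_from_variance(variance_along(
        a, compute_pcs(a, scaling_mode), scaling_mode))$auc)
    odd <- seq(1L, ncol(a), by = 2L)
    b1 <- a[, odd, drop = FALSE]
    b2 <- a[, -odd, drop = FALSE]
    mean(c(
      auc_from_variance(variance_along(
        activity_matrix(b2), compute_pcs(activity_matrix(b1), scaling_mode),
        scaling_mode))$auc,
      auc_from_variance(variance_along(
        activity_matrix(b1), compute_pcs(activity_matrix(b2), scaling_mode),
        scaling_mode))$auc))
  }
  across <- subspace_generalization(a1, a2, scaling_mode, symmetrize = symmetrize)
  w <- if (symmetrize) mean(c(self_auc(a1), self_auc(a2))) else self_auc(a1)
  as.numeric(w - across)
}

#' Uniformly random orthonormal basis
#'
#' Draws an `n x n` orthogonal matrix Haar-uniformly (QR of a Gaussian
#' matrix with the sign-corrected R diagonal) and wraps it as a `pc_basis`
#' with zero eigenvalues. Useful as the chance reference for the AUC.
#'
#' @param n Dimension.
#' @param k Number of columns to keep (default `n`).
#' @return A `pc_basis`.
#' @export
random_orthonormal_basis <- function(n, k = n) {
  z <- matrix(stats::rnorm(n * n), n, n)
  qrz <- qr(z)
  q <- qr.Q(qrz)
  d <- sign(diag(qr.R(qrz)))
  d[d == 0] <- 1
  q <- q * rep(d, each = n)
  basis <- list(directions = q[, seq_len(k), drop = FALSE],
                eigenvalues = rep(0, k), scaling_mode = "raw")
  class(basis) <- "pc_basis"
  basis
}

#' Empirical chance level of the AUC under random bases
#'
#' Projects a fixed activity matrix onto `n_draws` Haar-random orthonormal
#' bases and averages the resulting AUCs. By linearity of expectation this
#' converges to 0.5 for any data matrix.
#'
#' @param A An `activity_matrix`.
#' @param n_draws Number of random bases.
#' @param scaling_mode Preparation for `A`.
#' @param seed Optional integer seed.
#' @return List with `mean_auc` and the vector of per-draw `aucs`.
#' @export
chance_auc <- function(A, n_draws = 2000,
                       scaling_mode = c("raw", "centered", "zscored"),
                       seed = NULL) {
  scaling_mode <- match.arg(scaling_mode)
  a <- as_activity_matrix(A)
  ap <- prepare_matrix(a, scaling_mode)
  total <- sum(ap^2)
  n <- nrow(ap)
  aucs <- with_seed(seed, vapply(seq_len(n_draws), function(i) {
    b <- random_orthonormal_basis(n)
    v <- rowSums(crossprod(b$directions, ap)^2)
    cf <- c(0, cumsum(v) / total)
    sum((cf[-1L] + cf[-(n + 1L)]) / 2) / n
  }, numeric(1)))
  list(mean_auc = mean(aucs), aucs = aucs)
}

# Run code with a temporarily-set RNG seed, restoring the caller's RNG state.
# seed = NULL runs in the ambient RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
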