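#' Container for a distribution of AUC differences
#'
#' @param values Numeric vector of within-minus-across AUC differences.
#' @param provenance One of `"permutation"`, `"bootstrap"`, `"subsample"`.
#' @param seed The seed used, if any.
#' @return An object of class `"auc_difference_distribution"`.
#' @export
auc_difference_distribution <- function(values,
                                        provenance = c("permutation",
                                                       "bootstrap",
                                                       "subsample"),
                                        seed = NULL) {
  provenance <- match.arg(provenance)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("distribution values must be finite")
  structure(list(values = values, n_draws = length(values),
                 provenance = provenance, seed = seed),
            class = "auc_difference_distribution")
}

#' @export
print.auc_difference_distribution <- function(x, ...) {
  cat("AUC-difference distribution (", x$provenance, "): ", x$n_draws,
      " draws, mean ", format(mean(x$values), digits = 4), "\n", sep = "")
  invisible(x)
}

# one-sided permutation p with the +1 smoothing; "le" tests observed SMALLER
# than the null (generalization better than chance)
perm_p <- function(observed, null, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(null)
  p_less <- (1 + sum(null <= observed)) / (1 + n)
  p_greater <- (1 + sum(null >= observed)) / (1 + n)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

#' Identity-shuffle permutation test for subspace generalization
#'
#' Tests whether the within-minus-across AUC difference between two
#' environments is smaller than expected if cell identities carried no
#' information — i.e. whether the population's coactivation structure is
#' preserved. The null permutes the unit labels of the second environment's
#' matrix and recomputes the statistic; the within-environment baseline is
#' invariant under this shuffle. One-sided toward "smaller than chance" by
#' default, with the +1 permutation smoothing.
#'
#' @param A1,A2 `activity_matrix` objects over the same ordered units
#'   (environment 1 and 2).
#' @param n_perms Number of permutations (>= 100 recommended, minimum 1).
#' @param seed Optional integer seed.
#' @param scaling_mode Scaling for the subspace analysis.
#' @param symmetrize Use both projection directions (default TRUE).
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @return List with `observed` (the AUC difference), `null` (an
#'   `auc_difference_distribution`), and `p`.
#' @export
permutation_test_identity <- function(A1, A2, n_perms = 1000, seed = NULL,
                                      scaling_mode = c("zscored", "raw",
                                                       "centered"),
                                      symmetrize = TRUE,
                                      alternative = c("less", "greater",
                                                      "two.sided")) {
  scaling_mode <- match.arg(scaling_mode)
  alternative <- match.arg(alternative)
  a1 <- as_activity_matrix(A1); a2 <- as_activity_matrix(A2)
  check_matched_units(a1, a2)
  n <- nrow(a1)
  if (n < 3L) stop("need at least 3 units for a nontrivial identity shuffle")
  p1 <- prepare_matrix(a1, scaling_mode)
  p2 <- prepare_matrix(a2, scaling_mode)
  b1 <- compute_pcs(a1, scaling_mode)
  b2 <- compute_pcs(a2, scaling_mode)
  t1 <- sum(p1^2); t2 <- sum(p2^2)
  k <- n
  auc_of <- function(proj, total) {
    cf <- c(0, cumsum(rowSums(proj^2)) / total)
    sum((cf[-1L] + cf[-(k + 1L)]) / 2) / k
  }
  within <- mean(c(auc_of(crossprod(b1$directions, p1), t1),
                   auc_of(crossprod(b2$directions, p2), t2)))
  cross_auc <- function(perm) {
    # PCs of env1 explaining permuted env2, and PCs of permuted env2
    # explaining env1 (a row permutation of A2 permutes its PC loadings)
    a12 <- auc_of(crossprod(b1$directions[perm, , drop = FALSE], p2), t2)
    if (!symmetrize) return(a12)
    a21 <- auc_of(crossprod(b2$directions, p1[perm, , drop = FALSE]), t1)
    (a12 + a21) / 2
  }
  observed <- within - cross_auc(seq_len(n))
  null_vals <- with_seed(seed, vapply(seq_len(n_perms), function(i)
    within - cross_auc(sample.int(n)), numeric(1)))
  list(observed = observed,
       null = auc_difference_distribution(null_vals, "permutation", seed),
       p = perm_p(observed, null_vals, alternative))
}

#' Count-matched subsampling test of grid vs place generalization
#'
#' Builds a null distribution of AUC differences from control (place-cell)
#' populations subsampled to the same cell counts as the grid populations:
#' each draw subsamples every animal's place cells (without replacement) to
#' its matched count, computes the within-minus-across AUC difference per
#' animal, and pools the values across animals and draws. Each observed grid
#' statistic is then compared against the pooled null (one-sided toward
#' "smaller", +1 smoothing).
#'
#' @param grid_stats Numeric vector: observed AUC difference per animal.
#' @param place_pairs List (one per animal) of `list(env1 = , env2 = )`
#'   activity matrices of that animal's place cells.
#' @param n_match Integer vector: matched cell count per animal.
#' @param n_draws Subsampling draws (default 1000).
#' @param seed Optional integer seed.
#' @param scaling_mode Scaling for the subspace analysis.
#' @return List with `null` (an `auc_difference_distribution`), `p`
#'   (one p per grid statistic) and `n_match`.
#' @export
matched_subsample_test <- function(grid_stats, place_pairs, n_match,
                                   n_draws = 1000, seed = NULL,
                                   scaling_mode = c("zscored", "raw",
                                                    "centered")) {
  scaling_mode <- match.arg(scaling_mode)
  n_match <- rep_len(as.integer(n_match), length(place_pairs))
  for (i in seq_along(place_pairs)) {
    avail <- nrow(place_pairs[[i]]$env1)
    if (avail < n_match[i])
      stop("animal ", i, " has ", avail, " place cells; cannot subsample ",
           n_match[i])
  }
  null_vals <- with_seed(seed, {
    draws <- lapply(seq_len(n_draws), function(d) {
      vapply(seq_along(place_pairs), function(i) {
        idx <- sample.int(nrow(place_pairs[[i]]$env1), n_match[i])
        auc_difference(place_pairs[[i]]$env1[idx, , drop = FALSE],
                       place_pairs[[i]]$env2[idx, , drop = FALSE],
                       scaling_mode)
      }, numeric(1))
    })
    unlist(draws)
  })
  p <- vapply(grid_stats, function(g) perm_p(g, null_vals, "less"), numeric(1))
  list(null = auc_difference_distribution(null_vals, "subsample", seed),
       p = p, n_match = n_match)
}

#' Low-resolution bootstrap of the AUC difference
#'
#' Emulates supra-cellular (voxel-like) resolution from single cells: per
#' draw and per animal, two groups of `cells_per_group` cells are sampled
#' with replacement (groups drawn independently; the same cells are used in
#' both environments) and each group's maps are averaged, yielding a
#' `n_groups`-long unit vector per animal. Vectors are concatenated across
#' animals, and the within-minus-across AUC difference is computed for both
#' projection directions — so `n_boot` draws give `2 * n_boot` distribution
#' values (the default 400 draws give 800).
#'
#' @param pairs List (one per animal) of `list(env1 = , env2 = )` activity
#'   matrices (cells x bins, typically peak-normalized rate maps).
#' @param cells_per_group Cells sampled per group (default 7).
#' @param n_groups Groups per animal (default 2).
#' @param n_boot Bootstrap draws (default 400).
#' @param seed Optional integer seed.
#' @param scaling_mode Scaling for the subspace analysis.
#' @return An `auc_difference_distribution` with `2 * n_boot` values.
#' @export
lowres_bootstrap <- function(pairs, cells_per_group = 7, n_groups = 2,
                             n_boot = 400, seed = NULL,
                             scaling_mode = c("zscored", "raw", "centered")) {
  scaling_mode <- match.arg(scaling_mode)
  if (!length(pairs)) stop("need at least one animal")
  for (i in seq_along(pairs))
    if (is.null(pairs[[i]]$env1) || nrow(pairs[[i]]$env1) < 1L)
      stop("animal ", i, " has no cells")
  vals <- with_seed(seed, {
    out <- numeric(2L * n_boot)
    for (b in seq_len(n_boot)) {
      m1 <- list(); m2 <- list()
      for (i in seq_along(pairs)) {
        e1 <- pairs[[i]]$env1; e2 <- pairs[[i]]$env2
        for (g in seq_len(n_groups)) {
          idx <- sample.int(nrow(e1), cells_per_group, replace = TRUE)
          m1[[length(m1) + 1L]] <- colMeans(e1[idx, , drop = FALSE])
          m2[[length(m2) + 1L]] <- colMeans(e2[idx, , drop = FALSE])
        }
      }
      M1 <- activity_matrix(do.call(rbind, m1))
      M2 <- activity_matrix(do.call(rbind, m2))
      d1 <- auc_difference(M1, M2, scaling_mode, symmetrize = FALSE)
      d2 <- auc_difference(M2, M1, scaling_mode, symmetrize = FALSE)
      out[2L * b - 1L] <- d1
      out[2L * b] <- d2
    }
    out
  })
  auc_difference_distribution(vals, "bootstrap", seed)
}

#' Compare two AUC-difference distributions
#'
#' Two-sample Kolmogorov–Smirnov test plus a smoothed histogram summary of
#' both samples on a common grid (50 bins, moving-average smoothing window
#' of 9 bins by default — the display convention used for bootstrap
#' distributions).
#'
#' @param d1,d2 `auc_difference_distribution`s or numeric vectors.
#' @param bins Histogram bins (default 50).
#' @param smooth_window Odd moving-average window in bins (default 9).
#' @return List with `ks_statistic`, `p_value`, and `histogram` (data.frame
#'   with bin midpoints and smoothed densities of both samples).
#' @export
compare_distributions <- function(d1, d2, bins = 50, smooth_window = 9) {
  v1 <- if (inherits(d1, "auc_difference_distribution")) d1$values else as.numeric(d1)
  v2 <- if (inherits(d2, "auc_difference_distribution")) d2$values else as.numeric(d2)
  if (!length(v1) || !length(v2)) stop("both distributions must be non-empty")
  if (length(v1) < 5L || length(v2) < 5L)
    warning("fewer than 5 values in a sample; the KS test will be unreliable")
  ks <- suppressWarnings(stats::ks.test(v1, v2))
  rng <- range(c(v1, v2))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h1 <- graphics::hist(v1, breaks = breaks, plot = FALSE)$density
  h2 <- graphics::hist(v2, breaks = breaks, plot = FALSE)$density
  smooth1d <- function(x, w) {
    if (w <= 1L) return(x)
    h <- (w - 1L) %/% 2L
    vapply(seq_along(x), function(i)
      mean(x[max(1L, i - h):min(length(x), i + h)]), numeric(1))
  }
  hist_df <- data.frame(mid = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
                        density1 = smooth1d(h1, smooth_window),
                        density2 = smooth1d(h2, smooth_window))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       histogram = hist_df)
}
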