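test_that("prepare_matrix applies the declared per-unit scalings", {
  a <- activity_matrix(rbind(c(1, 2, 3), c(2, 2, 2), c(0, 2, 4)))
  expect_equal(unclass(prepare_matrix(a, "raw"))[1, ], c(s1 = 1, s2 = 2, s3 = 3))
  expect_equal(unname(unclass(prepare_matrix(a, "centered"))[1, ]), c(-1, 0, 1))
  # population-sd convention: sd of (0,2,4) is 2, wired into the contract
  b <- activity_matrix(rbind(c(0, 2, 4), c(1, 5, 3)))
  expect_equal(unname(unclass(prepare_matrix(b, "zscored"))[1, ]), c(-1, 0, 1))
  expect_error(prepare_matrix(a, "zscored"), "zero-variance")
  expect_error(prepare_matrix(a, "zscored"), "u2")  # names the offending unit
})

test_that("activity_matrix enforces its invariants", {
  expect_error(activity_matrix(matrix(1:3, 1, 3)), "at least 2 units")
  expect_error(activity_matrix(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
  expect_error(activity_matrix(matrix(1:6, 2, 3), unit_labels = "only-one"),
               "unit_labels")
})

test_that("compute_pcs matches an independent SVD oracle and conserves trace", {
  a <- activity_matrix(rbind(c(1, 0), c(0, 0)))
  b <- compute_pcs(a, "raw")
  expect_equal(b$eigenvalues, c(1, 0))
  expect_equal(abs(b$directions[, 1]), c(1, 0))
  for (s in 1:10) {
    set.seed(s)
    m <- activity_matrix(matrix(rnorm(15), 3, 5))
    for (mode in c("raw", "centered", "zscored")) {
      basis <- compute_pcs(m, mode)
      prep <- prepare_matrix(m, mode)
      expect_equal(sum(basis$eigenvalues), sum(prep^2), tolerance = 1e-8)
      expect_equal(basis$eigenvalues, oracle_eigenvalues_svd(unclass(prep)),
                   tolerance = 1e-8)
      expect_equal(crossprod(basis$directions), diag(3), tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_true(all(diff(basis$eigenvalues) <= 1e-10))
    }
  }
})

test_that("variance_along reproduces hand-computable projections", {
  a <- activity_matrix(rbind(c(1, 1, 0), c(0, 0, 2)))
  idbasis <- structure(list(directions = diag(2), eigenvalues = c(0, 0),
                            scaling_mode = "raw"), class = "pc_basis")
  v <- variance_along(a, idbasis, "raw")
  expect_equal(unname(v$per_pc_variance), c(2, 4))
  expect_equal(v$total_variance, 6)
  # projecting data on its own PCs recovers the eigenvalues
  set.seed(21)
  m <- activity_matrix(matrix(rnorm(80), 8, 10))
  basis <- compute_pcs(m, "centered")
  v2 <- variance_along(m, basis, "centered")
  expect_equal(unname(v2$per_pc_variance), basis$eigenvalues, tolerance = 1e-8)
  expect_error(variance_along(activity_matrix(matrix(rnorm(12), 3, 4)),
                              basis, "centered"), "mismatch")
})

test_that("auc_from_variance implements the origin-anchored trapezoid", {
  k <- 10
  single <- structure(list(per_pc_variance = c(5, rep(0, k - 1)),
                           total_variance = 5),
                      class = "generalization_curve")
  expect_equal(auc_from_variance(single)$auc, 1 - 1 / (2 * k))
  uniform <- structure(list(per_pc_variance = rep(2, k), total_variance = 20),
                       class = "generalization_curve")
  done <- auc_from_variance(uniform)
  expect_equal(done$auc, 0.5)
  expect_equal(done$cumulative_fraction[1], 0)
  expect_equal(done$cumulative_fraction[k + 1], 1)
  expect_true(all(diff(done$cumulative_fraction) >= 0))
  set.seed(3)
  v <- runif(7)
  curve <- structure(list(per_pc_variance = v, total_variance = sum(v)),
                     class = "generalization_curve")
  expect_equal(auc_from_variance(curve)$auc, oracle_auc_trapz(v, sum(v)))
  bad <- structure(list(per_pc_variance = rep(0, 3), total_variance = 0),
                   class = "generalization_curve")
  expect_error(auc_from_variance(bad), "degenerate")
})

test_that("subspace generalization is invariant to state order and scale", {
  set.seed(11)
  a1 <- activity_matrix(matrix(rnorm(20 * 50), 20, 50))
  a2 <- activity_matrix(matrix(rnorm(20 * 50), 20, 50))
  base <- subspace_generalization(a1, a2, "centered")
  perm <- activity_matrix(unclass(a2)[, sample(50)])
  expect_equal(as.numeric(subspace_generalization(a1, perm, "centered")),
               as.numeric(base), tolerance = 1e-10)
  scaled <- activity_matrix(unclass(a2) * -3.7)
  expect_equal(as.numeric(subspace_generalization(a1, scaled, "centered")),
               as.numeric(base), tolerance = 1e-10)
  # self-projection is recovered when the two tasks coincide
  self <- subspace_generalization(a1, a1, "centered")
  v <- auc_from_variance(variance_along(a1, compute_pcs(a1, "centered"),
                                        "centered"))
  expect_equal(as.numeric(self), v$auc)
  a3 <- activity_matrix(matrix(rnorm(20 * 50), 20, 50),
                        unit_labels = paste0("x", 1:20))
  expect_error(subspace_generalization(a1, a3), "labels")
})

test_that("self PCs dominate random bases at every partial sum", {
  set.seed(5)
  for (rep in 1:5) {
    m <- activity_matrix(matrix(rnorm(8 * 40), 8, 40))
    basis <- compute_pcs(m, "centered")
    self_part <- cumsum(variance_along(m, basis, "centered")$per_pc_variance)
    for (b in 1:30) {
      rb <- random_orthonormal_basis(8)
      rnd_part <- cumsum(variance_along(m, rb, "centered")$per_pc_variance)
      expect_true(all(self_part - rnd_part >= -1e-8))
    }
  }
})

test_that("random-basis AUC is at chance for arbitrary fixed data", {
  set.seed(9)
  m <- activity_matrix(matrix(rexp(12 * 100), 12, 100))  # skewed, not centered
  ch <- chance_auc(m, n_draws = 400, scaling_mode = "raw", seed = 42)
  expect_lt(abs(ch$mean_auc - 0.5), 0.02)
  # symmetrized cross-AUC of independent noise also sits near chance
  set.seed(13)
  aucs <- replicate(60, {
    x <- activity_matrix(matrix(rnorm(20 * 200), 20, 200))
    y <- activity_matrix(matrix(rnorm(20 * 200), 20, 200))
    as.numeric(subspace_generalization(x, y, "centered"))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("seeded helpers restore the caller's RNG state", {
  set.seed(77)
  a <- activity_matrix(matrix(rnorm(40), 4, 10))
  before <- .Random.seed
  invisible(chance_auc(a, n_draws = 5, seed = 3))
  expect_identical(.Random.seed, before)
})
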