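# tiny deterministic beta set: nv voxels, nc conditions, 4 runs x 4 graphs
tiny_beta_set <- function(nv = 12, nc = 6, seed = 1, identical_all = FALSE) {
  set.seed(seed)
  base <- matrix(rnorm(nv * nc), nv, nc)
  runs <- lapply(1:4, function(r) {
    out <- lapply(c(Hl = 1, Hs = 2, Cl = 3, Cs = 4), function(g) {
      if (identical_all) base else matrix(rnorm(nv * nc), nv, nc)
    })
    names(out) <- c("Hl", "Hs", "Cl", "Cs")
    out
  })
  beta_set(runs)
}

test_that("beta_set validates its contract", {
  bs <- tiny_beta_set()
  expect_equal(bs$n_runs, 4)
  expect_equal(bs$n_voxels, 12)
  bad <- bs$betas
  bad[[2]]$Hs <- bad[[2]]$Hs[1:5, ]
  expect_error(beta_set(bad), "12 voxels")
  bad2 <- bs$betas
  bad2[[3]]$Cl <- matrix(rnorm(12), 12, 1)
  expect_error(beta_set(bad2), "2 conditions")
})

test_that("cross-validated AUC matrix: symmetry, range and recovery", {
  ident <- tiny_beta_set(identical_all = TRUE)
  m <- crossval_auc_matrix(ident, "raw")
  expect_true(all(abs(m - m[1, 1]) < 1e-10))   # all entries equal
  bs <- tiny_beta_set(seed = 3)
  m2 <- crossval_auc_matrix(bs, "raw")
  expect_true(all(m2 > 0 & m2 <= 1))
  # planted shared subspaces: same-family entries dominate cross-family
  hh_hc <- replicate(15, {
    sp <- planted_beta_spec(1, c(4, 4, 2), n_conditions = 8, shared_dim = 3,
                            overlap = 1, noise_sd = 0.2, effect_region = 1:32,
                            seed = sample.int(1e6, 1))
    mm <- crossval_auc_matrix(generate_beta_set(sp)[[1]], "raw")
    mean(mm[c("Hl", "Hs"), c("Hl", "Hs")]) -
      mean(mm[c("Hl", "Hs"), c("Cl", "Cs")])
  })
  expect_true(all(hh_hc > 0))
  # permuting the graph labels of the input permutes rows and columns
  perm <- c("Cl", "Hl", "Cs", "Hs")
  bs_perm <- beta_set(lapply(bs$betas, function(run) run[perm]))
  m3 <- crossval_auc_matrix(bs_perm, "raw")
  expect_equal(unclass(m3), unclass(m2)[perm, perm], tolerance = 1e-10)
})

test_that("contrasts implement the printed weight patterns", {
  m <- matrix(0, 4, 4, dimnames = list(GRAPHS <- c("Hl", "Hs", "Cl", "Cs"),
                                       GRAPHS))
  expect_equal(apply_contrast(m, "structural"), 0)
  m[] <- 0.6   # constant matrix, zero-sum weights
  expect_equal(apply_contrast(m, "structural"), 0)
  expect_equal(apply_contrast(m, "visual"), 0)
  m[c("Hl", "Hs"), c("Hl", "Hs")] <- 0.9
  m[c("Hl", "Hs"), c("Cl", "Cs")] <- 0.7
  expect_equal(apply_contrast(m, "structural"), 4 * 0.9 - 4 * 0.7)
  # visual contrast: +diagonal, -same-structure off-diagonal
  w <- contrast_spec("visual")$weights
  expect_equal(sum(w), 0)
  expect_equal(w["Hl", "Hl"] + w["Cs", "Cs"], 2)
  expect_equal(w["Hl", "Hs"] + w["Cl", "Cs"], -2)
  expect_equal(w["Hl", "Cl"], 0)
  expect_error(apply_contrast(matrix(0, 3, 3), "structural"), "match")
})

test_that("searchlight neighborhoods and whole-mask degeneracy", {
  pr_spec <- planted_beta_spec(1, c(3, 3, 2), n_conditions = 6,
                               shared_dim = 2, overlap = 1, noise_sd = 0.1,
                               effect_region = 1:18, seed = 4)
  bs <- generate_beta_set(pr_spec)[[1]]
  nb <- subgen:::searchlight_neighbors(bs$coords, 5)
  expect_true(all(vapply(seq_along(nb), function(i) i %in% nb[[i]],
                         logical(1))))
  # k = mask size: every center sees the whole mask, so all values agree.
  # Exact invariance to the per-center voxel reordering requires full-rank
  # training matrices (conditions >= voxels); under rank deficiency the
  # ordering of null-space PCs is genuinely arbitrary.
  fr <- planted_beta_spec(1, c(3, 3, 2), n_conditions = 24, shared_dim = 2,
                          overlap = 1, noise_sd = 0.1, effect_region = 1:18,
                          seed = 4)
  bs_fr <- generate_beta_set(fr)[[1]]
  vals <- searchlight_run(bs_fr, k_neighbors = 18, contrast = "structural")
  expect_true(all(abs(vals - vals[1]) < 1e-10))
  expect_error(searchlight_run(bs, k_neighbors = 100), "exceeds")
})

test_that("searchlight contrast is elevated only where structure is planted", {
  pr <- preset("fmri_small", seed = 21)
  vals <- searchlight_run(pr$subjects[[1]], pr$k_neighbors, "structural")
  expect_gt(mean(vals[pr$effect_region]), mean(vals[pr$null_region]) + 0.05)
  expect_lt(abs(mean(vals[pr$null_region])), 0.05)
})

test_that("sign-flip inference: antisymmetry, exhaustive oracle, smoothing", {
  set.seed(9)
  maps <- matrix(rnorm(6 * 10), 6, 10)
  res <- group_signflip(maps, n_flips = 200, seed = 2)
  res_neg <- group_signflip(-maps, n_flips = 200, seed = 2)
  expect_equal(res$t, -res_neg$t)
  expect_true(all(res$p_fwe > 0 & res$p_fwe <= 1))
  # exhaustive enumeration: equal positive values in a single voxel
  const <- matrix(1, 10, 1)
  ex <- group_signflip(const, n_flips = 2000)
  expect_true(ex$exhaustive)
  expect_equal(ex$p_fwe, 1 / 1024)
  expect_error(group_signflip(matrix(1, 1, 3)), "at least 2")
})

test_that("sign-flip FWE is calibrated on sign-symmetric null data", {
  set.seed(55)
  hits <- replicate(150, {
    maps <- matrix(rnorm(8 * 12), 8, 12)
    any(group_signflip(maps, n_flips = 99,
                       seed = sample.int(1e6, 1))$p_fwe < 0.05)
  })
  # familywise false-positive rate stays near the nominal level
  expect_lte(sum(hits), qbinom(0.995, 150, 0.05) + 1)
})

test_that("NIfTI round-trip preserves geometry through the searchlight path", {
  td <- withr::local_tempdir()
  dims <- c(4, 4, 3)
  mask <- array(1L, dims)
  mask_file <- file.path(td, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(mask), mask_file)
  set.seed(12)
  files <- lapply(1:4, function(r) {
    out <- lapply(c(Hl = "Hl", Hs = "Hs", Cl = "Cl", Cs = "Cs"), function(g) {
      f <- file.path(td, sprintf("beta_r%d_%s.nii.gz", r, g))
      RNifti::writeNifti(RNifti::asNifti(array(rnorm(prod(dims) * 5),
                                               c(dims, 5))), f)
      f
    })
    out
  })
  bs <- read_beta_nifti(files, mask_file)
  expect_equal(bs$n_voxels, prod(dims))
  expect_equal(ncol(bs$betas[[1]]$Hl), 5)
  out <- file.path(td, "stat.nii.gz")
  write_stat_nifti(seq_len(bs$n_voxels), bs, out)
  img <- RNifti::readNifti(out)
  expect_equal(dim(img), dims)
  expect_equal(as.numeric(img[2, 1, 1]), 2)  # voxel order preserved
  expect_equal(RNifti::pixdim(img), RNifti::pixdim(RNifti::readNifti(mask_file)))
})
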