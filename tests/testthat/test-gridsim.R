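test_that("grid cell maps are thresholded, periodic and hexagonal", {
  spec <- grid_module_spec(3, 0.2, c(4, 4), box_size = 10, resolution = 50)
  m <- grid_cell_map(spec, phase = c(0.7, 0.3))
  expect_true(min(m) >= 0)
  expect_equal(dim(m), c(50, 50))
  # translating the phase by one lattice vector reproduces the map exactly
  A <- subgen:::grid_geometry(spec)$A
  m_shift <- grid_cell_map(spec, phase = c(0.7, 0.3) + A[, 1])
  expect_equal(m, m_shift, tolerance = 1e-10)
  expect_equal(sqrt(colSums(A^2)), c(3, 3), tolerance = 1e-10)
  # autocorrelation ring: inner peaks at radius ~ spacing
  ac <- oracle_autocorr(m, 25)
  bin <- 10 / 50
  ctr <- 26
  peaks <- which(ac > 0.5, arr.ind = TRUE)
  radii <- sqrt((peaks[, 1] - ctr)^2 + (peaks[, 2] - ctr)^2) * bin
  ring <- radii[radii > 1]   # exclude the central peak blob
  expect_true(length(ring) > 0)
  expect_lt(abs(min(ring) - 3), 1.5 * bin + 0.35)
})

test_that("a module tiles the rhombus: counts, wrap-around, flat mean map", {
  sp <- small_module_pair()
  expect_equal(dim(sp$m1$maps)[1], 20 * 20)
  mm <- apply(sp$m1$maps, c(2, 3), mean)
  expect_lt(stats::sd(mm) / mean(mm), 0.05)
  # phases one full lattice vector apart give identical cells: compare the
  # built cell at fraction 0 with an explicit map shifted by a1
  A <- subgen:::grid_geometry(sp$spec)$A
  direct <- grid_cell_map(sp$spec, phase = as.numeric(sp$m1$phases[1, ]) + A %*% c(1, 0))
  expect_equal(matrix(sp$m1$maps[1, , ], 30, 30), direct, tolerance = 1e-10)
})

test_that("realignment preserves the population's pairwise structure", {
  sp <- small_module_pair()
  same <- realign_module(sp$m1, environment_realignment(c(0, 0)))
  expect_equal(same$maps, sp$m1$maps, tolerance = 1e-12)
  idx <- seq(1, 400, by = 10)
  f1 <- matrix(sp$m1$maps[idx, , ], length(idx))
  f2 <- matrix(sp$m2$maps[idx, , ], length(idx))
  dc <- abs(stats::cor(t(f1)) - stats::cor(t(f2)))
  expect_lt(max(dc), 0.06)
  expect_lt(mean(dc), 0.02)
  # end-to-end: the full population generalizes across environments
  d <- auc_difference(flatten_maps(sp$m1), flatten_maps(sp$m2), "zscored")
  expect_lt(abs(d), 0.01)
})

test_that("voxel grouping splits cells evenly and respects ratio_random", {
  sp <- small_module_pair()
  for (r in c(0, 0.37, 1)) {
    lab <- make_grouping(sp$m1, 4, r, seed = 5)
    expect_equal(length(lab), 400)
    expect_true(diff(range(table(lab))) <= 2)
  }
  lab0 <- make_grouping(sp$m1, 4, 0, seed = 5)
  # phase-contiguous: labels are blocks along the lexicographic phase order
  expect_false(is.unsorted(lab0[order(sp$m1$phase_idx[, 1],
                                      sp$m1$phase_idx[, 2])]))
  expect_error(make_grouping(sp$m1, 500, 0), "groups")
  expect_error(make_grouping(sp$m1, 4, 1.5), "ratio_random")
})

test_that("voxel averaging: counts, amplitude contrast, commutation", {
  sp <- small_module_pair()
  asn <- list(make_grouping(sp$m1, 4, 0, seed = 2))
  v0 <- group_into_voxels(list(sp$m1), asn)
  expect_equal(dim(v0), c(4, 900))
  # voxel map equals the mean of its member cells' peak-normalized maps
  flat <- unclass(flatten_maps(sp$m1))
  flat <- flat / apply(flat, 1, max)
  expect_equal(unname(unclass(v0)[2, ]),
               unname(colMeans(flat[asn[[1]] == 2, ])), tolerance = 1e-12)
  asn1 <- list(sample(rep_len(1:4, 400)))
  vr <- group_into_voxels(list(sp$m1), asn1)
  expect_gt(mean(apply(v0, 1, var)) / mean(apply(vr, 1, var)), 10)
  # grouping then realigning equals realigning then grouping
  v2a <- group_into_voxels(list(sp$m2), asn)
  m2b <- realign_module(sp$m1, environment_realignment(c(0.31, 0.67)))
  v2b <- group_into_voxels(list(m2b), asn)
  expect_equal(unclass(v2a), unclass(v2b), tolerance = 1e-12)
})

test_that("voxel noise has the declared scale and a zero identity", {
  sp <- small_module_pair()
  v <- group_into_voxels(list(sp$m1), list(make_grouping(sp$m1, 4, 0, 1)))
  expect_identical(unclass(add_voxel_noise(v, 0)), unclass(v))
  noisy <- add_voxel_noise(v, 0.1, seed = 3)
  expect_lt(abs(stats::sd(noisy - v) - 0.1) / 0.1, 0.05)
  expect_identical(unclass(add_voxel_noise(v, 0.1, seed = 3)),
                   unclass(noisy))  # bit-reproducible
  expect_error(add_voxel_noise(v, -0.01), "non-negative")
})

test_that("place cells remap across environments; grids do not", {
  pc_same <- simulate_place_cells(10, seed = 6, remap = FALSE)
  expect_equal(pc_same$env1$maps, pc_same$env2$maps)
  expect_equal(auc_difference(flatten_maps(pc_same$env1),
                              flatten_maps(pc_same$env2), "zscored"), 0)
  expect_error(simulate_place_cells(1), "at least 2")
  sp <- small_module_pair()
  set.seed(31)
  wins <- replicate(20, {
    idx <- sample(400, 20)
    g1 <- activity_matrix(matrix(sp$m1$maps[idx, , ], 20))
    g2 <- activity_matrix(matrix(sp$m2$maps[idx, , ], 20))
    pc <- simulate_place_cells(20, field_width = 1.2, box = 10,
                               resolution = 30,
                               seed = sample.int(1e6, 1))
    auc_difference(g1, g2, "zscored") <
      auc_difference(flatten_maps(pc$env1), flatten_maps(pc$env2), "zscored")
  })
  expect_gte(mean(wins), 0.95)
})

test_that("a one-point sweep reduces to a single generalization analysis", {
  sp <- small_module_pair()
  tab <- power_sweep(list(sp$m1), list(sp$m2), ratio_grid = 0,
                     sigma_grid = 0, n_reps = 1, seed = 9, n_perms = 0)
  expect_equal(nrow(tab), 1)
  asn <- lapply(1, function(mi) make_grouping(sp$m1, 4, 0, (9 + 7919L) %% .Machine$integer.max + mi))
  v1 <- group_into_voxels(list(sp$m1), asn)
  v2 <- group_into_voxels(list(sp$m2), asn)
  expect_equal(tab$auc_between,
               as.numeric(subspace_generalization(v1, v2, "zscored")))
  expect_equal(tab$auc_diff, tab$auc_within - tab$auc_between)
})
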