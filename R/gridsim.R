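#' Specification of a simulated grid-cell module
#'
#' A module is a population of grid cells sharing spacing and orientation
#' and differing only in spatial phase. Cell rate maps are a thresholded
#' (zero-clipped) sum of three 2-D cosines whose wave vectors are 60 degrees
#' apart, giving hexagonal firing fields. Phases tile the unit rhombus of
#' the hexagonal lattice on a `phase_lattice` grid, so the module covers all
#' relative phases uniformly (the default 116 x 116 lattice gives 13,456
#' cells and a near-constant population-mean map).
#'
#' @param spacing Grid period in environment units (> 0).
#' @param orientation Grid orientation in radians.
#' @param phase_lattice Integer pair: phase-grid resolution along the two
#'   rhombus axes (default `c(116, 116)`).
#' @param box_size Side of the square environment (default 10).
#' @param resolution Bins per axis of the evaluated rate map (default 50,
#'   minimum 8).
#' @return An object of class `"grid_module_spec"`.
#' @export
grid_module_spec <- function(spacing, orientation = 0,
                             phase_lattice = c(116, 116),
                             box_size = 10, resolution = 50) {
  if (spacing <= 0) stop("spacing must be positive")
  if (length(phase_lattice) == 1L) phase_lattice <- rep(phase_lattice, 2L)
  phase_lattice <- as.integer(phase_lattice)
  if (any(phase_lattice < 1L)) stop("phase_lattice entries must be >= 1")
  resolution <- as.integer(resolution)
  if (resolution < 8L) stop("resolution must be at least 8")
  structure(list(spacing = spacing, orientation = orientation,
                 phase_lattice = phase_lattice, box_size = box_size,
                 resolution = resolution),
            class = "grid_module_spec")
}

#' Coherent realignment of a module between environments
#'
#' Across environments a grid module shifts as a whole: every cell's firing
#' pattern is translated by the same offset, so relative phases — and hence
#' the cells' coactivation structure — are preserved. The shift is given in
#' rhombus coordinates (fractions of the two lattice vectors, wrapped into
#' `[0, 1)`); an optional rigid rotation of the whole pattern is supported.
#'
#' @param phase_shift Length-2 numeric, fractions of the lattice vectors.
#' @param rotation Radians (default 0).
#' @return An object of class `"environment_realignment"`.
#' @export
environment_realignment <- function(phase_shift = c(0, 0), rotation = 0) {
  structure(list(phase_shift = phase_shift %% 1, rotation = rotation),
            class = "environment_realignment")
}

# wave vectors (3 x 2) and lattice vectors (2 x 2, columns a1, a2)
grid_geometry <- function(spec, rotation = 0) {
  ang <- spec$orientation + rotation + c(0, pi / 3, 2 * pi / 3)
  kmag <- 4 * pi / (sqrt(3) * spec$spacing)
  K <- kmag * cbind(cos(ang), sin(ang))
  A <- 2 * pi * solve(K[1:2, ])   # columns a_j satisfy k_i . a_j = 2 pi delta_ij
  list(K = K, A = A)
}

# bin-center coordinates of the evaluation grid, x-fastest (res^2 x 2)
box_coords <- function(spec) {
  ctr <- (seq_len(spec$resolution) - 0.5) * spec$box_size / spec$resolution
  as.matrix(expand.grid(x = ctr, y = ctr))
}

#' Rate map of a single grid cell
#'
#' `r(x) = max(0, sum_i cos(k_i . (x - phase - shift)))` with the three wave
#' vectors 60 degrees apart and `|k| = 4*pi / (sqrt(3) * spacing)`, evaluated
#' at the bin centers of the module's box.
#'
#' @param spec A `grid_module_spec`.
#' @param phase Length-2 numeric phase offset in environment (x, y) units.
#' @param env An `environment_realignment` (default: none).
#' @return `resolution x resolution` numeric matrix, non-negative.
#' @export
grid_cell_map <- function(spec, phase = c(0, 0),
                          env = environment_realignment()) {
  g <- grid_geometry(spec, env$rotation)
  shift <- as.numeric(g$A %*% env$phase_shift)
  X <- box_coords(spec)
  ph <- as.numeric(g$K %*% (phase + shift))   # 3 phase angles
  vals <- cos(X %*% t(g$K) - rep(ph, each = nrow(X)))
  m <- pmax(0, rowSums(vals))
  matrix(m, spec$resolution, spec$resolution)
}

#' Build a full grid module
#'
#' One cell per phase-lattice offset covering the unit rhombus of the
#' hexagonal lattice. The population-mean map is near-constant across the
#' box (the phases tile all translations uniformly).
#'
#' @param spec A `grid_module_spec`.
#' @param env An `environment_realignment`.
#' @return A `ratemap_stack` with extra fields `spec`, `env`, `phases`
#'   (cells x 2, environment units) and `phase_idx` (cells x 2, integer
#'   lattice coordinates).
#' @export
build_module <- function(spec, env = environment_realignment()) {
  g <- grid_geometry(spec, env$rotation)
  shift <- as.numeric(g$A %*% env$phase_shift)
  n1 <- spec$phase_lattice[1]; n2 <- spec$phase_lattice[2]
  idx <- as.matrix(expand.grid(u = seq_len(n1) - 1L, v = seq_len(n2) - 1L))
  frac <- cbind(idx[, 1] / n1, idx[, 2] / n2)
  phases <- frac %*% t(g$A)                     # n x 2 in (x, y) units
  X <- box_coords(spec)
  CX <- cos(X %*% t(g$K)); SX <- sin(X %*% t(g$K))
  delta <- (phases + rep(shift, each = nrow(phases))) %*% t(g$K)  # n x 3
  M <- CX %*% t(cos(delta)) + SX %*% t(sin(delta))  # bins x cells
  M[M < 0] <- 0
  maps <- array(t(M), c(nrow(phases), spec$resolution, spec$resolution))
  dimnames(maps) <- list(paste0("g", idx[, 1], "_", idx[, 2]), NULL, NULL)
  edges <- seq(0, spec$box_size, length.out = spec$resolution + 1L)
  stack <- ratemap_stack(maps, edges, edges)
  stack$spec <- spec
  stack$env <- env
  stack$phases <- phases
  stack$phase_idx <- idx
  stack
}

#' Realign a module to a new environment
#'
#' Rebuilds every cell's map with the same module-level spec and phases but
#' the new environment's common shift, modeling coherent grid realignment:
#' pairwise relationships between cells are preserved exactly.
#'
#' @param module A module built by [build_module()].
#' @param env2 An `environment_realignment` for the new environment.
#' @return A `ratemap_stack` for the new environment.
#' @export
realign_module <- function(module, env2) {
  if (is.null(module$spec)) stop("module must come from build_module()")
  build_module(module$spec, env2)
}

#' Assign a module's cells to pseudo-voxel groups
#'
#' Two-stage assignment: a fraction `ratio_random` of cells is removed
#' first and spread uniformly at random over the groups; the remaining
#' cells are sorted lexicographically by their rhombus phase coordinates
#' and cut into contiguous, equal-size phase blocks. `ratio_random = 0`
#' gives purely phase-organized voxels; `1` gives purely random voxels.
#'
#' @param module A module from [build_module()].
#' @param n_groups Groups (pseudo-voxels) per module, default 4.
#' @param ratio_random Fraction in `[0, 1]` of randomly assigned cells.
#' @param seed Optional integer seed for the random stage.
#' @return Integer vector of group labels (1..n_groups), one per cell.
#' @export
make_grouping <- function(module, n_groups = 4, ratio_random = 0, seed = NULL) {
  n <- n_cells(module)
  n_groups <- as.integer(n_groups)
  if (n_groups > n) stop("more groups (", n_groups, ") than cells (", n, ")")
  if (ratio_random < 0 || ratio_random > 1) stop("ratio_random must be in [0, 1]")
  labels <- integer(n)
  with_seed(seed, {
    n_rand <- round(ratio_random * n)
    rand_cells <- if (n_rand > 0) sample.int(n, n_rand) else integer(0)
    if (n_rand > 0)
      labels[rand_cells] <- sample(rep_len(seq_len(n_groups), n_rand))
    rest <- setdiff(seq_len(n), rand_cells)
    if (length(rest)) {
      ord <- rest[order(module$phase_idx[rest, 1], module$phase_idx[rest, 2])]
      sizes <- diff(round(seq(0, length(rest), length.out = n_groups + 1L)))
      labels[ord] <- rep(seq_len(n_groups), times = sizes)
    }
  })
  labels
}

#' Average grouped cells into pseudo-voxels
#'
#' Each voxel's map is the mean of its member cells' rate maps (after
#' per-cell peak normalization by default, so the phase-organized vs random
#' amplitude contrast is not confounded by absolute rates). Voxel vectors
#' from all modules are concatenated into one `voxels x bins` activity
#' matrix.
#'
#' @param modules List of module stacks sharing box and resolution. Entries
#'   may also be pre-flattened `cells x bins` matrices (as from
#'   [flatten_maps()]), which avoids re-flattening when many groupings of
#'   the same modules are drawn.
#' @param assignments List of group-label vectors, one per module (from
#'   [make_grouping()]), or `NULL` to build them here.
#' @param n_groups,ratio_random,seed Used when `assignments` is `NULL`.
#' @param normalize Peak-normalize each cell before averaging (default TRUE).
#' @return An `activity_matrix` (`n_modules * n_groups` voxels x bins) with
#'   attributes `"assignments"` and `"map_dim"`.
#' @export
group_into_voxels <- function(modules, assignments = NULL, n_groups = 4,
                              ratio_random = 0, seed = NULL, normalize = TRUE) {
  if (inherits(modules, "ratemap_stack")) modules <- list(modules)
  res <- if (inherits(modules[[1]], "ratemap_stack")) dim(modules[[1]]$maps)[2:3]
         else attr(modules[[1]], "map_dim")
  if (is.null(res)) stop("flattened modules must carry a 'map_dim' attribute")
  if (is.null(assignments)) {
    if (!all(vapply(modules, inherits, logical(1), "ratemap_stack")))
      stop("pre-flattened modules require explicit assignments ",
           "(phase information is lost in flattening)")
    seeds <- if (is.null(seed)) vector("list", length(modules))
             else as.list(seed + seq_along(modules) - 1L)
    assignments <- lapply(seq_along(modules), function(i)
      make_grouping(modules[[i]], n_groups, ratio_random, seeds[[i]]))
  }
  rows <- list()
  for (mi in seq_along(modules)) {
    stack <- modules[[mi]]
    if (inherits(stack, "ratemap_stack")) {
      if (!all(dim(stack$maps)[2:3] == res))
        stop("modules must share box resolution")
      n <- n_cells(stack)
      Mflat <- matrix(stack$maps, n, prod(res))  # cells x bins
    } else {
      Mflat <- unclass(stack)
      n <- nrow(Mflat)
      if (ncol(Mflat) != prod(res))
        stop("modules must share box resolution")
    }
    if (normalize) {
      peaks <- Mflat[cbind(seq_len(n), max.col(Mflat, ties.method = "first"))]
      if (any(peaks <= 0)) stop("cell with all-zero map cannot be peak-normalized")
      Mflat <- Mflat / peaks
    }
    lab <- assignments[[mi]]
    ng <- max(lab)
    G <- matrix(0, n, ng)
    G[cbind(seq_len(n), lab)] <- 1
    G <- sweep(G, 2L, colSums(G), "/")
    vox <- crossprod(G, Mflat)                   # groups x bins
    rownames(vox) <- paste0("mod", mi, "_vox", seq_len(ng))
    rows[[mi]] <- vox
  }
  vals <- do.call(rbind, rows)
  labs <- as.vector(outer(seq_len(res[1]), seq_len(res[2]),
                          function(i, j) paste0("x", i, "_y", j)))
  out <- activity_matrix(vals, state_labels = labs)
  attr(out, "map_dim") <- res
  attr(out, "assignments") <- assignments
  out
}

#' Add spatial white noise to voxel maps
#'
#' Independent zero-mean Gaussian noise, standard deviation `sigma`, added
#' to every voxel at every spatial bin. `sigma = 0` returns the input
#' unchanged.
#'
#' @param A An `activity_matrix` (voxels x bins).
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return The noisy `activity_matrix`.
#' @export
add_voxel_noise <- function(A, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative, got ", sigma)
  a <- as_activity_matrix(A)
  if (sigma == 0) return(a)
  noisy <- a + with_seed(seed, matrix(stats::rnorm(length(a), sd = sigma),
                                      nrow(a), ncol(a)))
  attributes(noisy) <- attributes(a)
  noisy
}

#' Simulate remapping place cells in two environments
#'
#' Each cell fires in a single Gaussian field; field centers are uniform in
#' the box. In environment 2 the centers are redrawn independently (global
#' remapping), destroying the population's coactivation structure while
#' leaving the within-environment structure intact.
#'
#' @param n_cells Number of cells (>= 2).
#' @param field_width Gaussian field sd, environment units (default 1).
#' @param box Box side (default 10).
#' @param resolution Bins per axis (default 50).
#' @param seed Optional integer seed.
#' @param remap Redraw centers in environment 2 (default TRUE; `FALSE`
#'   duplicates environment 1).
#' @return List with `env1` and `env2` (`ratemap_stack`s) and the center
#'   matrices `centers1`, `centers2`.
#' @export
simulate_place_cells <- function(n_cells, field_width = 1, box = 10,
                                 resolution = 50, seed = NULL, remap = TRUE) {
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop("need at least 2 place cells for subspace analysis")
  ctr <- (seq_len(resolution) - 0.5) * box / resolution
  X <- as.matrix(expand.grid(x = ctr, y = ctr))
  bump_stack <- function(centers) {
    d2 <- outer(X[, 1], centers[, 1], "-")^2 + outer(X[, 2], centers[, 2], "-")^2
    M <- exp(-d2 / (2 * field_width^2))         # bins x cells
    maps <- array(t(M), c(nrow(centers), resolution, resolution))
    dimnames(maps) <- list(paste0("p", seq_len(nrow(centers))), NULL, NULL)
    edges <- seq(0, box, length.out = resolution + 1L)
    ratemap_stack(maps, edges, edges)
  }
  with_seed(seed, {
    centers1 <- matrix(stats::runif(2 * n_cells, 0, box), n_cells, 2)
    centers2 <- if (remap) matrix(stats::runif(2 * n_cells, 0, box), n_cells, 2)
                else centers1
    list(env1 = bump_stack(centers1), env2 = bump_stack(centers2),
         centers1 = centers1, centers2 = centers2)
  })
}

#' Default module spacings and orientations
#'
#' Four modules with spacing ratios near sqrt(2) — the standard module
#' progression — and staggered orientations.
#'
#' @param phase_lattice,box_size,resolution Passed to [grid_module_spec()].
#' @return List of four `grid_module_spec`s.
#' @export
default_module_specs <- function(phase_lattice = c(116, 116),
                                 box_size = 10, resolution = 50) {
  spacings <- c(3.0, 4.2, 5.9, 8.3)
  orientations <- c(0, 7.5, 15, 22.5) * pi / 180
  Map(function(s, o) grid_module_spec(s, o, phase_lattice, box_size, resolution),
      spacings, orientations)
}

#' Default environment-2 realignments for a set of modules
#'
#' Every module realigns by the same fraction of its own unit cell: the
#' same rhombus-coordinate shift is applied to each module's phase lattice.
#' This realignment leaves the population's pairwise activity relationships
#' (within and across modules) essentially unchanged, which is the defining
#' property of coherent grid realignment. Environment 1 is the unshifted
#' reference.
#'
#' @param specs List of `grid_module_spec`s (default: the package's four
#'   standard modules); only its length is used.
#' @param frac Length-2 rhombus-coordinate shift shared by all modules
#'   (fixed default `c(0.31, 0.67)`).
#' @return List of `environment_realignment`s, one per module.
#' @export
default_env2_shifts <- function(specs = default_module_specs(),
                                frac = c(0.31, 0.67)) {
  lapply(seq_along(specs), function(i) environment_realignment(frac))
}

#' Sweep pseudo-voxel grouping and noise conditions
#'
#' For every combination of `ratio_random`, noise `sigma` and replicate:
#' group the modules' cells into pseudo-voxels (fresh random grouping per
#' replicate), add noise independently in the two environments, and record
#' the within-environment AUC, the symmetrized between-environment AUC,
#' their difference, and an identity-permutation p-value.
#'
#' @param modules_env1,modules_env2 Lists of module stacks for the two
#'   environments (same specs and phases, different realignment).
#' @param ratio_grid,sigma_grid Numeric grids to sweep.
#' @param n_reps Replicates per cell of the sweep.
#' @param seed Integer seed; every replicate derives its own sub-seed.
#' @param n_groups Groups per module (default 4).
#' @param n_perms Permutations for the p-value (default 100; 0 skips it).
#' @param scaling_mode Scaling for the subspace analysis (default
#'   `"zscored"`, the rate-map convention).
#' @return A data.frame with one row per (ratio, sigma, rep).
#' @export
power_sweep <- function(modules_env1, modules_env2, ratio_grid = c(0, 0.5, 1),
                        sigma_grid = c(0, 0.1), n_reps = 1, seed = 1,
                        n_groups = 4, n_perms = 100,
                        scaling_mode = "zscored") {
  grid <- expand.grid(ratio_random = ratio_grid, sigma = sigma_grid,
                      rep = seq_len(n_reps))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$ratio_random[i]; s <- grid$sigma[i]; rep_i <- grid$rep[i]
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    asn <- lapply(seq_along(modules_env1), function(mi)
      make_grouping(modules_env1[[mi]], n_groups, r, sub_seed + mi))
    v1 <- group_into_voxels(modules_env1, asn)
    v2 <- group_into_voxels(modules_env2, asn)
    v1 <- add_voxel_noise(v1, s, sub_seed + 101L)
    v2 <- add_voxel_noise(v2, s, sub_seed + 102L)
    within <- mean(c(
      auc_from_variance(variance_along(v1, compute_pcs(v1, scaling_mode),
                                       scaling_mode))$auc,
      auc_from_variance(variance_along(v2, compute_pcs(v2, scaling_mode),
                                       scaling_mode))$auc))
    between <- as.numeric(subspace_generalization(v1, v2, scaling_mode))
    p <- NA_real_
    if (n_perms > 0)
      p <- permutation_test_identity(v1, v2, n_perms = n_perms,
                                     seed = sub_seed + 103L,
                                     scaling_mode = scaling_mode)$p
    data.frame(ratio_random = r, sigma = s, rep = rep_i,
               auc_within = within, auc_between = between,
               auc_diff = within - between, p_perm = p)
  })
  do.call(rbind, rows)
}
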