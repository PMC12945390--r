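GRAPHS <- c("Hl", "Hs", "Cl", "Cs")

#' Construct a run-by-graph beta set
#'
#' Holds one subject's condition-activation ("beta") matrices: for each of
#' 4 scanner runs and each of 4 task graphs (`Hl`, `Hs` — hexagonal large /
#' small; `Cl`, `Cs` — community-structured large / small) a `voxels x
#' conditions` matrix over a common voxel set. Optionally carries voxel
#' grid coordinates (for searchlight mode) and a reference NIfTI image.
#'
#' @param betas List of runs, each a named list of per-graph matrices
#'   (names `Hl`, `Hs`, `Cl`, `Cs`), every matrix `n_voxels x n_conditions`
#'   with `n_conditions >= 2`.
#' @param coords Optional `n_voxels x 3` matrix of integer voxel-grid
#'   coordinates.
#' @param mask_dim Optional volume dimensions `c(nx, ny, nz)`.
#' @param reference Optional NIfTI image supplying geometry for outputs.
#' @return An object of class `"beta_set"`.
#' @export
beta_set <- function(betas, coords = NULL, mask_dim = NULL, reference = NULL) {
  if (!length(betas)) stop("betas must contain at least one run")
  graphs <- names(betas[[1]])
  if (is.null(graphs)) stop("each run must be a named list of graph matrices")
  nv <- nrow(betas[[1]][[1]])
  for (r in seq_along(betas)) {
    if (!identical(sort(names(betas[[r]])), sort(graphs)))
      stop("run ", r, " does not contain the same graphs as run 1")
    for (g in graphs) {
      m <- betas[[r]][[g]]
      if (!is.matrix(m) || nrow(m) != nv)
        stop("run ", r, " graph ", g, ": expected a matrix with ", nv, " voxels")
      if (ncol(m) < 2L)
        stop("run ", r, " graph ", g, ": need at least 2 conditions")
      if (!all(is.finite(m)))
        stop("run ", r, " graph ", g, ": non-finite values")
    }
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != nv) stop("coords must have one row per voxel")
  }
  structure(list(betas = betas, graphs = graphs, n_voxels = nv,
                 n_runs = length(betas), coords = coords,
                 mask_dim = mask_dim, reference = reference),
            class = "beta_set")
}

#' @export
print.beta_set <- function(x, ...) {
  cat("Beta set:", x$n_runs, "runs x {", paste(x$graphs, collapse = ", "),
      "},", x$n_voxels, "voxels,", ncol(x$betas[[1]][[1]]), "conditions\n")
  invisible(x)
}

# restrict a beta set to a voxel subset (parent already validated, so the
# subset is built without re-validation — searchlights call this per center)
subset_beta_set <- function(bs, idx) {
  betas <- lapply(bs$betas, function(run)
    lapply(run, function(m) m[idx, , drop = FALSE]))
  structure(list(betas = betas, graphs = bs$graphs, n_voxels = length(idx),
                 n_runs = bs$n_runs,
                 coords = if (!is.null(bs$coords)) bs$coords[idx, , drop = FALSE],
                 mask_dim = NULL, reference = NULL),
            class = "beta_set")
}

#' Cross-validated graph-by-graph AUC matrix
#'
#' For each held-out run `j` and each ordered graph pair `(a, b)`: estimate
#' the PCs of graph `a` from the mean beta matrix over the other runs, then
#' project graph `b`'s held-out-run matrix on them and take the AUC of the
#' normalized cumulative variance-explained curve (normalized by the
#' held-out matrix's own total variance). Entries are averaged over the
#' held-out runs. Diagonal entries therefore always compare data across
#' different runs of the same graph, never a matrix with itself.
#'
#' @param bs A `beta_set` with at least 2 runs (4 in the standard design).
#' @param scaling_mode Scaling for the subspace analysis; `"raw"` (the
#'   uncentered-beta convention) by default.
#' @param truncate Optional PC truncation (default full voxel basis).
#' @return A `graphs x graphs` numeric matrix of class `"auc_matrix"`;
#'   rows index the PC-source graph `a`, columns the projected graph `b`.
#' @export
crossval_auc_matrix <- function(bs, scaling_mode = c("raw", "centered",
                                                     "zscored"),
                                truncate = NULL) {
  scaling_mode <- match.arg(scaling_mode)
  if (!inherits(bs, "beta_set")) stop("bs must be a 'beta_set'")
  if (bs$n_runs < 2L) stop("cross-validation requires at least 2 runs")
  g <- bs$graphs
  nv <- bs$n_voxels
  k <- if (is.null(truncate)) nv else min(as.integer(truncate), nv)
  prep <- function(m) {
    if (scaling_mode == "raw") return(m)
    m <- m - rowMeans(m)
    if (scaling_mode == "zscored") {
      s <- sqrt(rowSums(m^2) / (ncol(m) - 1L))
      if (any(s == 0)) stop("zero-variance voxel under zscored scaling")
      m <- m / s
    }
    m
  }
  prepared <- lapply(bs$betas, function(run) lapply(run, prep))
  acc <- matrix(0, length(g), length(g), dimnames = list(g, g))
  for (j in seq_len(bs$n_runs)) {
    held <- prepared[[j]]
    totals <- vapply(held, function(m) sum(m^2), numeric(1))
    for (a in g) {
      train <- Reduce(`+`, lapply(bs$betas[-j], `[[`, a)) / (bs$n_runs - 1L)
      U <- eigen(tcrossprod(prep(train)), symmetric = TRUE)$vectors
      if (k < nv) U <- U[, seq_len(k), drop = FALSE]
      for (b in g) {
        cf <- c(0, cumsum(rowSums(crossprod(U, held[[b]])^2)) / totals[[b]])
        acc[a, b] <- acc[a, b] + sum((cf[-1L] + cf[-(k + 1L)]) / 2) / k
      }
    }
  }
  out <- acc / bs$n_runs
  class(out) <- c("auc_matrix", class(out))
  out
}

#' Built-in and custom contrasts over the 4 x 4 AUC matrix
#'
#' `"structural"` compares hexagonal-graph data projected on (cross-run)
#' hexagonal-graph PCs against the same data projected on community-graph
#' PCs: `[HlHl + HlHs + HsHl + HsHs] - [HlCl + HlCs + HsCl + HsCs]`.
#' `"visual"` compares same-stimulus pairs against same-structure,
#' different-stimulus pairs:
#' `[HlHl + ClCl + HsHs + CsCs] - [HlHs + HsHl + ClCs + CsCl]`.
#'
#' @param name `"structural"`, `"visual"`, or a custom name for `weights`.
#' @param weights Optional 4 x 4 weight matrix (rows = PC-source graph,
#'   columns = data graph) for a custom contrast; difference contrasts
#'   should have zero-sum weights.
#' @return An object of class `"contrast_spec"` (name + weight matrix).
#' @export
contrast_spec <- function(name = c("structural", "visual"), weights = NULL) {
  if (is.null(weights)) {
    name <- match.arg(name)
    w <- matrix(0, 4, 4, dimnames = list(GRAPHS, GRAPHS))
    if (name == "structural") {
      w[c("Hl", "Hs"), c("Hl", "Hs")] <- 1
      w[c("Hl", "Hs"), c("Cl", "Cs")] <- -1
    } else {
      w[cbind(GRAPHS, GRAPHS)] <- 1
      w[cbind(c("Hl", "Hs", "Cl", "Cs"), c("Hs", "Hl", "Cs", "Cl"))] <- -1
    }
  } else {
    w <- as.matrix(weights)
    if (!all(dim(w) == c(4, 4))) stop("custom contrast weights must be 4 x 4")
    if (is.null(dimnames(w))) dimnames(w) <- list(GRAPHS, GRAPHS)
  }
  structure(list(name = if (is.character(name)) name[1] else "custom",
                 weights = w),
            class = "contrast_spec")
}

#' Apply a contrast to an AUC matrix
#'
#' @param m An `auc_matrix` (or plain matrix) from [crossval_auc_matrix()].
#' @param contrast A `contrast_spec` or a built-in contrast name.
#' @return Numeric scalar `sum(weights * m)`.
#' @export
apply_contrast <- function(m, contrast = "structural") {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  w <- contrast$weights
  if (!all(dim(m) == dim(w)))
    stop("contrast weights (", paste(dim(w), collapse = "x"),
         ") do not match the AUC matrix (", paste(dim(m), collapse = "x"), ")")
  if (!is.null(dimnames(m)) && !is.null(dimnames(w)))
    w <- w[rownames(m), colnames(m)]
  sum(w * unclass(m))
}

# k nearest in-mask voxels of each center by Euclidean distance on grid
# coordinates, center included, ties broken by linear voxel index
searchlight_neighbors <- function(coords, k) {
  n <- nrow(coords)
  if (k > n) stop("searchlight size k = ", k, " exceeds mask size ", n)
  lapply(seq_len(n), function(i) {
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2 +
      (coords[, 3] - coords[i, 3])^2
    order(d2, seq_len(n))[seq_len(k)]
  })
}

#' Searchlight subspace-generalization contrast map
#'
#' For every voxel in the mask: take its `k_neighbors` nearest in-mask
#' voxels (Euclidean distance on voxel-grid coordinates, center included,
#' ties broken by linear index), compute the cross-validated AUC matrix on
#' that neighborhood's beta submatrices, and apply the contrast. Returns
#' one contrast value per voxel.
#'
#' @param bs A `beta_set` carrying voxel `coords`.
#' @param k_neighbors Searchlight size (default 100).
#' @param contrast A `contrast_spec` or name (default `"structural"`).
#' @param scaling_mode Scaling for the subspace analysis (default `"raw"`).
#' @param truncate Optional PC truncation.
#' @return Numeric vector of per-voxel contrast values, with the AUC-matrix
#'   run averages computed per neighborhood.
#' @export
searchlight_run <- function(bs, k_neighbors = 100, contrast = "structural",
                            scaling_mode = "raw", truncate = NULL) {
  if (is.null(bs$coords)) stop("searchlight mode requires voxel coordinates")
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  nb <- searchlight_neighbors(bs$coords, k_neighbors)
  vapply(seq_along(nb), function(i) {
    sub <- subset_beta_set(bs, nb[[i]])
    apply_contrast(crossval_auc_matrix(sub, scaling_mode, truncate), contrast)
  }, numeric(1))
}

#' Group-level sign-flip test with max-statistic FWE control
#'
#' One-sample t statistic per voxel across subjects; the null is built by
#' randomly flipping each subject's map sign and recording the maximum t
#' over the mask in each iteration, so the resulting p-values are
#' familywise-error corrected. With `exhaustive = TRUE` (or whenever all
#' `2^n_subjects` flip patterns fit within `n_flips`) the full enumeration
#' is used and p-values are exact fractions of the enumeration; otherwise
#' `n_flips` random draws are used with the +1 smoothing.
#'
#' Voxels where the across-subject standard deviation is zero get
#' `t = sign(mean) * Inf` (0 when the mean is also zero).
#'
#' @param maps Numeric `n_subjects x n_voxels` matrix of per-subject
#'   contrast maps (or a list of equal-length vectors).
#' @param n_flips Sign-flip iterations (default 10000).
#' @param seed Optional integer seed.
#' @param exhaustive Force or forbid full enumeration (default: automatic).
#' @return List with `t` (observed per-voxel t), `p_fwe` (per-voxel
#'   FWE-corrected p), `null_max` (null distribution of the max statistic)
#'   and `exhaustive`.
#' @export
group_signflip <- function(maps, n_flips = 10000, seed = NULL,
                           exhaustive = NULL) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 2L) stop("group inference requires at least 2 subjects")
  nv <- ncol(maps)
  ss <- colSums(maps^2)
  tstat <- function(colmeans) {
    v <- (ss - n * colmeans^2) / (n - 1L)
    v[v < 0] <- 0
    t <- colmeans / sqrt(v / n)
    zero_sd <- v == 0
    t[zero_sd] <- sign(colmeans[zero_sd]) * Inf
    t[zero_sd & colmeans == 0] <- 0
    t
  }
  t_obs <- tstat(colMeans(maps))
  use_exh <- if (is.null(exhaustive)) 2^n <= n_flips else isTRUE(exhaustive)
  if (use_exh) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    signs <- with_seed(seed, matrix(sample(c(1, -1), n * n_flips,
                                           replace = TRUE), n_flips, n))
  }
  M <- (signs %*% maps) / n                    # flips x voxels of means
  null_max <- vapply(seq_len(nrow(M)), function(i) max(tstat(M[i, ])),
                     numeric(1))
  p_fwe <- if (use_exh) {
    vapply(t_obs, function(tv) mean(null_max >= tv), numeric(1))
  } else {
    vapply(t_obs, function(tv)
      (1 + sum(null_max >= tv)) / (1 + nrow(M)), numeric(1))
  }
  list(t = t_obs, p_fwe = p_fwe, null_max = null_max, exhaustive = use_exh)
}

#' Read beta volumes and a mask from NIfTI-1 files
#'
#' Each (run, graph) is a 4-D NIfTI file whose 4th dimension indexes
#' conditions; the mask is a 3-D binary volume on the same grid. In-mask
#' voxels become the rows of the beta matrices and their grid coordinates
#' are kept for searchlight mode.
#'
#' @param files List of runs, each a named list (graph -> file path).
#' @param mask_file Path to the binary mask volume.
#' @return A `beta_set`.
#' @export
read_beta_nifti <- function(files, mask_file) {
  mask_img <- RNifti::readNifti(mask_file)
  mask <- array(as.logical(mask_img > 0), dim(mask_img))
  coords <- which(mask, arr.ind = TRUE)
  betas <- lapply(files, function(run) {
    out <- lapply(run, function(f) {
      img <- RNifti::readNifti(f)
      d <- dim(img)
      if (length(d) != 4L) stop("expected a 4-D beta volume: ", f)
      m <- matrix(img, prod(d[1:3]), d[4])
      m[mask, , drop = FALSE]
    })
    out
  })
  beta_set(betas, coords = coords, mask_dim = dim(mask_img),
           reference = mask_img)
}

#' Write a per-voxel statistic map as NIfTI-1
#'
#' Values are placed at the beta set's in-mask voxel coordinates of a
#' volume with the mask's dimensions and geometry; out-of-mask voxels
#' are 0.
#'
#' @param values Numeric vector, one value per in-mask voxel.
#' @param bs The `beta_set` the values were computed from (supplies
#'   coordinates, dimensions and the reference geometry).
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stat_nifti <- function(values, bs, path) {
  if (is.null(bs$coords) || is.null(bs$mask_dim))
    stop("beta set lacks mask geometry; cannot write a volume")
  vol <- array(0, bs$mask_dim)
  vol[bs$coords] <- values
  img <- if (!is.null(bs$reference))
    RNifti::asNifti(vol, reference = bs$reference) else RNifti::asNifti(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Serialize a beta set as a directory of delimited text
#'
#' One CSV per (run, graph) matrix plus coordinates and a JSON manifest;
#' [read_beta_set()] round-trips losslessly.
#'
#' @param bs A `beta_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_beta_set <- function(bs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_len(bs$n_runs))
    for (g in bs$graphs)
      utils::write.table(bs$betas[[r]][[g]],
                         file.path(dir, sprintf("beta_run%d_%s.csv", r, g)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(bs$coords))
    utils::write.table(bs$coords, file.path(dir, "coords.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_runs = bs$n_runs, graphs = bs$graphs,
                            n_voxels = bs$n_voxels,
                            mask_dim = bs$mask_dim,
                            has_coords = !is.null(bs$coords)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a beta set written by [write_beta_set()]
#'
#' @param dir Directory path.
#' @return A `beta_set`.
#' @export
read_beta_set <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("corrupt beta set: missing manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  betas <- lapply(seq_len(manifest$n_runs), function(r) {
    out <- lapply(manifest$graphs, function(g) {
      f <- file.path(dir, sprintf("beta_run%d_%s.csv", r, g))
      if (!file.exists(f)) stop("corrupt beta set: missing ", f)
      unname(as.matrix(utils::read.csv(f, header = FALSE)))
    })
    names(out) <- manifest$graphs
    out
  })
  coords <- NULL
  if (isTRUE(manifest$has_coords))
    coords <- unname(as.matrix(utils::read.csv(file.path(dir, "coords.csv"),
                                               header = FALSE)))
  beta_set(betas, coords = coords, mask_dim = manifest$mask_dim)
}
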