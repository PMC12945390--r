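#' Specification for planted-subspace beta volumes
#'
#' Defines a synthetic group dataset in which graphs of the same structural
#' family (hexagonal `Hl`/`Hs`, community `Cl`/`Cs`) share a low-dimensional
#' voxel-loading subspace inside an effect region, while loadings elsewhere
#' (and condition codes everywhere) are fresh random draws per run — so any
#' cross-run, cross-graph generalization the analysis finds can only come
#' from the planted shared loadings.
#'
#' @param n_subjects Number of subjects.
#' @param vol_dim Volume dimensions `c(nx, ny, nz)`; the full volume is the
#'   mask.
#' @param n_conditions Conditions ("piles") per graph (default 10).
#' @param shared_dim Latent dimension per structure family (default 4).
#' @param overlap In `[0, 1]`: consistency of a graph's per-run voxel
#'   loadings with its family's shared loading matrix inside the effect
#'   region (0 = fresh loadings every run, i.e. no recoverable structure;
#'   1 = identical family loadings in every run and graph).
#' @param noise_sd Independent Gaussian noise sd added to every beta.
#' @param effect_region Integer vector of linear voxel indices carrying the
#'   planted structure (default: none).
#' @param n_runs Scanner runs (default 4).
#' @param seed Integer seed.
#' @return An object of class `"planted_beta_spec"`.
#' @export
planted_beta_spec <- function(n_subjects, vol_dim = c(6, 6, 6),
                              n_conditions = 10, shared_dim = 4,
                              overlap = 0.9, noise_sd = 0.3,
                              effect_region = integer(0), n_runs = 4,
                              seed = 1) {
  n_voxels <- prod(vol_dim)
  if (shared_dim >= n_voxels) stop("shared_dim must be below the voxel count")
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  if (length(effect_region) && (min(effect_region) < 1 ||
                                max(effect_region) > n_voxels))
    stop("effect_region indices out of range")
  structure(list(n_subjects = n_subjects, vol_dim = vol_dim,
                 n_voxels = n_voxels, n_conditions = n_conditions,
                 shared_dim = shared_dim, overlap = overlap,
                 noise_sd = noise_sd,
                 effect_region = as.integer(effect_region),
                 n_runs = n_runs, seed = as.integer(seed)),
            class = "planted_beta_spec")
}

#' Generate planted-subspace beta sets
#'
#' Per subject, graph and run the beta matrix is `W %*% Z + noise`, where
#' the voxel loadings `W` mix the graph's family loading matrix with fresh
#' run-specific noise, `W = sqrt(a) * W_family + sqrt(1 - a) * E`, with
#' `a = overlap` inside the effect region and 0 elsewhere; condition codes
#' `Z` are fresh standard-normal draws per run and graph (no condition
#' correspondence across runs or graphs). Bit-reproducible given the spec.
#'
#' @param spec A `planted_beta_spec`.
#' @return List of `beta_set`s, one per subject, each carrying the full
#'   volume's voxel coordinates.
#' @export
generate_beta_set <- function(spec) {
  if (!inherits(spec, "planted_beta_spec")) stop("spec must be a 'planted_beta_spec'")
  nv <- spec$n_voxels; d <- spec$shared_dim
  family_of <- c(Hl = "H", Hs = "H", Cl = "C", Cs = "C")
  mix <- rep(0, nv)
  mix[spec$effect_region] <- spec$overlap
  a <- sqrt(mix); b <- sqrt(1 - mix)
  coords <- as.matrix(expand.grid(x = seq_len(spec$vol_dim[1]),
                                  y = seq_len(spec$vol_dim[2]),
                                  z = seq_len(spec$vol_dim[3])))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(s) {
      W_family <- list(H = matrix(stats::rnorm(nv * d), nv, d),
                       C = matrix(stats::rnorm(nv * d), nv, d))
      runs <- lapply(seq_len(spec$n_runs), function(r) {
        out <- lapply(GRAPHS, function(g) {
          E <- matrix(stats::rnorm(nv * d), nv, d)
          W <- a * W_family[[family_of[[g]]]] + b * E
          Z <- matrix(stats::rnorm(d * spec$n_conditions), d, spec$n_conditions)
          W %*% Z + spec$noise_sd *
            matrix(stats::rnorm(nv * spec$n_conditions), nv, spec$n_conditions)
        })
        names(out) <- GRAPHS
        out
      })
      beta_set(runs, coords = coords, mask_dim = spec$vol_dim)
    })
  })
}

#' Simulate a foraging session from a known rate surface
#'
#' Random-walk trajectory (Gaussian steps, reflected at the walls) plus
#' inhomogeneous Poisson spikes for each cell: at every time step the
#' cell's rate is looked up at the nearest bin of its rate surface and a
#' Poisson spike count for the step duration is drawn.
#'
#' @param rate_surface A `ratemap_stack` (rates in Hz) defining the cells
#'   and the environment.
#' @param duration Session length in seconds.
#' @param dt Position sampling interval (default 0.02 s).
#' @param step_sd Random-walk step sd per sample, environment units
#'   (default 2.5 percent of the box side).
#' @param seed Optional integer seed.
#' @return An `event_table`.
#' @export
generate_session <- function(rate_surface, duration, dt = 0.02,
                             step_sd = NULL, seed = NULL) {
  if (!inherits(rate_surface, "ratemap_stack"))
    stop("rate_surface must be a 'ratemap_stack'")
  if (duration <= 0) stop("duration must be positive")
  ex <- rate_surface$bin_edges_x; ey <- rate_surface$bin_edges_y
  box <- c(min(ex), max(ex), min(ey), max(ey))
  if (is.null(step_sd)) step_sd <- 0.025 * (box[2] - box[1])
  n_steps <- max(2L, ceiling(duration / dt))
  times <- (seq_len(n_steps) - 1L) * dt
  with_seed(seed, {
    reflect <- function(p, lo, hi) {
      rng <- hi - lo
      p <- (p - lo) %% (2 * rng)
      lo + ifelse(p > rng, 2 * rng - p, p)
    }
    x <- reflect(box[1] + (box[2] - box[1]) / 2 +
                   cumsum(stats::rnorm(n_steps, sd = step_sd)), box[1], box[2])
    y <- reflect(box[3] + (box[4] - box[3]) / 2 +
                   cumsum(stats::rnorm(n_steps, sd = step_sd)), box[3], box[4])
    bx <- findInterval(x, ex, rightmost.closed = TRUE, all.inside = TRUE)
    by <- findInterval(y, ey, rightmost.closed = TRUE, all.inside = TRUE)
    spikes <- lapply(seq_len(n_cells(rate_surface)), function(ci) {
      rate <- rate_surface$maps[ci, , ][cbind(bx, by)]
      counts <- stats::rpois(n_steps, rate * dt)
      st <- rep(times, counts) + stats::runif(sum(counts), 0, dt)
      sort(pmin(st, max(times)))
    })
    names(spikes) <- dimnames(rate_surface$maps)[[1]]
    event_table(times, x, y, spikes, bounds = box)
  })
}

#' Named, seeded fixture bundles
#'
#' Deterministic synthetic datasets used by the test-suite and the
#' documentation:
#' \describe{
#'   \item{`grid_pair`}{20 cells sampled from one reduced grid module
#'     (20 x 20 phase lattice, 30 x 30 box resolution) in two coherently
#'     realigned environments.}
#'   \item{`place_pair`}{20 remapping place cells in the same two-box
#'     geometry.}
#'   \item{`mixed_animals`}{3 pseudo-animals x 20 cells of each type —
#'     the grid-vs-place dissociation setup.}
#'   \item{`fmri_small`}{12 synthetic subjects on a 6 x 6 x 6 volume with
#'     the shared-subspace structure planted in a 3 x 3 x 3 corner block.}
#' }
#'
#' @param name One of `"grid_pair"`, `"place_pair"`, `"mixed_animals"`,
#'   `"fmri_small"`.
#' @param seed Integer seed (default 1); the same (name, seed) always
#'   regenerates the identical bundle.
#' @return A named list; contents depend on the preset.
#' @export
preset <- function(name = c("grid_pair", "place_pair", "mixed_animals",
                            "fmri_small"), seed = 1) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  switch(name,
    grid_pair = grid_pair_preset(seed),
    place_pair = place_pair_preset(seed),
    mixed_animals = list(
      animals = lapply(seq_len(3L), function(i) {
        gp <- grid_pair_preset(seed + 31L * i)
        pp <- place_pair_preset(seed + 31L * i + 17L)
        list(grid = gp, place = pp)
      }),
      seed = seed),
    fmri_small = {
      vol_dim <- c(6L, 6L, 6L)
      coords <- as.matrix(expand.grid(x = 1:6, y = 1:6, z = 1:6))
      effect <- which(coords[, 1] <= 3 & coords[, 2] <= 3 & coords[, 3] <= 3)
      # null evaluation centers are kept far enough from the effect block
      # that their 27-voxel searchlights contain no planted voxels
      null_ctr <- which(coords[, 1] >= 5 & coords[, 2] >= 5 & coords[, 3] >= 5)
      spec <- planted_beta_spec(n_subjects = 12, vol_dim = vol_dim,
                                n_conditions = 10, shared_dim = 4,
                                overlap = 0.9, noise_sd = 0.3,
                                effect_region = effect, seed = seed)
      list(spec = spec, subjects = generate_beta_set(spec),
           effect_region = effect, null_region = null_ctr,
           k_neighbors = 27L, seed = seed)
    })
}

# 20 cells sampled from a reduced module, two realigned environments
grid_pair_preset <- function(seed) {
  spec <- grid_module_spec(spacing = 3, orientation = 0.1,
                           phase_lattice = c(20, 20), box_size = 10,
                           resolution = 30)
  m1 <- build_module(spec)
  m2 <- realign_module(m1, environment_realignment(c(0.31, 0.67)))
  idx <- with_seed(seed, sample.int(n_cells(m1), 20L))
  sub <- function(m, i) {
    s <- ratemap_stack(m$maps[i, , , drop = FALSE], m$bin_edges_x,
                       m$bin_edges_y)
    s
  }
  list(env1 = flatten_maps(sub(m1, idx)), env2 = flatten_maps(sub(m2, idx)),
       cells = idx, spec = spec, seed = seed)
}

place_pair_preset <- function(seed) {
  pc <- simulate_place_cells(20L, field_width = 1.2, box = 10,
                             resolution = 30, seed = seed)
  list(env1 = flatten_maps(pc$env1), env2 = flatten_maps(pc$env2),
       centers1 = pc$centers1, centers2 = pc$centers2, seed = seed)
}
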