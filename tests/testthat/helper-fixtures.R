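# Shared, lazily-built fixtures. The full-scale grid-module cache is large
# (~2 GB of flattened maps) and is built once, used by the acceptance
# checks, and dropped explicitly with drop_grid_cache().

.fixture_env <- new.env(parent = emptyenv())

# small two-environment module pair for unit tests (400 cells, 30x30 box)
small_module_pair <- function() {
  if (is.null(.fixture_env$small_pair)) {
    spec <- grid_module_spec(3, 0.1, phase_lattice = c(20, 20),
                             box_size = 10, resolution = 30)
    m1 <- build_module(spec)
    m2 <- realign_module(m1, environment_realignment(c(0.31, 0.67)))
    .fixture_env$small_pair <- list(spec = spec, m1 = m1, m2 = m2)
  }
  .fixture_env$small_pair
}

# full-scale cache: peak-normalized flattened cell maps for the four
# standard modules in both environments, plus grouping stubs that retain
# the phase lattice
full_grid_cache <- function() {
  if (is.null(.fixture_env$full_grid)) {
    specs <- default_module_specs()
    envs2 <- default_env2_shifts(specs)
    flat_norm <- function(spec, env) {
      st <- build_module(spec, env)
      f <- flatten_maps(st)
      stub <- structure(list(maps = array(0, c(nrow(f), 1, 1)),
                             phase_idx = st$phase_idx),
                        class = "ratemap_stack")
      pk <- f[cbind(seq_len(nrow(f)), max.col(f, ties.method = "first"))]
      out <- unclass(f) / pk
      attr(out, "map_dim") <- attr(f, "map_dim")
      list(flat = out, stub = stub)
    }
    e1 <- lapply(specs, flat_norm, env = environment_realignment())
    e2 <- Map(flat_norm, specs, envs2)
    .fixture_env$full_grid <- list(
      specs = specs,
      flat1 = lapply(e1, `[[`, "flat"),
      flat2 = lapply(e2, `[[`, "flat"),
      stubs = lapply(e1, `[[`, "stub"))
  }
  .fixture_env$full_grid
}

drop_grid_cache <- function() {
  .fixture_env$full_grid <- NULL
  invisible(gc())
}

# grouped pseudo-voxels from the full cache under one grouping seed
full_voxel_pair <- function(ratio_random, seed, n_groups = 4) {
  gc_ <- full_grid_cache()
  asn <- lapply(seq_along(gc_$stubs), function(mi)
    make_grouping(gc_$stubs[[mi]], n_groups, ratio_random, seed + mi))
  list(v1 = group_into_voxels(gc_$flat1, asn, normalize = FALSE),
       v2 = group_into_voxels(gc_$flat2, asn, normalize = FALSE))
}

# within-vs-across AUC summaries for a voxel pair
voxel_within_between <- function(v1, v2, scaling = "zscored") {
  within <- mean(c(
    auc_from_variance(variance_along(v1, compute_pcs(v1, scaling), scaling))$auc,
    auc_from_variance(variance_along(v2, compute_pcs(v2, scaling), scaling))$auc))
  between <- as.numeric(subspace_generalization(v1, v2, scaling))
  c(within = within, between = between)
}
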