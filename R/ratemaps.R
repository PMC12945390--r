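#' Construct a spike/position event table
#'
#' Holds one recording session: a position trace sampled at (strictly
#' increasing) times and one spike-time vector per cell. Positions are in
#' environment units within `bounds`.
#'
#' @param times Numeric vector of sample times (seconds), strictly increasing.
#' @param x,y Numeric position samples, same length as `times`.
#' @param spikes Named list of numeric spike-time vectors, one per cell;
#'   spike times must lie within `[min(times), max(times)]`.
#' @param bounds Numeric `c(xmin, xmax, ymin, ymax)`; defaults to the data
#'   range.
#' @return An object of class `"event_table"`.
#' @export
event_table <- function(times, x, y, spikes, bounds = NULL) {
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing with at least 2 samples")
  if (length(x) != length(times) || length(y) != length(times))
    stop("positions and times must have equal length")
  if (is.null(bounds)) bounds <- c(range(x), range(y))
  if (any(x < bounds[1] | x > bounds[2] | y < bounds[3] | y > bounds[4]))
    stop("positions outside the declared environment bounds")
  if (is.null(names(spikes)) || any(names(spikes) == ""))
    names(spikes) <- paste0("cell", seq_along(spikes))
  tr <- range(times)
  for (nm in names(spikes)) {
    st <- spikes[[nm]]
    if (length(st) && (min(st) < tr[1] || max(st) > tr[2]))
      stop("spike times of ", nm, " fall outside the session time range")
  }
  structure(list(times = times, x = as.numeric(x), y = as.numeric(y),
                 spikes = lapply(spikes, as.numeric), bounds = bounds),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat("Event table:", length(x$times), "position samples,",
      length(x$spikes), "cells,",
      format(diff(range(x$times)), digits = 4), "s\n")
  invisible(x)
}

#' Construct a rate-map stack directly from map arrays
#'
#' @param maps Numeric array `n_cells x n_bins_x x n_bins_y` (Hz), or a list
#'   of equally-sized matrices.
#' @param bin_edges_x,bin_edges_y Bin edges in environment units.
#' @param occupancy Optional `n_bins_x x n_bins_y` matrix of seconds per bin.
#' @return An object of class `"ratemap_stack"`.
#' @export
ratemap_stack <- function(maps, bin_edges_x = NULL, bin_edges_y = NULL,
                          occupancy = NULL) {
  if (is.list(maps)) {
    nms <- names(maps) %||% paste0("cell", seq_along(maps))
    maps <- aperm(simplify2array(maps), c(3, 1, 2))
    dimnames(maps) <- list(nms, NULL, NULL)
  }
  if (length(dim(maps)) != 3L) stop("maps must be a cells x binsx x binsy array")
  if (is.null(dimnames(maps)[[1]]))
    dimnames(maps)[[1]] <- paste0("cell", seq_len(dim(maps)[1]))
  if (is.null(bin_edges_x)) bin_edges_x <- seq(0, dim(maps)[2])
  if (is.null(bin_edges_y)) bin_edges_y <- seq(0, dim(maps)[3])
  if (!is.null(occupancy) && any(occupancy < 0, na.rm = TRUE))
    stop("occupancy must be non-negative")
  structure(list(maps = maps, bin_edges_x = bin_edges_x,
                 bin_edges_y = bin_edges_y, occupancy = occupancy),
            class = "ratemap_stack")
}

#' @export
print.ratemap_stack <- function(x, ...) {
  d <- dim(x$maps)
  cat("Rate-map stack:", d[1], "cells,", d[2], "x", d[3], "bins\n")
  invisible(x)
}

n_cells <- function(stack) dim(stack$maps)[1]

#' Build firing-rate maps from an event table
#'
#' Bins the environment into `n_bins` half-open bins (final bin closed),
#' accumulates occupancy time per bin (each position sample carries the
#' interval to the next sample; the last sample carries the median interval)
#' and spike counts per bin (each spike is assigned the position of the
#' nearest time sample), and divides to get Hz.
#'
#' Bins with occupancy below `occupancy_epsilon` are unvisited. Under the
#' default policy `unvisited = "na"` they are set to `NA` and are expected
#' to be imputed from the neighborhood mean by [boxcar_smooth()];
#' `"zero"` fills them with 0 immediately.
#'
#' @param events An `event_table`.
#' @param n_bins Integer pair (or scalar) of bins per axis; default `c(64, 64)`.
#' @param occupancy_epsilon Seconds below which a bin counts as unvisited
#'   (default 0.1).
#' @param unvisited Unvisited-bin policy, `"na"` or `"zero"`.
#' @return A `ratemap_stack` with per-bin occupancy attached.
#' @export
make_ratemaps <- function(events, n_bins = c(64, 64),
                          occupancy_epsilon = 0.1,
                          unvisited = c("na", "zero")) {
  unvisited <- match.arg(unvisited)
  if (!inherits(events, "event_table")) stop("events must be an 'event_table'")
  if (length(n_bins) == 1L) n_bins <- rep(n_bins, 2L)
  n_bins <- as.integer(n_bins)
  b <- events$bounds
  ex <- seq(b[1], b[2], length.out = n_bins[1] + 1L)
  ey <- seq(b[3], b[4], length.out = n_bins[2] + 1L)
  bx <- findInterval(events$x, ex, rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(events$y, ey, rightmost.closed = TRUE, all.inside = TRUE)
  dt <- diff(events$times)
  dt <- c(dt, stats::median(dt))
  idx <- (by - 1L) * n_bins[1] + bx
  occ <- matrix(0, n_bins[1], n_bins[2])
  tab <- rowsum(dt, idx)
  occ[as.integer(rownames(tab))] <- tab[, 1]
  if (sum(occ) <= 0) stop("zero total occupancy")
  visited <- occ >= occupancy_epsilon
  if (mean(visited) < 0.5)
    warning("fewer than half the bins are visited; rate maps will be sparse")
  maps <- array(0, c(length(events$spikes), n_bins))
  dimnames(maps) <- list(names(events$spikes), NULL, NULL)
  for (ci in seq_along(events$spikes)) {
    st <- events$spikes[[ci]]
    if (!length(st)) {
      warning("cell ", names(events$spikes)[ci],
              " has no spikes; its rate map is zero")
      cnt <- matrix(0, n_bins[1], n_bins[2])
    } else {
      si <- pmin(pmax(findInterval(st, events$times, all.inside = TRUE), 1L),
                 length(events$times))
      # nearest time sample, not just the preceding one
      nxt <- pmin(si + 1L, length(events$times))
      use_next <- abs(events$times[nxt] - st) < abs(st - events$times[si])
      si[use_next] <- nxt[use_next]
      cnt <- matrix(0, n_bins[1], n_bins[2])
      stab <- rowsum(rep(1, length(si)), (by[si] - 1L) * n_bins[1] + bx[si])
      cnt[as.integer(rownames(stab))] <- stab[, 1]
    }
    m <- matrix(NA_real_, n_bins[1], n_bins[2])
    m[visited] <- cnt[visited] / occ[visited]
    if (unvisited == "zero") m[!visited] <- 0
    maps[ci, , ] <- m
  }
  ratemap_stack(maps, ex, ey, occ)
}

# NA-aware renormalized 2-D moving average of one matrix
boxcar2d <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nx <- nrow(m); ny <- ncol(m)
  val <- ifelse(is.na(m), 0, m)
  ind <- ifelse(is.na(m), 0, 1)
  acc <- matrix(0, nx, ny)
  nrm <- matrix(0, nx, ny)
  for (dx in -h:h) {
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    xd <- xs + dx
    for (dy in -h:h) {
      ys <- max(1, 1 - dy):min(ny, ny - dy)
      yd <- ys + dy
      acc[xs, ys] <- acc[xs, ys] + val[xd, yd]
      nrm[xs, ys] <- nrm[xs, ys] + ind[xd, yd]
    }
  }
  out <- acc / nrm
  out[nrm == 0] <- NA_real_
  out
}

#' Boxcar-smooth a rate-map stack
#'
#' 2-D moving average with an odd square window (default 5 bins). At the
#' map edges the kernel is renormalized over in-bounds bins, so constant
#' maps are exactly preserved; total mass is conserved up to this edge
#' renormalization. `NA` (unvisited) bins are excluded from every local
#' average and are imputed by their smoothed neighborhood mean; a bin with
#' no valid neighbor becomes 0.
#'
#' @param stack A `ratemap_stack`.
#' @param window_bins Odd positive window width (default 5).
#' @return The smoothed `ratemap_stack`.
#' @export
boxcar_smooth <- function(stack, window_bins = 5L) {
  if (!inherits(stack, "ratemap_stack")) stop("stack must be a 'ratemap_stack'")
  w <- as.integer(window_bins)
  if (w < 1L || w %% 2L == 0L)
    stop("window_bins must be odd and positive, got ", window_bins)
  if (w == 1L) {
    out <- stack
    out$maps[is.na(out$maps)] <- 0
    return(out)
  }
  out <- stack
  for (ci in seq_len(n_cells(stack))) {
    sm <- boxcar2d(stack$maps[ci, , ], w)
    sm[is.na(sm)] <- 0
    out$maps[ci, , ] <- sm
  }
  out
}

#' Normalize each cell's rate map
#'
#' `"peak"` divides each cell's map by its maximum (peak becomes 1);
#' `"zscore"` recenters each map to mean 0 and (sample) standard deviation 1
#' across bins.
#'
#' @param stack A `ratemap_stack` (no `NA` bins; smooth or use the `"zero"`
#'   policy first).
#' @param method `"peak"` or `"zscore"`.
#' @return The normalized `ratemap_stack`.
#' @export
normalize_maps <- function(stack, method = c("peak", "zscore")) {
  method <- match.arg(method)
  if (anyNA(stack$maps))
    stop("rate maps contain NA bins; smooth or fill unvisited bins first")
  out <- stack
  for (ci in seq_len(n_cells(stack))) {
    m <- stack$maps[ci, , ]
    if (method == "peak") {
      mx <- max(m)
      if (mx <= 0)
        stop("degenerate cell ", dimnames(stack$maps)[[1]][ci],
             ": all-zero map cannot be peak-normalized")
      out$maps[ci, , ] <- m / mx
    } else {
      s <- stats::sd(m)
      if (s == 0)
        stop("degenerate cell ", dimnames(stack$maps)[[1]][ci],
             ": constant map cannot be z-scored")
      out$maps[ci, , ] <- (m - mean(m)) / s
    }
  }
  out
}

#' Flatten a rate-map stack into an activity matrix
#'
#' Spatial bins become states, ordered x-fastest (column-major over the
#' `n_bins_x x n_bins_y` map), labelled `"x<i>_y<j>"`. Inverse of
#' [unflatten_maps()].
#'
#' @param stack A `ratemap_stack` without `NA` bins.
#' @return An `activity_matrix` (`n_cells x n_bins_x*n_bins_y`).
#' @export
flatten_maps <- function(stack) {
  if (!inherits(stack, "ratemap_stack")) stop("stack must be a 'ratemap_stack'")
  if (anyNA(stack$maps))
    stop("rate maps contain NA bins; smooth or fill unvisited bins first")
  d <- dim(stack$maps)
  vals <- matrix(stack$maps, d[1], d[2] * d[3])
  labs <- as.vector(outer(seq_len(d[2]), seq_len(d[3]),
                          function(i, j) paste0("x", i, "_y", j)))
  out <- activity_matrix(vals, unit_labels = dimnames(stack$maps)[[1]],
                         state_labels = labs)
  attr(out, "map_dim") <- d[2:3]
  out
}

#' Rebuild a rate-map stack from a flattened activity matrix
#'
#' @param A An `activity_matrix` produced by [flatten_maps()] (or any matrix
#'   plus an explicit bin dimension).
#' @param map_dim Integer pair `c(n_bins_x, n_bins_y)`; defaults to the
#'   `"map_dim"` attribute.
#' @return A `ratemap_stack`.
#' @export
unflatten_maps <- function(A, map_dim = attr(A, "map_dim")) {
  if (is.null(map_dim)) stop("map_dim is required to unflatten")
  if (prod(map_dim) != ncol(A))
    stop("map_dim ", paste(map_dim, collapse = "x"),
         " does not match ", ncol(A), " states")
  maps <- array(as.numeric(A), c(nrow(A), map_dim))
  dimnames(maps) <- list(rownames(A), NULL, NULL)
  ratemap_stack(maps)
}

#' Serialize a rate-map stack as a directory of delimited text
#'
#' Writes one CSV per cell plus a JSON manifest (bin edges, occupancy,
#' cell names). [read_ratemap_stack()] round-trips losslessly.
#'
#' @param stack A `ratemap_stack`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ratemap_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nms <- dimnames(stack$maps)[[1]]
  for (ci in seq_along(nms))
    utils::write.table(stack$maps[ci, , ],
                       file.path(dir, sprintf("map_%04d.csv", ci)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(stack$occupancy))
    utils::write.table(stack$occupancy, file.path(dir, "occupancy.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  manifest <- list(cells = nms, bin_edges_x = stack$bin_edges_x,
                   bin_edges_y = stack$bin_edges_y,
                   has_occupancy = !is.null(stack$occupancy))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a rate-map stack written by [write_ratemap_stack()]
#'
#' @param dir Directory path.
#' @return A `ratemap_stack`.
#' @export
read_ratemap_stack <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("corrupt rate-map stack: missing manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  nms <- manifest$cells
  maps <- NULL
  for (ci in seq_along(nms)) {
    f <- file.path(dir, sprintf("map_%04d.csv", ci))
    if (!file.exists(f)) stop("corrupt rate-map stack: missing ", f)
    m <- as.matrix(utils::read.csv(f, header = FALSE))
    if (is.null(maps)) maps <- array(NA_real_, c(length(nms), dim(m)))
    maps[ci, , ] <- m
  }
  dimnames(maps) <- list(nms, NULL, NULL)
  occ <- NULL
  if (isTRUE(manifest$has_occupancy))
    occ <- unname(as.matrix(utils::read.csv(file.path(dir, "occupancy.csv"),
                                            header = FALSE)))
  ratemap_stack(maps, manifest$bin_edges_x, manifest$bin_edges_y, occ)
}
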