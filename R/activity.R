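#' Construct an activity matrix
#'
#' The universal input container of the package: a real `n_units x n_states`
#' matrix of population activity. Rows are recording units (cells or voxels),
#' columns are task states (spatial bins or experimental conditions).
#'
#' @param values Numeric matrix, units in rows, states in columns. All values
#'   must be finite; at least 2 units and 2 states are required.
#' @param unit_labels Character vector of unit identifiers (defaults to
#'   existing rownames or `"u1"..."un"`).
#' @param state_labels Character vector of state identifiers (defaults to
#'   existing colnames or `"s1"..."sm"`).
#' @return A numeric matrix of class `"activity_matrix"` with dimnames set.
#' @examples
#' a <- activity_matrix(matrix(rnorm(12), 3, 4))
#' dim(a)
#' @export
activity_matrix <- function(values, unit_labels = NULL, state_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("an activity matrix needs at least 2 units and 2 states, got ",
         nrow(values), " x ", ncol(values))
  if (!all(is.finite(values)))
    stop("activity matrix contains non-finite values")
  if (is.null(unit_labels))
    unit_labels <- rownames(values) %||% paste0("u", seq_len(nrow(values)))
  if (is.null(state_labels))
    state_labels <- colnames(values) %||% paste0("s", seq_len(ncol(values)))
  if (length(unit_labels) != nrow(values))
    stop("unit_labels length (", length(unit_labels),
         ") does not match the number of rows (", nrow(values), ")")
  if (length(state_labels) != ncol(values))
    stop("state_labels length (", length(state_labels),
         ") does not match the number of columns (", ncol(values), ")")
  dimnames(values) <- list(as.character(unit_labels), as.character(state_labels))
  class(values) <- c("activity_matrix", class(values))
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce to an activity matrix
#'
#' @param x Matrix-like object.
#' @return An `activity_matrix`.
#' @export
as_activity_matrix <- function(x) {
  if (inherits(x, "activity_matrix")) return(x)
  activity_matrix(x)
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat("Activity matrix:", nrow(x), "units x", ncol(x), "states\n")
  invisible(x)
}

#' Prepare an activity matrix for subspace analysis
#'
#' Applies the per-unit scaling that defines which second-moment structure
#' the principal components summarize: `"raw"` leaves the matrix untouched
#' (uncentered sums of squares), `"centered"` removes each unit's mean across
#' states (covariance), `"zscored"` additionally divides each unit by its
#' across-state standard deviation (correlation structure). The standard
#' deviation uses the usual sample convention (division by `n - 1` states),
#' so the unit row `(0, 2, 4)` z-scores to `(-1, 0, 1)`.
#'
#' @param raw An `activity_matrix` (or plain matrix).
#' @param scaling_mode One of `"raw"`, `"centered"`, `"zscored"`.
#' @return A prepared `activity_matrix` of the same dimensions.
#' @examples
#' a <- activity_matrix(rbind(c(1, 2, 3), c(0, 2, 4)))
#' prepare_matrix(a, "centered")
#' @export
prepare_matrix <- function(raw, scaling_mode = c("raw", "centered", "zscored")) {
  scaling_mode <- match.arg(scaling_mode)
  a <- as_activity_matrix(raw)
  if (scaling_mode == "raw") return(a)
  mu <- rowMeans(a)
  out <- a - mu
  if (scaling_mode == "zscored") {
    s <- sqrt(rowSums(out^2) / (ncol(out) - 1L))
    bad <- which(s == 0)
    if (length(bad))
      stop("zscored scaling is undefined for zero-variance unit(s): ",
           paste(rownames(a)[bad], collapse = ", "))
    out <- out / s
  }
  class(out) <- class(a)
  dimnames(out) <- dimnames(a)
  out
}

# shared argument check: two matrices over the same ordered unit set
check_matched_units <- function(a1, a2) {
  if (nrow(a1) != nrow(a2))
    stop("unit count mismatch: ", nrow(a1), " vs ", nrow(a2))
  if (!identical(rownames(a1), rownames(a2)))
    stop("unit labels of the two activity matrices do not match")
  invisible(TRUE)
}

#' Read an activity matrix from delimited text
#'
#' Expects comma-separated UTF-8 text with a header row of state labels and
#' the first column holding unit labels, as written by
#' [write_activity_csv()].
#'
#' @param path File path.
#' @return An `activity_matrix`.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 3L)
    stop("malformed activity matrix file (need a label column plus >= 2 states): ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in activity matrix file: ", path)
  activity_matrix(m, unit_labels = as.character(df[[1L]]),
                  state_labels = colnames(df)[-1L])
}

#' Write an activity matrix as delimited text
#'
#' @param a An `activity_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(a, path) {
  a <- as_activity_matrix(a)
  df <- data.frame(unit = rownames(a), unclass(a), check.names = FALSE)
  colnames(df) <- c("unit", colnames(a))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
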