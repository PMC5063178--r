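## Shape PCA on Procrustes-aligned coordinates: eigenleaves, variance
## explained, per-leaf scores, projection of new leaves.

# Remove the radial (unit-consensus-direction) component of the
# deviations from the column mean, keeping the mean itself: maps the
# sphere of unit-size shapes onto the tangent hyperplane at the consensus.
tangent_project <- function(X, cvec) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  Xc <- Xc - (Xc %*% cvec) %*% t(cvec)
  sweep(Xc, 2L, ctr, `+`)
}

#' Fit a principal-component morphospace to aligned shapes
#'
#' Eigendecomposition (via [stats::prcomp()]) of the covariance (divisor
#' n - 1) of the flattened aligned coordinates, in (x1, y1, ..., x17, y17)
#' order. Covariance PCA, not correlation: all coordinates share units
#' after Procrustes alignment. Axis signs are fixed deterministically so
#' each axis's largest-magnitude loading is positive (PC signs are
#' otherwise arbitrary). Eigenvalues below `1e-12 * max` are reported as
#' exactly zero — after alignment of 17-landmark data, at most
#' min(n - 1, 30) eigenvalues can be nonzero (34 coordinates minus the 4
#' similarity degrees of freedom).
#'
#' With `tangent = TRUE` (default) the coordinates are first projected
#' onto the tangent space at the consensus, i.e. the component along the
#' unit consensus vector is removed. Unit-size aligned shapes lie on a
#' sphere, not a linear subspace; without this projection the sphere's
#' curvature leaves a spurious radial variance direction in the PCA and
#' the similarity rank bound above cannot hold. The projection is
#' second-order small and is the standard treatment before shape PCA.
#'
#' @param aligned An `aligned_shapes` object (or `n x k x 2` array in the
#'   GPA frame).
#' @param tangent Project out the radial (consensus) direction before the
#'   eigendecomposition (default `TRUE`; use `FALSE` for data not scaled
#'   to unit centroid size).
#' @return Object of class `morphospace`: `mean_vector` (length 2k),
#'   `axes` (2k x m orthonormal columns), `eigenvalues` (nonincreasing),
#'   `variance_fraction`, `scores` (n x m), `consensus_vector` (unit
#'   flattened consensus used for the tangent projection, or `NULL`),
#'   `leaf_id`, `meta`.
#' @export
fit_pca <- function(aligned, tangent = TRUE) {
  arr <- if (inherits(aligned, "aligned_shapes")) aligned$aligned else aligned
  n <- dim(arr)[1]
  if (n < 2L) stop("fit_pca: need at least 2 leaves")
  X <- flatten_coords(arr)
  cvec <- NULL
  if (tangent) {
    cm <- if (inherits(aligned, "aligned_shapes"))
      as.vector(t(aligned$mean_shape)) else colMeans(X)
    cvec <- cm / sqrt(sum(cm^2))
    X <- tangent_project(X, cvec)
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  if (max(ev) > 0) ev[ev < 1e-12 * max(ev)] <- 0
  axes <- pr$rotation
  scores <- pr$x
  # deterministic sign: largest-|loading| positive per axis
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) {
      axes[, j] <- -axes[, j]
      scores[, j] <- -scores[, j]
    }
  }
  vf <- if (sum(ev) > 0) ev / sum(ev) else ev
  colnames(axes) <- colnames(scores) <- paste0("PC", seq_len(ncol(axes)))
  structure(list(mean_vector = pr$center, axes = axes, eigenvalues = ev,
                 variance_fraction = vf, scores = scores,
                 consensus_vector = cvec,
                 leaf_id = if (inherits(aligned, "aligned_shapes"))
                   aligned$leaf_id else as.character(seq_len(n)),
                 meta = if (inherits(aligned, "aligned_shapes"))
                   aligned$meta else NULL),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  npc <- min(4L, length(x$eigenvalues))
  cat("morphospace: ", nrow(x$scores), " leaves, ",
      sum(x$eigenvalues > 0), " nonzero axes\n", sep = "")
  cat("variance explained: ",
      paste0(colnames(x$axes)[seq_len(npc)], " ",
             sprintf("%.1f%%", 100 * x$variance_fraction[seq_len(npc)]),
             collapse = ", "),
      " (first ", npc, " PCs: ",
      sprintf("%.1f%%", 100 * sum(x$variance_fraction[seq_len(npc)])),
      ")\n", sep = "")
  invisible(x)
}

#' Project aligned leaves into an existing morphospace
#'
#' Scores of new leaves on the stored axes; the space is unchanged. The
#' new leaves must be aligned in the same Procrustes frame (same
#' consensus) as the training set.
#'
#' @param space A `morphospace`.
#' @param aligned An `aligned_shapes` object or `n x k x 2` array.
#' @return Numeric matrix of scores (rows = new leaves).
#' @export
project_shapes <- function(space, aligned) {
  arr <- if (inherits(aligned, "aligned_shapes")) aligned$aligned else aligned
  X <- flatten_coords(arr)
  if (ncol(X) != length(space$mean_vector))
    stop("project_shapes: dimension mismatch (", ncol(X), " coordinates vs ",
         length(space$mean_vector), " in the morphospace)")
  D <- sweep(X, 2L, space$mean_vector)
  if (!is.null(space$consensus_vector))
    D <- D - (D %*% space$consensus_vector) %*% t(space$consensus_vector)
  scores <- D %*% space$axes
  rownames(scores) <- if (inherits(aligned, "aligned_shapes"))
    aligned$leaf_id else NULL
  scores
}

#' Reconstruct an eigenleaf along a morphospace axis
#'
#' The leaf shape at `k_sd` standard deviations from the mean along one
#' principal component: mean + k_sd * sqrt(eigenvalue) * axis, returned as
#' a 17 x 2 landmark configuration. This is the standard way of rendering
#' what a PC "means" as a morph (e.g. at +/- 3 SD).
#'
#' @param space A `morphospace`.
#' @param axis_index Which axis (1-based).
#' @param k_sd How many standard deviations along it (0 gives the mean
#'   shape).
#' @return `k x 2` landmark matrix.
#' @export
eigenleaf <- function(space, axis_index, k_sd) {
  if (axis_index < 1L || axis_index > ncol(space$axes))
    stop("eigenleaf: no such axis: ", axis_index)
  ev <- space$eigenvalues[axis_index]
  if (ev <= 0)
    stop("eigenleaf: axis ", axis_index, " has zero variance")
  v <- space$mean_vector + k_sd * sqrt(ev) * space$axes[, axis_index]
  unflatten_coords(v)[1L, , ]
}

#' Write morphospace scores as CSV
#'
#' @param space A `morphospace`.
#' @param path Output CSV (`leaf_id,PC1,PC2,...`).
#' @return Invisibly, `path`.
#' @export
write_scores <- function(space, path) {
  df <- data.frame(leaf_id = space$leaf_id, space$scores,
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a morphospace to JSON
#'
#' Stores the mean vector, axes and eigenvalues so the space can be reused
#' by [project_shapes()] and the discriminant tools in a later session.
#'
#' @param space A `morphospace`.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_morphospace <- function(space, path) {
  jsonlite::write_json(list(mean_vector = space$mean_vector,
                            axes = space$axes,
                            eigenvalues = space$eigenvalues,
                            variance_fraction = space$variance_fraction,
                            consensus_vector = space$consensus_vector),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a morphospace serialized by [write_morphospace()]
#'
#' @param path JSON file.
#' @return A `morphospace` (without scores/leaf ids).
#' @export
read_morphospace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  axes <- as.matrix(obj$axes)
  colnames(axes) <- paste0("PC", seq_len(ncol(axes)))
  structure(list(mean_vector = as.numeric(obj$mean_vector), axes = axes,
                 eigenvalues = as.numeric(obj$eigenvalues),
                 variance_fraction = as.numeric(obj$variance_fraction),
                 consensus_vector = if (!is.null(obj$consensus_vector))
                   as.numeric(obj$consensus_vector),
                 scores = NULL, leaf_id = NULL, meta = NULL),
            class = "morphospace")
}
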