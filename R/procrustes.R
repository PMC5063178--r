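## Procrustes superimposition: ordinary (pairwise) and generalized (GPA).
## Configurations are k x 2 matrices; rotations act on the right (X %*% R).

#' Centroid size of a landmark configuration
#'
#' The standard morphometric size measure removed by Procrustes scaling:
#' the square root of the summed squared distances of the landmarks to
#' their centroid.
#'
#' @param config Numeric `k x 2` matrix of landmarks.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("centroid_size: need at least 2 landmarks")
  cs <- sqrt(sum(sweep(config, 2L, colMeans(config))^2))
  if (cs == 0)
    stop("centroid_size: degenerate configuration (all landmarks coincide)")
  cs
}

# Optimal orthogonal map R (acting as B %*% R) minimizing ||A - B R||_F.
# With allow_reflection, R may have determinant -1 (reflect = TRUE
# behaviour); otherwise the smaller singular direction is flipped to force
# a proper rotation (Kabsch).
optimal_rotation <- function(A, B, allow_reflection = TRUE) {
  sv <- svd(crossprod(A, B))             # C = t(A) B = U D t(V)
  R <- sv$v %*% t(sv$u)
  if (!allow_reflection && det(R) < 0)
    R <- sv$v %*% diag(c(1, -1)) %*% t(sv$u)
  R
}

center_config <- function(x) sweep(x, 2L, colMeans(x))

#' Superimpose one configuration onto another
#'
#' Ordinary Procrustes analysis: `b` is optimally translated, rotated
#' (orthogonal map; determinant -1 permitted iff `allow_reflection`) and,
#' if `scale = TRUE`, scaled onto `a`. The optimal map comes from the
#' singular value decomposition of the cross-covariance of the centered
#' configurations.
#'
#' The reported distance is the root-sum-of-squares residual between the
#' two configurations after both are centered and scaled to unit centroid
#' size and `b` is optimally rotated — i.e. the residual the rotation
#' actually minimizes on preshapes.
#'
#' @param a,b Numeric `k x 2` landmark matrices with equal `k`.
#' @param allow_reflection Permit an improper (reflecting) map (default
#'   `TRUE`).
#' @param scale Scale `b` optimally onto `a` (default `TRUE`).
#' @return List with `aligned` (b mapped into a's frame), `rotation`
#'   (the 2 x 2 orthogonal matrix), and `distance`.
#' @export
superimpose_pair <- function(a, b, allow_reflection = TRUE, scale = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("superimpose_pair: landmark count mismatch (", nrow(a), " vs ",
         nrow(b), ")")
  csa <- centroid_size(a)                 # errors on degenerate input
  csb <- centroid_size(b)
  Ac <- center_config(a); Bc <- center_config(b)
  Au <- Ac / csa; Bu <- Bc / csb
  R <- optimal_rotation(Au, Bu, allow_reflection)
  distance <- sqrt(sum((Au - Bu %*% R)^2))
  beta <- if (scale) sum(diag(crossprod(Ac, Bc %*% R))) / sum(Bc^2) else 1
  aligned <- sweep(beta * (Bc %*% R), 2L, colMeans(a), `+`)
  list(aligned = aligned, rotation = R, distance = distance)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a set of landmark configurations: all are
#' centered and (optionally) scaled to unit centroid size, the consensus
#' is initialized as the first configuration, and the set is repeatedly
#' rotated onto the consensus (reflections permitted when
#' `allow_reflection`, mirroring `reflect = TRUE` usage) with the
#' consensus recomputed as the re-normalized mean, until the consensus
#' moves less than `tol` (root-sum-of-squares) or `max_iter` is reached.
#'
#' Because the Procrustes frame is arbitrary up to a joint rotation (and
#' reflection), the output is standardized deterministically: the set is
#' rotated so the consensus axis from landmark 1 (petiolar junction) to
#' landmark 2 (midvein tip) points along the positive y axis and, when
#' reflections are allowed, mirrored if needed so the first off-axis
#' landmark lies on a fixed side. Outputs are therefore reproducible
#' across runs and invariant to how the raw configurations were placed.
#'
#' @param x A `leaf_dataset` or an `n x k x 2` array of configurations.
#' @param allow_reflection Permit improper maps (default `TRUE`).
#' @param scale Remove size by scaling to unit centroid size (default
#'   `TRUE`); original sizes are kept in `centroid_sizes`.
#' @param tol Convergence tolerance on the consensus change
#'   (default `1e-10`).
#' @param max_iter Iteration cap (default 100).
#' @return Object of class `aligned_shapes`: `aligned` (`n x k x 2`),
#'   `mean_shape` (`k x 2`, unit centroid size when scaling), `centroid_sizes`,
#'   `n_iter`, `final_delta`, `objective_trace` (summed squared distances
#'   to the consensus per iteration), `leaf_id`, `meta` (carried from the
#'   dataset when available), `allow_reflection`, `scale`.
#' @export
gpa <- function(x, allow_reflection = TRUE, scale = TRUE,
                tol = 1e-10, max_iter = 100L) {
  if (inherits(x, "leaf_dataset")) {
    arr <- x$coords
    ids <- x$meta$leaf_id
    meta <- x$meta
  } else {
    arr <- x
    ids <- as.character(seq_len(dim(arr)[1]))
    meta <- NULL
  }
  n <- dim(arr)[1]
  if (n < 2L) stop("gpa: need at least 2 configurations")
  k <- dim(arr)[2]
  configs <- vector("list", n)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cfg <- arr[i, , ]
    cs <- tryCatch(centroid_size(cfg), error = function(e)
      stop("gpa: leaf '", ids[i], "': ", conditionMessage(e)))
    sizes[i] <- cs
    cfg <- center_config(cfg)
    configs[[i]] <- if (scale) cfg / cs else cfg
  }
  consensus <- configs[[1L]]
  if (scale) consensus <- consensus / sqrt(sum(consensus^2))
  delta <- Inf
  obj_trace <- numeric(0)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))
      configs[[i]] <- configs[[i]] %*%
        optimal_rotation(consensus, configs[[i]], allow_reflection)
    new_mean <- Reduce(`+`, configs) / n
    if (scale) new_mean <- new_mean / sqrt(sum(new_mean^2))
    obj_trace <- c(obj_trace,
                   sum(vapply(configs,
                              function(c) sum((c - new_mean)^2), 0)))
    delta <- sqrt(sum((new_mean - consensus)^2))
    consensus <- new_mean
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("gpa: no convergence after ", max_iter,
         " iterations (final consensus change ", format(delta), ")")
  # Deterministic frame: landmark 1 -> 2 axis of the consensus along +y.
  v <- consensus[2L, ] - consensus[1L, ]
  u <- v / sqrt(sum(v^2))
  R0 <- matrix(c(u[2L], -u[1L], u[1L], u[2L]), 2L, 2L)
  consensus <- consensus %*% R0
  for (i in seq_len(n)) configs[[i]] <- configs[[i]] %*% R0
  if (allow_reflection && k >= 3L) {
    # Chirality fix: first landmark clearly off the 1->2 axis must lie at
    # negative x (the "left" side in the landmark scheme).
    dx <- consensus[, 1L] - consensus[1L, 1L]
    off <- which(abs(dx) > 1e-9 * sqrt(sum(consensus^2)))
    off <- off[off >= 3L]
    if (length(off) > 0L && dx[off[1L]] > 0) {
      consensus[, 1L] <- -consensus[, 1L]
      for (i in seq_len(n)) configs[[i]][, 1L] <- -configs[[i]][, 1L]
    }
  }
  aligned <- array(NA_real_, dim = c(n, k, 2L))
  for (i in seq_len(n)) aligned[i, , ] <- configs[[i]]
  structure(list(aligned = aligned, mean_shape = consensus,
                 centroid_sizes = sizes, n_iter = iter,
                 final_delta = delta, objective_trace = obj_trace,
                 leaf_id = ids, meta = meta,
                 allow_reflection = allow_reflection, scale = scale),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("aligned_shapes: ", dim(x$aligned)[1], " configurations, ",
      dim(x$aligned)[2], " landmarks; GPA converged in ", x$n_iter,
      " iterations (final delta ", format(x$final_delta, digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' Export aligned coordinates as a wide CSV
#'
#' Writes one row per leaf with the dataset metadata (when present) and
#' `aligned_x1,aligned_y1,...` coordinate columns; the consensus is
#' written alongside as a single-row CSV when `consensus_path` is given.
#'
#' @param aligned An `aligned_shapes` object.
#' @param path Output CSV.
#' @param consensus_path Optional CSV for the consensus (mean shape).
#' @return Invisibly, `path`.
#' @export
write_aligned <- function(aligned, path, consensus_path = NULL) {
  cm <- flatten_coords(aligned$aligned)
  colnames(cm) <- paste0("aligned_", wide_header()[-(1:6)])
  df <- as.data.frame(cm)
  df <- cbind(leaf_id = aligned$leaf_id, df, stringsAsFactors = FALSE)
  if (!is.null(aligned$meta))
    df <- cbind(aligned$meta,
                as.data.frame(cm))
  df$centroid_size <- aligned$centroid_sizes
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(consensus_path)) {
    mm <- flatten_coords(array(aligned$mean_shape,
                               dim = c(1L, dim(aligned$aligned)[2], 2L)))
    colnames(mm) <- paste0("aligned_", wide_header()[-(1:6)])
    utils::write.csv(format(as.data.frame(mm), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     consensus_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read aligned coordinates written by [write_aligned()]
#'
#' @param path CSV produced by [write_aligned()].
#' @return An `aligned_shapes` object (without convergence trace).
#' @export
read_aligned <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cc <- paste0("aligned_", wide_header()[-(1:6)])
  if (!all(cc %in% names(df)))
    stop("read_aligned: ", path, " lacks aligned_x*/aligned_y* columns")
  arr <- unflatten_coords(as.matrix(df[, cc, drop = FALSE]))
  meta_cols <- intersect(c("leaf_id", "vine_id", "species", "stage",
                           "leaf_number", "organ_opposite"), names(df))
  mean_shape <- apply(arr, c(2L, 3L), mean)
  mean_shape <- mean_shape / sqrt(sum(center_config(mean_shape)^2))
  structure(list(aligned = arr, mean_shape = mean_shape,
                 centroid_sizes = if ("centroid_size" %in% names(df))
                   df$centroid_size else rep(NA_real_, nrow(df)),
                 n_iter = NA_integer_, final_delta = NA_real_,
                 objective_trace = numeric(0),
                 leaf_id = if ("leaf_id" %in% names(df))
                   as.character(df$leaf_id) else as.character(seq_len(nrow(df))),
                 meta = if (length(meta_cols) >= 6L)
                   df[, meta_cols, drop = FALSE] else NULL,
                 allow_reflection = NA, scale = NA),
            class = "aligned_shapes")
}
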