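## Linear discriminant "latent shapes" on Procrustes coordinates: fit,
## reallocation to apparent classes, confusion matrices, and
## cross-collection developmental staging.

#' Fit a linear discriminant model on aligned shapes
#'
#' Gaussian equal-covariance LDA on the flattened Procrustes coordinates.
#' The aligned shape space is rank deficient (the similarity group removes
#' 4 degrees of freedom), so coordinates are first reduced to the PCA
#' sub-basis whose eigenvalues exceed `rank_tol * max`; class means and
#' the pooled within-class covariance (divisor n - g) are then estimated
#' in that sub-basis. A small ridge (`1e-8 * trace/dim`) is added if the
#' pooled covariance is numerically singular.
#'
#' @param aligned An `aligned_shapes` object (or `n x k x 2` array).
#' @param labels Per-leaf class labels (factor or coercible); species,
#'   developmental stage or leaf number.
#' @param prior_mode `"proportional"` (class frequencies; default) or
#'   `"uniform"`.
#' @param rank_tol Relative eigenvalue cutoff for the PCA pre-reduction
#'   (default `1e-8`).
#' @param target_kind Optional tag recording what the labels mean
#'   (`"species"`, `"stage"`, `"leaf_number"`).
#' @param consensus Optional consensus shape (`17 x 2` matrix or flattened
#'   vector) defining the tangent projection applied before the reduction.
#'   Unit-size aligned shapes lie on a sphere whose radial direction
#'   carries (second-order) between-class offsets but essentially no
#'   within-class variance, which destabilizes the pooled covariance;
#'   projecting it out removes the artifact. Defaults to the consensus of
#'   `aligned` when that is an `aligned_shapes` object.
#' @return Object of class `leaf_lda`: `class_labels`, `priors`,
#'   `class_means` (g x r), `pooled_covariance` (r x r),
#'   `reduction` (list: `center`, `basis`, `consensus`), `target_kind`,
#'   `n`.
#' @export
fit_lda <- function(aligned, labels, prior_mode = c("proportional", "uniform"),
                    rank_tol = 1e-8, target_kind = "unspecified",
                    consensus = NULL) {
  prior_mode <- match.arg(prior_mode)
  arr <- if (inherits(aligned, "aligned_shapes")) aligned$aligned else aligned
  if (is.null(consensus) && inherits(aligned, "aligned_shapes"))
    consensus <- aligned$mean_shape
  cvec <- if (!is.null(consensus)) {
    v <- if (is.matrix(consensus)) as.vector(t(consensus)) else
      as.numeric(consensus)
    v / sqrt(sum(v^2))
  }
  X <- flatten_coords(arr)
  labels <- factor(labels)
  if (nrow(X) != length(labels))
    stop("fit_lda: ", nrow(X), " leaves but ", length(labels), " labels")
  counts <- table(labels)
  if (length(counts) < 2L)
    stop("fit_lda: need at least 2 classes, got ", length(counts))
  if (any(counts < 2L))
    stop("fit_lda: every class needs >= 2 leaves; offending class(es): ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  if (!is.null(cvec)) Xc <- Xc - (Xc %*% cvec) %*% t(cvec)
  pr <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  keep <- which(ev > rank_tol * max(ev))
  basis <- pr$rotation[, keep, drop = FALSE]
  Z <- Xc %*% basis
  g <- length(counts)
  r <- ncol(Z)
  n <- nrow(Z)
  class_means <- matrix(NA_real_, g, r,
                        dimnames = list(names(counts), NULL))
  W <- matrix(0, r, r)
  for (cl in names(counts)) {
    Zc <- Z[labels == cl, , drop = FALSE]
    m <- colMeans(Zc)
    class_means[cl, ] <- m
    W <- W + crossprod(sweep(Zc, 2L, m))
  }
  W <- W / (n - g)
  eW <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(eW) <= 1e-12 * max(eW)) {
    W <- W + diag(1e-8 * sum(diag(W)) / r, r)
    eW <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    if (min(eW) <= 0)
      stop("fit_lda: pooled within-class covariance is singular even after ",
           "regularization")
  }
  priors <- if (prior_mode == "proportional") as.numeric(counts) / n
            else rep(1 / g, g)
  names(priors) <- names(counts)
  structure(list(class_labels = names(counts), priors = priors,
                 class_means = class_means, pooled_covariance = W,
                 reduction = list(center = center, basis = basis,
                                  consensus = cvec),
                 target_kind = target_kind, n = n),
            class = "leaf_lda")
}

#' @export
print.leaf_lda <- function(x, ...) {
  cat("leaf_lda (", x$target_kind, "): ", length(x$class_labels),
      " classes, ", x$n, " training leaves, ",
      ncol(x$reduction$basis), " reduced dimensions\n", sep = "")
  invisible(x)
}

#' Reallocate leaves to apparent classes
#'
#' Gaussian discriminant posteriors under the shared pooled covariance;
#' the apparent class is the posterior argmax, with exact ties broken
#' toward the first class in label order (deterministic).
#'
#' @param model A `leaf_lda`.
#' @param aligned An `aligned_shapes` object or `n x k x 2` array in the
#'   same Procrustes frame as the training data.
#' @return List with `apparent` (factor of assigned classes) and
#'   `posterior` (n x g matrix; rows sum to 1).
#' @export
predict_classes <- function(model, aligned) {
  arr <- if (inherits(aligned, "aligned_shapes")) aligned$aligned else aligned
  X <- flatten_coords(arr)
  if (ncol(X) != length(model$reduction$center))
    stop("predict_classes: dimension mismatch")
  D <- sweep(X, 2L, model$reduction$center)
  if (!is.null(model$reduction$consensus)) {
    cvec <- model$reduction$consensus
    D <- D - (D %*% cvec) %*% t(cvec)
  }
  Z <- D %*% model$reduction$basis
  Winv <- solve(model$pooled_covariance)
  g <- length(model$class_labels)
  logd <- matrix(NA_real_, nrow(Z), g,
                 dimnames = list(NULL, model$class_labels))
  for (j in seq_len(g)) {
    D <- sweep(Z, 2L, model$class_means[j, ])
    logd[, j] <- log(model$priors[j]) - 0.5 * rowSums((D %*% Winv) * D)
  }
  m <- apply(logd, 1L, max)
  post <- exp(logd - m)
  post <- post / rowSums(post)
  # ties (posteriors equal to within numerical noise) go to the first
  # class in label order, deterministically
  pick <- apply(post, 1L, function(p) which(p >= max(p) - 1e-12)[1L])
  apparent <- factor(model$class_labels[pick], levels = model$class_labels)
  list(apparent = apparent, posterior = post)
}

#' Confusion matrix of actual vs apparent labels
#'
#' Cross-tabulation of true against classifier-assigned labels, with row
#' (per actual class) proportions; the diagonal of the proportions is the
#' per-class correct-allocation rate.
#'
#' @param actual,apparent Equal-length label vectors over a shared label
#'   set.
#' @return Object of class `confusion_matrix`: `labels`, `counts`
#'   (actual x apparent), `proportions` (rows sum to 1 for nonempty rows).
#' @export
confusion <- function(actual, apparent) {
  if (length(actual) == 0L) stop("confusion: empty input")
  if (length(actual) != length(apparent))
    stop("confusion: length mismatch (", length(actual), " vs ",
         length(apparent), ")")
  labs <- if (is.factor(actual)) levels(actual) else
    sort(unique(c(as.character(actual), as.character(apparent))))
  labs <- union(labs, unique(as.character(apparent)))
  counts <- table(factor(actual, levels = labs),
                  factor(apparent, levels = labs))
  counts <- matrix(as.integer(counts), nrow = length(labs),
                   dimnames = list(actual = labs, apparent = labs))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0L, 1L, rs)
  structure(list(labels = labs, counts = counts, proportions = props),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (", sum(x$counts), " leaves); counts:\n", sep = "")
  print(x$counts)
  cat("per-class correct-allocation rate:\n")
  print(round(diag(x$proportions), 3))
  invisible(x)
}

#' Cross-collection developmental staging
#'
#' Stages one collection of leaves against another: both collections are
#' restricted to the shoot-position window, aligned together in a single
#' joint Procrustes analysis (a separate analysis per combined dataset, so
#' no projection of new leaves into a foreign frame is needed; a
#' project-into-train mode is available), an LDA is fitted on the training
#' rows with the integer Sn or Ln values as unordered classes, and each
#' test leaf receives the apparent (classifier-assigned) integer value.
#'
#' @param train,test `leaf_dataset` objects (e.g. wild-species training
#'   data and domesticated-grape test data).
#' @param target_kind `"stage"` (Sn) or `"leaf_number"` (Ln).
#' @param window Integer bounds `c(lo, hi)` on the target index (default
#'   `c(1, 10)`, where sampling is dense).
#' @param mode `"joint"` (default; single GPA over train + test) or
#'   `"project"` (GPA on train only, test leaves superimposed onto its
#'   consensus).
#' @param allow_reflection,prior_mode,rank_tol Passed to [gpa()] /
#'   [fit_lda()].
#' @return Object of class `stage_prediction`: `predictions` (data frame
#'   `leaf_id, vine_id, species, actual, apparent, posterior_max` for the
#'   test rows), `model`, `aligned`, `target_kind`, `window`.
#' @export
cross_stage <- function(train, test, target_kind = c("stage", "leaf_number"),
                        window = c(1L, 10L), mode = c("joint", "project"),
                        allow_reflection = TRUE,
                        prior_mode = "proportional", rank_tol = 1e-8) {
  target_kind <- match.arg(target_kind)
  mode <- match.arg(mode)
  wmode <- if (target_kind == "stage") "stage_window" else "leafnum_window"
  train <- select_positions(train, wmode, window[1], window[2])
  test <- select_positions(test, wmode, window[1], window[2])
  if (nrow(train$meta) == 0L) stop("cross_stage: empty training window")
  if (nrow(test$meta) == 0L) stop("cross_stage: empty test window")
  value_of <- function(d) if (target_kind == "stage") d$meta$stage else
    d$meta$leaf_number
  # drop classes with < 2 training leaves
  tv <- value_of(train)
  counts <- table(tv)
  small <- as.numeric(names(counts)[counts < 2L])
  if (length(small) > 0L) {
    warning("cross_stage: dropping ", target_kind, " classes with < 2 ",
            "training leaves: ", paste(small, collapse = ", "))
    train <- ld_subset(train, which(!tv %in% small))
    tv <- value_of(train)
  }
  if (length(unique(tv)) < 2L)
    stop("cross_stage: fewer than 2 usable training classes")
  if (mode == "joint") {
    both <- ld_rbind(train, test)
    ali <- gpa(both, allow_reflection = allow_reflection)
    tr_idx <- seq_len(nrow(train$meta))
    te_idx <- nrow(train$meta) + seq_len(nrow(test$meta))
    tr_arr <- ali$aligned[tr_idx, , , drop = FALSE]
    te_arr <- ali$aligned[te_idx, , , drop = FALSE]
  } else {
    ali <- gpa(train, allow_reflection = allow_reflection)
    tr_arr <- ali$aligned
    te_arr <- array(NA_real_, dim = c(nrow(test$meta), N_LANDMARKS, 2L))
    for (i in seq_len(nrow(test$meta)))
      te_arr[i, , ] <- superimpose_pair(ali$mean_shape, test$coords[i, , ],
                                        allow_reflection = allow_reflection,
                                        scale = TRUE)$aligned
  }
  model <- fit_lda(tr_arr, factor(tv), prior_mode = prior_mode,
                   rank_tol = rank_tol, target_kind = target_kind,
                   consensus = ali$mean_shape)
  pred <- predict_classes(model, te_arr)
  apparent <- as.integer(as.character(pred$apparent))
  predictions <- data.frame(
    leaf_id = test$meta$leaf_id,
    vine_id = test$meta$vine_id,
    species = test$meta$species,
    actual = as.integer(value_of(test)),
    apparent = apparent,
    posterior_max = apply(pred$posterior, 1L, max),
    stringsAsFactors = FALSE)
  structure(list(predictions = predictions, model = model, aligned = ali,
                 target_kind = target_kind, window = window),
            class = "stage_prediction")
}

#' @export
print.stage_prediction <- function(x, ...) {
  cat("stage_prediction (", x$target_kind, ", window ", x$window[1], "-",
      x$window[2], "): ", nrow(x$predictions), " test leaves; mean ",
      "relative value ",
      sprintf("%+.2f", mean(x$predictions$apparent - x$predictions$actual)),
      " nodes\n", sep = "")
  invisible(x)
}

#' Serialize a discriminant model to JSON
#'
#' @param model A `leaf_lda`.
#' @param path Output JSON.
#' @return Invisibly, `path`.
#' @export
write_lda <- function(model, path) {
  jsonlite::write_json(list(class_labels = model$class_labels,
                            priors = model$priors,
                            class_means = model$class_means,
                            pooled_covariance = model$pooled_covariance,
                            reduction_center = model$reduction$center,
                            reduction_basis = model$reduction$basis,
                            reduction_consensus = model$reduction$consensus,
                            target_kind = model$target_kind, n = model$n),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a discriminant model serialized by [write_lda()]
#'
#' @param path JSON file.
#' @return A `leaf_lda`.
#' @export
read_lda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cm <- as.matrix(obj$class_means)
  rownames(cm) <- obj$class_labels
  structure(list(class_labels = obj$class_labels,
                 priors = stats::setNames(as.numeric(obj$priors),
                                          obj$class_labels),
                 class_means = cm,
                 pooled_covariance = as.matrix(obj$pooled_covariance),
                 reduction = list(center = as.numeric(obj$reduction_center),
                                  basis = as.matrix(obj$reduction_basis),
                                  consensus = if (!is.null(obj$reduction_consensus))
                                    as.numeric(obj$reduction_consensus)),
                 target_kind = obj$target_kind, n = obj$n),
            class = "leaf_lda")
}
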