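# Fixtures and independent oracles used across the suite. All data are
# built in code; oracles are deliberately naive (grid search, brute-force
# agglomeration, direct density evaluation) and independent of the code
# paths they check.

# Apply one random similarity transform (optionally a reflection) to a
# k x 2 configuration.
random_similarity <- function(cfg, reflect = FALSE) {
  th <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  if (reflect && stats::runif(1) < 0.5) R <- R %*% diag(c(1, -1))
  sc <- stats::runif(1, 0.3, 3)
  tr <- stats::runif(2, -20, 20)
  sweep(sc * (cfg %*% R), 2, tr, `+`)
}

# Same transform draw applied independently to every leaf of a dataset.
transform_dataset <- function(ds, reflect = TRUE) {
  for (i in seq_len(nrow(ds$meta)))
    ds$coords[i, , ] <- random_similarity(ds$coords[i, , ], reflect)
  ds
}

# Small hand-assembled dataset: each vine carries `total` leaves, shapes
# are jittered copies of the template (deterministic given the RNG state).
manual_dataset <- function(n_vines = 2, total = 5, species = "sp1",
                           organ = NULL, jitter = 0.05) {
  tmpl <- leaf_template()
  rows <- list(); coords <- list()
  for (v in seq_len(n_vines)) {
    for (l in seq_len(total)) {
      rows[[length(rows) + 1]] <- data.frame(
        leaf_id = sprintf("%s_v%d_L%d", species, v, l),
        vine_id = sprintf("%s_v%d", species, v), species = species,
        stage = total + 1 - l, leaf_number = l,
        organ_opposite = if (is.null(organ)) "unknown" else organ[l],
        stringsAsFactors = FALSE)
      coords[[length(coords) + 1]] <-
        tmpl + matrix(stats::rnorm(34, 0, jitter), 17, 2)
    }
  }
  arr <- array(NA_real_, dim = c(length(coords), 17, 2))
  for (i in seq_along(coords)) arr[i, , ] <- coords[[i]]
  leaf_dataset(do.call(rbind, rows), arr, provenance = "manual fixture")
}

# Brute-force rotation-grid Procrustes distance between unit preshapes:
# min over a theta grid (and, if allowed, the reflected branch) of
# ||A_u - B_u R(theta)||. Uses the closed form of the objective on the
# grid; independent of the SVD kernel.
grid_procrustes_distance <- function(a, b, allow_reflection = TRUE,
                                     step = 1e-4) {
  unitize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  A <- unitize(a)
  theta <- seq(0, 2 * pi, by = step)
  best <- Inf
  branches <- if (allow_reflection) list(b, b %*% diag(c(1, -1))) else list(b)
  for (bb in branches) {
    B <- unitize(bb)
    C <- crossprod(A, B)
    # tr(t(A) B R(theta)) with R = [[cos,-sin],[sin,cos]], acting B %*% R
    tr <- (C[1, 1] + C[2, 2]) * cos(theta) + (C[1, 2] - C[2, 1]) * sin(theta)
    best <- min(best, min(2 - 2 * tr))
  }
  sqrt(best)
}

# Brute-force O(n^3) agglomeration on a distance matrix; returns the
# sorted merge heights.
bf_linkage_heights <- function(d, linkage = "complete") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  cluster_dist <- function(ci, cj) {
    vals <- d[ci, cj, drop = FALSE]
    switch(linkage, complete = max(vals), single = min(vals),
           average = mean(vals))
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < bd) { bd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Build an aligned-shapes-like array whose flattened rows are
# mean_vec + t_i * v for a unit direction v (1-D latent toys for LDA).
rank1_shape_array <- function(tvals, v, mean_cfg = NULL) {
  if (is.null(mean_cfg)) {
    m <- leaf_template()
    m <- sweep(m, 2, colMeans(m))
    mean_cfg <- m / sqrt(sum(m^2))
  }
  mean_vec <- as.vector(t(mean_cfg))
  arr <- array(NA_real_, dim = c(length(tvals), 17, 2))
  for (i in seq_along(tvals)) {
    x <- mean_vec + tvals[i] * v
    arr[i, , ] <- matrix(x, 17, 2, byrow = TRUE)
  }
  arr
}

# A unit 34-vector orthogonal to the similarity null space of the
# template (so Procrustes/tangent operations leave it intact).
shape_direction <- function(seed = 1) {
  set.seed(seed)
  ortho <- latentleaf:::similarity_nullspace(leaf_template())
  v <- latentleaf:::draw_orthogonal_unit(ortho)
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v
}
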