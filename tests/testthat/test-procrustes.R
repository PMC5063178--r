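# Ordinary and generalized Procrustes superimposition.

test_that("centroid size follows the direct formula and similarity rules", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  set.seed(1)
  cfg <- leaf_template()
  expect_equal(centroid_size(cfg * 3), 3 * centroid_size(cfg),
               tolerance = 1e-12)
  expect_equal(centroid_size(sweep(cfg, 2, c(5, -7), `+`)),
               centroid_size(cfg), tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("pairwise superimposition removes similarity transforms", {
  a <- leaf_template()
  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  b <- sweep(a %*% R, 2, c(13, -4), `+`)
  expect_lt(superimpose_pair(a, b)$distance, 1e-10)

  # mirror image recovered when reflection is allowed
  b_mirror <- a %*% diag(c(-1, 1))
  expect_lt(superimpose_pair(a, b_mirror, allow_reflection = TRUE)$distance,
            1e-10)
  expect_gt(superimpose_pair(a, b_mirror, allow_reflection = FALSE)$distance,
            0.01)
  expect_error(superimpose_pair(a, a[1:10, ]), "mismatch")
})

test_that("pairwise distance matches the rotation-grid oracle", {
  set.seed(42)
  scalene <- matrix(c(0, 0, 3, 0, 0.7, 1.9), ncol = 2, byrow = TRUE)
  mirror <- scalene %*% diag(c(-1, 1))
  d <- superimpose_pair(scalene, mirror, allow_reflection = FALSE)$distance
  expect_equal(d, grid_procrustes_distance(scalene, mirror, FALSE),
               tolerance = 1e-4)
  for (i in 1:30) {
    a <- matrix(rnorm(6), 3, 2)
    b <- matrix(rnorm(6), 3, 2)
    refl <- i %% 2 == 0
    expect_equal(superimpose_pair(a, b, allow_reflection = refl)$distance,
                 grid_procrustes_distance(a, b, refl),
                 tolerance = 1e-4)
  }
})

test_that("GPA collapses copies of one shape and converges fast", {
  set.seed(7)
  tmpl <- leaf_template()
  arr <- array(NA_real_, dim = c(20, 17, 2))
  for (i in 1:20) arr[i, , ] <- random_similarity(tmpl, reflect = TRUE)
  ali <- gpa(arr)
  expect_lte(ali$n_iter, 3)
  for (i in 2:20)
    expect_lt(max(abs(ali$aligned[i, , ] - ali$aligned[1, , ])), 1e-8)
  # unit centroid sizes with scaling on
  for (i in 1:20)
    expect_equal(sum(latentleaf:::center_config(ali$aligned[i, , ])^2), 1,
                 tolerance = 1e-9)
  expect_equal(sum(ali$mean_shape^2), 1, tolerance = 1e-9)
})

test_that("GPA output is invariant to per-leaf placement of the input", {
  set.seed(8)
  sim <- generate_shoots(synthetic_config(n_species = 2,
                                          vines_per_species = 2,
                                          mean_total_leaves = 10,
                                          transform = FALSE, seed = 31))
  ref <- gpa(sim$dataset)
  for (rep in 1:3) {
    tds <- transform_dataset(sim$dataset, reflect = TRUE)
    ali <- gpa(tds)
    expect_lt(max(abs(ali$aligned - ref$aligned)), 1e-8)
    expect_lt(max(abs(ali$mean_shape - ref$mean_shape)), 1e-8)
  }
})

test_that("the GPA objective is monotone and sizes are preserved", {
  set.seed(9)
  sim <- generate_shoots(synthetic_config(n_species = 2,
                                          vines_per_species = 3,
                                          mean_total_leaves = 12, seed = 12))
  ali <- gpa(sim$dataset)
  tr <- ali$objective_trace
  if (length(tr) > 1)
    expect_true(all(diff(tr) <= 1e-12))
  expect_true(all(ali$centroid_sizes > 0))
  # centroid sizes recorded before scaling
  expect_equal(ali$centroid_sizes[1],
               centroid_size(sim$dataset$coords[1, , ]), tolerance = 1e-12)
})

test_that("the two-triangle consensus minimizes summed squared full Procrustes distances", {
  set.seed(10)
  t1 <- matrix(c(0, 0, 2, 0, 0.4, 1.5), 3, 2, byrow = TRUE)
  t2 <- matrix(c(0, 0, 1.7, 0.2, 1.1, 1.2), 3, 2, byrow = TRUE)
  arr <- array(NA_real_, dim = c(2, 3, 2))
  arr[1, , ] <- t1; arr[2, , ] <- t2
  ali <- gpa(arr, allow_reflection = FALSE)

  # independent numerical oracle: minimize the summed squared full
  # Procrustes distance d_F^2 = 1 - (sum of singular values)^2 over a
  # free consensus preshape
  unitize <- function(m) {
    m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2))
  }
  dF2 <- function(x, mu) {
    sv <- svd(crossprod(unitize(mu), unitize(x)))$d
    1 - (sv[1] + sv[2])^2
  }
  objective <- function(par) {
    mu <- matrix(par, 3, 2)
    if (sum(latentleaf:::center_config(mu)^2) < 1e-6) return(1e6)
    dF2(t1, mu) + dF2(t2, mu)
  }
  opt <- optim(as.vector(ali$mean_shape) + rnorm(6, 0, 0.1), objective,
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  mu_opt <- matrix(opt$par, 3, 2)
  # compare in shape space (the frame is arbitrary)
  expect_lt(superimpose_pair(ali$mean_shape, mu_opt,
                             allow_reflection = FALSE)$distance, 1e-6)
  # and the achieved objective is not worse than the oracle's
  expect_lte(dF2(t1, ali$mean_shape) + dF2(t2, ali$mean_shape),
             opt$value + 1e-10)
})

test_that("degenerate members and non-convergence are reported", {
  set.seed(13)
  ds <- manual_dataset(1, 3)
  ds$coords[2, , ] <- 1  # all landmarks coincide
  expect_error(gpa(ds), "degenerate")
  sim <- generate_shoots(synthetic_config(n_species = 2,
                                          vines_per_species = 2,
                                          mean_total_leaves = 10, seed = 3))
  expect_error(gpa(sim$dataset, max_iter = 1, tol = 1e-16), "convergence")
})

test_that("aligned coordinates roundtrip through the wide export", {
  set.seed(14)
  sim <- generate_shoots(synthetic_config(n_species = 2,
                                          vines_per_species = 2,
                                          mean_total_leaves = 10, seed = 5))
  ali <- gpa(sim$dataset)
  path <- withr::local_tempfile(fileext = ".csv")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_aligned(ali, path, cpath)
  back <- read_aligned(path)
  expect_equal(back$aligned, ali$aligned, tolerance = 1e-12)
  expect_equal(back$leaf_id, ali$leaf_id)
  expect_equal(back$centroid_sizes, ali$centroid_sizes, tolerance = 1e-12)
  cons <- read.csv(cpath)
  expect_equal(nrow(cons), 1)
})
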