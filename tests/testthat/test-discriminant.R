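# Latent-shape discriminants: LDA fit, reallocation, confusion matrices,
# cross-collection staging.

test_that("separable classes are reallocated perfectly", {
  sim <- generate_shoots(synthetic_config(
    n_species = 3, vines_per_species = 4, mean_total_leaves = 10,
    stage_effect_scale = 0, leafnum_effect_scale = 0,
    species_effect_scale = 1, noise_sd = 0.02, seed = 41))
  ali <- gpa(sim$dataset)
  m <- fit_lda(ali, sim$dataset$meta$species, target_kind = "species")
  pred <- predict_classes(m, ali)
  expect_equal(as.character(pred$apparent), sim$dataset$meta$species)
  expect_true(all(abs(rowSums(pred$posterior) - 1) < 1e-9))
})

test_that("the 1-D two-Gaussian boundary sits at the midpoint", {
  # exact sample means 0 and 1 and exact unit pooled variance by
  # construction: class A at -a, a and class B at 1 - a, 1 + a with
  # a = 1/sqrt(2) give pooled var 4 a^2 / (4 - 2) = 1
  a <- 1 / sqrt(2)
  v <- shape_direction(3)
  arr <- rank1_shape_array(c(-a, a, 1 - a, 1 + a) * 0.01, v)
  labels <- factor(c("A", "A", "B", "B"))
  m <- fit_lda(arr, labels)
  # t is in template units; the latent scale is 0.01 per unit mean gap
  post_at <- function(t) {
    predict_classes(m, rank1_shape_array(t * 0.01, v))$posterior[1, ]
  }
  p_mid <- post_at(0.5)
  expect_equal(unname(p_mid), c(0.5, 0.5), tolerance = 1e-9)
  # bisection for the boundary where the posterior difference changes sign
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    d <- post_at(mid)[1] - post_at(mid)[2]
    if (d > 0) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, 0.5, tolerance = 1e-6)
  # posteriors match direct evaluation of the two Gaussian densities
  # (empirical means 0 and 1, pooled sd 1, equal priors)
  for (t in c(-0.7, 0.2, 0.9, 1.8)) {
    dens <- dnorm(t, mean = c(0, 1), sd = 1)
    expect_equal(unname(post_at(t)), dens / sum(dens), tolerance = 1e-9)
  }
  # exactly equidistant leaf: tie broken to the first class in order
  expect_equal(as.character(
    predict_classes(m, rank1_shape_array(0.5 * 0.01, v))$apparent), "A")
})

test_that("the reallocation agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(47)
  n <- 60
  arr <- array(rnorm(n * 17 * 2, sd = 0.1), dim = c(n, 17, 2))
  for (i in seq_len(n)) arr[i, , ] <- arr[i, , ] + leaf_template()
  labels <- factor(rep(c("A", "B", "C"), each = n / 3))
  shift <- shape_direction(5)
  for (i in which(labels == "B"))
    arr[i, , ] <- arr[i, , ] + matrix(0.08 * shift, 17, 2, byrow = TRUE)
  for (i in which(labels == "C"))
    arr[i, , ] <- arr[i, , ] - matrix(0.08 * shift, 17, 2, byrow = TRUE)
  m <- fit_lda(arr, labels)
  pred <- predict_classes(m, arr)
  X <- latentleaf:::flatten_coords(arr)
  ref <- MASS::lda(X, grouping = labels)
  ref_pred <- predict(ref, X)
  expect_equal(as.character(pred$apparent), as.character(ref_pred$class))
  expect_equal(unname(pred$posterior), unname(ref_pred$posterior),
               tolerance = 1e-6)
})

test_that("degenerate label configurations are rejected", {
  set.seed(53)
  arr <- array(rnorm(6 * 34, sd = 0.1), dim = c(6, 17, 2))
  expect_error(fit_lda(arr, rep("A", 6)), "at least 2 classes")
  expect_error(fit_lda(arr, c("A", "A", "A", "A", "A", "B")),
               ">= 2 leaves")
})

test_that("confusion matrices count and normalize correctly", {
  cm <- confusion(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(unname(cm$counts), matrix(c(1, 0, 1, 2), 2))
  expect_equal(unname(cm$proportions), matrix(c(0.5, 0, 0.5, 1), 2))
  expect_true(all(abs(rowSums(cm$proportions) - 1) < 1e-12))
  expect_equal(sum(cm$counts), 4)

  ident <- confusion(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(unname(ident$proportions), diag(3))
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion(c("A", "B"), "A"), "length mismatch")
})

test_that("misclassification respects distances in shape space", {
  # three classes along one latent direction at 0, 1, 3 effect units:
  # the close pair (0,1) must be confused more than the far pairs
  v <- shape_direction(7)
  rates <- sapply(1:5, function(seed) {
    set.seed(seed)
    n <- 40
    centers <- rep(c(0, 1, 3), each = n)
    tvals <- (centers + rnorm(3 * n, sd = 0.6)) * 0.01
    arr <- rank1_shape_array(tvals, v)
    labels <- factor(rep(c("lo", "mid", "hi"), each = n),
                     levels = c("lo", "mid", "hi"))
    m <- fit_lda(arr, labels)
    pred <- predict_classes(m, arr)
    cm <- confusion(labels, pred$apparent)$counts
    conf <- function(a, b) cm[a, b] + cm[b, a]
    c(near = conf("lo", "mid"), far = conf("lo", "hi"))
  })
  expect_true(all(rates["near", ] > rates["far", ]))
  # rank correlation between confusion rate and generating distance < 0
  mean_near <- mean(rates["near", ]); mean_far <- mean(rates["far", ])
  expect_lt(cor(c(1, 3), c(mean_near, mean_far), method = "spearman"), 0)
})

test_that("cross-collection staging recovers noiseless test positions", {
  base <- synthetic_config(n_species = 1, vines_per_species = 8,
                           mean_total_leaves = 14, seed = 61)
  train_cfg <- synthetic_config(n_species = 1, vines_per_species = 8,
                                mean_total_leaves = 14,
                                stage_effect_scale = 0,
                                noise_sd = 0.1 * base$noise_sd,
                                heterochrony_sd = 0, seed = 61)
  test_cfg <- synthetic_config(n_species = 1, vines_per_species = 6,
                               mean_total_leaves = 14, noise_sd = 0,
                               stage_effect_scale = 0,
                               heterochrony_sd = 0, seed = 62,
                               structure_seed = 61)
  train <- generate_shoots(train_cfg)$dataset
  test <- generate_shoots(test_cfg)$dataset
  st <- cross_stage(train, test, target_kind = "leaf_number",
                    window = c(1, 10))
  expect_equal(st$predictions$apparent, st$predictions$actual)
})

test_that("staging a collection against itself reproduces in-sample reallocation", {
  sim <- generate_shoots(synthetic_config(n_species = 1,
                                          vines_per_species = 6,
                                          mean_total_leaves = 14,
                                          heterochrony_sd = 0, seed = 67))
  st <- cross_stage(sim$dataset, sim$dataset, target_kind = "stage",
                    window = c(1, 10))
  # refit on the aligned training rows and reallocate them directly
  ntr <- nrow(select_positions(sim$dataset, "stage_window", 1, 10)$meta)
  tr_arr <- st$aligned$aligned[seq_len(ntr), , , drop = FALSE]
  pred <- predict_classes(st$model, tr_arr)
  expect_equal(st$predictions$apparent,
               as.integer(as.character(pred$apparent)))
})

test_that("an injected heteroblastic shift is recovered by staging", {
  # +2-node shift, 20 vines/species; pooled over two generation seeds.
  # Recovery is structurally below +2: a shifted L9/L10 leaf has no
  # L11/L12 class inside the window, capping the ideal mean at +1.7.
  rels <- sapply(1:2, function(s) {
    train <- generate_shoots(synthetic_config(
      n_species = 1, vines_per_species = 20, heterochrony_sd = 0,
      seed = 70 + s))$dataset
    test <- generate_shoots(synthetic_config(
      n_species = 1, vines_per_species = 20, heterochrony_sd = 0,
      heterochrony_mean = 2, seed = 80 + s, structure_seed = 70 + s))$dataset
    st <- cross_stage(train, test, target_kind = "leaf_number",
                      window = c(1, 10))
    mean(st$predictions$apparent - st$predictions$actual)
  })
  expect_lt(abs(mean(rels) - 2), 0.5)
})
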