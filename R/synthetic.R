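## Synthetic shoots of 17-landmark leaves with full ground truth: additive
## species, ontogeny (Sn) and heteroblasty (Ln) latent-shape effects,
## vine-level heterochronic shifts coupled to the organ series, landmark
## noise, and arbitrary placement of the raw configurations.

#' The built-in 17-landmark grape-like leaf template
#'
#' A hard-coded, bilaterally symmetric outline with the proportions of a
#' generic Vitis leaf (midvein along +y, petiolar junction at the origin):
#' distal and proximal lobes and sinuses, petiolar-vein termini, and the
#' major-vein branch points, in the scheme order of [landmark_names()].
#' Tests depend only on the template's structure, never on its exact
#' coordinates.
#'
#' @return `17 x 2` numeric matrix (arbitrary length units).
#' @export
leaf_template <- function() {
  m <- matrix(c(
     0.0,  0.0,   # petiolar junction
     0.0, 10.0,   # midvein tip
    -2.2,  6.5,   # left distal sinus
     2.2,  6.5,   # right distal sinus
    -5.0,  7.5,   # left distal lobe tip
     5.0,  7.5,   # right distal lobe tip
    -3.5,  2.5,   # left proximal sinus
     3.5,  2.5,   # right proximal sinus
    -6.5,  3.0,   # left proximal lobe tip
     6.5,  3.0,   # right proximal lobe tip
    -2.5, -1.0,   # left terminus petiolar vein
     2.5, -1.0,   # right terminus petiolar vein
     0.0,  1.5,   # branch point midvein
    -1.2,  2.8,   # branch point left distal vein
     1.2,  2.8,   # branch point right distal vein
    -0.8,  0.8,   # branch point left proximal vein
     0.8,  0.8),  # branch point right proximal vein
    ncol = 2L, byrow = TRUE)
  dimnames(m) <- list(landmark_names(), c("x", "y"))
  m
}

#' Mean node-to-node latent-shape step over a position window
#'
#' The average displacement (in shape units) that a one-node move along
#' the heteroblastic (Ln) trajectory produces across the analysis window —
#' the natural scale of the effect a heterochronic node shift has on a
#' leaf, and the yardstick against which landmark noise is set. For the
#' saturating trajectory `f(l) = 1 - exp(-(l - 1)/tau_L)` this is
#' `effect_scale * (f(hi) - f(lo)) / (hi - lo)`.
#'
#' @param leafnum_effect_scale,tau_L Trajectory parameters (see
#'   [synthetic_config()]).
#' @param window Position window, default `c(1, 10)`.
#' @return Positive scalar (shape units per node).
#' @export
effect_step_scale <- function(leafnum_effect_scale = 1, tau_L = 3,
                              window = c(1, 10)) {
  f <- function(l) 1 - exp(-(l - 1) / tau_L)
  leafnum_effect_scale * (f(window[2]) - f(window[1])) /
    (window[2] - window[1])
}

#' Configuration of the synthetic shoot generator
#'
#' Defaults describe the study conditions the generator emulates: a
#' germplasm-style collection of several species, many vines per species,
#' shoots of ~25 leaves so the S1-S10 and L1-L10 windows are fully
#' populated, saturating ontogenetic and heteroblastic latent-shape
#' trajectories steepest near the shoot tip/base (decay constants of 3
#' nodes), vine-level heterochronic shifts of ~1 node, a cluster-to-tendril
#' organ series with every third node skipped, and raw configurations
#' placed arbitrarily (rotation, translation, scale, reflection).
#'
#' `noise_sd` (per-coordinate landmark noise) defaults to a quarter of the
#' mean node-to-node latent-shape step over the L1-L10 window (see
#' [effect_step_scale()]): digitization error small relative to the
#' between-node shape differences being classified, as in carefully
#' landmarked scans.
#'
#' @param n_species Number of species.
#' @param vines_per_species Vines (genetic accessions) per species.
#' @param mean_total_leaves Center of the per-shoot leaf-count (Poisson)
#'   distribution; floored at 10 so both position windows are populated.
#' @param template Base `17 x 2` leaf shape (default [leaf_template()]).
#' @param species_effect_scale Norm of each species' latent-shape effect.
#' @param stage_effect_scale,tau_S Amplitude and decay constant (nodes) of
#'   the ontogenetic (Sn) trajectory `exp(-(Sn - 1)/tau_S)`.
#' @param leafnum_effect_scale,tau_L Amplitude and decay constant of the
#'   heteroblastic (Ln) trajectory `1 - exp(-(Ln - 1)/tau_L)`.
#' @param heterochrony_mean,heterochrony_sd Mean and SD (nodes) of the
#'   vine-level heterochronic shift `delta_v`; a nonzero mean injects a
#'   known shift for recovery experiments.
#' @param tendril_base Baseline first-tendril node (Ln frame).
#' @param tendril_coupling Nodes of first-tendril-node change per node of
#'   `delta_v` (the heteroblastic coupling `gamma`; precocious vines show
#'   tendrils closer to the base).
#' @param noise_sd Per-coordinate landmark noise SD; `NULL` (default)
#'   sets `0.25 * effect_step_scale(leafnum_effect_scale, tau_L)`.
#' @param transform Logical: place raw configurations under random
#'   similarity transforms (default `TRUE`).
#' @param rotation_range,translation_range,scale_range Placement ranges.
#' @param reflect Allow random reflection of raw configurations (default
#'   `TRUE`).
#' @param confound_cos Cosine between the heteroblastic direction and the
#'   ontogenetic direction (default 0: developmental subspaces orthogonal
#'   to each other and to all species effects; > 0 tests robustness to
#'   confounded axes).
#' @param seed Integer seed; fixes the output bit-for-bit.
#' @param structure_seed Seed for the latent structure (species effects
#'   and the two developmental directions); defaults to `seed`. Two
#'   collections generated with the same `structure_seed` but different
#'   `seed`s share a morphospace while differing in vines, noise and
#'   placement — the cross-collection staging scenario.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 3L, vines_per_species = 10L,
                             mean_total_leaves = 25,
                             template = leaf_template(),
                             species_effect_scale = 1,
                             stage_effect_scale = 1, tau_S = 3,
                             leafnum_effect_scale = 1, tau_L = 3,
                             heterochrony_mean = 0, heterochrony_sd = 1,
                             tendril_base = 5L, tendril_coupling = 1,
                             noise_sd = NULL, transform = TRUE,
                             rotation_range = c(0, 2 * pi),
                             translation_range = c(-50, 50),
                             scale_range = c(0.5, 2),
                             reflect = TRUE, confound_cos = 0,
                             seed = 1L, structure_seed = NULL) {
  if (is.null(noise_sd))
    noise_sd <- 0.25 * effect_step_scale(leafnum_effect_scale, tau_L)
  cfg <- list(n_species = as.integer(n_species),
              vines_per_species = as.integer(vines_per_species),
              mean_total_leaves = mean_total_leaves,
              template = template,
              species_effect_scale = species_effect_scale,
              stage_effect_scale = stage_effect_scale, tau_S = tau_S,
              leafnum_effect_scale = leafnum_effect_scale, tau_L = tau_L,
              heterochrony_mean = heterochrony_mean,
              heterochrony_sd = heterochrony_sd,
              tendril_base = as.integer(tendril_base),
              tendril_coupling = tendril_coupling,
              noise_sd = noise_sd, transform = isTRUE(transform),
              rotation_range = rotation_range,
              translation_range = translation_range,
              scale_range = scale_range, reflect = isTRUE(reflect),
              confound_cos = confound_cos, seed = as.integer(seed),
              structure_seed = as.integer(if (is.null(structure_seed)) seed
                                          else structure_seed))
  scales <- c("species_effect_scale", "stage_effect_scale",
              "leafnum_effect_scale", "heterochrony_sd", "noise_sd",
              "tau_S", "tau_L")
  for (s in scales)
    if (!is.numeric(cfg[[s]]) || cfg[[s]] < 0)
      stop("synthetic_config: ", s, " must be a nonnegative number")
  if (cfg$mean_total_leaves < 10)
    stop("synthetic_config: mean_total_leaves must be >= 10 so the S1-S10 ",
         "and L1-L10 windows are populated")
  if (abs(cfg$confound_cos) >= 1)
    stop("synthetic_config: confound_cos must lie in (-1, 1)")
  if (length(dim(cfg$template)) != 2L || nrow(cfg$template) != N_LANDMARKS)
    stop("synthetic_config: template must be a 17 x 2 matrix")
  class(cfg) <- "synthetic_config"
  cfg
}

# Orthonormal basis of the similarity-transform null directions of a
# configuration: x/y translation, isotropic scaling, infinitesimal
# rotation. Effects are drawn orthogonal to these so they survive
# Procrustes alignment.
similarity_nullspace <- function(template) {
  k <- nrow(template)
  ctr <- center_config(template)
  rot <- cbind(-ctr[, 2L], ctr[, 1L])
  basis <- cbind(rep(c(1, 0), k),             # translate x
                 rep(c(0, 1), k),             # translate y
                 as.vector(t(ctr)),           # scale
                 as.vector(t(rot)))           # rotate
  qr.Q(qr(basis))
}

# Draw a unit vector orthogonal to the columns of `ortho`.
draw_orthogonal_unit <- function(ortho) {
  repeat {
    v <- stats::rnorm(nrow(ortho))
    v <- v - ortho %*% crossprod(ortho, v)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(as.numeric(v / nv))
  }
}

#' Generate synthetic shoots with ground truth
#'
#' For each vine v of species s: total leaves `T_v ~ Poisson(mean) floored
#' at 10`; for the leaf at node `Ln = l` (so `Sn = T_v + 1 - l`) the
#' noiseless flattened shape is
#'
#' `vec(template) + A_s + stage_scale * exp(-(S_eff - 1)/tau_S) * u
#'   + leafnum_scale * (1 - exp(-(L_eff - 1)/tau_L)) * w`,
#'
#' where the vine's heterochronic shift
#' `delta_v ~ Normal(heterochrony_mean, heterochrony_sd)` displaces the
#' whole developmental program by `delta_v` nodes: the leaf takes the
#' shape of effective node `L_eff = l + delta_v`, equivalently effective
#' stage `S_eff = Sn - delta_v` (the two indices count the same nodes from
#' opposite ends). A precocious vine (`delta_v > 0`) therefore looks ahead
#' of its actual leaf number and ahead of its actual developmental stage
#' in opposite node directions, mirroring the inverse relation between the
#' two relative indices seen in real shoots. Species effects
#' `A_s` and the latent directions `u` (ontogeny) and `w` (heteroblasty)
#' are constructed mutually orthonormal and orthogonal to the similarity
#' null space, so species identity and the two developmental axes occupy
#' separable shape subspaces by construction (set `confound_cos > 0` to
#' relax this). Per-coordinate Gaussian noise is added and, when
#' `transform` is on, each raw configuration is placed under a random
#' similarity transform (reflection with probability 1/2 when `reflect`).
#'
#' The organ series runs from the base: the target first-tendril node is
#' `t_v = clamp(round(tendril_base - gamma * delta_v + Normal(0, 1)), 1,
#' T_v)`; nodes below `t_v` carry a cluster (C), nodes at or above carry a
#' tendril (T), and every third node carries no organ (N) regardless.
#'
#' @param config A `synthetic_config`.
#' @return List with `dataset` (a valid `leaf_dataset`; Sn + Ln = T_v + 1
#'   holds by construction) and `truth` (class `synthetic_truth`): species
#'   effect vectors `A` (34 x S), latent directions `u`, `w`, per-vine
#'   table `vines` (`vine_id, species, total_leaves, delta,
#'   tendril_target, first_tendril_node`), and the per-leaf `noiseless`
#'   flattened shapes.
#' @export
generate_shoots <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tmpl_vec <- as.vector(t(config$template))   # (x1, y1, ..., x17, y17)
  ortho <- similarity_nullspace(config$template)
  # latent structure under its own seed, so collections can share a
  # morphospace while being sampled independently
  set.seed(config$structure_seed)
  A <- matrix(NA_real_, 2L * N_LANDMARKS, config$n_species)
  for (s in seq_len(config$n_species)) {
    a <- draw_orthogonal_unit(cbind(ortho, A[, seq_len(s - 1L),
                                             drop = FALSE]))
    A[, s] <- a
  }
  u <- draw_orthogonal_unit(cbind(ortho, A))
  w0 <- draw_orthogonal_unit(cbind(ortho, A, u))
  w <- sqrt(1 - config$confound_cos^2) * w0 + config$confound_cos * u
  set.seed(config$seed)
  A_scaled <- A * config$species_effect_scale
  species_names <- paste0("species_", LETTERS[seq_len(config$n_species)])
  meta_rows <- list()
  noiseless <- list()
  coords <- list()
  vines <- list()
  for (s in seq_len(config$n_species)) {
    for (vi in seq_len(config$vines_per_species)) {
      vine_id <- sprintf("%s_v%02d", species_names[s], vi)
      T_v <- max(10L, stats::rpois(1L, config$mean_total_leaves))
      delta <- stats::rnorm(1L, config$heterochrony_mean,
                            config$heterochrony_sd)
      t_target <- round(config$tendril_base -
                          config$tendril_coupling * delta +
                          stats::rnorm(1L))
      t_target <- min(max(t_target, 1L), T_v)
      organs <- ifelse(seq_len(T_v) %% 3L == 0L, "N",
                       ifelse(seq_len(T_v) < t_target, "C", "T"))
      obs_t <- which(organs == "T")
      obs_t <- if (length(obs_t) > 0L) min(obs_t) else NA_real_
      for (l in seq_len(T_v)) {
        sn <- T_v + 1L - l
        l_eff <- l + delta
        s_eff <- sn - delta
        shape <- tmpl_vec + A_scaled[, s] +
          config$stage_effect_scale * exp(-(s_eff - 1) / config$tau_S) * u +
          config$leafnum_effect_scale *
            (1 - exp(-(l_eff - 1) / config$tau_L)) * w
        noiseless[[length(noiseless) + 1L]] <- shape
        obs <- shape + stats::rnorm(length(shape), 0, config$noise_sd)
        cfg_mat <- unflatten_coords(obs)[1L, , ]
        if (config$transform) {
          th <- stats::runif(1L, config$rotation_range[1],
                             config$rotation_range[2])
          R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
          if (config$reflect && stats::runif(1L) < 0.5)
            R <- R %*% diag(c(1, -1))
          sc <- stats::runif(1L, config$scale_range[1],
                             config$scale_range[2])
          tr <- stats::runif(2L, config$translation_range[1],
                             config$translation_range[2])
          cfg_mat <- sc * (cfg_mat %*% R)
          cfg_mat <- sweep(cfg_mat, 2L, tr, `+`)
        }
        coords[[length(coords) + 1L]] <- cfg_mat
        meta_rows[[length(meta_rows) + 1L]] <- data.frame(
          leaf_id = sprintf("%s_L%02d", vine_id, l),
          vine_id = vine_id, species = species_names[s],
          stage = sn, leaf_number = l, organ_opposite = organs[l],
          stringsAsFactors = FALSE)
      }
      vines[[length(vines) + 1L]] <- data.frame(
        vine_id = vine_id, species = species_names[s],
        total_leaves = T_v, delta = delta, tendril_target = t_target,
        first_tendril_node = obs_t, stringsAsFactors = FALSE)
    }
  }
  n <- length(coords)
  arr <- array(NA_real_, dim = c(n, N_LANDMARKS, 2L))
  for (i in seq_len(n)) arr[i, , ] <- coords[[i]]
  dataset <- leaf_dataset(do.call(rbind, meta_rows), arr,
                          provenance = sprintf(
                            "synthetic shoots (seed %d, image-convention coordinates)",
                            config$seed))
  truth <- structure(list(A = A_scaled, u = u, w = w,
                          vines = do.call(rbind, vines),
                          noiseless = do.call(rbind, noiseless),
                          config = config),
                     class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Summarize generator ground truth
#'
#' The per-vine quantities recovery tests compare against: heterochronic
#' shift `delta_v`, target and observed first tendril node, total leaves,
#' and the species effect norm.
#'
#' @param truth A `synthetic_truth` from [generate_shoots()].
#' @return Data frame, one row per vine.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  v <- truth$vines
  norms <- sqrt(colSums(truth$A^2))
  v$species_effect_norm <- norms[match(v$species,
                                       paste0("species_",
                                              LETTERS[seq_along(norms)]))]
  v
}

#' Write generator ground truth as JSON
#'
#' @param truth A `synthetic_truth`.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(vines = truth$vines, u = truth$u, w = truth$w,
                            A = truth$A,
                            noise_sd = truth$config$noise_sd,
                            seed = truth$config$seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
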