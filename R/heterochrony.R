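## Heterochrony indices: relative developmental stage / leaf number
## (apparent - actual), per-vine means, per-species deviation tests, and
## the correlation with the first tendril node.

#' Relative developmental values (apparent minus actual)
#'
#' The per-leaf heterochrony index: how many nodes ahead (+) or behind (-)
#' a leaf appears to be, computed as the classifier-assigned (apparent)
#' stage or leaf number minus the true (actual) one. An S5 leaf staged as
#' S7 scores +2; an L4 leaf staged as L2 scores -2.
#'
#' @param actual,apparent Equal-length vectors of positive integers.
#' @return Integer vector `apparent - actual` (signed nodes).
#' @export
relative_values <- function(actual, apparent) {
  if (length(actual) != length(apparent))
    stop("relative_values: length mismatch (", length(actual), " vs ",
         length(apparent), ")")
  chk <- function(v, nm) {
    if (!is.numeric(v) || any(is.na(v)) || any(v != round(v)) || any(v < 1))
      stop("relative_values: ", nm, " must be positive integers")
  }
  chk(actual, "actual"); chk(apparent, "apparent")
  as.integer(apparent) - as.integer(actual)
}

#' Per-vine mean relative values
#'
#' @param relatives Per-leaf relative values (see [relative_values()]).
#' @param vine_id Per-leaf vine identifiers.
#' @return Data frame `vine_id, mean_relative, n_leaves` (one row per
#'   vine, in first-appearance order).
#' @export
vine_means <- function(relatives, vine_id) {
  if (length(relatives) != length(vine_id))
    stop("vine_means: length mismatch")
  vine_id <- as.character(vine_id)
  vines <- unique(vine_id)
  data.frame(
    vine_id = vines,
    mean_relative = vapply(vines, function(v)
      mean(relatives[vine_id == v]), 0),
    n_leaves = vapply(vines, function(v) sum(vine_id == v), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-species deviation of relative values from zero
#'
#' One-sample, two-tailed t-test of the per-vine mean relative values of
#' each species against zero (exact t distribution; vine counts are
#' small). Species with fewer than 3 vines or zero variance among vine
#' means are reported with a reason code instead of a test. Raw p-values
#' are reported alongside Benjamini-Hochberg adjusted ones (computed
#' across the tested species); no correction choice is asserted.
#'
#' @param per_vine Data frame from [vine_means()], or any frame with a
#'   `mean_relative` column and one row per vine.
#' @param species Per-vine species labels.
#' @return Data frame `species, n_vines, mean_relative, t_statistic,
#'   p_value, p_adjusted, reason` (reason `""` when tested,
#'   `"too_few_vines"` or `"zero_variance"` otherwise).
#' @export
species_offsets <- function(per_vine, species) {
  vals <- per_vine$mean_relative
  if (length(vals) != length(species))
    stop("species_offsets: one species label per vine required")
  species <- as.character(species)
  sp <- unique(species)
  out <- data.frame(species = sp, n_vines = NA_integer_,
                    mean_relative = NA_real_, t_statistic = NA_real_,
                    p_value = NA_real_, p_adjusted = NA_real_,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(sp)) {
    v <- vals[species == sp[i]]
    out$n_vines[i] <- length(v)
    out$mean_relative[i] <- mean(v)
    if (length(v) < 3L) {
      out$reason[i] <- "too_few_vines"
    } else if (stats::sd(v) == 0) {
      out$reason[i] <- "zero_variance"
    } else {
      tt <- stats::t.test(v, mu = 0, alternative = "two.sided")
      out$t_statistic[i] <- unname(tt$statistic)
      out$p_value[i] <- tt$p.value
    }
  }
  tested <- out$reason == ""
  if (any(tested)) out$p_adjusted[tested] <- bh_adjust(out$p_value[tested])
  out
}

#' First tendril node of each vine
#'
#' The node nearest the shoot base whose opposite-leaf organ is a tendril:
#' per vine, the smallest Ln with organ code `T`. Indexed from the base
#' (Ln frame) because the heteroblastic transition runs base-to-tip —
#' clusters at basal nodes give way to tendrils above — so a precocious
#' vine shows its first tendril at a lower Ln. Codes `N` (skipped nodes)
#' are simply non-tendril; `unknown` codes are excluded from the scan with
#' a warning.
#'
#' @param dataset A `leaf_dataset` with organ codes.
#' @param frame `"leaf_number"` (default, Ln from the base) or `"stage"`
#'   (Sn from the tip, for sensitivity checks).
#' @return Data frame `vine_id, first_tendril_node` (NA when the vine
#'   shows no tendril).
#' @export
first_tendril_node <- function(dataset, frame = c("leaf_number", "stage")) {
  frame <- match.arg(frame)
  meta <- dataset$meta
  if (any(meta$organ_opposite == "unknown"))
    warning("first_tendril_node: leaves with unknown organ codes are ",
            "excluded from the scan")
  idxcol <- if (frame == "leaf_number") meta$leaf_number else meta$stage
  vines <- unique(meta$vine_id)
  node <- vapply(vines, function(v) {
    sel <- meta$vine_id == v & meta$organ_opposite == "T"
    if (!any(sel)) NA_real_ else min(idxcol[sel])
  }, 0)
  data.frame(vine_id = vines, first_tendril_node = node,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between per-vine relative values and first tendril node
#'
#' Spearman's rho on vine-level pairs (mean relative value, first tendril
#' node); vines missing either value are dropped.
#'
#' @param mean_relative Per-vine mean relative values.
#' @param tendril_node Per-vine first tendril nodes (NA = no tendril).
#' @return List `rho`, `p_value`, `n_vines`.
#' @export
tendril_correlation <- function(mean_relative, tendril_node) {
  ok <- is.finite(mean_relative) & is.finite(tendril_node)
  if (sum(ok) < 4L)
    stop("tendril_correlation: need at least 4 vines with both values")
  s <- spearman_cor(mean_relative[ok], tendril_node[ok])
  list(rho = s$rho, p_value = s$p_value, n_vines = sum(ok))
}

#' Assemble a full heterochrony report
#'
#' Combines the per-leaf relative values, per-vine means, per-species
#' one-sample t-tests, and (when organ codes are available) the Spearman
#' correlation between per-vine mean relative values and the first tendril
#' node.
#'
#' @param predictions Data frame with columns `leaf_id, vine_id, species,
#'   actual, apparent` (e.g. from [cross_stage()]).
#' @param dataset Optional `leaf_dataset` providing organ codes for the
#'   tendril correlation.
#' @return Object of class `heterochrony_report` with elements `per_leaf`,
#'   `per_vine`, `per_species`, `tendril` (or `NULL`).
#' @export
heterochrony_report <- function(predictions, dataset = NULL) {
  need <- c("leaf_id", "vine_id", "species", "actual", "apparent")
  if (!all(need %in% names(predictions)))
    stop("heterochrony_report: predictions must have columns ",
         paste(need, collapse = ", "))
  per_leaf <- data.frame(
    leaf_id = predictions$leaf_id,
    vine_id = predictions$vine_id,
    species = predictions$species,
    actual = as.integer(predictions$actual),
    apparent = as.integer(predictions$apparent),
    relative = relative_values(predictions$actual, predictions$apparent),
    stringsAsFactors = FALSE)
  pv <- vine_means(per_leaf$relative, per_leaf$vine_id)
  pv$species <- predictions$species[match(pv$vine_id, predictions$vine_id)]
  per_species <- species_offsets(pv, pv$species)
  tendril <- NULL
  if (!is.null(dataset) && any(dataset$meta$organ_opposite != "unknown")) {
    ftn <- first_tendril_node(dataset)
    m <- match(pv$vine_id, ftn$vine_id)
    tendril <- tryCatch(
      tendril_correlation(pv$mean_relative, ftn$first_tendril_node[m]),
      error = function(e) NULL)
  }
  structure(list(per_leaf = per_leaf, per_vine = pv,
                 per_species = per_species, tendril = tendril),
            class = "heterochrony_report")
}

#' @export
print.heterochrony_report <- function(x, ...) {
  cat("heterochrony_report: ", nrow(x$per_leaf), " leaves, ",
      nrow(x$per_vine), " vines\n", sep = "")
  print(x$per_species[, c("species", "n_vines", "mean_relative",
                          "t_statistic", "p_value")], row.names = FALSE)
  if (!is.null(x$tendril))
    cat(sprintf("first tendril node vs mean relative value: rho = %.3f, p = %.3g (n = %d vines)\n",
                x$tendril$rho, x$tendril$p_value, x$tendril$n_vines))
  invisible(x)
}
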