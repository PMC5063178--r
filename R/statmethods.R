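## Supporting statistics: Spearman's rho, Kruskal-Wallis, Benjamini-
## Hochberg FDR, pairwise-complete correlation matrices, and correlation-
## distance hierarchical clustering with newick export.

#' Spearman's rank correlation with a two-sided p-value
#'
#' Rho is the Pearson correlation of midranks (ties receive their average
#' rank). The two-sided p-value uses the exact permutation distribution of
#' rho when n <= 8 and the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 df otherwise —
#' sample sizes in these analyses range from a handful of vines to
#' thousands of leaves, so both regimes occur.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return List `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("spearman_cor: length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("spearman_cor: need at least 4 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_cor: constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    # exact two-sided permutation p over all n! orderings of y's ranks
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p_value <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p_value = p_value, n = n)
}

# All permutations of 1..n as rows (n <= 8 keeps this small: 8! = 40320).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(NA_integer_, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(i, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference on g - 1 degrees
#' of freedom (delegates to [stats::kruskal.test()]); used to test
#' variability of morphospace PC values across species.
#'
#' @param values Numeric vector.
#' @param groups Group labels, at least 2 groups.
#' @return List `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("kruskal_wallis: need at least 2 groups")
  if (length(unique(values)) < 2L)
    stop("kruskal_wallis: all values are tied; H is undefined")
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment (via [stats::p.adjust()]): sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1, returned in
#' the input order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NAs passed
#'   through).
#' @return Adjusted vector, same order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pairwise-complete Spearman correlation matrix with FDR control
#'
#' For every pair of trait columns, Spearman's rho on the rows where both
#' are observed; Benjamini-Hochberg adjustment is applied across all
#' upper-triangle p-values. Pairs with fewer than 4 complete observations
#' are reported as NA rather than failing.
#'
#' @param table Data frame or matrix of named numeric trait columns
#'   (morphospace PCs, predicted Sn/Ln, arbitrary trait scores); missing
#'   values permitted.
#' @return List of matrices `rho`, `p`, `q`, `n` (complete pairs used).
#' @export
corr_matrix <- function(table) {
  tb <- as.data.frame(table)
  if (ncol(tb) < 2L) stop("corr_matrix: need at least 2 columns")
  if (anyDuplicated(names(tb))) stop("corr_matrix: duplicate column names")
  m <- ncol(tb)
  nm <- names(tb)
  rho <- p <- q <- matrix(NA_real_, m, m, dimnames = list(nm, nm))
  nmat <- matrix(0L, m, m, dimnames = list(nm, nm))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(m)) nmat[i, i] <- sum(is.finite(tb[[i]]))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      ok <- is.finite(tb[[i]]) & is.finite(tb[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      res <- tryCatch(spearman_cor(tb[[i]][ok], tb[[j]][ok]),
                      error = function(e) NULL)
      if (!is.null(res)) {
        rho[i, j] <- rho[j, i] <- res$rho
        p[i, j] <- p[j, i] <- res$p_value
      }
    }
  }
  up <- upper.tri(p)
  q[up] <- bh_adjust(p[up])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  list(rho = rho, p = p, q = q, n = nmat)
}

#' Correlation-distance hierarchical clustering
#'
#' Agglomerative clustering (via [stats::hclust()]) of trait columns or
#' named numeric vectors on the distance `d(i, j) = 1 - r(i, j)`, with r a
#' pairwise-complete Spearman (default, consistent with [corr_matrix()])
#' or Pearson correlation. Linkage defaults to complete.
#'
#' @param items Data frame/matrix whose columns are clustered, or a
#'   precomputed correlation matrix (symmetric with unit diagonal).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @return An object of class `hclust` (merge history, nondecreasing
#'   heights, labels), ready for [to_newick()].
#' @export
hcluster <- function(items, linkage = c("complete", "average", "single"),
                     cor_method = c("spearman", "pearson")) {
  linkage <- match.arg(linkage)
  cor_method <- match.arg(cor_method)
  if (is.matrix(items) && nrow(items) == ncol(items) &&
      !is.null(rownames(items)) && identical(rownames(items),
                                             colnames(items)) &&
      all(abs(diag(items) - 1) < 1e-12)) {
    r <- items
  } else {
    tb <- as.data.frame(items)
    if (ncol(tb) < 2L) stop("hcluster: need at least 2 items")
    r <- stats::cor(tb, use = "pairwise.complete.obs", method = cor_method)
  }
  if (anyNA(r))
    stop("hcluster: undefined correlation for at least one pair ",
         "(insufficient complete observations)")
  d <- stats::as.dist(1 - r)
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as a newick string
#'
#' Converts the merge history to a phylogeny with [ape::as.phylo()] and
#' serializes it with [ape::write.tree()]. Branch lengths are height
#' differences: a node sits at its merge height, leaves at height 0, so
#' two leaves merged at height h yield `(A:h,B:h);` ([ape::as.phylo()]
#' places nodes at half the merge height; the lengths are rescaled to the
#' height-difference convention). The string is parseable by any standard
#' newick reader.
#'
#' @param d An `hclust` object (e.g. from [hcluster()]).
#' @param path Optional file to write (`.nwk`); when `NULL` the string is
#'   returned only.
#' @return The newick string, invisibly when `path` is given.
#' @export
to_newick <- function(d, path = NULL) {
  if (!inherits(d, "hclust")) stop("to_newick: need an hclust dendrogram")
  phy <- ape::as.phylo(d)
  phy$edge.length <- phy$edge.length * 2
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
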