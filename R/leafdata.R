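#' @keywords internal
"_PACKAGE"

# Number of landmarks in the scheme and their anatomical identities, in order.
N_LANDMARKS <- 17L

#' Names of the 17 leaf landmarks, in scheme order
#'
#' The fixed landmarking scheme used throughout the package: homologous
#' points shared by all Vitis leaves (petiolar junction, vein tips, lobe
#' tips, sinuses, and major vein branch points). Landmark identity is
#' carried purely by position in the coordinate list.
#'
#' @return Character vector of length 17.
#' @export
landmark_names <- function() {
  c("petiolar_junction", "midvein_tip",
    "left_distal_sinus", "right_distal_sinus",
    "left_distal_lobe_tip", "right_distal_lobe_tip",
    "left_proximal_sinus", "right_proximal_sinus",
    "left_proximal_lobe_tip", "right_proximal_lobe_tip",
    "left_terminus_petiolar_vein", "right_terminus_petiolar_vein",
    "branch_point_midvein", "branch_point_left_distal_vein",
    "branch_point_right_distal_vein", "branch_point_left_proximal_vein",
    "branch_point_right_proximal_vein")
}

ORGAN_CODES <- c("C", "T", "N", "unknown")

## ---- flattening helpers -------------------------------------------------
## Flattened vector order is (x1, y1, x2, y2, ..., x17, y17).

flatten_coords <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] == 2L)
  n <- dim(arr)[1]
  k <- dim(arr)[2]
  m <- matrix(arr, nrow = n, ncol = 2L * k)  # x1..xk, y1..yk
  m[, as.vector(rbind(seq_len(k), k + seq_len(k))), drop = FALSE]
}

unflatten_coords <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  k <- ncol(mat) / 2L
  stopifnot(k == floor(k))
  n <- nrow(mat)
  xs <- mat[, 2L * seq_len(k) - 1L, drop = FALSE]
  ys <- mat[, 2L * seq_len(k), drop = FALSE]
  arr <- array(NA_real_, dim = c(n, k, 2L))
  arr[, , 1L] <- xs
  arr[, , 2L] <- ys
  arr
}

## ---- construction and validation ---------------------------------------

#' Assemble a leaf dataset from metadata and landmark coordinates
#'
#' A `leaf_dataset` couples per-leaf shoot metadata with 17-landmark
#' configurations. Developmental stage `stage` (Sn) counts from the shoot
#' tip (S1 = youngest measured leaf); `leaf_number` (Ln) counts from the
#' shoot base (L1 = first initiated leaf). Within one vine the two indices
#' therefore satisfy Sn + Ln = total leaves + 1 on every leaf.
#'
#' @param meta Data frame with columns `leaf_id`, `vine_id`, `species`,
#'   `stage`, `leaf_number`, `organ_opposite`. A missing `organ_opposite`
#'   column is filled with `"unknown"`.
#' @param coords Numeric array `n x 17 x 2` of landmark coordinates, rows
#'   matching `meta`; landmark order follows [landmark_names()].
#' @param provenance Free-text label recording origin (collection, year,
#'   coordinate convention).
#' @param strict Logical; if `TRUE` (default) a violation of the per-vine
#'   stage/leaf-number bookkeeping (unique Sn, unique Ln, Sn + Ln constant)
#'   is an error, otherwise a warning. Field collections can contain
#'   un-flattenable tip leaves that break the bookkeeping; synthetic data
#'   never does.
#' @return Object of class `leaf_dataset` with elements `meta`, `coords`,
#'   `provenance`.
#' @export
leaf_dataset <- function(meta, coords, provenance = "", strict = TRUE) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"organ_opposite" %in% names(meta)) meta$organ_opposite <- "unknown"
  required <- c("leaf_id", "vine_id", "species", "stage", "leaf_number",
                "organ_opposite")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L)
    stop("leaf_dataset: missing metadata columns: ",
         paste(missing_cols, collapse = ", "))
  meta <- meta[, required]
  meta$leaf_id <- as.character(meta$leaf_id)
  meta$vine_id <- as.character(meta$vine_id)
  meta$species <- as.character(meta$species)
  meta$organ_opposite <- as.character(meta$organ_opposite)
  meta$organ_opposite[is.na(meta$organ_opposite)] <- "unknown"
  if (length(dim(coords)) != 3L ||
      dim(coords)[2] != N_LANDMARKS || dim(coords)[3] != 2L)
    stop("leaf_dataset: coords must be an n x 17 x 2 array (17 landmarks)")
  if (dim(coords)[1] != nrow(meta))
    stop("leaf_dataset: coords rows (", dim(coords)[1],
         ") do not match metadata rows (", nrow(meta), ")")
  rownames(meta) <- NULL
  x <- structure(list(meta = meta, coords = coords,
                      provenance = as.character(provenance)[1]),
                 class = "leaf_dataset")
  validate_leaf_dataset(x, strict = strict)
  x
}

#' Validate a leaf dataset against its invariants
#'
#' Checks landmark-count/finiteness/degeneracy of every configuration,
#' positivity and integrality of `stage` and `leaf_number`, organ codes,
#' unique leaf ids, and the per-vine shoot bookkeeping (unique Sn, unique
#' Ln, Sn + Ln constant across the vine).
#'
#' @param x A `leaf_dataset`.
#' @param strict Logical; see [leaf_dataset()].
#' @return Invisibly `TRUE`; stops (or warns, for the per-vine bookkeeping
#'   under `strict = FALSE`) on violation, naming the offending leaf and
#'   rule.
#' @export
validate_leaf_dataset <- function(x, strict = TRUE) {
  meta <- x$meta
  n <- nrow(meta)
  if (n == 0L) return(invisible(TRUE))
  if (anyDuplicated(meta$leaf_id))
    stop("validation: duplicated leaf_id: ",
         meta$leaf_id[duplicated(meta$leaf_id)][1])
  bad_int <- function(v) !is.numeric(v) | is.na(v) | v < 1 | v != round(v)
  for (col in c("stage", "leaf_number")) {
    bad <- bad_int(meta[[col]])
    if (any(bad))
      stop("validation: leaf '", meta$leaf_id[bad][1], "': ", col,
           " must be a positive integer")
  }
  bad_org <- !(meta$organ_opposite %in% ORGAN_CODES)
  if (any(bad_org))
    stop("validation: leaf '", meta$leaf_id[bad_org][1],
         "': organ_opposite must be one of ",
         paste(ORGAN_CODES, collapse = ", "))
  for (i in seq_len(n)) {
    cfg <- x$coords[i, , ]
    if (!all(is.finite(cfg)))
      stop("validation: leaf '", meta$leaf_id[i],
           "': landmark coordinates must be finite (17 landmarks, x and y)")
    if (max(apply(cfg, 2L, function(c) diff(range(c)))) <= 0)
      stop("validation: leaf '", meta$leaf_id[i],
           "': degenerate configuration (all landmarks coincide)")
  }
  # Per-vine shoot bookkeeping.
  report <- if (strict) stop else warning
  for (v in unique(meta$vine_id)) {
    idx <- meta$vine_id == v
    sn <- meta$stage[idx]
    ln <- meta$leaf_number[idx]
    if (anyDuplicated(sn))
      report("validation: vine '", v, "': duplicated stage (Sn) values",
             call. = FALSE)
    if (anyDuplicated(ln))
      report("validation: vine '", v, "': duplicated leaf_number (Ln) values",
             call. = FALSE)
    if (length(unique(sn + ln)) > 1L)
      report("validation: vine '", v,
             "': stage + leaf_number is not constant across the vine ",
             "(Sn + Ln must equal total leaves + 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.leaf_dataset <- function(x, ...) {
  cat("leaf_dataset: ", nrow(x$meta), " leaves, ",
      length(unique(x$meta$vine_id)), " vines, ",
      length(unique(x$meta$species)), " species",
      if (nzchar(x$provenance)) paste0(" [", x$provenance, "]"), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.leaf_dataset <- function(x) nrow(x$meta)

# Row subset keeping metadata and coordinates in step.
ld_subset <- function(x, idx) {
  structure(list(meta = x$meta[idx, , drop = FALSE],
                 coords = x$coords[idx, , , drop = FALSE],
                 provenance = x$provenance),
            class = "leaf_dataset")
}

# Row-bind two datasets (used for joint Procrustes of train + test).
ld_rbind <- function(a, b) {
  structure(list(meta = rbind(a$meta, b$meta),
                 coords = {
                   arr <- array(NA_real_,
                                dim = c(nrow(a$meta) + nrow(b$meta),
                                        N_LANDMARKS, 2L))
                   if (nrow(a$meta) > 0L) arr[seq_len(nrow(a$meta)), , ] <- a$coords
                   if (nrow(b$meta) > 0L)
                     arr[nrow(a$meta) + seq_len(nrow(b$meta)), , ] <- b$coords
                   arr
                 },
                 provenance = paste(a$provenance, b$provenance, sep = " + ")),
            class = "leaf_dataset")
}

## ---- reading and writing ------------------------------------------------

wide_header <- function() {
  c("leaf_id", "vine_id", "species", "stage", "leaf_number",
    "organ_opposite",
    as.vector(rbind(paste0("x", 1:N_LANDMARKS), paste0("y", 1:N_LANDMARKS))))
}

#' Read a landmark table into a leaf dataset
#'
#' Three dialects are supported. `wide_csv` (canonical): one row per leaf,
#' header `leaf_id,vine_id,species,stage,leaf_number,organ_opposite,
#' x1,y1,...,x17,y17`. `long_csv`: one row per landmark with columns
#' `leaf_id,...,landmark,x,y`, landmark in 1..17. `tps`: standard `LM=17`
#' blocks keyed by `ID=`; metadata are supplied through `metadata`, a data
#' frame whose `leaf_id` column matches the TPS IDs (TPS is read-only
#' convenience).
#'
#' Coordinates are accepted in image convention (y may grow downward); no
#' axis flip is applied, because Procrustes alignment with reflection
#' allowed makes the convention immaterial.
#'
#' @param path File to read.
#' @param dialect One of `"wide_csv"`, `"long_csv"`, `"tps"`.
#' @param metadata For `tps`, a data frame of per-leaf metadata keyed by
#'   `leaf_id`; ignored otherwise.
#' @param strict Passed to [leaf_dataset()].
#' @param provenance Provenance label; defaults to the file name.
#' @return A validated `leaf_dataset`. Rows with a landmark count other
#'   than 17 raise a parse/validation error naming the record.
#' @export
read_landmark_table <- function(path,
                                dialect = c("wide_csv", "long_csv", "tps"),
                                metadata = NULL, strict = TRUE,
                                provenance = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_landmark_table: no such file: ", path)
  switch(dialect,
         wide_csv = read_wide_csv(path, strict, provenance),
         long_csv = read_long_csv(path, strict, provenance),
         tps = read_tps(path, metadata, strict, provenance))
}

read_wide_csv <- function(path, strict, provenance) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  hdr <- wide_header()
  if (!all(hdr %in% names(df)))
    stop("parse error in ", path, ": wide CSV must contain columns ",
         paste(setdiff(hdr, names(df)), collapse = ", "),
         " (17 landmarks: x1,y1,...,x17,y17)")
  coord_cols <- hdr[-(1:6)]
  cm <- as.matrix(df[, coord_cols, drop = FALSE])
  suppressWarnings(storage.mode(cm) <- "double")
  bad <- which(!stats::complete.cases(cm))
  if (length(bad) > 0L)
    stop("parse error in ", path, ", record ", bad[1], " (leaf '",
         df$leaf_id[bad[1]], "'): non-numeric or missing coordinate; ",
         "each row needs 17 landmarks")
  meta <- df[, hdr[1:6], drop = FALSE]
  meta$stage <- as.numeric(meta$stage)
  meta$leaf_number <- as.numeric(meta$leaf_number)
  leaf_dataset(meta, unflatten_coords(cm), provenance, strict)
}

read_long_csv <- function(path, strict, provenance) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("leaf_id", "vine_id", "species", "stage", "leaf_number",
            "organ_opposite", "landmark", "x", "y")
  if (!all(need %in% names(df)))
    stop("parse error in ", path, ": long CSV must contain columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  ids <- unique(df$leaf_id)
  n <- length(ids)
  coords <- array(NA_real_, dim = c(n, N_LANDMARKS, 2L))
  meta <- NULL
  for (i in seq_along(ids)) {
    rows <- df[df$leaf_id == ids[i], ]
    if (nrow(rows) != N_LANDMARKS ||
        !setequal(rows$landmark, seq_len(N_LANDMARKS)))
      stop("validation error for leaf '", ids[i],
           "': expected 17 landmarks numbered 1..17, found ",
           nrow(rows))
    rows <- rows[order(rows$landmark), ]
    coords[i, , 1L] <- rows$x
    coords[i, , 2L] <- rows$y
    meta <- rbind(meta, rows[1, c("leaf_id", "vine_id", "species", "stage",
                                  "leaf_number", "organ_opposite")])
  }
  leaf_dataset(meta, coords, provenance, strict)
}

read_tps <- function(path, metadata, strict, provenance) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i], ignore.case = TRUE))
      stop("parse error in ", path, " line ", i, ": expected 'LM=' header")
    nl <- as.integer(sub("^LM=", "", lines[i], ignore.case = TRUE))
    if (is.na(nl) || nl != N_LANDMARKS)
      stop("validation error in ", path, " line ", i,
           ": TPS block must declare 17 landmarks (LM=17), found LM=", nl)
    pts <- matrix(NA_real_, nl, 2L)
    for (j in seq_len(nl)) {
      xy <- suppressWarnings(as.numeric(strsplit(lines[i + j], "[ \t]+")[[1]]))
      if (length(xy) != 2L || anyNA(xy))
        stop("parse error in ", path, " line ", i + j,
             ": expected 'x y' coordinate pair")
      pts[j, ] <- xy
    }
    i <- i + nl + 1L
    id <- NA_character_
    while (i <= length(lines) && grepl("^[A-Z]+=", lines[i]) &&
           !grepl("^LM=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID=", lines[i], ignore.case = TRUE))
        id <- sub("^ID=", "", lines[i], ignore.case = TRUE)
      i <- i + 1L
    }
    if (is.na(id))
      stop("parse error in ", path, ": TPS block without ID= key")
    blocks[[length(blocks) + 1L]] <- list(id = id, pts = pts)
  }
  n <- length(blocks)
  coords <- array(NA_real_, dim = c(n, N_LANDMARKS, 2L))
  for (b in seq_len(n)) coords[b, , ] <- blocks[[b]]$pts
  ids <- vapply(blocks, `[[`, "", "id")
  if (is.null(metadata)) {
    meta <- data.frame(leaf_id = ids, vine_id = ids, species = "unknown",
                       stage = NA_real_, leaf_number = NA_real_,
                       organ_opposite = "unknown",
                       stringsAsFactors = FALSE)
    stop("read_landmark_table(tps): a metadata sidecar data frame keyed ",
         "by leaf_id is required (TPS files carry no shoot metadata)")
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"leaf_id" %in% names(metadata))
    stop("read_landmark_table(tps): metadata must have a leaf_id column")
  m <- match(ids, metadata$leaf_id)
  if (anyNA(m))
    stop("validation error: TPS ID '", ids[is.na(m)][1],
         "' has no row in the metadata sidecar")
  leaf_dataset(metadata[m, , drop = FALSE], coords, provenance, strict)
}

#' Write a leaf dataset to a landmark table
#'
#' Writes the canonical wide CSV or the long CSV dialect; coordinates are
#' preserved to at least 15 significant digits so that
#' [read_landmark_table()] recovers an equal dataset.
#'
#' @param dataset A `leaf_dataset`.
#' @param path Output file.
#' @param dialect `"wide_csv"` (default) or `"long_csv"`.
#' @return Invisibly, `path`.
#' @export
write_landmark_table <- function(dataset, path,
                                 dialect = c("wide_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  meta <- dataset$meta
  n <- nrow(meta)
  if (dialect == "wide_csv") {
    cm <- flatten_coords(dataset$coords)
    colnames(cm) <- wide_header()[-(1:6)]
    df <- if (n > 0L) cbind(meta, as.data.frame(cm)) else
      stats::setNames(as.data.frame(matrix(nrow = 0L, ncol = 40L)),
                      wide_header())
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rows[[i]] <- data.frame(meta[i, , drop = FALSE],
                              landmark = seq_len(N_LANDMARKS),
                              x = dataset$coords[i, , 1L],
                              y = dataset$coords[i, , 2L],
                              row.names = NULL)
    }
    df <- if (n > 0L) do.call(rbind, rows) else
      stats::setNames(as.data.frame(matrix(nrow = 0L, ncol = 9L)),
                      c("leaf_id", "vine_id", "species", "stage",
                        "leaf_number", "organ_opposite", "landmark", "x", "y"))
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

## ---- subsetting rules ---------------------------------------------------

#' Subset a dataset by shoot position
#'
#' The three selection rules used throughout the analyses:
#' `stage_window` keeps leaves with `lo <= Sn <= hi` (e.g. S1-S10, where
#' sampling is dense); `leafnum_window` the analogue on Ln; `midshoot`
#' keeps, per vine, the `n_mid` leaves whose Ln is closest to the shoot
#' midpoint `(total leaves + 1)/2`, ties broken toward the shoot base
#' (lower Ln) so the selection is deterministic.
#'
#' @param dataset A `leaf_dataset`.
#' @param mode `"stage_window"`, `"leafnum_window"` or `"midshoot"`.
#' @param lo,hi Window bounds (window modes).
#' @param n_mid Number of mid-shoot leaves per vine (midshoot mode).
#' @return A `leaf_dataset` with the selected rows (possibly empty). The
#'   operation is idempotent and always returns a subset of its input.
#' @export
select_positions <- function(dataset,
                             mode = c("stage_window", "leafnum_window",
                                      "midshoot"),
                             lo = 1L, hi = 10L, n_mid = 4L) {
  mode <- match.arg(mode)
  meta <- dataset$meta
  if (mode %in% c("stage_window", "leafnum_window")) {
    if (lo > hi) stop("select_positions: lo must be <= hi")
    v <- if (mode == "stage_window") meta$stage else meta$leaf_number
    return(ld_subset(dataset, which(v >= lo & v <= hi)))
  }
  if (n_mid < 1L) stop("select_positions: n_mid must be >= 1")
  keep <- integer(0)
  for (v in unique(meta$vine_id)) {
    idx <- which(meta$vine_id == v)
    total <- max(meta$stage[idx] + meta$leaf_number[idx]) - 1
    mid <- (total + 1) / 2
    ln <- meta$leaf_number[idx]
    # ties toward the base: among equal |Ln - mid|, prefer the lower Ln
    ord <- order(abs(ln - mid), ln)
    keep <- c(keep, idx[ord[seq_len(min(n_mid, length(idx)))]])
  }
  ld_subset(dataset, sort(keep))
}

#' Summarize a leaf dataset
#'
#' Per-species vine and leaf counts, per-stage (Sn) and per-leaf-number
#' (Ln) counts, and organ-code counts.
#'
#' @param object A `leaf_dataset`.
#' @param ... Unused.
#' @return A list of class `leaf_dataset_summary` with elements
#'   `species` (data frame: species, n_vines, n_leaves), `stage`,
#'   `leaf_number`, `organ` (named count tables), and `n_leaves`.
#' @export
summary.leaf_dataset <- function(object, ...) {
  meta <- object$meta
  if (nrow(meta) == 0L) {
    out <- list(species = data.frame(species = character(0),
                                     n_vines = integer(0),
                                     n_leaves = integer(0)),
                stage = table(integer(0)), leaf_number = table(integer(0)),
                organ = table(character(0)), n_leaves = 0L)
    class(out) <- "leaf_dataset_summary"
    return(out)
  }
  sp <- sort(unique(meta$species))
  species <- data.frame(
    species = sp,
    n_vines = vapply(sp, function(s)
      length(unique(meta$vine_id[meta$species == s])), 0L),
    n_leaves = vapply(sp, function(s) sum(meta$species == s), 0L),
    row.names = NULL)
  out <- list(species = species,
              stage = table(meta$stage),
              leaf_number = table(meta$leaf_number),
              organ = table(meta$organ_opposite),
              n_leaves = nrow(meta))
  class(out) <- "leaf_dataset_summary"
  out
}

#' @export
print.leaf_dataset_summary <- function(x, ...) {
  cat("Leaves:", x$n_leaves, "\n")
  if (x$n_leaves > 0L) {
    cat("Per species:\n")
    print(x$species, row.names = FALSE)
    cat("Organ codes opposite the node:\n")
    print(x$organ)
  }
  invisible(x)
}
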