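#' Seed-voxel x target connectivity matrix
#'
#' Rows are seed voxels in scan order (x fastest, then y, then z — the
#' package's fixed linear-index order), columns are target voxels or named
#' regions, entries are non-negative streamline counts (or count-derived
#' connection values).
#'
#' @param counts numeric matrix, one row per seed voxel; no negative entries.
#'   Row names are kept as voxel ids, column names as target ids.
#' @param seed_voxel_ids integer vector of linear indices into the seed mask,
#'   strictly increasing (scan order).  Defaults to `1:nrow(counts)`.
#' @param subject_id optional subject tag.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(counts, seed_voxel_ids = NULL,
                                subject_id = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("streamline counts must be non-negative")
  if (is.null(seed_voxel_ids)) seed_voxel_ids <- seq_len(nrow(counts))
  seed_voxel_ids <- as.integer(seed_voxel_ids)
  if (length(seed_voxel_ids) != nrow(counts))
    stop("one seed voxel id per row is required")
  if (is.unsorted(seed_voxel_ids, strictly = TRUE))
    stop("seed voxel ids must be strictly increasing (scan order)")
  structure(list(counts = counts, seed_voxel_ids = seed_voxel_ids,
                 target_ids = colnames(counts), subject_id = subject_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", nrow(x$counts), " seed voxels x ",
      ncol(x$counts), " targets",
      if (!is.null(x$subject_id)) paste0(" (", x$subject_id, ")"), "\n",
      sep = "")
  invisible(x)
}

#' Assemble a connectivity matrix from a count table and a seed mask
#'
#' The table's row ids must name exactly the nonzero voxels of `seed_mask`,
#' as `v<linear index>` (or bare linear indices).  Rows are reordered to scan
#' order; counts are unchanged.
#'
#' @param count_table named numeric matrix as returned by
#'   [read_matrix_table()].
#' @param seed_mask [label_volume()]; its nonzero voxels define the seed.
#' @param subject_id optional subject tag.
#' @return A [connectivity_matrix()].
#' @export
build_connectivity_matrix <- function(count_table, seed_mask,
                                      subject_id = NULL) {
  stopifnot(is.matrix(count_table), inherits(seed_mask, "label_volume"))
  idx <- mask_indices(seed_mask)
  ids <- rownames(count_table)
  num <- suppressWarnings(as.integer(sub("^v0*", "", ids)))
  if (anyNA(num)) stop("row ids must be voxel linear indices ('v123' or '123')")
  missing <- setdiff(idx, num)
  if (length(missing) > 0L)
    stop("seed-mask voxels absent from the count table: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  extra <- setdiff(num, idx)
  if (length(extra) > 0L)
    stop("count-table rows outside the seed mask: ",
         paste(utils::head(extra, 10L), collapse = ", "),
         if (length(extra) > 10L) ", ...")
  ord <- order(num)
  connectivity_matrix(count_table[ord, , drop = FALSE],
                      seed_voxel_ids = num[ord], subject_id = subject_id)
}

#' Voxel-by-voxel similarity of connectivity profiles
#'
#' Computes the square matrix whose (i, j) entry is the Pearson correlation
#' between the connectivity profiles (count rows) of seed voxels i and j —
#' the cross-correlation matrix that is subsequently clustered.  Voxels with
#' a constant profile (zero variance, e.g. no streamlines) are retained with
#' similarity 0 to every other voxel and 1 on the diagonal, with a warning,
#' so that label volumes keep their geometry.
#'
#' @param conn a [connectivity_matrix()] with >= 2 seed voxels and >= 2
#'   targets.
#' @return Symmetric numeric matrix with unit diagonal, entries in \[-1, 1\].
#' @export
build_similarity <- function(conn) {
  stopifnot(inherits(conn, "connectivity_matrix"))
  x <- conn$counts
  if (nrow(x) < 2L) stop("at least 2 seed voxels are required")
  if (ncol(x) < 2L) stop("at least 2 targets are required")
  sds <- apply(x, 1L, stats::sd)
  flat <- sds == 0
  sim <- matrix(0, nrow(x), nrow(x))
  if (any(flat))
    warning(sum(flat), " seed voxel(s) have constant connectivity profiles; ",
            "their similarity to all other voxels is set to 0")
  ok <- !flat
  if (sum(ok) >= 2L)
    sim[ok, ok] <- stats::cor(t(x[ok, , drop = FALSE]))
  diag(sim) <- 1
  sim <- (sim + t(sim)) / 2          # exact symmetry against FP noise
  dimnames(sim) <- list(rownames(x), rownames(x))
  sim
}
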