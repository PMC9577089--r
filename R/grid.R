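#' Voxel grid with world-space affine
#'
#' A `volume_grid` holds the shape (voxels), voxel size (mm) and a 4x4 affine
#' mapping 0-based voxel indices to world coordinates in mm.  All cross-volume
#' operations in the package require the two volumes to share a grid (same
#' shape, affine equal within 1e-4 mm); registration is assumed upstream.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#'   Defaults to a diagonal scaling by `voxel_size` with origin at 0.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive reals (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Test whether two grids are compatible
#'
#' Grids are compatible when shapes are identical and affines agree within
#' `tol` mm elementwise.
#'
#' @param a,b `volume_grid` objects.
#' @param tol numeric tolerance on affine entries (mm).
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "volume_grid"), inherits(b, "volume_grid"))
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) <= tol)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " are defined on different grids ",
         "(no implicit resampling is performed)")
  invisible(TRUE)
}

#' Integer label volume
#'
#' Labels are integers per voxel with 0 meaning background and 1..K meaning
#' clusters or regions.  Voxel storage is an R array in scan order: the first
#' (x) index varies fastest, then y, then z, matching linear indexing by
#' `which()`.
#'
#' @param labels integer array with `dim` equal to `grid$shape` (a vector is
#'   reshaped).  All values must be >= 0.
#' @param grid a [volume_grid()].
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(dim(labels))) {
    if (length(labels) != prod(grid$shape))
      stop("label vector length does not match grid shape")
    dim(labels) <- grid$shape
  }
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label array dimensions do not match grid shape")
  if (anyNA(labels)) stop("labels contain NA")
  lab <- as.vector(labels)
  if (is.double(lab)) {
    r <- round(lab)
    if (any(abs(lab - r) > 1e-6)) stop("non-integer label data")
    lab <- r
  }
  if (any(lab < 0)) stop("labels must be >= 0")
  arr <- array(as.integer(lab), dim = grid$shape)
  structure(list(grid = grid, labels = arr), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(x$labels)
  cat("<label_volume> ", paste(x$grid$shape, collapse = " x "),
      ", labels: ", paste(names(tab), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Linear voxel indices carrying a nonzero label, in scan order
#' @param vol a `label_volume`.
#' @return Integer vector of 1-based linear indices.
#' @export
mask_indices <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  which(as.vector(vol$labels) > 0L)
}

#' Ordered set of named target regions
#'
#' Holds the fixed, ordered list of target-region names used as the shared
#' coordinate system for connectivity fingerprints (for example the 19
#' homologous target ROIs), optionally with a label volume whose labels
#' 1..n index the names.
#'
#' @param names character vector of unique region names; order is preserved
#'   through every fingerprint operation.
#' @param labels optional [label_volume()] with labels in 0..length(names).
#' @return An object of class `region_set`.
#' @export
region_set <- function(names, labels = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("region names must be unique")
  if (length(names) == 0L) stop("at least one region name is required")
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_volume"))
    if (max(labels$labels) > length(names))
      stop("label volume contains labels beyond the region list")
  }
  structure(list(names = names, labels = labels), class = "region_set")
}

#' The 19 homologous target regions used for cross-species fingerprints
#'
#' Returns the fixed, ordered list of the 19 homologous target ROI names
#' (motor, auditory, language, memory and higher-cognitive regions) used as
#' the default common coordinate system for connectivity fingerprints.
#'
#' @return Character vector of length 19.
#' @export
default_target_rois <- function() {
  c("9/46d", "44v", "SMA", "8m", "M1", "S1", "ParOp", "aIPS", "pIPS",
    "pIPL", "23ab", "rsplC", "perirhinal", "ventrStr", "hippoc",
    "35/36r", "9m", "8dL", "granular insula")
}

# 26-neighbourhood offsets: the 3x3x3 cube minus the centre.
neighbourhood26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[rowSums(off == 0L) != 3L, , drop = FALSE]
}
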