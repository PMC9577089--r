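#' Read an integer label volume from NIfTI
#'
#' Reads a 3-D NIfTI image as a [label_volume()].  Voxel values must be
#' integers; values within 1e-6 of an integer are rounded, anything further
#' away is an error.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  # trailing singleton dims (e.g. 3-D stored as 4-D with nt = 1) are squeezed
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
    dim(arr) <- d[1:3]
    d <- dim(arr)
  }
  if (length(d) != 3L) stop("expected a 3-D image, got ", length(d), "-D")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  vox <- RNifti::pixdim(img)[1:3]
  grid <- volume_grid(d, vox, aff)
  label_volume(arr, grid)
}

#' Write a label volume to NIfTI
#'
#' @param vol a [label_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$labels)
  RNifti::pixdim(img) <- vol$grid$voxel_size
  aff <- vol$grid$affine
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a named numeric matrix from a TSV/CSV table
#'
#' The first row holds column names, the first column holds row ids.  Row and
#' column order is preserved exactly as in the file.
#'
#' @param path path to a tab- (default) or comma-separated table.
#' @param sep field separator, `"\t"` or `","`.
#' @return Numeric matrix with `rownames`/`colnames`.
#' @export
read_matrix_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "")
  if (ncol(df) < 2L) stop("table must have a row-id column and >= 1 value column")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("duplicate row ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1L])) stop("duplicate column ids")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num) && !anyNA(vals)) {
    bad <- which(is.na(num) & !is.na(vals))[1L]
    stop("non-numeric cell in table: '", vals[bad], "'")
  }
  if (anyNA(num)) stop("missing values in table")
  dimnames(num) <- list(ids, colnames(df)[-1L])
  num
}

#' Write a named numeric matrix as TSV
#'
#' Tab-delimited, UTF-8, `.` decimal; full double precision so that a
#' write/read round trip is lossless to better than 1e-12.
#'
#' @param mat numeric matrix with `rownames` and `colnames`.
#' @param path output path.
#' @param id_name header of the row-id column.
#' @return Invisibly, `path`.
#' @export
write_matrix_table <- function(mat, path, id_name = "id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_name, colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r)
    paste(format(r, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}
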