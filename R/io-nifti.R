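#' Read an integer label volume from NIfTI
#'
#' Reads a 3-D NIfTI file whose voxel values are integer label IDs. If a
#' sidecar label table \code{<path sans .nii/.nii.gz>_labels.tsv} exists
#' (two tab-separated columns: id, name), it is attached.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return A [LabelVolume-class]; values and affine preserved exactly.
#' @details Values must be integer-representable: a file containing e.g.
#'   3.5 is rejected. 4-D inputs are rejected; use [readDirectionField()]
#'   for direction fields.
#' @seealso [writeLabelVolume()]
#' @export
readLabelVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("dimensionality error: expected a 3-D volume, got ",
         length(d), "-D", call. = FALSE)
  arr <- as.array(img)
  if (any(arr != round(arr)) || any(arr < 0))
    stop("format error: label volume must contain non-negative integers",
         call. = FALSE)
  lt <- NULL
  side <- .labelTablePath(path)
  if (file.exists(side)) lt <- readLabelTable(side)
  labelVolume(array(as.integer(round(arr)), dim = d),
              affine = .xformMatrix(img), labelTable = lt)
}

#' Write a label volume to NIfTI
#'
#' Written files round-trip exactly through [readLabelVolume()]; the
#' affine is stored as the sform (code 2). A non-NULL label table is
#' persisted to a \code{_labels.tsv} sidecar next to the image.
#'
#' @param vol a [LabelVolume-class].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  .writeNiftiArray(vol@data, vol@affine, path, datatype = "int32")
  if (!is.null(vol@labelTable))
    writeLabelTable(vol@labelTable, .labelTablePath(path))
  invisible(path)
}

#' Read or write a binary mask volume
#'
#' @param path NIfTI path.
#' @return \code{readMaskVolume}: a [MaskVolume-class].
#' @export
readMaskVolume <- function(path) {
  v <- readLabelVolume(path)
  if (any(!v@data %in% c(0L, 1L)))
    stop("format error: mask must be binary", call. = FALSE)
  maskVolume(v@data, v@affine)
}

#' @rdname readMaskVolume
#' @param mask a [MaskVolume-class].
#' @export
writeMaskVolume <- function(mask, path) {
  stopifnot(is(mask, "MaskVolume"))
  .writeNiftiArray(mask@data, mask@affine, path, datatype = "uint8")
  invisible(path)
}

#' Read / write a principal-direction field
#'
#' The field is stored as a 4-D NIfTI with 3 volumes (vector components);
#' the tracking mask travels as a separate binary NIfTI.
#'
#' @param path 4-D NIfTI with last dimension 3.
#' @param maskPath path to the tracking-mask NIfTI.
#' @return \code{readDirectionField}: a [DirectionField-class].
#' @export
readDirectionField <- function(path, maskPath) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("dimensionality error: expected an (nx, ny, nz, 3) volume",
         call. = FALSE)
  mask <- readMaskVolume(maskPath)
  directionField(array(as.numeric(img), dim = d), mask, .xformMatrix(img))
}

#' @rdname readDirectionField
#' @param field a [DirectionField-class].
#' @export
writeDirectionField <- function(field, path, maskPath) {
  stopifnot(is(field, "DirectionField"))
  .writeNiftiArray(field@directions, field@affine, path, datatype = "double")
  writeMaskVolume(field@mask, maskPath)
  invisible(path)
}

#' Read / write a two-column label table
#'
#' Tab-separated, two columns (integer id, region name), no header.
#'
#' @param path TSV path.
#' @return \code{readLabelTable}: \code{data.frame} with columns
#'   \code{id}, \code{name}.
#' @export
readLabelTable <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "name"),
                          colClasses = c("integer", "character"),
                          quote = "", comment.char = "")
  tb
}

#' @rdname readLabelTable
#' @param table \code{data.frame} with columns \code{id} and \code{name}.
#' @export
writeLabelTable <- function(table, path) {
  utils::write.table(table[, c("id", "name")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

.labelTablePath <- function(path)
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.tsv")

.xformMatrix <- function(img) {
  m <- RNifti::xform(img)
  attributes(m) <- list(dim = dim(m))
  m
}

.writeNiftiArray <- function(arr, affine, path, datatype) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
}
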