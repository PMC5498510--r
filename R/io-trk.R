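# TrackVis .trk format, version 2: 1000-byte little-endian header followed
# by one record per streamline (int32 n_points, then n_points float32
# triples, plus optional scalars/properties which we do not produce).
#
# TrackVis stores points in "voxmm" coordinates with the voxel *corner* at
# the origin: mm = (index + 0.5) * voxel_size for our center-at-integer
# 0-based indices. The half-voxel shift is applied symmetrically at read
# and write time, so internal coordinates always have voxel centers at
# integer positions.

.TRK_HDR_SIZE <- 1000L

#' Read a TrackVis tractogram
#'
#' Streamline points are converted from the file's voxel-mm convention to
#' the internal 0-based voxel-index convention of \code{reference}.
#'
#' @param path a \code{.trk} file.
#' @param reference a [LabelVolume-class] or [MaskVolume-class] defining
#'   the grid the tractogram belongs to; its shape and voxel size must
#'   match the file header (voxel size within 1 percent).
#' @return A [Tractogram-class].
#' @seealso [writeTractogram()]
#' @export
readTractogram <- function(path, reference) {
  vs <- voxelSize(reference)
  shape <- as.integer(volumeShape(reference))
  con <- file(path, "rb")
  on.exit(close(con))

  id <- readBin(con, "raw", 6L)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("format error: not a TrackVis .trk file", call. = FALSE)
  dim_ <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  invisible(readBin(con, "numeric", 3L, size = 4L, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))                       # scalar names
  n_properties <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", 200L))                       # property names
  invisible(readBin(con, "numeric", 16L, size = 4L, endian = "little"))
  invisible(readBin(con, "raw", 444L))                       # reserved
  invisible(readBin(con, "raw", 4L))                         # voxel_order
  invisible(readBin(con, "raw", 4L))                         # pad2
  invisible(readBin(con, "numeric", 6L, size = 4L, endian = "little"))
  invisible(readBin(con, "raw", 2L))                         # pad1
  invisible(readBin(con, "raw", 6L))                         # invert/swap
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != .TRK_HDR_SIZE)
    stop("format error: unexpected .trk header size ", hdr_size,
         call. = FALSE)

  if (any(dim_ != shape))
    stop("space error: .trk grid ", paste(dim_, collapse = "x"),
         " does not match reference ", paste(shape, collapse = "x"),
         call. = FALSE)
  if (any(abs(voxel_size - vs) > 0.01 * vs))
    stop("space error: .trk voxel size (",
         paste(signif(voxel_size, 6), collapse = ", "),
         ") differs from reference by more than 1%", call. = FALSE)

  streamlines <- list()
  repeat {
    np <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(np) == 0L) break
    vals <- readBin(con, "numeric", np * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (n_properties > 0L)
      invisible(readBin(con, "numeric", n_properties, size = 4L,
                        endian = "little"))
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                             drop = FALSE]
    # voxmm (corner origin) -> 0-based voxel indices, centers at integers
    pts <- sweep(pts, 2, voxel_size, "/") - 0.5
    streamlines[[length(streamlines) + 1L]] <- pts
  }
  if (n_count > 0L && length(streamlines) != n_count)
    warning("streamline count in header (", n_count,
            ") differs from records read (", length(streamlines), ")")
  tractogram(streamlines, shape, volumeAffine(reference))
}

#' Write a TrackVis tractogram
#'
#' @param t a [Tractogram-class] (points validated finite before any byte
#'   is written).
#' @param path output \code{.trk} path.
#' @return \code{path}, invisibly.
#' @export
writeTractogram <- function(t, path) {
  stopifnot(is(t, "Tractogram"))
  validObject(t)
  vs <- voxelSize(t)
  con <- file(path, "wb")
  on.exit(close(con))

  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(t@shape), con, size = 2L, endian = "little")
  writeBin(as.numeric(vs), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")   # origin
  writeBin(0L, con, size = 2L, endian = "little")           # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")           # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t@affine), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)
  writeBin(c(charToRaw("RAS"), as.raw(0L)), con)            # voxel_order
  writeBin(raw(4L), con)                                    # pad2
  writeBin(numeric(6), con, size = 4L, endian = "little")
  writeBin(raw(2L), con)                                    # pad1
  writeBin(raw(6L), con)                                    # invert/swap
  writeBin(length(t@streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")           # version
  writeBin(.TRK_HDR_SIZE, con, size = 4L, endian = "little")

  for (s in t@streamlines) {
    writeBin(nrow(s), con, size = 4L, endian = "little")
    mm <- sweep(s + 0.5, 2, vs, "*")
    writeBin(as.numeric(base::t(mm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
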