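# User-facing constructors and accessors. Slots are never touched directly
# by downstream code; these are the supported surface.

#' Construct a label volume
#'
#' @param data 3-D array of non-negative integer label IDs.
#' @param affine 4x4 voxel-to-world matrix; defaults to identity (1 mm
#'   isotropic voxels, origin at voxel (0,0,0)).
#' @param labelTable optional \code{data.frame} with columns \code{id},
#'   \code{name}.
#' @return A [LabelVolume-class].
#' @examples
#' v <- labelVolume(array(0L, c(4, 4, 4)))
#' dim(volumeData(v))
#' @export
labelVolume <- function(data, affine = diag(4), labelTable = NULL) {
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, affine = affine, labelTable = labelTable)
}

#' Construct a binary mask volume
#'
#' @param data 3-D array coercible to 0/1 integers.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A [MaskVolume-class].
#' @export
maskVolume <- function(data, affine = diag(4)) {
  storage.mode(data) <- "integer"
  new("MaskVolume", data = data, affine = affine)
}

#' Construct a principal-direction field
#'
#' @param directions \code{(nx, ny, nz, 3)} array of unit (or zero)
#'   vectors.
#' @param mask a [MaskVolume-class] tracking mask.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A [DirectionField-class].
#' @export
directionField <- function(directions, mask, affine = diag(4)) {
  new("DirectionField", directions = directions, mask = mask,
      affine = affine)
}

#' Construct a tractogram
#'
#' @param streamlines list of n-by-3 matrices of 0-based voxel-index
#'   coordinates (voxel centers at integers).
#' @param shape reference grid dimensions.
#' @param affine reference voxel-to-world matrix.
#' @return A [Tractogram-class].
#' @export
tractogram <- function(streamlines, shape, affine = diag(4)) {
  new("Tractogram", streamlines = streamlines, shape = as.integer(shape),
      affine = affine)
}

#' Construct voting parameters
#'
#' @param wLocal,wNeighbor weights of the local and neighbor probability
#'   terms; must sum to 1. Default 0.5/0.5 (the symmetric point of the
#'   admissible range).
#' @param neighborhood offset matrix; defaults to the full 26-connected
#'   neighborhood.
#' @param normalizeNeighbors divide the neighbor term by the summed
#'   inverse-distance weight of contributing neighbors (default
#'   \code{FALSE}: the literal, unnormalized formulation).
#' @return A [VotingParams-class].
#' @examples
#' votingParams(0.7, 0.3)
#' @export
votingParams <- function(wLocal = 0.5, wNeighbor = 1 - wLocal,
                         neighborhood = neighborhood26(),
                         normalizeNeighbors = FALSE) {
  new("VotingParams", wLocal = wLocal, wNeighbor = wNeighbor,
      neighborhood = neighborhood, normalizeNeighbors = normalizeNeighbors)
}

#' The 26-connected neighborhood offsets
#'
#' @return A 26-by-3 integer matrix of all offsets in \{-1,0,1\}^3 except
#'   \code{(0,0,0)}.
#' @export
neighborhood26 <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

#' Construct FACT tracking parameters
#'
#' @param angleThreshold stopping angle in degrees (default 35).
#' @param maxSteps maximum voxel transitions per half-track.
#' @param minPoints minimum points for a track to be kept.
#' @return A [TrackingParams-class].
#' @export
trackingParams <- function(angleThreshold = 35, maxSteps = 2000L,
                           minPoints = 2L) {
  new("TrackingParams", angleThreshold = angleThreshold,
      maxSteps = as.integer(maxSteps), minPoints = as.integer(minPoints))
}

## ---- accessors ------------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname accessors
#' @export
setGeneric("volumeAffine", function(x) standardGeneric("volumeAffine"))

#' @rdname accessors
#' @export
setGeneric("volumeShape", function(x) standardGeneric("volumeShape"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Accessors for volume-like objects
#'
#' \code{volumeData} returns the raw array, \code{volumeAffine} the 4x4
#' voxel-to-world matrix, \code{volumeShape} the grid dimensions, and
#' \code{voxelSize} the per-axis voxel edge lengths in mm (column norms of
#' the affine's rotation block).
#'
#' @param x a \code{LabelVolume}, \code{MaskVolume}, \code{DirectionField}
#'   or \code{Tractogram}.
#' @name accessors
#' @aliases volumeData volumeAffine volumeShape voxelSize
NULL

setMethod("volumeData", "LabelVolume", function(x) x@data)
setMethod("volumeData", "MaskVolume", function(x) x@data)
setMethod("volumeAffine", "LabelVolume", function(x) x@affine)
setMethod("volumeAffine", "MaskVolume", function(x) x@affine)
setMethod("volumeAffine", "DirectionField", function(x) x@affine)
setMethod("volumeAffine", "Tractogram", function(x) x@affine)
setMethod("volumeShape", "LabelVolume", function(x) dim(x@data))
setMethod("volumeShape", "MaskVolume", function(x) dim(x@data))
setMethod("volumeShape", "DirectionField",
          function(x) dim(x@directions)[1:3])
setMethod("volumeShape", "Tractogram", function(x) x@shape)

.voxelSizeFromAffine <- function(affine)
  sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))

setMethod("voxelSize", "LabelVolume",
          function(x) .voxelSizeFromAffine(x@affine))
setMethod("voxelSize", "MaskVolume",
          function(x) .voxelSizeFromAffine(x@affine))
setMethod("voxelSize", "DirectionField",
          function(x) .voxelSizeFromAffine(x@affine))
setMethod("voxelSize", "Tractogram",
          function(x) .voxelSizeFromAffine(x@affine))

#' @rdname labelTable
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' Label table of a label volume
#'
#' @param x a [LabelVolume-class].
#' @return The \code{data.frame} of (id, name) pairs, or \code{NULL}.
#' @name labelTable
#' @export
setMethod("labelTable", "LabelVolume", function(x) x@labelTable)

#' @rdname streamlines
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' Streamlines and labels of a tractogram
#'
#' @param x a [Tractogram-class] or [LabeledTractogram-class].
#' @return \code{streamlines}: list of n-by-3 point matrices.
#'   \code{streamlineLabels}: integer label per streamline.
#'   \code{nDropped}: count of unlabeled streamlines discarded by
#'   [labelStreamlines()].
#' @name streamlines
#' @export
setMethod("streamlines", "Tractogram", function(x) x@streamlines)

#' @rdname streamlines
#' @export
setGeneric("streamlineLabels", function(x) standardGeneric("streamlineLabels"))
setMethod("streamlineLabels", "LabeledTractogram", function(x) x@labels)

#' @rdname streamlines
#' @export
setGeneric("nDropped", function(x) standardGeneric("nDropped"))
setMethod("nDropped", "LabeledTractogram", function(x) x@nDropped)

#' @rdname candidate-accessors
#' @export
setGeneric("candidateLabels", function(x) standardGeneric("candidateLabels"))

#' @rdname candidate-accessors
#' @export
setGeneric("candidateCounts", function(x, voxel) standardGeneric("candidateCounts"))

#' Accessors for candidate images
#'
#' \code{candidateLabels} returns the global ordered label list;
#' \code{candidateCounts} the label-count vector of one voxel (0-based
#' \code{c(i, j, k)} index), named by label ID.
#'
#' @param x a [CandidateImage-class].
#' @param voxel integer vector of length 3, 0-based voxel index.
#' @name candidate-accessors
NULL

setMethod("candidateLabels", "CandidateImage", function(x) x@labels)
setMethod("candidateCounts", "CandidateImage", function(x, voxel) {
  stopifnot(length(voxel) == 3L)
  row <- .linearIndex(matrix(as.integer(voxel), 1), x@shape)
  cnt <- x@counts[row, ]
  names(cnt) <- x@labels
  cnt
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "LabelVolume", function(object) {
  labs <- setdiff(sort(unique(as.vector(object@data))), 0L)
  cat(sprintf("LabelVolume %s | %d label(s) | voxel size %s mm\n",
              paste(dim(object@data), collapse = "x"), length(labs),
              paste(signif(.voxelSizeFromAffine(object@affine), 4),
                    collapse = "x")))
})

setMethod("show", "MaskVolume", function(object) {
  cat(sprintf("MaskVolume %s | %d voxels set\n",
              paste(dim(object@data), collapse = "x"),
              sum(object@data != 0L)))
})

setMethod("show", "DirectionField", function(object) {
  cat(sprintf("DirectionField %s | %d voxels with direction\n",
              paste(dim(object@directions)[1:3], collapse = "x"),
              sum(object@directions[, , , 1] != 0 |
                  object@directions[, , , 2] != 0 |
                  object@directions[, , , 3] != 0)))
})

setMethod("show", "Tractogram", function(object) {
  np <- vapply(object@streamlines, nrow, integer(1))
  cat(sprintf("Tractogram | %d streamline(s) on grid %s%s\n",
              length(object@streamlines),
              paste(object@shape, collapse = "x"),
              if (length(np)) sprintf(" | %d-%d points", min(np), max(np))
              else ""))
})

setMethod("show", "LabeledTractogram", function(object) {
  cat(sprintf(
    "LabeledTractogram | %d labeled streamline(s), %d label(s), %d dropped\n",
    length(object@streamlines), length(unique(object@labels)),
    object@nDropped))
})

setMethod("show", "CandidateImage", function(object) {
  nz <- length(unique(object@counts@i))
  cat(sprintf(
    "CandidateImage %s | %d labels | %d voxel(s) with counts | total mass %d\n",
    paste(object@shape, collapse = "x"), length(object@labels), nz,
    as.integer(sum(object@counts))))
})

setMethod("show", "VotingParams", function(object) {
  cat(sprintf("VotingParams | wLocal = %g, wNeighbor = %g | %d offsets%s\n",
              object@wLocal, object@wNeighbor, nrow(object@neighborhood),
              if (object@normalizeNeighbors) " | normalized" else ""))
})

setMethod("show", "TrackingParams", function(object) {
  cat(sprintf("TrackingParams | angle %g deg | maxSteps %d | minPoints %d\n",
              object@angleThreshold, object@maxSteps, object@minPoints))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %s | %d bundle(s) | noise %g | seed %d\n",
              paste(object@shape, collapse = "x"), length(object@bundles),
              object@noise, object@rngSeed))
})
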