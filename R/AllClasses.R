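#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums
#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Integer label volume
#'
#' A 3-D grid of non-negative integer label IDs (0 = background/unlabeled)
#' together with a 4x4 voxel-index-to-world affine and an optional label
#' table mapping label IDs to region names. All computation in the package
#' happens in 0-based continuous voxel-index coordinates with voxel centers
#' at integer positions; the affine is only consulted at I/O boundaries and
#' for physical (mm) distances.
#'
#' @slot data 3-D integer array of label IDs (>= 0).
#' @slot affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#' @slot labelTable \code{data.frame} with columns \code{id} and \code{name},
#'   or \code{NULL}.
#'
#' @seealso [labelVolume()], [readLabelVolume()], [assignLabels()]
#' @export
setClass("LabelVolume",
  representation(data = "array", affine = "matrix",
                 labelTable = "data.frameOrNULL"),
  prototype(labelTable = NULL))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (!is.integer(object@data) && !all(object@data == round(object@data)))
    msg <- c(msg, "data must contain integer values")
  if (any(object@data < 0))
    msg <- c(msg, "label IDs must be >= 0")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine)) < .Machine$double.eps * 64)
    msg <- c(msg, "affine must be invertible")
  if (!is.null(object@labelTable) &&
      !all(c("id", "name") %in% names(object@labelTable)))
    msg <- c(msg, "labelTable needs columns 'id' and 'name'")
  if (length(msg)) msg else TRUE
})

#' Binary mask volume
#'
#' A 3-D grid of 0/1 values sharing the shape and affine conventions of
#' [LabelVolume-class]. Used for the white-matter domain and for tracking
#' masks.
#'
#' @slot data 3-D integer array with values in \{0, 1\}.
#' @slot affine 4x4 numeric voxel-to-world matrix.
#' @export
setClass("MaskVolume",
  representation(data = "array", affine = "matrix"))

setValidity("MaskVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (!all(object@data %in% c(0L, 1L)))
    msg <- c(msg, "mask values must be 0 or 1")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Principal-diffusion-direction field
#'
#' Per-voxel unit 3-vectors (the principal eigenvector of the diffusion
#' tensor), zero where undefined, plus the mask inside which tracking is
#' allowed. Directions are axial: \code{v} and \code{-v} are equivalent,
#' and the tracker resolves the sign at every step.
#'
#' @slot directions 4-D numeric array \code{(nx, ny, nz, 3)}; each nonzero
#'   vector has unit Euclidean norm (tolerance 1e-6).
#' @slot mask a [MaskVolume-class] delimiting where tracking may propagate.
#' @slot affine 4x4 numeric voxel-to-world matrix.
#' @export
setClass("DirectionField",
  representation(directions = "array", mask = "MaskVolume",
                 affine = "matrix"))

setValidity("DirectionField", function(object) {
  msg <- character()
  d <- dim(object@directions)
  if (length(d) != 4L || d[4] != 3L)
    msg <- c(msg, "directions must be an (nx, ny, nz, 3) array")
  else {
    if (!identical(d[1:3], dim(object@mask@data)))
      msg <- c(msg, "directions and mask shapes differ")
    n2 <- sqrt(object@directions[, , , 1]^2 + object@directions[, , , 2]^2 +
               object@directions[, , , 3]^2)
    bad <- n2 > 0 & abs(n2 - 1) > 1e-6
    if (any(bad))
      msg <- c(msg, "nonzero direction vectors must have unit norm")
  }
  if (length(msg)) msg else TRUE
})

#' Tractogram
#'
#' A collection of streamlines, each an n-by-3 matrix of continuous
#' positions in the package's internal 0-based voxel-index convention
#' (voxel centers at integer coordinates), plus the space metadata of the
#' reference grid the points live on.
#'
#' @slot streamlines list of numeric matrices, each with >= 2 rows and 3
#'   columns; consecutive points distinct, all coordinates finite.
#' @slot shape integer vector \code{(nx, ny, nz)} of the reference grid.
#' @slot affine 4x4 numeric voxel-to-world matrix of the reference grid.
#' @export
setClass("Tractogram",
  representation(streamlines = "list", shape = "integer",
                 affine = "matrix"))

setValidity("Tractogram", function(object) {
  msg <- character()
  if (length(object@shape) != 3L)
    msg <- c(msg, "shape must have length 3")
  ok <- vapply(object@streamlines, function(s) {
    is.matrix(s) && ncol(s) == 3L && nrow(s) >= 2L && all(is.finite(s)) &&
      all(rowSums(abs(diff(s))) > 0)
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, sprintf(
      "streamline(s) %s invalid: need >= 2 finite, pairwise-distinct consecutive 3-D points",
      paste(utils::head(which(!ok), 5), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Labeled tractogram
#'
#' A [Tractogram-class] whose streamlines each carry the cortex label of
#' their region of origin, oriented so that the first point lies at the
#' cortical end that supplied the label.
#'
#' @slot labels integer vector, one label (> 0) per streamline.
#' @slot nDropped number of input streamlines discarded because neither
#'   endpoint lay in a labeled cortex voxel.
#' @export
setClass("LabeledTractogram", contains = "Tractogram",
  representation(labels = "integer", nDropped = "integer"),
  prototype(nDropped = 0L))

setValidity("LabeledTractogram", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@streamlines))
    msg <- c(msg, "one label per streamline required")
  if (any(object@labels <= 0L))
    msg <- c(msg, "streamline labels must be > 0")
  if (length(msg)) msg else TRUE
})

#' Candidate image of per-voxel label counts
#'
#' For every white-matter voxel, the count of labeled streamlines of each
#' cortical label that pass through it. A single global label ordering is
#' shared by all voxels, so counts form a sparse voxel-by-label matrix.
#'
#' @slot shape integer \code{(nx, ny, nz)} grid dimensions.
#' @slot labels sorted integer vector: the global ordered label list.
#' @slot counts sparse \code{dgCMatrix} of dimension
#'   \code{prod(shape) x length(labels)}; row \code{v + 1} holds the count
#'   vector of the voxel with 0-based linear index
#'   \code{v = i + nx * j + nx * ny * k}.
#' @slot wmMask the [MaskVolume-class] the image was built over.
#' @export
setClass("CandidateImage",
  representation(shape = "integer", labels = "integer",
                 counts = "Matrix", wmMask = "MaskVolume"))

setValidity("CandidateImage", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 positive integers")
  if (is.unsorted(object@labels, strictly = TRUE) || any(object@labels <= 0L))
    msg <- c(msg, "labels must be strictly increasing positive integers")
  if (!all(dim(object@counts) ==
           c(prod(object@shape), length(object@labels))))
    msg <- c(msg, "counts must be prod(shape) x length(labels)")
  if (any(object@counts@x < 0) || any(object@counts@x != round(object@counts@x)))
    msg <- c(msg, "counts must be non-negative integers")
  if (!identical(dim(object@wmMask@data), as.integer(object@shape)))
    msg <- c(msg, "wmMask shape must match")
  else {
    inwm <- which(object@wmMask@data != 0L)
    nz <- unique(object@counts@i) + 1L   # rows with any nonzero entry
    if (length(setdiff(nz, inwm)))
      msg <- c(msg, "nonzero count vectors found outside the WM mask")
  }
  if (length(msg)) msg else TRUE
})

#' Voting parameters
#'
#' Weights and neighborhood for the combined local/neighbor label vote:
#' the probability of label i at a voxel is
#' \code{p_i = wLocal * pL_i + wNeighbor * pN_i}, where \code{pL} is the
#' voxel's own normalized label-count distribution and \code{pN} sums the
#' neighbors' distributions weighted by inverse Euclidean offset distance.
#'
#' @slot wLocal weight of the local term, in \[0, 1\].
#' @slot wNeighbor weight of the neighbor term; must satisfy
#'   \code{wLocal + wNeighbor == 1}.
#' @slot neighborhood integer matrix of relative offsets, one per row;
#'   defaults to the 26-connected neighborhood (all offsets in
#'   \{-1,0,1\}^3 except the zero offset).
#' @slot normalizeNeighbors if \code{TRUE}, divide the neighbor term by the
#'   total inverse-distance weight of contributing neighbors (off by
#'   default: the literal formulation does not renormalize).
#'
#' @seealso [votingParams()], [assignLabels()]
#' @export
setClass("VotingParams",
  representation(wLocal = "numeric", wNeighbor = "numeric",
                 neighborhood = "matrix", normalizeNeighbors = "logical"))

setValidity("VotingParams", function(object) {
  msg <- character()
  if (object@wLocal < 0 || object@wLocal > 1 ||
      object@wNeighbor < 0 || object@wNeighbor > 1)
    msg <- c(msg, "weights must lie in [0, 1]")
  if (abs(object@wLocal + object@wNeighbor - 1) > 1e-12)
    msg <- c(msg, "wLocal + wNeighbor must equal 1")
  if (ncol(object@neighborhood) != 3L)
    msg <- c(msg, "neighborhood offsets must be 3-D")
  if (any(rowSums(abs(object@neighborhood)) == 0))
    msg <- c(msg, "neighborhood must exclude the zero offset")
  if (length(msg)) msg else TRUE
})

#' FACT tracking parameters
#'
#' Stopping criteria and limits for the deterministic voxel-boundary
#' tracker.
#'
#' @slot angleThreshold maximum sign-resolved turning angle in degrees
#'   between consecutive voxel directions (default 35, the standard
#'   deterministic-tracking stopping angle).
#' @slot maxSteps maximum voxel transitions per half-track.
#' @slot minPoints minimum number of points for a track to be kept.
#'
#' @seealso [trackingParams()], [factTrack()]
#' @export
setClass("TrackingParams",
  representation(angleThreshold = "numeric", maxSteps = "integer",
                 minPoints = "integer"))

setValidity("TrackingParams", function(object) {
  msg <- character()
  if (object@angleThreshold <= 0 || object@angleThreshold >= 90)
    msg <- c(msg, "angleThreshold must lie in (0, 90) degrees")
  if (object@maxSteps < 1L) msg <- c(msg, "maxSteps must be >= 1")
  if (object@minPoints < 2L) msg <- c(msg, "minPoints must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Synthetic phantom specification
#'
#' Describes a synthetic test scene: fiber bundles with known cortical
#' regions of origin, cortex slabs at volume faces, and an optional
#' candidate-count mixing noise level used by [makeCandidateFixture()].
#'
#' @slot shape integer grid dimensions \code{(nx, ny, nz)}.
#' @slot bundles list of bundle descriptions; each a list with elements
#'   \code{geometry} ("straight", "arc" or one leg of a crossing pair),
#'   \code{axis}, \code{center}, \code{radius}, \code{startLabel},
#'   \code{endLabel} (see [phantomPreset()]).
#' @slot slabThickness thickness in voxels of the cortex slabs placed at
#'   the volume faces where bundles terminate.
#' @slot noise probability that a white-matter voxel's candidate counts
#'   are corrupted in [makeCandidateFixture()].
#' @slot rngSeed integer seed from which every pseudo-random artifact
#'   stream is derived.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", bundles = "list",
                 slabThickness = "integer", noise = "numeric",
                 rngSeed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 8L))
    msg <- c(msg, "shape must be 3 integers >= 8")
  if (object@noise < 0 || object@noise > 1)
    msg <- c(msg, "noise must be a probability")
  # a bundle may carry one label at both ends, but two bundles never
  # share a label
  labsPer <- lapply(object@bundles,
                    function(b) unique(c(b$startLabel, b$endLabel)))
  if (length(labsPer) && any(duplicated(unlist(labsPer))))
    msg <- c(msg, "slab labels must be unique across bundles")
  if (length(msg)) msg else TRUE
})
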