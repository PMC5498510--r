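# Deterministic FACT tracking: within each voxel the path is a straight
# segment along that voxel's principal direction; the direction switches
# at voxel boundaries. Stopping criteria: leaving the tracking mask,
# turning more than the angle threshold (sign-resolved, since tensor
# directions are axial), a zero direction, or the step cap.

.EPS_NUDGE <- 1e-6

# Grow one half-track from `seed` with initial travel direction `dir0`.
# Returns the list of points *after* the seed (possibly empty).
.growHalf <- function(dirs, mask, shape, seed, dir0, cosThresh, maxSteps) {
  pts <- vector("list", 64L)
  n <- 0L
  pos <- seed
  vox <- .voxelOf(matrix(pos, 1))[1, ]
  d <- dir0
  for (step in seq_len(maxSteps)) {
    # distance to the boundary of the current voxel along d
    tmin <- Inf
    for (ax in 1:3) {
      if (abs(d[ax]) < .EPS_NUDGE) next
      bound <- vox[ax] + 0.5 * sign(d[ax])
      tax <- (bound - pos[ax]) / d[ax]
      if (tax < tmin) tmin <- tax
    }
    if (!is.finite(tmin)) break           # direction numerically zero
    if (tmin < 0) tmin <- 0
    exitPos <- pos + tmin * d
    # nudge across the face to land unambiguously in the next voxel
    nextPos <- pos + (tmin + .EPS_NUDGE) * d
    nextVox <- .voxelOf(matrix(nextPos, 1))[1, ]
    n <- n + 1L
    if (n > length(pts)) pts <- c(pts, vector("list", length(pts)))
    pts[[n]] <- exitPos
    if (!all(nextVox >= 0L & nextVox < shape)) break       # volume exit
    if (mask[nextVox[1] + 1L, nextVox[2] + 1L, nextVox[3] + 1L] == 0L)
      break                                                # mask exit
    dNext <- dirs[nextVox[1] + 1L, nextVox[2] + 1L, nextVox[3] + 1L, ]
    if (all(dNext == 0)) break                             # undefined dir
    dt <- sum(d * dNext)
    if (dt < 0) { dNext <- -dNext; dt <- -dt }             # axial sign fix
    if (dt < cosThresh) break                              # sharp turn
    pos <- nextPos
    vox <- nextVox
    d <- dNext
  }
  if (n == 0L) list() else pts[seq_len(n)]
}

#' Track one streamline with FACT
#'
#' Grows a streamline bidirectionally from a seed point: two half-tracks
#' are propagated along \code{+v} and \code{-v} of the seed voxel's
#' direction and concatenated. Propagation follows each voxel's direction
#' in a straight line to the voxel boundary, then switches to the next
#' voxel's direction (sign-resolved to within 90 degrees of the incoming
#' step). It stops when the next voxel is outside the tracking mask, has a
#' zero direction, or would require a turn sharper than
#' \code{angleThreshold}, or when \code{maxSteps} is reached.
#'
#' @param field a [DirectionField-class].
#' @param seed numeric length-3 continuous seed position (0-based voxel
#'   coordinates); must lie inside the tracking mask.
#' @param params a [TrackingParams-class].
#' @return An n-by-3 matrix of streamline points, or \code{NULL} if fewer
#'   than \code{minPoints} points were produced (e.g. seed voxel direction
#'   undefined).
#' @examples
#' m <- maskVolume(array(1L, c(9, 9, 9)))
#' dirs <- array(0, c(9, 9, 9, 3)); dirs[, , , 1] <- 1
#' f <- directionField(dirs, m)
#' s <- factTrack(f, c(4, 4, 4), trackingParams())
#' range(s[, 1])   # spans the grid along x
#' @export
factTrack <- function(field, seed, params = trackingParams()) {
  stopifnot(is(field, "DirectionField"), is(params, "TrackingParams"))
  shape <- volumeShape(field)
  seed <- as.numeric(seed)
  vox <- .voxelOf(matrix(seed, 1))[1, ]
  if (!all(vox >= 0L & vox < shape))
    stop("domain error: seed outside volume bounds", call. = FALSE)
  if (field@mask@data[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L] == 0L)
    stop("domain error: seed outside the tracking mask", call. = FALSE)
  d0 <- field@directions[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L, ]
  if (all(d0 == 0)) return(NULL)
  cosThresh <- cos(params@angleThreshold * pi / 180)

  fwd <- .growHalf(field@directions, field@mask@data, shape, seed, d0,
                   cosThresh, params@maxSteps)
  bwd <- .growHalf(field@directions, field@mask@data, shape, seed, -d0,
                   cosThresh, params@maxSteps)
  pts <- c(rev(bwd), list(seed), fwd)
  m <- do.call(rbind, pts)
  # drop consecutive duplicates (seed exactly on a boundary etc.)
  if (nrow(m) > 1L) {
    keep <- c(TRUE, base::rowSums(abs(diff(m))) > 1e-12)
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < params@minPoints) return(NULL)
  m
}

#' Deterministic seed points for a cortex region
#'
#' For \code{seedsPerVoxel = 1} the seed set is the center of every voxel
#' carrying \code{regionLabel}. For \code{k > 1} a fixed regular
#' \code{m^3} sub-grid (\code{m = ceiling(k^(1/3))}) is laid inside each
#' voxel and its first \code{k} points are used, so seed sets are
#' reproducible across runs.
#'
#' @param cortex a [LabelVolume-class] cortical parcellation.
#' @param regionLabel integer label to seed from.
#' @param seedsPerVoxel seeds per labeled voxel.
#' @return An n-by-3 matrix of seed positions (0 rows, with a warning, if
#'   the label is absent).
#' @export
seedPointsFromCortex <- function(cortex, regionLabel, seedsPerVoxel = 1L) {
  stopifnot(is(cortex, "LabelVolume"), seedsPerVoxel >= 1L)
  idx <- which(cortex@data == as.integer(regionLabel), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("label ", regionLabel, " absent from cortex volume")
    return(matrix(numeric(0), ncol = 3))
  }
  centers <- idx - 1L    # to 0-based voxel centers
  k <- as.integer(seedsPerVoxel)
  if (k == 1L) return(matrix(as.numeric(centers), ncol = 3))
  m <- ceiling(k^(1 / 3) - 1e-9)
  off1 <- (seq_len(m) - (m + 1) / 2) / m      # symmetric sub-grid in (-0.5, 0.5)
  offs <- as.matrix(expand.grid(off1, off1, off1))[seq_len(k), , drop = FALSE]
  out <- matrix(0, nrow(centers) * k, 3)
  for (v in seq_len(nrow(centers)))
    out[((v - 1L) * k + 1L):(v * k), ] <-
      sweep(offs, 2, as.numeric(centers[v, ]), "+")
  out
}

#' Track a whole tractogram out of every cortex region
#'
#' Seeds every voxel of every nonzero cortex label (via
#' [seedPointsFromCortex()]), runs [factTrack()] from each seed, and
#' returns the resulting tractogram. Seed-region labels are not attached
#' here; [labelStreamlines()] recovers them from streamline endpoints,
#' which keeps externally supplied tractograms on the same code path.
#'
#' @param field a [DirectionField-class]; its tracking mask must include
#'   the cortex voxels being seeded.
#' @param cortex a [LabelVolume-class] in the same space.
#' @param params a [TrackingParams-class].
#' @param seedsPerVoxel seeds per cortex voxel.
#' @return A [Tractogram-class].
#' @export
trackFromCortex <- function(field, cortex, params = trackingParams(),
                            seedsPerVoxel = 1L) {
  .checkSameSpace(field, cortex, "direction field and cortex")
  labs <- setdiff(sort(unique(as.vector(cortex@data))), 0L)
  shape <- volumeShape(field)
  out <- list()
  for (lab in labs) {
    seeds <- seedPointsFromCortex(cortex, lab, seedsPerVoxel)
    for (i in seq_len(nrow(seeds))) {
      vox <- .voxelOf(seeds[i, , drop = FALSE])[1, ]
      if (field@mask@data[vox[1] + 1L, vox[2] + 1L, vox[3] + 1L] == 0L)
        next
      s <- factTrack(field, seeds[i, ], params)
      if (!is.null(s)) out[[length(out) + 1L]] <- s
    }
  }
  tractogram(out, shape, field@affine)
}
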