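# First pass of the parcellation: attach a cortical origin label to every
# streamline, find the white-matter voxels each labeled streamline
# traverses, and accumulate per-voxel label counts into the candidate
# image.

#' Label streamlines by cortical region of origin
#'
#' Each streamline endpoint lying in a voxel with a nonzero cortex label
#' produces one labeled streamline carrying that label, oriented to start
#' at that endpoint: a fiber running from region 7 to region 9 is emitted
#' twice (once per end), matching the semantics of seeding the same field
#' from both regions. Streamlines touching no cortex label at either
#' endpoint are dropped and counted in \code{nDropped}.
#'
#' @param t a [Tractogram-class].
#' @param cortex a [LabelVolume-class] sharing the tractogram's space.
#' @return A [LabeledTractogram-class].
#' @export
labelStreamlines <- function(t, cortex) {
  stopifnot(is(t, "Tractogram"), is(cortex, "LabelVolume"))
  .checkSameSpace(t, cortex, "tractogram and cortex")
  shape <- volumeShape(cortex)
  out <- list(); labs <- integer(); dropped <- 0L
  for (s in t@streamlines) {
    ends <- .voxelOf(s[c(1L, nrow(s)), , drop = FALSE])
    endLab <- integer(2)
    for (e in 1:2) {
      v <- ends[e, ]
      endLab[e] <- if (all(v >= 0L & v < shape))
        cortex@data[v[1] + 1L, v[2] + 1L, v[3] + 1L] else 0L
    }
    emitted <- FALSE
    if (endLab[1] > 0L) {
      out[[length(out) + 1L]] <- s
      labs <- c(labs, endLab[1]); emitted <- TRUE
    }
    if (endLab[2] > 0L) {
      out[[length(out) + 1L]] <- s[nrow(s):1L, , drop = FALSE]
      labs <- c(labs, endLab[2]); emitted <- TRUE
    }
    if (!emitted) dropped <- dropped + 1L
  }
  if (dropped > 0L)
    message(dropped, " streamline(s) touched no cortex label and were dropped")
  new("LabeledTractogram", streamlines = out, shape = t@shape,
      affine = t@affine, labels = labs, nDropped = dropped)
}

#' White-matter voxels traversed by a streamline
#'
#' Every polyline segment is sampled at a fixed sub-step of
#' \code{substep} voxels (default 0.25, which cannot skip a unit voxel)
#' plus both endpoints; sample positions are mapped to voxels and
#' restricted to the white-matter mask.
#'
#' @param s an n-by-3 streamline point matrix (0-based voxel coords).
#' @param wmMask a [MaskVolume-class]; voxels outside it are excluded.
#' @param substep sampling interval along segments, in voxels.
#' @param countTraversals if \code{FALSE} (default) return the
#'   deduplicated voxel set: a fiber contributes at most once per voxel no
#'   matter how often it re-enters. If \code{TRUE}, return one row per
#'   distinct entry into a voxel (contiguous runs of samples collapse to
#'   one traversal).
#' @return Integer matrix of voxel indices (n-by-3, 0-based); out-of-bounds
#'   samples are skipped.
#' @export
voxelizeStreamline <- function(s, wmMask, substep = 0.25,
                               countTraversals = FALSE) {
  stopifnot(is(wmMask, "MaskVolume"), substep > 0)
  shape <- volumeShape(wmMask)
  samples <- .sampleSegments(s, substep)
  vox <- .voxelOf(samples)
  ok <- .inBounds(vox, shape)
  vox <- vox[ok, , drop = FALSE]
  if (nrow(vox) == 0L) return(vox)
  lin <- .linearIndex(vox, shape)
  inWM <- wmMask@data[cbind(vox[, 1] + 1L, vox[, 2] + 1L, vox[, 3] + 1L)] != 0L
  if (countTraversals) {
    # one row per contiguous run of samples inside the same WM voxel
    runs <- rle(lin * as.integer(inWM))    # 0 encodes non-WM samples
    vals <- runs$values[runs$values != 0L]
    if (length(vals) == 0L) return(matrix(integer(0), ncol = 3))
    return(.unlinearIndex(vals, shape))
  }
  lin <- unique(lin[inWM])
  if (length(lin) == 0L) return(matrix(integer(0), ncol = 3))
  .unlinearIndex(lin, shape)
}

.sampleSegments <- function(s, substep) {
  pieces <- vector("list", nrow(s) - 1L)
  for (i in seq_len(nrow(s) - 1L)) {
    a <- s[i, ]; b <- s[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / substep))
    tt <- seq(0, 1, length.out = nseg + 1L)
    if (i > 1L) tt <- tt[-1L]              # endpoint shared with previous
    pieces[[i]] <- cbind(a[1] + tt * (b[1] - a[1]),
                         a[2] + tt * (b[2] - a[2]),
                         a[3] + tt * (b[3] - a[3]))
  }
  do.call(rbind, pieces)
}

.unlinearIndex <- function(lin, shape) {
  lin0 <- lin - 1L
  i <- lin0 %% shape[1]
  j <- (lin0 %/% shape[1]) %% shape[2]
  k <- lin0 %/% (shape[1] * shape[2])
  cbind(i, j, k, deparse.level = 0)
}

#' Populate the candidate image
#'
#' For every labeled streamline, each white-matter voxel it traverses has
#' its count for the streamline's label incremented by one (a streamline
#' contributes at most one count per voxel regardless of re-entry, unless
#' \code{countTraversals}).
#'
#' @param labeled a [LabeledTractogram-class].
#' @param wmMask a [MaskVolume-class] defining the white-matter domain.
#' @param labelList global ordered label list; defaults to the sorted
#'   distinct streamline labels. Every streamline label must appear in it.
#' @param substep,countTraversals passed to [voxelizeStreamline()].
#' @return A [CandidateImage-class].
#' @export
populateCandidates <- function(labeled, wmMask, labelList = NULL,
                               substep = 0.25, countTraversals = FALSE) {
  stopifnot(is(labeled, "LabeledTractogram"), is(wmMask, "MaskVolume"))
  .checkSameSpace(labeled, wmMask, "tractogram and WM mask")
  if (is.null(labelList))
    labelList <- sort(unique(labeled@labels))
  labelList <- as.integer(sort(labelList))
  unknown <- setdiff(labeled@labels, labelList)
  if (length(unknown))
    stop("configuration error: streamline label(s) ",
         paste(unknown, collapse = ", "), " missing from labelList",
         call. = FALSE)
  shape <- as.integer(volumeShape(wmMask))
  rows <- vector("list", length(labeled@streamlines))
  cols <- vector("list", length(labeled@streamlines))
  for (si in seq_along(labeled@streamlines)) {
    vox <- voxelizeStreamline(labeled@streamlines[[si]], wmMask,
                              substep = substep,
                              countTraversals = countTraversals)
    if (nrow(vox) == 0L) next
    rows[[si]] <- .linearIndex(vox, shape)
    cols[[si]] <- rep.int(match(labeled@labels[si], labelList), nrow(vox))
  }
  i <- unlist(rows); j <- unlist(cols)
  counts <- sparseMatrix(i = if (is.null(i)) integer(0) else i,
                         j = if (is.null(j)) integer(0) else j,
                         x = if (is.null(i)) numeric(0) else rep(1, length(i)),
                         dims = c(prod(shape), length(labelList)))
  new("CandidateImage", shape = shape, labels = labelList,
      counts = methods::as(counts, "CsparseMatrix"), wmMask = wmMask)
}
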