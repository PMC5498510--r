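# Synthetic phantoms with known ground truth: tubular fiber bundles whose
# direction field follows the bundle tangent, cortex slabs at the volume
# faces where bundles terminate, a white-matter mask covering the tube
# interiors, and the true cortex-association of every WM voxel.

#' Construct a phantom specification
#'
#' @param shape grid dimensions (default 40^3, large enough for bundles
#'   of several voxels radius with separated cortex slabs).
#' @param bundles list of bundle descriptors as produced by
#'   [phantomPreset()]; each is a list with \code{geometry}
#'   (\code{"straight"} or \code{"arc"}), \code{axis} (1, 2 or 3; the
#'   propagation axis for straight bundles), \code{center} (tube axis
#'   position on the two transverse axes, or arc parameters),
#'   \code{radius} (tube radius in voxels), \code{startLabel},
#'   \code{endLabel}.
#' @param slabThickness cortex slab depth in voxels at each end face.
#' @param noise candidate-count corruption probability used by
#'   [makeCandidateFixture()].
#' @param rngSeed master seed; every random artifact stream derives from
#'   it, so phantoms are pure functions of the spec.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(40L, 40L, 40L), bundles,
                        slabThickness = 2L, noise = 0, rngSeed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), bundles = bundles,
      slabThickness = as.integer(slabThickness), noise = as.numeric(noise),
      rngSeed = as.integer(rngSeed))
}

#' Ready-made phantom specifications
#'
#' \describe{
#'   \item{two-bundle}{two parallel, disjoint straight bundles along x
#'     (labels 7/8 and 9/10 at the two end faces) — the fully separable
#'     case where the parcellation must recover truth exactly.}
#'   \item{crossing}{two orthogonal straight bundles (x and y) crossing at
#'     the volume center; crossing voxels carry genuinely ambiguous truth
#'     and are flagged separately.}
#'   \item{arc}{one quarter-circle bundle from the x face to the y face,
#'     for curvature handling in the tracker.}
#' }
#'
#' @param preset \code{"two-bundle"}, \code{"crossing"} or \code{"arc"}.
#' @param shape grid dimensions.
#' @param radius tube radius in voxels.
#' @param noise see [phantomSpec()].
#' @param rngSeed master seed.
#' @return A [PhantomSpec-class].
#' @export
phantomPreset <- function(preset = c("two-bundle", "crossing", "arc"),
                          shape = c(40L, 40L, 40L), radius = 2.5,
                          noise = 0, rngSeed = 1L) {
  preset <- match.arg(preset)
  shape <- as.integer(shape)
  cy <- (shape[2] - 1) / 2; cz <- (shape[3] - 1) / 2
  bundles <- switch(preset,
    "two-bundle" = list(
      list(geometry = "straight", axis = 1L,
           center = c(round(cy - shape[2] / 5), cz), radius = radius,
           startLabel = 7L, endLabel = 8L),
      list(geometry = "straight", axis = 1L,
           center = c(round(cy + shape[2] / 5), cz), radius = radius,
           startLabel = 9L, endLabel = 10L)),
    "crossing" = list(
      list(geometry = "straight", axis = 1L, center = c(cy, cz),
           radius = radius, startLabel = 7L, endLabel = 8L),
      list(geometry = "straight", axis = 2L,
           center = c((shape[1] - 1) / 2, cz), radius = radius,
           startLabel = 9L, endLabel = 10L)),
    "arc" = list(
      list(geometry = "arc", axis = 3L,
           center = c(0, 0, cz, (shape[1] + shape[2]) / 4), radius = radius,
           startLabel = 7L, endLabel = 9L)))
  phantomSpec(shape = shape, bundles = bundles, noise = noise,
              rngSeed = rngSeed)
}

# For a bundle and a 0-based voxel-center coordinate matrix (n x 3):
# returns list(inside = logical n, tangent = n x 3, axialDist = n) where
# axialDist is the transverse distance to the bundle axis (used for
# crossing-voxel dominance) and tangent the unit local fiber direction.
.bundleGeometry <- function(b, pts) {
  n <- nrow(pts)
  if (b$geometry == "straight") {
    tr <- setdiff(1:3, b$axis)
    d <- sqrt((pts[, tr[1]] - b$center[1])^2 +
              (pts[, tr[2]] - b$center[2])^2)
    tan_ <- matrix(0, n, 3); tan_[, b$axis] <- 1
    list(inside = d <= b$radius, tangent = tan_, axialDist = d)
  } else if (b$geometry == "arc") {
    # quarter circle in the xy-plane around (cx, cy) at height cz with
    # curve radius R: center = c(cx, cy, cz, R)
    cx <- b$center[1]; cy <- b$center[2]; cz <- b$center[3]
    R <- b$center[4]
    dx <- pts[, 1] - cx; dy <- pts[, 2] - cy
    rad <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    d <- sqrt((rad - R)^2 + (pts[, 3] - cz)^2)
    inside <- d <= b$radius & theta >= 0 & theta <= pi / 2
    tan_ <- cbind(-dy / pmax(rad, 1e-9), dx / pmax(rad, 1e-9), 0)
    list(inside = inside, tangent = tan_, axialDist = d)
  } else stop("unknown bundle geometry: ", b$geometry)
}

# End-face cortex slabs of a bundle: voxels within the tube cross-section
# in the first/last `thick` planes along the propagation axis.
.bundleSlabs <- function(b, pts, shape, thick) {
  g <- .bundleGeometry(b, pts)
  if (b$geometry == "straight") {
    ax <- pts[, b$axis]
    list(start = g$inside & ax < thick,
         end = g$inside & ax > shape[b$axis] - 1 - thick)
  } else {
    # arc from theta ~ 0 (x face) to theta ~ pi/2 (y face): slabs where the
    # curve meets the x = cx and y = cy planes
    theta <- atan2(pts[, 2] - b$center[2], pts[, 1] - b$center[1])
    R <- b$center[4]
    arcThick <- thick / R     # angular thickness matching `thick` voxels
    list(start = g$inside & theta <= arcThick,
         end = g$inside & theta >= pi / 2 - arcThick)
  }
}

#' Generate a phantom scene
#'
#' Builds, from a [PhantomSpec-class], the full set of inputs and ground
#' truth for the parcellation pipeline: a cortex parcellation (slabs at
#' the faces where bundles terminate), a white-matter mask (tube interiors
#' minus the slabs), a direction field following each bundle's tangent
#' (with a tracking mask covering tubes and slabs), the true white-matter
#' parcellation, and a mask flagging crossing voxels where truth is
#' ambiguous. In voxels shared by several bundles the direction and the
#' true label come from the bundle whose axis is nearest (ties to the
#' bundle listed first); such voxels are flagged in \code{crossingMask}.
#'
#' All outputs are pure functions of the spec (including its seed).
#'
#' @param spec a [PhantomSpec-class].
#' @return List with elements \code{cortex} ([LabelVolume-class]),
#'   \code{wmMask} ([MaskVolume-class]), \code{directions}
#'   ([DirectionField-class]), \code{truth} ([LabelVolume-class]) and
#'   \code{crossingMask} ([MaskVolume-class]).
#' @examples
#' ph <- makePhantom(phantomPreset("two-bundle", shape = c(24, 24, 24)))
#' ph$truth
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  shape <- spec@shape
  nv <- prod(shape)
  pts <- .unlinearIndex(seq_len(nv), shape)   # 0-based voxel centers

  cortex <- integer(nv); wm <- integer(nv)
  truth <- integer(nv); crossing <- integer(nv)
  dirs <- matrix(0, nv, 3)
  bestDist <- rep(Inf, nv)
  nOwners <- integer(nv)

  for (b in spec@bundles) {
    g <- .bundleGeometry(b, pts)
    sl <- .bundleSlabs(b, pts, shape, spec@slabThickness)
    slab <- sl$start | sl$end
    if (any(cortex[sl$start] != 0L) || any(cortex[sl$end] != 0L))
      stop("spec error: overlapping cortex slabs", call. = FALSE)
    cortex[sl$start] <- b$startLabel
    cortex[sl$end] <- b$endLabel
    tube <- g$inside & !slab
    nOwners[tube] <- nOwners[tube] + 1L
    own <- tube & g$axialDist < bestDist
    bestDist[own] <- g$axialDist[own]
    dirs[own, ] <- g$tangent[own, , drop = FALSE]
    truth[own] <- b$startLabel
    wm[tube] <- 1L
    # direction must also be defined in the slabs so tracks can seed there
    slabOwn <- slab & g$axialDist < bestDist
    bestDist[slabOwn] <- g$axialDist[slabOwn]
    dirs[slabOwn, ] <- g$tangent[slabOwn, , drop = FALSE]
  }
  crossing[nOwners > 1L] <- 1L
  truth[wm == 0L] <- 0L

  aff <- diag(4)
  wmVol <- maskVolume(array(wm, shape), aff)
  trackMask <- maskVolume(array(as.integer(wm == 1L | cortex > 0L), shape),
                          aff)
  # normalize tangents (arc tangents are already unit, belt and braces)
  nrm <- sqrt(base::rowSums(dirs^2))
  pos <- nrm > 0
  dirs[pos, ] <- dirs[pos, , drop = FALSE] / nrm[pos]
  list(
    cortex = labelVolume(array(cortex, shape), aff),
    wmMask = wmVol,
    directions = directionField(array(dirs, c(shape, 3L)), trackMask, aff),
    truth = labelVolume(array(truth, shape), aff),
    crossingMask = maskVolume(array(crossing, shape), aff))
}

#' Generate a candidate-image fixture directly (bypassing tracking)
#'
#' Builds a [CandidateImage-class] from the phantom's ground truth: every
#' WM voxel gets a count for its true label drawn uniformly from 8..12
#' fibers. With probability \code{noise} a voxel is corrupted: a uniformly
#' chosen wrong label receives a count strictly larger than the true one
#' (so the purely local vote misclassifies the voxel, while typically its
#' neighbors still carry the true label). Used to exercise the voting
#' stage in isolation.
#'
#' @param spec a [PhantomSpec-class] (its \code{noise} and \code{rngSeed}
#'   slots drive the corruption).
#' @return List with \code{cand} ([CandidateImage-class]), \code{truth}
#'   ([LabelVolume-class]) and \code{corrupted} ([MaskVolume-class],
#'   flagging the voxels whose counts were perturbed).
#' @export
makeCandidateFixture <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  ph <- makePhantom(spec)
  shape <- spec@shape
  truthV <- as.vector(ph$truth@data)
  wmV <- as.vector(ph$wmMask@data) != 0L
  labs <- sort(unique(truthV[truthV > 0L]))
  vox <- which(wmV & truthV > 0L)
  corrupted <- integer(prod(shape))

  dat <- .withStream(spec@rngSeed, "counts", {
    trueCnt <- sample(8:12, length(vox), replace = TRUE)
    flip <- .withStream(spec@rngSeed, "noise",
                        stats::runif(length(vox)) < spec@noise)
    wrongPick <- .withStream(spec@rngSeed, "fixture",
                             sample.int(max(1L, length(labs) - 1L),
                                        length(vox), replace = TRUE))
    list(trueCnt = trueCnt, flip = flip, wrongPick = wrongPick)
  })

  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (v in seq_along(vox)) {
    tl <- match(truthV[vox[v]], labs)
    i <- c(i, vox[v]); j <- c(j, tl); x <- c(x, dat$trueCnt[v])
    if (dat$flip[v] && length(labs) > 1L) {
      others <- setdiff(seq_along(labs), tl)
      wl <- others[(dat$wrongPick[v] - 1L) %% length(others) + 1L]
      i <- c(i, vox[v]); j <- c(j, wl); x <- c(x, dat$trueCnt[v] + 3)
      corrupted[vox[v]] <- 1L
    }
  }
  counts <- sparseMatrix(i = i, j = j, x = x,
                         dims = c(prod(shape), length(labs)))
  cand <- new("CandidateImage", shape = shape, labels = as.integer(labs),
              counts = methods::as(counts, "CsparseMatrix"),
              wmMask = ph$wmMask)
  list(cand = cand, truth = ph$truth,
       corrupted = maskVolume(array(corrupted, shape), diag(4)))
}
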