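# Second stage: per-voxel label probabilities and argmax assignment.
#
# For voxel v with count vector L (one entry per label in the global
# ordered list):
#   local:    pL_i = L_i / sum_j L_j                     (empty voxel: 0)
#   neighbor: pN_i = sum_{n in N} ||n||^-1 * L_i^n / sum_j L_j^n
#             (empty or out-of-volume neighbors contribute nothing;
#              no renormalization by the total neighbor weight unless
#              normalizeNeighbors is set)
#   combined: p_i  = wL * pL_i + wN * pN_i
# The assigned label is argmax_i p_i, ties broken by lowest label ID.

#' Local label probability of one count vector
#'
#' @param counts numeric vector of label counts in the global ordering.
#' @return \code{counts / sum(counts)}; the zero vector if all counts are
#'   zero (the empty-voxel signal, resolved by [assignLabels()], not an
#'   error).
#' @examples
#' localProbability(c(3, 1, 0))   # 0.75 0.25 0
#' @export
localProbability <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(numeric(length(counts)))
  counts / tot
}

#' Neighborhood label probability at one voxel
#'
#' Sums the local probability vectors of the (by default 26) neighboring
#' voxels, each weighted by the inverse Euclidean length of its offset
#' (face neighbors weight 1, edge 1/sqrt(2), corner 1/sqrt(3)). Neighbors
#' outside the volume or with all-zero counts contribute nothing.
#'
#' @param voxel 0-based integer voxel index (length 3).
#' @param cand a [CandidateImage-class].
#' @param params a [VotingParams-class] (supplies the neighborhood and the
#'   \code{normalizeNeighbors} switch).
#' @return Numeric vector over the candidate image's label list.
#' @export
neighborProbability <- function(voxel, cand, params = votingParams()) {
  stopifnot(is(cand, "CandidateImage"), is(params, "VotingParams"))
  voxel <- as.integer(voxel)
  if (!all(voxel >= 0L & voxel < cand@shape))
    stop("voxel outside the candidate image", call. = FALSE)
  offs <- params@neighborhood
  w <- 1 / sqrt(base::rowSums(offs^2))
  p <- numeric(length(cand@labels))
  wTot <- 0
  for (r in seq_len(nrow(offs))) {
    nb <- voxel + offs[r, ]
    if (!all(nb >= 0L & nb < cand@shape)) next
    cnt <- cand@counts[.linearIndex(matrix(nb, 1), cand@shape), ]
    tot <- sum(cnt)
    if (tot == 0) next
    p <- p + w[r] * cnt / tot
    wTot <- wTot + w[r]
  }
  if (params@normalizeNeighbors && wTot > 0) p <- p / wTot
  p
}

#' Combined label probability at one voxel
#'
#' @inheritParams neighborProbability
#' @return \code{wLocal * pL + wNeighbor * pN} over the label list, with
#'   the local term taken as the zero vector for an empty voxel.
#' @export
combinedProbability <- function(voxel, cand, params = votingParams()) {
  voxel <- as.integer(voxel)
  cnt <- cand@counts[.linearIndex(matrix(voxel, 1), cand@shape), ]
  params@wLocal * localProbability(cnt) +
    params@wNeighbor * neighborProbability(voxel, cand, params)
}

#' Assign a label to every white-matter voxel
#'
#' Computes the combined probability vector of every voxel in the
#' white-matter mask and assigns the label with the highest probability,
#' breaking exact ties by the lowest label ID. Voxels whose probability
#' vector is identically zero (no fibers locally nor in any neighbor) and
#' voxels outside the mask receive 0.
#'
#' @param cand a [CandidateImage-class].
#' @param wmMask a [MaskVolume-class]; must match the candidate image's
#'   grid (defaults to the mask stored in \code{cand}).
#' @param params a [VotingParams-class].
#' @return A [LabelVolume-class] white-matter parcellation.
#' @export
assignLabels <- function(cand, wmMask = NULL, params = votingParams()) {
  stopifnot(is(cand, "CandidateImage"), is(params, "VotingParams"))
  if (is.null(wmMask)) wmMask <- cand@wmMask
  if (!identical(as.integer(volumeShape(wmMask)), cand@shape))
    stop("space error: WM mask shape does not match candidate image",
         call. = FALSE)
  shape <- cand@shape
  nl <- length(cand@labels)
  nv <- prod(shape)

  # Row-normalized local probabilities, dense (nv x nl); zero rows stay 0.
  tot <- rowSums(cand@counts)
  PL <- as.matrix(cand@counts)
  nzr <- tot > 0
  PL[nzr, ] <- PL[nzr, , drop = FALSE] / tot[nzr]

  # Neighbor term by shifted-array accumulation over the offsets.
  offs <- params@neighborhood
  w <- 1 / sqrt(base::rowSums(offs^2))
  PLarr <- array(PL, dim = c(shape, nl))
  PN <- array(0, dim = c(shape, nl))
  if (params@normalizeNeighbors)
    WT <- array(0, dim = shape)
  nzArr <- array(as.numeric(nzr), dim = shape)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    # destination voxel v receives PL[v + o]
    lo <- pmax(1L, 1L - o); hi <- pmin(shape, shape - o)
    if (any(hi < lo)) next          # offset shifts everything off-grid
    dst <- lapply(1:3, function(ax) lo[ax]:hi[ax])
    src <- lapply(1:3, function(ax) dst[[ax]] + o[ax])
    PN[dst[[1]], dst[[2]], dst[[3]], ] <-
      PN[dst[[1]], dst[[2]], dst[[3]], , drop = FALSE] +
      w[r] * PLarr[src[[1]], src[[2]], src[[3]], , drop = FALSE]
    if (params@normalizeNeighbors)
      WT[dst[[1]], dst[[2]], dst[[3]]] <-
        WT[dst[[1]], dst[[2]], dst[[3]]] +
        w[r] * nzArr[src[[1]], src[[2]], src[[3]]]
  }
  PN <- matrix(PN, nrow = nv, ncol = nl)
  if (params@normalizeNeighbors) {
    wt <- as.vector(WT)
    pos <- wt > 0
    PN[pos, ] <- PN[pos, , drop = FALSE] / wt[pos]
  }

  P <- params@wLocal * PL + params@wNeighbor * PN
  inWM <- as.vector(wmMask@data) != 0L

  out <- integer(nv)
  rows <- which(inWM & base::rowSums(P) > 0)
  if (length(rows)) {
    Pr <- P[rows, , drop = FALSE]
    best <- max.col(Pr, ties.method = "first")
    # max.col("first") equals lowest-label-ID tie-breaking because the
    # label list is sorted ascending.
    out[rows] <- cand@labels[best]
  }
  labelVolume(array(out, dim = shape), affine = wmMask@affine)
}
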