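# Comparators: the nearest-cortex baseline (the classic surface-software
# white-matter labeling: each WM voxel inherits the label of its closest
# cortical voxel), majority-vote group averaging, and Dice overlap.

#' Nearest-cortex white-matter parcellation
#'
#' Assigns every white-matter voxel the label of the Euclidean-nearest
#' cortex-labeled voxel. Distances are physical (mm, anisotropy-aware via
#' the voxel size); exact distance ties go to the lowest label ID.
#'
#' @param cortex a [LabelVolume-class] with at least one nonzero label.
#' @param wmMask a [MaskVolume-class] in the same space.
#' @param chunkSize number of WM voxels processed per distance block
#'   (memory/speed trade-off only; the result is independent of it).
#' @return A [LabelVolume-class].
#' @export
nearestCortexParcellation <- function(cortex, wmMask, chunkSize = 2048L) {
  stopifnot(is(cortex, "LabelVolume"), is(wmMask, "MaskVolume"))
  .checkSameSpace(cortex, wmMask, "cortex and WM mask")
  shape <- volumeShape(cortex)
  vs <- voxelSize(cortex)
  cIdx <- which(cortex@data > 0L, arr.ind = TRUE)
  if (nrow(cIdx) == 0L)
    stop("configuration error: cortex volume contains no labels",
         call. = FALSE)
  cLab <- cortex@data[cIdx]
  # order cortex voxels by label so that among equidistant candidates the
  # first (lowest-ID) wins
  o <- order(cLab)
  cIdx <- cIdx[o, , drop = FALSE]; cLab <- cLab[o]
  cMM <- sweep(cIdx - 1, 2, vs, "*")

  wIdx <- which(wmMask@data != 0L, arr.ind = TRUE)
  out <- array(0L, dim = shape)
  if (nrow(wIdx) == 0L)
    return(labelVolume(out, affine = cortex@affine,
                       labelTable = cortex@labelTable))
  wMM <- sweep(wIdx - 1, 2, vs, "*")
  cSq <- base::rowSums(cMM^2)
  for (start in seq(1L, nrow(wMM), by = chunkSize)) {
    rows <- start:min(start + chunkSize - 1L, nrow(wMM))
    blk <- wMM[rows, , drop = FALSE]
    # squared mm distances: |w|^2 - 2 w.c + |c|^2, blocks x cortex voxels
    d2 <- outer(base::rowSums(blk^2), cSq, "+") - 2 * blk %*% base::t(cMM)
    dmin <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    # equidistant within tolerance -> earliest (lowest-label) candidate
    pick <- max.col(-(d2 > dmin + 1e-9), ties.method = "first")
    out[wIdx[rows, , drop = FALSE]] <- cLab[pick]
  }
  labelVolume(out, affine = cortex@affine, labelTable = cortex@labelTable)
}

#' Majority-vote average of co-registered parcellations
#'
#' Per voxel, the most frequent nonzero label across the input volumes;
#' exact ties go to the lowest label ID; voxels where every input is 0
#' stay 0 (absence of a label is not a competing class).
#'
#' @param parcellations non-empty list of [LabelVolume-class] objects with
#'   identical shape and affine (registration to a common space is assumed
#'   done).
#' @return A [LabelVolume-class].
#' @export
majorityVoteAverage <- function(parcellations) {
  stopifnot(length(parcellations) >= 1L,
            all(vapply(parcellations, is, logical(1), "LabelVolume")))
  ref <- parcellations[[1L]]
  for (p in parcellations[-1L]) .checkSameSpace(ref, p, "parcellations")
  shape <- volumeShape(ref)
  labs <- setdiff(sort(unique(unlist(
    lapply(parcellations, function(p) unique(as.vector(p@data)))))), 0L)
  if (length(labs) == 0L)
    return(labelVolume(array(0L, shape), affine = ref@affine))
  best <- array(0L, shape)
  bestN <- array(0L, shape)
  for (lab in labs) {          # ascending: strict > keeps the lowest ID on ties
    n <- Reduce(`+`, lapply(parcellations,
                            function(p) (p@data == lab) + 0L))
    take <- n > bestN
    best[take] <- lab
    bestN[take] <- n[take]
  }
  labelVolume(best, affine = ref@affine, labelTable = ref@labelTable)
}

#' Dice overlap of one label between two parcellations
#'
#' \code{2 |A intersect B| / (|A| + |B|)} for the voxel sets carrying
#' \code{label}; defined as 1 when both sets are empty.
#'
#' @param a,b [LabelVolume-class] objects in the same space.
#' @param label integer label ID.
#' @return Score in \[0, 1\].
#' @export
diceOverlap <- function(a, b, label) {
  stopifnot(is(a, "LabelVolume"), is(b, "LabelVolume"))
  .checkSameSpace(a, b, "parcellations")
  A <- a@data == as.integer(label)
  B <- b@data == as.integer(label)
  den <- sum(A) + sum(B)
  if (den == 0L) return(1)
  2 * sum(A & B) / den
}

#' Per-label Dice table
#'
#' @param a,b parcellations in the same space.
#' @param labels labels to score; defaults to all nonzero labels present
#'   in either volume.
#' @return \code{data.frame} with columns \code{label}, \code{name} (if a
#'   label table is attached to \code{a}), \code{dice}.
#' @export
diceTable <- function(a, b, labels = NULL) {
  if (is.null(labels))
    labels <- setdiff(sort(unique(c(as.vector(a@data), as.vector(b@data)))),
                      0L)
  d <- vapply(labels, function(l) diceOverlap(a, b, l), numeric(1))
  tb <- data.frame(label = as.integer(labels), dice = d)
  lt <- labelTable(a)
  if (!is.null(lt))
    tb$name <- lt$name[match(tb$label, lt$id)]
  tb[, intersect(c("label", "name", "dice"), names(tb))]
}
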