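# Streamline labeling, voxelization and candidate-image accumulation.

allWM <- function(shape) maskVolume(array(1L, shape))

twoSlabCortex <- function(shape = c(12, 5, 5)) {
  arr <- array(0L, shape)
  arr[1, , ] <- 7L
  arr[shape[1], , ] <- 9L
  labelVolume(arr)
}

test_that("streamlines are labeled by their endpoint cortex regions", {
  cortex <- twoSlabCortex()
  inside <- rbind(c(4, 2, 2), c(7, 2, 2))        # touches no cortex
  fromA <- rbind(c(0, 2, 2), c(6, 2, 2))         # starts in label 7
  toB <- rbind(c(5, 2, 2), c(11, 2, 2))          # ends in label 9
  both <- rbind(c(0, 2, 2), c(11, 2, 2))         # 7 at start, 9 at end
  tr <- tractogram(list(inside, fromA, toB, both), c(12, 5, 5))
  expect_message(lab <- labelStreamlines(tr, cortex), "1 streamline")
  expect_equal(nDropped(lab), 1L)
  expect_equal(sort(streamlineLabels(lab)), c(7L, 7L, 9L, 9L))
  # reversed emission starts at the labeled end
  sl <- streamlines(lab)
  lb <- streamlineLabels(lab)
  for (i in seq_along(sl))
    expect_equal(volumeData(cortex)[rbind(floor(sl[[i]][1, ] + 0.5) + 1L)],
                 lb[i])
  # the cortex-to-cortex fiber is emitted once per end
  expect_length(sl, 4L)
})

test_that("labeling matches per-end seeding semantics on a two-slab field", {
  # a field connecting slab 7 to slab 9: labeling a whole-field tractogram
  # per endpoint equals the union of tracks labeled from each seed region
  shape <- c(12, 5, 5)
  cortex <- twoSlabCortex(shape)
  f <- uniformField(shape, c(1, 0, 0))
  tracts <- trackFromCortex(f, cortex)
  lab <- labelStreamlines(tracts, cortex)
  # tracks traverse the whole x extent; the low-x endpoint maps to voxel 0
  # (label 7); every track is emitted with label 7
  expect_true(all(streamlineLabels(lab) == 7L))
  expect_equal(nDropped(lab), 0L)
  # reversing the field direction leaves labeling unchanged (axial)
  fNeg <- directionField(-methods::slot(f, "directions"),
                         methods::slot(f, "mask"))
  lab2 <- labelStreamlines(trackFromCortex(fNeg, cortex), cortex)
  expect_equal(sort(streamlineLabels(lab2)), sort(streamlineLabels(lab)))
})

test_that("axis-aligned voxelization enumerates traversed voxels", {
  wm <- allWM(c(6, 6, 6))
  s <- rbind(c(1, 2, 2), c(4, 2, 2))
  vox <- voxelizeStreamline(s, wm)
  expect_equal(vox[order(vox[, 1]), ],
               cbind(1:4, rep(2L, 4), rep(2L, 4)), ignore_attr = TRUE)
  # empty mask excludes everything
  none <- voxelizeStreamline(s, maskVolume(array(0L, c(6, 6, 6))))
  expect_equal(nrow(none), 0L)
})

test_that("voxelization agrees with the exact segment-box oracle", {
  shape <- c(8, 8, 8)
  wm <- allWM(shape)
  set.seed(7)
  for (trial in 1:25) {
    n <- sample(2:5, 1)
    s <- cbind(runif(n, 0.2, 6.8), runif(n, 0.2, 6.8), runif(n, 0.2, 6.8))
    # sampling at sub-step h can only miss voxels whose chord is shorter
    # than h; check that guarantee at the default and at a fine sub-step,
    # and that no voxel outside the true traversal set is ever reported
    for (h in c(0.25, 0.05)) {
      got <- voxelizeStreamline(s, wm, substep = h)
      keyG <- apply(got, 1, paste, collapse = ",")
      keyMust <- apply(exactTraversalOracle(s, shape, minLen = h), 1,
                       paste, collapse = ",")
      keyMay <- apply(exactTraversalOracle(s, shape, minLen = 0), 1,
                      paste, collapse = ",")
      expect_true(all(keyMust %in% keyG))
      expect_true(all(keyG %in% keyMay))
    }
  }
})

test_that("out-of-bounds samples are skipped silently", {
  wm <- allWM(c(4, 4, 4))
  s <- rbind(c(-2, 1, 1), c(2, 1, 1))
  vox <- voxelizeStreamline(s, wm)
  expect_true(all(vox[, 1] >= 0))
  expect_true(all(vox[, 1] <= 2))
})

test_that("candidate counts accumulate one count per streamline per voxel", {
  shape <- c(6, 6, 6)
  wm <- allWM(shape)
  mk <- function(pts, label) {
    new("LabeledTractogram", streamlines = pts, shape = as.integer(shape),
        affine = diag(4), labels = as.integer(label))
  }
  one <- mk(list(rbind(c(1, 2, 2), c(3, 2, 2))), 7L)
  cand <- populateCandidates(one, wm, labelList = c(7L, 9L))
  expect_equal(unname(candidateCounts(cand, c(1, 2, 2))), c(1, 0))
  expect_equal(unname(candidateCounts(cand, c(2, 2, 2))), c(1, 0))
  expect_equal(unname(candidateCounts(cand, c(3, 2, 2))), c(1, 0))
  expect_equal(sum(methods::slot(cand, "counts")), 3)

  # two streamlines of different labels crossing one voxel
  two <- mk(list(rbind(c(0, 2, 2), c(4, 2, 2)),
                 rbind(c(2, 0, 2), c(2, 4, 2))), c(7L, 9L))
  cand2 <- populateCandidates(two, wm, labelList = c(7L, 9L))
  expect_equal(unname(candidateCounts(cand2, c(2, 2, 2))), c(1, 1))

  # a U-shaped streamline re-entering a voxel counts once...
  u <- mk(list(rbind(c(1, 1, 1), c(4, 1, 1), c(4, 3, 1), c(1, 3, 1),
               c(1, 1.4, 1))), 7L)
  cand3 <- populateCandidates(u, wm, labelList = 7L)
  expect_equal(unname(candidateCounts(cand3, c(1, 1, 1))), 1)
  # ...unless traversal counting is requested
  cand4 <- populateCandidates(u, wm, labelList = 7L,
                              countTraversals = TRUE)
  expect_equal(unname(candidateCounts(cand4, c(1, 1, 1))), 2)
})

test_that("unknown streamline labels are a configuration error", {
  wm <- allWM(c(4, 4, 4))
  lt <- new("LabeledTractogram",
            streamlines = list(rbind(c(1, 1, 1), c(2, 1, 1))),
            shape = c(4L, 4L, 4L), affine = diag(4), labels = 7L)
  expect_error(populateCandidates(lt, wm, labelList = c(3L, 9L)),
               "configuration error")
})

test_that("count mass is conserved and counts are monotone in streamlines", {
  shape <- c(10, 10, 10)
  wm0 <- array(1L, shape); wm0[, 6:10, ] <- 0L    # half-masked volume
  wm <- maskVolume(wm0)
  set.seed(11)
  pts <- lapply(1:12, function(i) {
    n <- sample(2:6, 1)
    cbind(runif(n, 0, 9), runif(n, 0, 9), runif(n, 0, 9))
  })
  labs <- sample(c(7L, 9L, 12L), 12, replace = TRUE)
  lt <- new("LabeledTractogram", streamlines = pts,
            shape = as.integer(shape), affine = diag(4), labels = labs)
  cand <- populateCandidates(lt, wm, labelList = c(7L, 9L, 12L))
  perStream <- vapply(pts, function(s)
    nrow(voxelizeStreamline(s, wm)), integer(1))
  expect_equal(sum(methods::slot(cand, "counts")), sum(perStream))

  # nonzero counts only inside the mask (also enforced by class validity)
  expect_true(validObject(cand))

  # adding a streamline never decreases any count
  lt2 <- new("LabeledTractogram", streamlines = c(pts, pts[1]),
             shape = as.integer(shape), affine = diag(4),
             labels = c(labs, labs[1]))
  cand2 <- populateCandidates(lt2, wm, labelList = c(7L, 9L, 12L))
  expect_true(all(methods::slot(cand2, "counts") -
                  methods::slot(cand, "counts") >= 0))
})

test_that("relabeling cortex regions permutes count columns identically", {
  shape <- c(8, 8, 8)
  wm <- allWM(shape)
  set.seed(3)
  pts <- lapply(1:8, function(i)
    cbind(runif(3, 0, 7), runif(3, 0, 7), runif(3, 0, 7)))
  labs <- sample(c(2L, 5L, 8L), 8, replace = TRUE)
  perm <- c(`2` = 8L, `5` = 2L, `8` = 5L)    # bijection on labels
  lt <- new("LabeledTractogram", streamlines = pts,
            shape = as.integer(shape), affine = diag(4), labels = labs)
  ltP <- new("LabeledTractogram", streamlines = pts,
             shape = as.integer(shape), affine = diag(4),
             labels = unname(perm[as.character(labs)]))
  cand <- populateCandidates(lt, wm, labelList = c(2L, 5L, 8L))
  candP <- populateCandidates(ltP, wm, labelList = c(2L, 5L, 8L))
  # column of original label l equals column of perm(l)
  for (l in c(2L, 5L, 8L)) {
    a <- methods::slot(cand, "counts")[, match(l, candidateLabels(cand))]
    b <- methods::slot(candP, "counts")[, match(perm[[as.character(l)]],
                                                candidateLabels(candP))]
    expect_equal(a, b)
  }
})
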