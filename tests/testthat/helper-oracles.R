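# Independent oracles used across the suite. These deliberately share no
# code with the package: naive loops and closed forms only.

# Random candidate image on an all-WM grid. Returns both the package
# container and the raw dense count array the oracles consume, so oracle
# computations never touch package internals.
randomCandidateImage <- function(shape, labels, seed, density = 0.6,
                                 maxCount = 9L) {
  set.seed(seed)
  nv <- prod(shape)
  nl <- length(labels)
  arr <- array(0L, c(shape, nl))
  filled <- runif(nv) < density
  for (v in which(filled)) {
    k <- sample.int(nl, 1L)
    which_ <- sample.int(nl, k)
    idx <- arrayInd(v, shape)
    arr[idx[1], idx[2], idx[3], which_] <- sample.int(maxCount, k,
                                                      replace = TRUE)
  }
  cnt <- matrix(arr, nrow = nv, ncol = nl)
  sm <- Matrix::Matrix(cnt, sparse = TRUE)
  mask <- maskVolume(array(1L, shape))
  cand <- new("CandidateImage", shape = as.integer(shape),
              labels = as.integer(labels),
              counts = methods::as(sm, "CsparseMatrix"), wmMask = mask)
  list(cand = cand, arr = arr)
}

# Naive per-voxel triple-loop evaluation of the local/neighbor/combined
# probabilities and the argmax assignment; ties to the lowest label ID.
naiveVoteOracle <- function(arr, labels, wL, wN, wmData = NULL,
                            normalize = FALSE) {
  shape <- dim(arr)[1:3]
  nl <- dim(arr)[4]
  out <- array(0L, shape)
  offs <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in seq_len(shape[1])) for (y in seq_len(shape[2]))
    for (z in seq_len(shape[3])) {
      if (!is.null(wmData) && wmData[x, y, z] == 0L) next
      Lv <- arr[x, y, z, ]
      pL <- if (sum(Lv) > 0) Lv / sum(Lv) else numeric(nl)
      pN <- numeric(nl)
      wTot <- 0
      for (r in seq_len(nrow(offs))) {
        nx <- x + offs$x[r]; ny <- y + offs$y[r]; nz <- z + offs$z[r]
        if (nx < 1 || ny < 1 || nz < 1 || nx > shape[1] ||
            ny > shape[2] || nz > shape[3]) next
        Ln <- arr[nx, ny, nz, ]
        if (sum(Ln) == 0) next
        w <- 1 / sqrt(offs$x[r]^2 + offs$y[r]^2 + offs$z[r]^2)
        pN <- pN + w * Ln / sum(Ln)
        wTot <- wTot + w
      }
      if (normalize && wTot > 0) pN <- pN / wTot
      p <- wL * pL + wN * pN
      if (max(p) > 0) {
        best <- which(p == max(p))
        out[x, y, z] <- labels[min(best)]   # labels sorted ascending
      }
    }
  out
}

# Exact segment-box intersection length of segment a->b with the voxel
# box [v - 0.5, v + 0.5) per axis (slab clipping).
segmentBoxLength <- function(a, b, v) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) return(0)
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    lo <- v[ax] - 0.5; hi <- v[ax] + 0.5
    if (abs(d[ax]) < 1e-12) {
      if (a[ax] < lo || a[ax] > hi) return(0)
    } else {
      ta <- (lo - a[ax]) / d[ax]; tb <- (hi - a[ax]) / d[ax]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 >= t1) return(0)
    }
  }
  (t1 - t0) * len
}

# All voxels of `shape` whose exact intersection length with the polyline
# exceeds `minLen` voxels.
exactTraversalOracle <- function(s, shape, minLen = 0) {
  hits <- new.env()
  for (i in seq_len(nrow(s) - 1L)) {
    a <- s[i, ]; b <- s[i + 1L, ]
    lo <- pmax(0L, floor(pmin(a, b) - 0.5))
    hi <- pmin(shape - 1L, ceiling(pmax(a, b) + 0.5))
    for (x in lo[1]:hi[1]) for (y in lo[2]:hi[2]) for (z in lo[3]:hi[3]) {
      key <- paste(x, y, z)
      prev <- if (is.null(hits[[key]])) 0 else hits[[key]]
      hits[[key]] <- prev + segmentBoxLength(a, b, c(x, y, z))
    }
  }
  keys <- ls(hits)
  keep <- keys[vapply(keys, function(k) hits[[k]] > minLen, logical(1))]
  if (length(keep) == 0L) return(matrix(integer(0), ncol = 3))
  m <- do.call(rbind, lapply(strsplit(keep, " "), as.integer))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Dense fixed-small-step integration of a direction field from a seed:
# the reference curve FACT tracks should approximate.
denseIntegrationOracle <- function(field, seed, h = 0.01, nmax = 2e5) {
  dirs <- methods::slot(field, "directions")
  mask <- volumeData(methods::slot(field, "mask"))
  sh <- dim(mask)
  runHalf <- function(d0) {
    pos <- seed; dprev <- d0
    out <- list()
    for (i in seq_len(nmax)) {
      v <- floor(pos + 0.5)
      if (any(v < 0 | v >= sh)) break
      if (mask[v[1] + 1, v[2] + 1, v[3] + 1] == 0) break
      d <- dirs[v[1] + 1, v[2] + 1, v[3] + 1, ]
      if (all(d == 0)) break
      if (sum(d * dprev) < 0) d <- -d
      pos <- pos + h * d
      dprev <- d
      out[[length(out) + 1L]] <- pos
    }
    out
  }
  v0 <- floor(seed + 0.5)
  d0 <- dirs[v0[1] + 1, v0[2] + 1, v0[3] + 1, ]
  do.call(rbind, c(rev(runHalf(-d0)), list(seed), runHalf(d0)))
}

# Brute-force nearest-cortex labeling: per-WM-voxel loop over every
# cortex voxel, mm distances, ties to the lowest label ID.
bruteNearestOracle <- function(cortex, wmMask) {
  cd <- volumeData(cortex); wd <- volumeData(wmMask)
  vs <- voxelSize(cortex)
  cIdx <- which(cd > 0L, arr.ind = TRUE)
  out <- array(0L, dim(cd))
  for (v in which(wd != 0L)) {
    idx <- arrayInd(v, dim(wd))
    d2 <- ((cIdx[, 1] - idx[1]) * vs[1])^2 +
          ((cIdx[, 2] - idx[2]) * vs[2])^2 +
          ((cIdx[, 3] - idx[3]) * vs[3])^2
    cands <- which(d2 <= min(d2) + 1e-9)
    out[idx] <- min(cd[cIdx[cands, , drop = FALSE]])
  }
  out
}

# Uniform direction field on a cuboid grid, all voxels tracking-enabled.
uniformField <- function(shape, dir) {
  dir <- dir / sqrt(sum(dir^2))
  dirs <- array(0, c(shape, 3))
  for (ax in 1:3) dirs[, , , ax] <- dir[ax]
  directionField(dirs, maskVolume(array(1L, shape)))
}
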