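# Internal coordinate helpers. Convention everywhere: 0-based voxel
# indices, voxel centers at integer coordinates, so voxel (i,j,k) covers
# the half-open box [i-0.5, i+0.5) x ... per axis.

# points: n x 3 continuous positions -> n x 3 integer voxel indices
.voxelOf <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  matrix(as.integer(floor(points + 0.5)), ncol = 3)
}

# n x 3 0-based voxel indices -> 1-based linear row index into a
# prod(shape)-row matrix (column-major, x fastest)
.linearIndex <- function(vox, shape) {
  1L + vox[, 1] + shape[1] * (vox[, 2] + shape[2] * vox[, 3])
}

.inBounds <- function(vox, shape) {
  vox[, 1] >= 0L & vox[, 1] < shape[1] &
  vox[, 2] >= 0L & vox[, 2] < shape[2] &
  vox[, 3] >= 0L & vox[, 3] < shape[3]
}

.sameSpace <- function(affA, affB, tol = 1e-4) {
  max(abs(affA - affB)) <= tol
}

.checkSameSpace <- function(a, b, what = "inputs") {
  if (!identical(as.integer(volumeShape(a)), as.integer(volumeShape(b))))
    stop("space error: ", what, " have different grid shapes", call. = FALSE)
  if (!.sameSpace(volumeAffine(a), volumeAffine(b)))
    stop("space error: ", what, " have different affines", call. = FALSE)
  invisible(TRUE)
}

# One named pseudo-random stream per artifact kind, derived from a single
# integer master seed: adding a new artifact kind never shifts the draws
# of existing ones.
.streamSeed <- function(seed, kind) {
  offsets <- c(directions = 101L, counts = 211L, noise = 307L,
               geometry = 401L, fixture = 503L, acceptance = 601L)
  off <- offsets[[kind]]
  (as.integer(seed) * 1009L + off) %% 2147483629L
}

.withStream <- function(seed, kind, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.streamSeed(seed, kind))
  expr
}
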