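# Independent brute-force oracles used to validate package algorithms.
# These are deliberately naive (enumeration over pairs, planes, lattice
# points) and share no code with the implementations they check.

# AUROC by explicit positive/negative pair counting, ties worth 1/2
brutePairAuroc <- function(scores, labels, positive = "SG2") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}

# lattice points inside the convex hull of `coords` by the half-space
# definition: a grid point is outside iff some plane through three of the
# points has every point on one side and the grid point strictly beyond.
# Before the O(m^3) plane enumeration the set is reduced to points that
# are min/max along some axis-parallel line through the set: a hull vertex
# v cannot have object points both directly above and below it on any
# axis line (it would be a convex combination of them), so every hull
# vertex survives and the hull — hence the count — is unchanged.
bruteReduce3 <- function(coords) {
  keep <- rep(FALSE, nrow(coords))
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    key <- coords[, others[1]] * 8192 + coords[, others[2]]
    for (f in list(min, max)) {
      agg <- tapply(coords[, ax], key, f)
      keep <- keep | (coords[, ax] == agg[as.character(key)])
    }
  }
  coords[keep, , drop = FALSE]
}

bruteConvexCount3 <- function(coords) {
  coords <- unique(round(as.matrix(coords)))
  coords <- bruteReduce3(coords)
  m <- nrow(coords)
  if (m < 3L) return(m)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  grid <- as.matrix(expand.grid(seq(lo[1], hi[1]), seq(lo[2], hi[2]),
                                seq(lo[3], hi[3])))
  out <- rep(FALSE, nrow(grid))
  for (i in 1:(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
    u <- coords[j, ] - coords[i, ]
    v <- coords[k, ] - coords[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    if (all(nrm == 0)) next
    d <- sum(nrm * coords[i, ])
    side <- as.vector(coords %*% nrm) - d
    if (all(side <= 0)) out <- out | (as.vector(grid %*% nrm) - d > 0)
    else if (all(side >= 0)) out <- out | (as.vector(grid %*% nrm) - d < 0)
  }
  sum(!out)
}

# 2D analogue: pixel centers inside the hull polygon by all-pairs edges
bruteConvexCount2 <- function(coords) {
  coords <- unique(round(as.matrix(coords)))
  m <- nrow(coords)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  grid <- as.matrix(expand.grid(seq(lo[1], hi[1]), seq(lo[2], hi[2])))
  out <- rep(FALSE, nrow(grid))
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    e <- coords[j, ] - coords[i, ]
    if (all(e == 0)) next
    side <- e[1] * (coords[, 2] - coords[i, 2]) -
            e[2] * (coords[, 1] - coords[i, 1])
    gp <- e[1] * (grid[, 2] - coords[i, 2]) -
          e[2] * (grid[, 1] - coords[i, 1])
    if (all(side <= 0)) out <- out | (gp > 0)
    else if (all(side >= 0)) out <- out | (gp < 0)
  }
  sum(!out)
}

# exact quarter-turn in-plane rotation by index permutation, in the
# package's convention (positive angles move the +x axis toward +y in
# array index order): output pixel (y, x) <- input pixel (Y + 1 - x, y),
# applied identically to every Z-plane
rot90Oracle <- function(vol) {
  d <- dim(vol)
  stopifnot(d[2] == d[3])  # square planes rotate onto the same grid
  out <- array(0, d)
  n <- d[2]
  for (y in seq_len(n)) for (x in seq_len(n))
    out[, y, x] <- vol[, n + 1 - x, y]
  out
}

# random concave voxel blob: union of a few balls minus one bite (kept
# small so the O(m^3) brute-force oracle stays fast)
randomBlobCoords <- function(seed, size = 10L) {
  set.seed(seed)
  grid <- as.matrix(expand.grid(1:size, 1:size, 1:size))
  keep <- rep(FALSE, nrow(grid))
  for (b in 1:3) {
    ctr <- runif(3, 3.5, size - 2.5)
    r <- runif(1, 2, 3.2)
    keep <- keep | rowSums(sweep(grid, 2, ctr)^2) <= r^2
  }
  bite <- runif(3, 3, size - 2)
  keep <- keep & rowSums(sweep(grid, 2, bite)^2) > 2.2^2
  grid[keep, , drop = FALSE]
}
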