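# SO(3) machinery.  Rotations are represented as unit quaternions
# (w, x, y, z), canonicalized to the hemisphere w >= 0 (ties at w = 0 broken
# by the first nonzero coordinate > 0); q and -q denote the same rotation.
# Composition follows R(a %then% b) = R(a) %*% R(b).

#' Canonicalize a quaternion to the w >= 0 hemisphere and unit norm
#'
#' @param q numeric length-4 quaternion or n x 4 matrix.
#' @return same shape, unit rows, first nonzero component positive.
#' @export
canonicalizeQuat <- function(q) {
  if (is.matrix(q)) {
    q <- q / sqrt(rowSums(q^2))
    nz <- (abs(q) > 1e-12) + 0
    idx <- max.col(nz, ties.method = "first")
    s <- sign(q[cbind(seq_len(nrow(q)), idx)])
    q * s
  } else {
    q <- q / sqrt(sum(q^2))
    i <- which(abs(q) > 1e-12)[1]
    if (q[i] < 0) q <- -q
    q
  }
}

#' Identity rotation
#' @return the identity unit quaternion.
#' @export
identityRotation <- function() c(1, 0, 0, 0)

#' Rotation about an axis by an angle
#'
#' @param axis 3-vector (normalized internally).
#' @param angle rotation angle in radians.
#' @return unit quaternion.
#' @export
axisAngle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  canonicalizeQuat(c(cos(angle / 2), sin(angle / 2) * axis))
}

#' Compose two rotations
#'
#' Quaternion product; \code{R(compose(a, b)) = R(a) R(b)}.
#'
#' @param a,b unit quaternions.
#' @return the canonicalized product quaternion.
#' @export
composeRotations <- function(a, b) {
  canonicalizeQuat(quatMultiply(a, b))
}

# raw (non-canonicalized) Hamilton product; a, b length-4 or n x 4
quatMultiply <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- if (is.matrix(a)) a else matrix(a, 1)
    b <- if (is.matrix(b)) b else matrix(b, 1)
    n <- max(nrow(a), nrow(b))
    if (nrow(a) == 1L) a <- a[rep(1L, n), , drop = FALSE]
    if (nrow(b) == 1L) b <- b[rep(1L, n), , drop = FALSE]
    cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
          a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
          a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
          a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1],
          deparse.level = 0)
  } else {
    c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
      a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
      a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
      a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
  }
}

#' Inverse rotation
#' @param q unit quaternion.
#' @return the conjugate quaternion, canonicalized.
#' @export
invertRotation <- function(q) canonicalizeQuat(c(q[1], -q[2:4]))

#' Quaternion to rotation matrix
#' @param q unit quaternion.
#' @return 3 x 3 rotation matrix.
#' @export
quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Geodesic angle between two rotations on SO(3)
#'
#' The rotation angle of \eqn{a^{-1} b}, computed as
#' \eqn{2\arccos|\langle q_a, q_b\rangle|}; a bi-invariant metric with
#' range \eqn{[0, \pi]}.
#'
#' @param a,b unit quaternions (length 4) or n x 4 matrices (rowwise,
#'   recycled).
#' @return angle(s) in radians.
#' @export
geodesicAngle <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- if (is.matrix(a)) a else matrix(a, 1)
    b <- if (is.matrix(b)) b else matrix(b, 1)
    n <- max(nrow(a), nrow(b))
    if (nrow(a) == 1L) a <- a[rep(1L, n), , drop = FALSE]
    if (nrow(b) == 1L) b <- b[rep(1L, n), , drop = FALSE]
    d <- abs(rowSums(a * b))
  } else {
    d <- abs(sum(a * b))
  }
  2 * acos(pmin(1, d))
}

#' Uniform random rotations on SO(3)
#'
#' Quaternions drawn uniformly on the 3-sphere (4 standard normals,
#' normalized), canonicalized.
#'
#' @param n number of rotations.
#' @return n x 4 matrix of unit quaternions.
#' @export
randomRotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  canonicalizeQuat(q)
}

#' Construct a finite symmetry group
#'
#' \code{"C1"} is the trivial group; \code{"C2"} the two-fold rotation
#' group about \code{axis}; \code{"friedel_z"} the order-2 group
#' \{identity, pi about the beam (z) axis\} that absorbs the Friedel
#' ambiguity of flat-Ewald diffraction patterns.
#'
#' @param name one of \code{"C1"}, \code{"C2"}, \code{"friedel_z"}.
#' @param axis rotation axis (default z); ignored for C1 and friedel_z.
#' @return a \linkS4class{SymmetryGroup}.
#' @export
makeGroup <- function(name = c("C1", "C2", "friedel_z"), axis = c(0, 0, 1)) {
  name <- match.arg(name)
  axis <- axis / sqrt(sum(axis^2))
  el <- switch(name,
    C1 = matrix(identityRotation(), 1),
    C2 = rbind(identityRotation(), axisAngle(axis, pi)),
    friedel_z = rbind(identityRotation(), axisAngle(c(0, 0, 1), pi)))
  new("SymmetryGroup", name = name, elements = el)
}

#' Symmetry-quotient rotation distance
#'
#' Distance on the quotient of SO(3) by the particle point group \code{s}
#' (acting on the left) and the Friedel group \code{z} (acting on the
#' right): the minimum over all group elements of
#' \eqn{\theta(\sigma\, a\, \zeta,\; b)}.  Never exceeds
#' \code{geodesicAngle(a, b)}.
#'
#' @param a,b unit quaternions.
#' @param s point group of the object (a \linkS4class{SymmetryGroup}).
#' @param z Friedel group (a \linkS4class{SymmetryGroup}).
#' @return quotient angle in radians.
#' @export
quotientAngle <- function(a, b, s = makeGroup("C1"), z = makeGroup("C1")) {
  stopifnot(is(s, "SymmetryGroup"), is(z, "SymmetryGroup"))
  if (nrow(s@elements) < 1L || nrow(z@elements) < 1L) stop("empty group")
  best <- Inf
  for (i in seq_len(nrow(s@elements)))
    for (j in seq_len(nrow(z@elements))) {
      cand <- quatMultiply(quatMultiply(s@elements[i, ], a), z@elements[j, ])
      best <- min(best, geodesicAngle(cand, b))
    }
  best
}

# ---------------------------------------------------------------------------
# 600-cell based SO(3) quadrature sampling
#
# The 120 vertices of the 600-cell are unit quaternions; its 600 tetrahedral
# cells triangulate the 3-sphere.  At refinement level n each cell is
# subdivided into n^3 sub-simplices on the barycentric lattice (Kuhn
# triangulation), sample points are projected to the sphere and antipodes
# identified, giving exactly 10(5 n^3 + n) rotation samples.  Coordinates of
# all lattice points are exact elements of Z[sqrt(5)]/4, so the antipodal and
# shared-point identification is performed in exact integer arithmetic.
# ---------------------------------------------------------------------------

.rotCache <- new.env(parent = emptyenv())

# 120 vertices as integer pairs (A, B): coordinate = (A + B*sqrt(5)) / 4
.cell600Vertices <- function() {
  if (!is.null(.rotCache$verts)) return(.rotCache$verts)
  evenPerms <- list(c(1, 2, 3, 4), c(1, 3, 4, 2), c(1, 4, 2, 3),
                    c(2, 1, 4, 3), c(2, 3, 1, 4), c(2, 4, 3, 1),
                    c(3, 1, 2, 4), c(3, 2, 4, 1), c(3, 4, 1, 2),
                    c(4, 1, 3, 2), c(4, 2, 1, 3), c(4, 3, 2, 1))
  A <- NULL; B <- NULL
  # (+-1, 0, 0, 0) and permutations
  for (i in 1:4) for (s in c(1, -1)) {
    a <- numeric(4); a[i] <- 4 * s
    A <- rbind(A, a); B <- rbind(B, numeric(4))
  }
  # (+-1/2)^4
  sg <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1), c(1, -1)))
  A <- rbind(A, 2 * sg); B <- rbind(B, matrix(0, 16, 4))
  # even permutations of (phi, 1, 1/phi, 0)/2 with free signs on the nonzeros
  baseA <- c(1, 2, -1, 0); baseB <- c(1, 0, 1, 0)
  sg3 <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  for (p in evenPerms) for (k in seq_len(nrow(sg3))) {
    s4 <- c(sg3[k, ], 1)  # the zero coordinate is unsigned
    A <- rbind(A, (baseA * s4)[order(p)])
    B <- rbind(B, (baseB * s4)[order(p)])
  }
  # order(p) places element i of the base at position p[i]
  stopifnot(nrow(A) == 120L)
  Vf <- (A + B * sqrt(5)) / 4
  stopifnot(max(abs(rowSums(Vf^2) - 1)) < 1e-12)
  .rotCache$verts <- list(A = unname(A), B = unname(B), Vf = unname(Vf))
  .rotCache$verts
}

# the 600 tetrahedral cells as vertex-index quadruples (4-cliques of the
# edge graph; adjacent vertices have dot product phi/2)
.cell600Cells <- function() {
  if (!is.null(.rotCache$cells)) return(.rotCache$cells)
  Vf <- .cell600Vertices()$Vf
  G <- Vf %*% t(Vf)
  adj <- G > 0.7 & G < 0.9
  nbr <- lapply(seq_len(120), function(i) which(adj[i, ]))
  cells <- vector("list", 600); nc <- 0L
  for (i in seq_len(120)) {
    ni <- nbr[[i]][nbr[[i]] > i]
    for (j in ni) {
      cij <- intersect(ni, nbr[[j]]); cij <- cij[cij > j]
      for (k in cij) {
        ckl <- intersect(cij, nbr[[k]]); ckl <- ckl[ckl > k]
        for (l in ckl) {
          nc <- nc + 1L
          cells[[nc]] <- c(i, j, k, l)
        }
      }
    }
  }
  stopifnot(nc == 600L)
  .rotCache$cells <- do.call(rbind, cells[seq_len(nc)])
  .rotCache$cells
}

# barycentric lattice points and Kuhn sub-simplices of a tetrahedron at
# subdivision level n; returns list(lambda = C x 4 integer barycentric
# coordinates summing to n, simplex = n^3 x 4 local point indices)
.kuhnSubdivision <- function(n) {
  key <- as.character(n)
  if (!is.null(.rotCache$kuhn[[key]])) return(.rotCache$kuhn[[key]])
  lam <- as.matrix(expand.grid(l1 = 0:n, l2 = 0:n, l3 = 0:n))
  lam <- lam[rowSums(lam) <= n, , drop = FALSE]
  lam <- cbind(n - rowSums(lam), lam)
  id <- array(NA_integer_, dim = c(n + 1, n + 1, n + 1))
  id[cbind(lam[, 2] + 1L, lam[, 3] + 1L, lam[, 4] + 1L)] <- seq_len(nrow(lam))
  # Kuhn triangulation in the coordinates n >= x1 >= x2 >= x3 >= 0 with
  # lambda = (n - x1, x1 - x2, x2 - x3, x3)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  cubes <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  simplex <- NULL
  for (p in seq_len(nrow(perms))) {
    vtx <- list(cubes)
    x <- cubes
    for (step in 1:3) {
      x <- x
      x[, perms[p, step]] <- x[, perms[p, step]] + 1L
      vtx[[step + 1]] <- x
    }
    keep <- rep(TRUE, nrow(cubes))
    for (v in vtx)
      keep <- keep & v[, 1] >= v[, 2] & v[, 2] >= v[, 3]
    if (!any(keep)) next
    loc <- sapply(vtx, function(v) {
      lamv <- cbind(n - v[keep, 1], v[keep, 1] - v[keep, 2],
                    v[keep, 2] - v[keep, 3], v[keep, 3])
      id[cbind(lamv[, 2] + 1L, lamv[, 3] + 1L, lamv[, 4] + 1L)]
    })
    if (!is.matrix(loc)) loc <- matrix(loc, ncol = 4)
    simplex <- rbind(simplex, loc)
  }
  stopifnot(nrow(simplex) == n^3)
  out <- list(lambda = lam, simplex = simplex)
  if (is.null(.rotCache$kuhn)) .rotCache$kuhn <- list()
  .rotCache$kuhn[[key]] <- out
  out
}

#' Sample SO(3) by 600-cell subdivision
#'
#' Subdivides each tetrahedral cell of the 600-cell at refinement level
#' \code{level}, projects the barycentric lattice points to the unit
#' 3-sphere, identifies antipodal quaternions (exactly, in integer
#' arithmetic over \eqn{\mathbf{Z}[\sqrt 5]}), and weights each sample by
#' the summed projected volume of its incident sub-simplices.  The sample
#' count is exactly \eqn{10(5n^3 + n)}; level 16 gives the 204960 samples
#' used for production-scale orientation refinement.
#'
#' @param level positive integer refinement level (\code{num_div}).
#' @return a \linkS4class{RotationSet}.
#' @examples
#' rs <- sampleRotations(2)
#' nrow(rs@quaternions)  # 10 * (5 * 8 + 2) = 420
#' @export
sampleRotations <- function(level) {
  level <- as.integer(level)
  if (is.na(level) || level < 1L) stop("level must be a positive integer")
  ck <- sprintf("set%d", level)
  if (!is.null(.rotCache[[ck]])) return(.rotCache[[ck]])
  vt <- .cell600Vertices()
  cells <- .cell600Cells()
  sub <- .kuhnSubdivision(level)
  lam <- sub$lambda; SS <- sub$simplex
  npt <- nrow(lam)
  keyList <- vector("list", 600)
  floatList <- vector("list", 600)
  for (ci in seq_len(600)) {
    vidx <- cells[ci, ]
    PA <- lam %*% vt$A[vidx, ]
    PB <- lam %*% vt$B[vidx, ]
    # canonical antipodal representative: first nonzero coordinate positive,
    # decided exactly (A + B*sqrt(5) = 0 only when A = B = 0)
    nz <- ((PA != 0) | (PB != 0)) + 0
    fi <- max.col(nz, ties.method = "first")
    sgn <- sign(PA[cbind(seq_len(npt), fi)] +
                PB[cbind(seq_len(npt), fi)] * sqrt(5))
    PA <- PA * sgn; PB <- PB * sgn
    keyList[[ci]] <- paste(PA[, 1], PB[, 1], PA[, 2], PB[, 2],
                           PA[, 3], PB[, 3], PA[, 4], PB[, 4])
    Pf <- (PA + PB * sqrt(5)) / 4
    floatList[[ci]] <- Pf / sqrt(rowSums(Pf^2))
  }
  keys <- unlist(keyList, use.names = FALSE)
  firstPos <- !duplicated(keys)
  gid <- match(keys, keys[firstPos])
  quats <- do.call(rbind, floatList)[firstPos, , drop = FALSE]
  nsamp <- sum(firstPos)
  stopifnot(nsamp == 10 * (5 * level^3 + level))
  # quadrature weights: accumulate projected sub-simplex volumes
  W <- numeric(nsamp)
  sv <- as.vector(SS)
  for (ci in seq_len(600)) {
    Pf <- floatList[[ci]]
    v0 <- Pf[SS[, 1], , drop = FALSE]
    e1 <- Pf[SS[, 2], , drop = FALSE] - v0
    e2 <- Pf[SS[, 3], , drop = FALSE] - v0
    e3 <- Pf[SS[, 4], , drop = FALSE] - v0
    g11 <- rowSums(e1 * e1); g22 <- rowSums(e2 * e2); g33 <- rowSums(e3 * e3)
    g12 <- rowSums(e1 * e2); g13 <- rowSums(e1 * e3); g23 <- rowSums(e2 * e3)
    det <- g11 * (g22 * g33 - g23^2) - g12 * (g12 * g33 - g23 * g13) +
      g13 * (g12 * g23 - g22 * g13)
    vol <- sqrt(pmax(det, 0)) / 6
    base <- (ci - 1L) * npt
    ids <- gid[base + sv]
    tb <- rowsum(rep(vol, 4), ids)
    ii <- as.integer(rownames(tb))
    W[ii] <- W[ii] + tb[, 1]
  }
  rs <- new("RotationSet", level = level, quaternions = unname(quats),
            weights = W / sum(W))
  if (level <= 8L) .rotCache[[ck]] <- rs
  rs
}

#' Number of rotation samples at a refinement level
#'
#' Closed form \eqn{10(5n^3 + n)} for the 600-cell subdivision sampling.
#' @param level refinement level.
#' @return sample count.
#' @export
rotationSampleCount <- function(level) {
  10 * (5 * as.numeric(level)^3 + as.numeric(level))
}

setMethod("show", "RotationSet", function(object) {
  cat(sprintf("RotationSet: level %d, %d samples, weights sum %.6f\n",
              object@level, nrow(object@quaternions), sum(object@weights)))
})

setMethod("show", "SymmetryGroup", function(object) {
  cat(sprintf("SymmetryGroup %s with %d element(s)\n", object@name,
              nrow(object@elements)))
})
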