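test_that("shell R-factor obeys its scale-invariance and bound identities", {
  v <- deskTruth()
  # proportional volumes: R = 0 in every shell
  v2 <- intensityVolume(v@values * 37.5, v@dq, volumeEdge(v))
  sr <- shellRFactor(v2, v)
  expect_lt(max(sr@shells$R, na.rm = TRUE), 1e-10)
  expect_lt(max(abs(sr@regionMeans), na.rm = TRUE), 1e-10)
  expect_error(shellRFactor(v, intensityVolume(v@values[1:31, 1:31, 1:31],
                                               v@dq, 31L)), "mismatch")
})

test_that("shell R-factor reproduces the two-voxel hand example and the cap", {
  e <- 3L; dq <- 0.05
  mk <- function(vplus, vminus) {
    a <- array(0, c(e, e, e))
    a[3, 2, 2] <- vplus  # (+dq, 0, 0)
    a[1, 2, 2] <- vminus # (-dq, 0, 0)
    intensityVolume(a, dq, e)
  }
  sp <- shellSpec(edges = c(0.025, 0.075))
  r <- suppressWarnings(shellRFactor(mk(1, 4), mk(4, 1), sp))
  expect_equal(r@shells$R[1], 2 / 3, tolerance = 1e-12)
  # disjoint support inside a shell: maximal disagreement R = 2
  r2 <- suppressWarnings(shellRFactor(mk(1, 0), mk(0, 1), sp))
  expect_equal(r2@shells$R[1], 2, tolerance = 1e-12)
  # empty / zero shells are skipped with a warning
  expect_warning(shellRFactor(mk(1, 4), mk(4, 1),
                              shellSpec(edges = c(0.025, 0.075, 0.125))),
                 "skipping")
})

test_that("region means follow the low-q < high-q ordering on a toy scan", {
  g <- deskGrid(); pm <- deskPixmap()
  for (tw in c(0, 10)) {
    hyd <- addWaterShell(deskParticle(), waterShellSpec(tw, seed = 2))
    truth <- idealIntensityVolume(hyd, g$edge, g$dq)
    noisy <- intensityVolume(
      truth@values * (1 + 0.3 * stats::runif(g$edge^3)) +
        0.1 * mean(truth@values), g$dq, g$edge)
    sr <- shellRFactor(noisy, truth)
    expect_lte(sr@regionMeans["A"], sr@regionMeans["C"])
  }
})

test_that("alignment recovers a known rotation up to the sampling step", {
  v <- deskTruth()
  e <- volumeEdge(v)
  g <- fixedQuats(1, seed = 21)[1, ]
  rot <- intensityVolume(
    spiOrient:::cpp_rotate_volume(as.vector(v@values), e, g), v@dq, e)
  al <- alignToReference(rot, v)
  expect_gt(al$correlation, 0.9)
  expect_lt(geodesicAngle(al$rotation, invertRotation(g)), 0.25)
  # identity alignment
  al0 <- alignToReference(v, v)
  expect_gt(al0$correlation, 0.999)
  expect_lt(geodesicAngle(al0$rotation, identityRotation()), 0.05)
  # noisy rotated copy: the exhaustive argmax beats non-optimal candidates
  set.seed(3)
  noisy <- intensityVolume(rot@values * (1 + 0.2 * runif(e^3)), v@dq, e)
  rs <- sampleRotations(2)
  aln <- alignToReference(noisy, v, rotations = rs, refineSteps = 0L)
  c0 <- (e - 1) / 2
  gcoord <- as.matrix(expand.grid(x = seq_len(e) - 1 - c0,
                                  y = seq_len(e) - 1 - c0,
                                  z = seq_len(e) - 1 - c0))
  rad <- sqrt(rowSums(gcoord^2))
  mask <- rad > 0 & rad <= c0 - 1
  cors <- spiOrient:::cpp_align_corr(
    as.vector(noisy@values), e, gcoord[mask, ],
    sqrt(pmax(as.vector(v@values)[mask], 0)), rs@quaternions)
  expect_equal(aln$correlation, max(cors), tolerance = 1e-9)
})

test_that("pattern log-likelihood matches the Poisson closed forms", {
  pm <- deskPixmap()
  v <- deskTruth()
  r <- fixedQuats(1, seed = 23)[1, ]
  w <- slicePattern(v, r, pm)
  vph <- intensityVolume(v@values * (500 / sum(w)), v@dq, volumeEdge(v))
  wph <- slicePattern(vph, r, pm)
  # all-zero pattern
  k0 <- integer(length(wph))
  expect_equal(patternLogLik(k0, vph, r, pm), -sum(wph), tolerance = 1e-9)
  # one pixel, W = 2, K = 3: ln(8 exp(-2) / 6)
  v1 <- intensityVolume(rep(0, 27), 1, 3L)
  pm1 <- new("PixelMap", q = matrix(0, 1, 3), qmag = 0, weight = 1,
             nFast = 1L, nSlow = 1L, wavelength = 2.5)
  v1@values[2, 2, 2] <- 2
  expect_equal(patternLogLik(3L, v1, identityRotation(), pm1),
               log(8 * exp(-2) / 6), tolerance = 1e-9)
  expect_equal(log(8 * exp(-2) / 6), -1.7123, tolerance = 1e-4)
  # Poisson scale identity
  k <- simulatePattern(v, r, pm, 400, seed = 2)$counts
  cc <- 2.5
  vs <- intensityVolume(vph@values * cc, v@dq, volumeEdge(v))
  expect_equal(patternLogLik(k, vs, r, pm) - patternLogLik(k, vph, r, pm),
               sum(k) * log(cc) - (cc - 1) * sum(wph), tolerance = 1e-6)
  expect_error(patternLogLik(c(-1L), v1, identityRotation(), pm1), "negative")
})

test_that("orientation posteriors are normalized and concentrate", {
  pm <- deskPixmap()
  v <- deskTruth()
  rs <- sampleRotations(4)
  z <- makeGroup("friedel_z")
  # uninformative (constant) volume: posterior equals the quadrature weights
  iso <- intensityVolume(rep(1, volumeEdge(v)^3), v@dq, volumeEdge(v))
  k <- simulatePattern(v, fixedQuats(1, seed = 30)[1, ], pm, 500, seed = 1)$counts
  pIso <- orientationPosterior(k, iso, rs, pm, epsilon = 0)
  expect_lt(max(abs(pIso$full - rs@weights) / rs@weights), 1e-9)
  expect_equal(sum(pIso$full), 1, tolerance = 1e-10)
  # photon-rich pattern: mass within one sampling step of the truth (up to z)
  ps <- generateDataset(v, 4, pm, meanPhotons = 1e5, seed = 33)
  K <- patternCounts(ps); ori <- trueOrientations(ps)
  step <- 0.35  # level-4 nearest-neighbour spacing
  for (d in 1:4) {
    post <- orientationPosterior(K[, d], v, rs, pm)
    expect_equal(sum(post$full), 1, tolerance = 1e-10)
    qsup <- rs@quaternions[post$index, , drop = FALSE]
    dd <- vapply(seq_len(nrow(qsup)), function(i)
      quotientAngle(qsup[i, ], ori[d, ], z = z), numeric(1))
    expect_gte(sum(post$prob[dd <= step]), 0.99)
  }
})

test_that("theta_sq matches hand expansions and full summation", {
  pm <- deskPixmap()
  v <- deskTruth()
  rs <- sampleRotations(3)
  s <- makeGroup("C1"); z <- makeGroup("friedel_z")
  # coincident delta posteriors -> 0
  qa <- rs@quaternions[100, ]
  th0 <- spiOrient:::cpp_theta_sq(matrix(identityRotation(), 1),
                                  matrix(qa, 1), 1, c(0L, 1L),
                                  matrix(qa, 1), 1, c(0L, 1L),
                                  s@elements, z@elements)
  expect_equal(th0[1, 1], 0)
  # half/half posteriors separated by phi -> phi^2 / 2
  phi <- 0.8
  qb <- composeRotations(qa, axisAngle(c(0, 1, 0), phi))
  th <- spiOrient:::cpp_theta_sq(matrix(identityRotation(), 1),
                                 rbind(qa, qb), c(0.5, 0.5), c(0L, 2L),
                                 rbind(qa, qb), c(0.5, 0.5), c(0L, 2L),
                                 makeGroup("C1")@elements,
                                 makeGroup("C1")@elements)
  expect_equal(th[1, 1], phi^2 / 2, tolerance = 1e-9)
  # truncated vs exhaustive summation
  k <- simulatePattern(v, fixedQuats(1, seed = 35)[1, ], pm, 100, seed = 3)$counts
  tEps <- thetaSq(k, v, v, rotations = rs, s = s, z = z, pixmap = pm,
                  epsilon = 1e-6)
  tFull <- thetaSq(k, v, v, rotations = rs, s = s, z = z, pixmap = pm,
                   epsilon = 0)
  expect_lt(abs(tEps - tFull) / max(tFull, 1e-12), 1e-3)
})

test_that("self-OD vanishes for delta-concentrated decoding", {
  pm <- deskPixmap()
  v <- deskTruth()
  sent <- generateDataset(v, 10, pm, meanPhotons = 1e5, seed = 37,
                          role = "sentinel")
  od <- disconcurrence(v, sentinels = sent,
                       config = odConfig(level = 4L, refineSteps = 1L))
  # photon-rich decoding is grid-limited: delta-theta well below one step
  expect_lt(od@deltaTheta, 0.25)
  expect_equal(length(od@perSentinelTheta), 10L)
  expect_error(disconcurrence(v, sentinels = sent[, 0]), "empty|subscript")
})

test_that("the OD minimization absorbs a global rotation of the volume", {
  pm <- deskPixmap()
  v <- deskTruth()
  e <- volumeEdge(v)
  sent <- generateDataset(v, 25, pm, meanPhotons = 2000, seed = 39,
                          role = "sentinel")
  cfg <- odConfig(level = 4L)
  od1 <- disconcurrence(v, sentinels = sent, config = cfg)
  g <- fixedQuats(1, seed = 41)[1, ]
  rot <- intensityVolume(
    spiOrient:::cpp_rotate_volume(as.vector(v@values), e, g), v@dq, e)
  od2 <- disconcurrence(rot, sentinels = sent, config = cfg)
  # invariance within one rotation-sampling step
  expect_lt(abs(od1@deltaTheta - od2@deltaTheta), 0.35)
})

test_that("declaring a C2 symmetry never hurts a C2-symmetric volume", {
  pm <- deskPixmap()
  g <- deskGrid()
  sym <- makeToyParticle(20, 25, seed = 3, symmetrize = TRUE)
  v <- idealIntensityVolume(sym, g$edge, g$dq)
  sent <- generateDataset(v, 20, pm, meanPhotons = 2000, seed = 43,
                          role = "sentinel")
  odC1 <- disconcurrence(v, sentinels = sent, config = odConfig(level = 4L))
  odC2 <- disconcurrence(v, sentinels = sent,
                         config = odConfig(level = 4L,
                                           pointGroup = makeGroup("C2")))
  expect_lte(odC2@deltaTheta, odC1@deltaTheta + 0.05)
})

test_that("sentinel leakage is caught by provenance tags", {
  pm <- deskPixmap()
  v <- deskTruth()
  ps <- generateDataset(v, 30, pm, meanPhotons = 500, seed = 45)
  cfg <- emcConfigDesk(mainIterations = 1L, finalIterations = 1L,
                       numDivStart = 2L, numDivCap = 2L)
  state <- runEMC(ps, cfg)
  expect_error(disconcurrence(state@volume, sentinels = ps,
                              config = odConfig(level = 2L)), "overlap")
  expect_warning(
    disconcurrence(state@volume, sentinels = ps,
                   config = odConfig(level = 2L), override = TRUE),
    "overlap")
})
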