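test_that("the annealing schedule follows the production recipe", {
  cfg <- emcConfig()  # production defaults
  sch <- emcSchedule(cfg)
  expect_equal(sch$beta[1], 0.01)
  expect_equal(sch$numDiv[1], 5L)
  expect_equal(sch$beta[11], 0.015)
  expect_equal(sch$numDiv[11], 6L)
  expect_equal(nrow(sch), 130L)
  fin <- sch[sch$phase == "final", ]
  expect_equal(nrow(fin), 10L)
  expect_true(all(fin$beta == 1))
  expect_true(all(fin$numDiv == 16L))
  # the level never exceeds the cap despite the +1-per-period arithmetic
  expect_lte(max(sch$numDiv), 16L)
  expect_error(emcConfig(betaStart = 0))
})

test_that("expand produces per-rotation Ewald slices of the model", {
  pm <- deskPixmap()
  g <- deskGrid()
  rs <- sampleRotations(2)
  # constant W: every tomogram identical
  vc <- intensityVolume(rep(2, g$edge^3), g$dq, g$edge)
  tomo <- expandVolume(vc, rs, pm)
  expect_lt(max(abs(tomo - 2)), 1e-9)
  # radial W: tomograms equal across rotations up to interpolation error
  qm <- volumeQmag(deskTruth())
  vr <- intensityVolume(exp(-(qm / 0.08)^2), g$dq, g$edge)
  tomo <- expandVolume(vr, rs, pm)
  spread <- apply(tomo, 1, function(x) diff(range(x)))
  expect_lt(max(spread) / max(tomo), 0.02)
  # identity tomogram is the direct slice
  v <- deskTruth()
  expect_equal(expandVolume(v, matrix(identityRotation(), 1), pm)[, 1],
               slicePattern(v, identityRotation(), pm), tolerance = 1e-12)
  # equivariance under resampling (smooth anisotropic model: an off-centre
  # Gaussian blob a few voxels wide, so interpolation error stays small)
  r <- fixedQuats(1, seed = 6)[1, ]
  e <- g$edge; c0 <- (e - 1) / 2
  ax <- (seq_len(e) - 1 - c0) * g$dq
  gr <- expand.grid(x = ax, y = ax, z = ax)
  blob <- exp(-((gr$x - 0.05)^2 + gr$y^2 + (gr$z + 0.03)^2) / (4 * g$dq)^2) +
    exp(-(gr$x^2 + (gr$y + 0.06)^2 + gr$z^2) / (5 * g$dq)^2)
  vb <- intensityVolume(array(blob, c(e, e, e)), g$dq, e)
  # rotate(v, g) samples v at R(g)^T x, so its slice at orientation g is
  # the identity slice of v
  vrot <- intensityVolume(
    spiOrient:::cpp_rotate_volume(as.vector(vb@values), e, r), g$dq, e)
  t1 <- expandVolume(vrot, matrix(r, 1), pm)[, 1]
  t0 <- expandVolume(vb, matrix(identityRotation(), 1), pm)[, 1]
  expect_lt(sqrt(mean((t1 - t0)^2)) / sqrt(mean(t0^2)), 0.05)
})

test_that("maximize reduces to the tempering and degenerate limits", {
  pm <- deskPixmap()
  rs <- sampleRotations(2)
  ps <- generateDataset(deskTruth(), 20, pm, meanPhotons = 300, seed = 31)
  tomo <- expandVolume(deskTruth(), rs, pm)
  tomo <- tomo * (300 / mean(colSums(tomo)))
  # beta -> 0+: responsibilities approach the rotation weights
  mx <- maximizeStep(tomo, ps, beta = 1e-9, weights = rs@weights)
  expect_lt(max(abs(mx$responsibilities -
                    matrix(rs@weights, nrow(rs@quaternions), 20))), 1e-5)
  # single available rotation: responsibilities 1, update = mean pattern
  one <- tomo[, 1, drop = FALSE]
  mx1 <- maximizeStep(one, ps, beta = 1, weights = 1)
  expect_equal(as.vector(mx1$responsibilities), rep(1, 20))
  expect_equal(mx1$tomograms[, 1],
               as.vector(Matrix::rowMeans(patternCounts(ps))),
               tolerance = 1e-6)
  expect_error(maximizeStep(tomo, ps, beta = 0, weights = rs@weights))
})

test_that("compress is the scatter-adjoint of expand", {
  pm <- deskPixmap()
  g <- deskGrid()
  rs <- sampleRotations(4)
  # constant tomograms deposit a constant on supported voxels
  tomoC <- matrix(3, nrow(pm@q), 50)
  vc <- compressTomograms(tomoC, rs@quaternions[1:50, ], pm, g$dq, g$edge)
  touched <- vc@values > 0
  expect_gt(sum(touched), 0)
  expect_lt(max(abs(vc@values[touched] - 3)), 1e-9)
  # linearity over disjoint supports
  t1 <- matrix(0, nrow(pm@q), 2); t1[10, 1] <- 5
  t2 <- matrix(0, nrow(pm@q), 2); t2[500, 2] <- 7
  q2 <- rs@quaternions[1:2, ]
  va <- compressTomograms(t1, q2, pm, g$dq, g$edge)@values
  vb <- compressTomograms(t2, q2, pm, g$dq, g$edge)@values
  vab <- compressTomograms(t1 + t2, q2, pm, g$dq, g$edge)@values
  expect_equal(vab[va > 0 | vb > 0], (va + vb)[va > 0 | vb > 0],
               tolerance = 1e-9)
  # round trip on a smooth model
  qm <- volumeQmag(deskTruth())
  smooth <- intensityVolume(exp(-(qm / 0.08)^2), g$dq, g$edge)
  rt <- compressTomograms(expandVolume(smooth, rs, pm), rs, pm, g$dq, g$edge)
  mask <- qm > 0.01 & qm <= (g$edge - 1) / 2 * g$dq & rt@values > 0
  expect_lt(sqrt(mean((rt@values[mask] - smooth@values[mask])^2)) /
            sqrt(mean(smooth@values[mask]^2)), 0.10)
})

test_that("runEMC is deterministic, non-negative and photon-consistent", {
  pm <- deskPixmap()
  ps <- generateDataset(deskTruth(), 150, pm, meanPhotons = 500, seed = 41)
  cfg <- emcConfigDesk(mainIterations = 2L, finalIterations = 3L,
                       numDivCap = 3L, numDivStart = 3L, initSeed = 5L)
  s1 <- runEMC(ps, cfg)
  s2 <- runEMC(ps, cfg)
  expect_identical(s1@volume@values, s2@volume@values)
  expect_true(all(s1@volume@values >= 0))
  expect_identical(nrow(s1@trace), 5L)
  # model photon total tracks the data mean
  rs <- sampleRotations(3)
  tomo <- expandVolume(s1@volume, rs, pm)
  meanCounts <- mean(Matrix::colSums(patternCounts(ps)))
  expect_lt(abs(mean(colSums(tomo)) / meanCounts - 1), 0.01)
  expect_equal(nrow(s1@bestOrientation), 150L)
  expect_true(all(s1@orientationEntropy >= -1e-9))
})
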