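test_that("a single scatterer gives an isotropic f(q)^2 volume", {
  s <- atomicStructure("O", matrix(0, 1, 3), center = FALSE)
  v <- idealIntensityVolume(s, 21, 0.01)
  qm <- volumeQmag(v)
  expect_lt(max(abs(v@values - formFactor("O", qm)^2) /
                formFactor("O", qm)^2), 1e-10)
})

test_that("two identical atoms interfere as 4 f^2 cos^2(pi q d)", {
  d <- 20
  s2 <- atomicStructure(c("C", "C"), rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)),
                        center = FALSE)
  v2 <- idealIntensityVolume(s2, 21, 0.01)
  c0 <- 11
  qx <- ((1:21) - c0) * 0.01
  pred <- 4 * formFactor("C", abs(qx))^2 * cos(pi * qx * d)^2
  got <- v2@values[, c0, c0]
  expect_equal(got, pred, tolerance = 1e-9)
  # zeros at qx = (2k+1)/(2d) = 0.025, 0.075 -- between grid points; check
  # the analytic form vanishes there while the envelope does not
  expect_lt(4 * formFactor("C", 0.025)^2 * cos(pi * 0.025 * d)^2, 1e-25)
})

test_that("real structures obey Friedel symmetry", {
  v <- deskTruth()
  e <- volumeEdge(v)
  expect_lt(max(abs(v@values - v@values[e:1, e:1, e:1])) / max(v@values), 1e-6)
  expect_error(idealIntensityVolume(deskParticle(), 32, 0.01), "odd")
})

test_that("intensity scales quadratically with atomic scale factors", {
  st <- makeToyParticle(8, 20, seed = 3)
  st2 <- new("AtomicStructure", elements = st@elements,
             positions = st@positions, occupancy = st@occupancy * 3)
  v1 <- idealIntensityVolume(st, 15, 0.01)
  v2 <- idealIntensityVolume(st2, 15, 0.01)
  expect_equal(v2@values, 9 * v1@values, tolerance = 1e-10)
})

test_that("slicing is exact on atoms and consistent through the volume", {
  pm <- deskPixmap()
  st <- makeToyParticle(5, 15, seed = 5)
  r <- fixedQuats(1, seed = 2)[1, ]
  # identity orientation, single atom: f(|q|)^2 per pixel
  s1 <- atomicStructure("C", matrix(0, 1, 3), center = FALSE)
  expect_equal(slicePattern(s1, identityRotation(), pm),
               formFactor("C", pm@qmag)^2, tolerance = 1e-10)
  # equivariance: rotating the structure by g = slicing at g^-1 o r
  g <- fixedQuats(1, seed = 3)[1, ]
  rot <- atomicStructure(st@elements, st@positions %*% t(quatToMatrix(g)),
                         center = FALSE)
  expect_equal(slicePattern(rot, r, pm),
               slicePattern(st, composeRotations(invertRotation(g), r), pm),
               tolerance = 1e-9)
  # volume path vs atom path
  v <- idealIntensityVolume(st, 33, max(pm@qmag) / 15)
  pa <- slicePattern(st, r, pm)
  pv <- slicePattern(v, r, pm)
  expect_lt(sqrt(mean((pa - pv)^2)) / sqrt(mean(pa^2)), 0.05)
})

test_that("simulated patterns hit the photon budget on average", {
  pm <- deskPixmap()
  st <- makeToyParticle(5, 15, seed = 5)
  r <- fixedQuats(1, seed = 2)[1, ]
  tot <- vapply(1:200, function(sd)
    sum(simulatePattern(st, r, pm, meanPhotons = 500, seed = sd)$counts),
    numeric(1))
  expect_lt(abs(mean(tot) - 500) / 500, 0.05)
  # static structure: expectation proportional to the slice
  p <- simulatePattern(st, r, pm, meanPhotons = 500, seed = 1)
  sl <- slicePattern(st, r, pm)
  expect_equal(p$expected / sum(p$expected), sl / sum(sl), tolerance = 1e-12)
  # Monte-Carlo mean converges to the expectation map
  mu <- p$expected
  acc <- rowSums(vapply(1:2000, function(sd)
    simulatePattern(st, r, pm, 500, seed = 1000 + sd)$counts,
    numeric(length(mu))))
  cosSim <- sum(acc * mu) / sqrt(sum(acc^2) * sum(mu^2))
  expect_gt(cosSim, 0.99)
})

test_that("time integration with zero damage is exactly static", {
  pm <- deskPixmap()
  st <- makeToyParticle(10, 20, seed = 6)
  pulse <- makeSasePulse(6, 9, seed = 1)
  traj <- makeDamageTrajectory(st, pulse, 0, 0)
  r <- fixedQuats(1, seed = 4)[1, ]
  expect_equal(slicePattern(traj, r, pm), slicePattern(st, r, pm),
               tolerance = 1e-10)
})

test_that("the final pulse bin contributes little under strong expansion", {
  g <- deskGrid()
  pulse <- makeSasePulse(8, 9, seed = 3)
  traj <- makeDamageTrajectory(deskParticle(), pulse, expansionRate = 1.0,
                               ionizationRate = 0.5)
  tv <- timeIntegratedVolume(traj, g$edge, g$dq, perBin = TRUE)
  pm <- deskPixmap()
  r <- fixedQuats(3, seed = 5)
  for (i in 1:3) {
    per <- vapply(seq_along(tv$bins), function(b)
      traj@fractions[b] * sum(slicePattern(tv$bins[[b]], r[i, ], pm)),
      numeric(1))
    expect_lt(per[length(per)] / sum(per), 0.05)
  }
})

test_that("datasets share orientations across conditions at fixed seed", {
  pm <- deskPixmap()
  v1 <- deskTruth()
  st2 <- makeToyParticle(40, 25, seed = 9)
  g <- deskGrid()
  v2 <- idealIntensityVolume(st2, g$edge, g$dq)
  ps1 <- generateDataset(v1, 40, pm, seed = 42)
  ps2 <- generateDataset(v2, 40, pm, seed = 42)
  expect_identical(trueOrientations(ps1), trueOrientations(ps2))
  expect_false(identical(patternCounts(ps1), patternCounts(ps2)))
  expect_error(generateDataset(v1, 0, pm), ">= 1")
})

test_that("generated orientations are uniform on SO(3)", {
  pm <- deskPixmap()
  ps <- generateDataset(deskTruth(), 5000, pm, meanPhotons = 5, seed = 8)
  q <- trueOrientations(ps)
  # geodesic angle to a fixed rotation: CDF (theta - sin theta) / pi
  th <- geodesicAngle(q, fixedQuats(1, seed = 10)[1, ])
  ks <- stats::ks.test(th, function(x) (x - sin(x)) / pi)
  expect_gt(ks$p.value, 0.01)
})

test_that("pattern sets round-trip through the text serialization", {
  pm <- deskPixmap()
  ps <- generateDataset(deskTruth(), 25, pm, meanPhotons = 100, seed = 12,
                        role = "sentinel")
  prefix <- file.path(tempdir(), "ps_roundtrip")
  writePatternSet(ps, prefix)
  ps2 <- readPatternSet(prefix)
  expect_equal(as.matrix(patternCounts(ps2)), as.matrix(patternCounts(ps)))
  expect_equal(trueOrientations(ps2), trueOrientations(ps))
  expect_equal(patternPixelMap(ps2)@q, patternPixelMap(ps)@q,
               tolerance = 1e-12)
})
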