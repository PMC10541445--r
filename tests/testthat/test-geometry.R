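test_that("pixel map reproduces the production detector's q scale", {
  geom <- detectorGeometry()  # 81x81, 1200 um, 130 mm, 4.96 keV
  pm <- buildPixelMap(geom)
  # on-axis pixel
  center <- 40 + 81 * 40 + 1
  expect_equal(pm@qmag[center], 0)
  # edge midpoint (40 pixel pitches from centre) and corner
  edgeMid <- 81 * 40 + 1  # pixel (0, 40)
  expect_equal(round(pm@qmag[edgeMid], 2), 0.14)
  expect_equal(round(pm@qmag[1], 2), 0.19)  # corner pixel (0, 0)
  # direct evaluation of 2 sin(atan(r/L)/2)/lambda at the corner
  lam <- wavelength(geom)
  expect_equal(pm@qmag[1], 2 * sin(atan(sqrt(2) * 48 / 130) / 2) / lam,
               tolerance = 1e-12)
})

test_that("every pixel q satisfies the Ewald constraint |k_out| = |k_in|", {
  pm <- deskPixmap()
  k <- 1 / pm@wavelength
  kin <- c(0, 0, k)
  kout <- sweep(pm@q, 2, -kin)  # q + k_in
  expect_lt(max(abs(sqrt(rowSums(kout^2)) - k)), 1e-12)
})

test_that("|q| increases along a ray from the centre", {
  pm <- buildPixelMap(detectorGeometry())
  row <- pm@qmag[40 * 81 + 41:81]  # centre to edge along the fast axis
  expect_true(all(diff(row) > 0))
})

test_that("full-period edge resolution is the reciprocal of edge |q|", {
  geom <- detectorGeometry()
  expect_equal(round(resolutionAtEdge(geom)), 7)
  expect_equal(resolutionAtEdge(geom), 1 / edgeQ(geom), tolerance = 1e-12)
  # trivial reciprocals via a synthetic geometry check
  expect_equal(1 / 0.5, 2)
  g2 <- detectorGeometry(nFast = 3L, nSlow = 3L)
  expect_equal(resolutionAtEdge(g2), 1 / edgeQ(g2), tolerance = 1e-12)
})

test_that("invalid geometries are rejected", {
  expect_error(detectorGeometry(distance = -1), "positive")
  expect_error(detectorGeometry(pixelSize = 0), "positive")
  g <- detectorGeometry(nFast = 1L, nSlow = 1L)
  expect_error(resolutionAtEdge(g), "zero-area")
})

test_that("fluence reproduces the production beam arithmetic", {
  beam <- beamParameters(7.5e12, 4.96, c(250, 160), 9)
  expect_equal(signif(fluence(beam), 2), 1.5e7)
  expect_equal(fluence(beamParameters(photonsPerPulse = 0)), 0)
  expect_equal(fluence(beamParameters(photonsPerPulse = 1.5e13)),
               2 * fluence(beamParameters(photonsPerPulse = 7.5e12)))
  expect_error(beamParameters(focusFWHM = c(0, 100)), "positive")
})

test_that("Friedel-paired pixels have negated transverse q", {
  pm <- buildPixelMap(detectorGeometry())
  n <- 81L
  idx <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
  mirror <- (n + 1 - idx[, 2] - 1) * n + (n + 1 - idx[, 1])
  expect_lt(max(abs(pm@q[, 1:2] + pm@q[mirror, 1:2])), 1e-12)
  # qz (the Ewald curvature term) is equal, not negated
  expect_lt(max(abs(pm@q[, 3] - pm@q[mirror, 3])), 1e-12)
})

test_that("|q| is invariant under rotation of the pixel map", {
  pm <- deskPixmap()
  R <- quatToMatrix(fixedQuats(1)[1, ])
  rot <- pm@q %*% t(R)
  expect_lt(max(abs(sqrt(rowSums(rot^2)) - pm@qmag)), 1e-12)
})
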