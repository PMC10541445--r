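test_that("toy particles are bounded, reproducible and optionally C2", {
  st <- makeToyParticle(30, 100, seed = 4)
  d <- as.matrix(dist(st@positions))
  expect_lte(max(d), 100)
  expect_identical(st@positions, makeToyParticle(30, 100, seed = 4)@positions)
  expect_false(identical(st@positions, makeToyParticle(30, 100, seed = 5)@positions))
  sym <- makeToyParticle(15, 60, seed = 2, symmetrize = TRUE)
  R <- quatToMatrix(axisAngle(c(0, 0, 1), pi))
  rot <- sym@positions %*% t(R)
  # rotated atom set equals the original set (as sets)
  m <- as.matrix(dist(rbind(sym@positions, rot)))[seq_len(30), 31:60]
  expect_lt(max(apply(m, 1, min)), 1e-9)
})

test_that("form factors reproduce electron counts and decay", {
  zmap <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, Fe = 26, HOH = 10)
  for (el in names(zmap))
    expect_equal(formFactor(el, 0), zmap[[el]], tolerance = 0.1)
  q <- seq(0, 0.5, by = 0.01)
  for (el in supportedElements())
    expect_true(all(diff(formFactor(el, q)) < 0))
  # direct evaluation of the oxygen coefficients at q = 0.2
  a <- c(3.04850, 2.28680, 1.54630, 0.867000)
  b <- c(13.2771, 5.70110, 0.323900, 32.9089)
  expect_equal(formFactor("O", 0.2), sum(a * exp(-b * 0.01)) + 0.250800,
               tolerance = 1e-10)
  expect_error(formFactor("Xx", 0.1), "unknown")
})

test_that("water shells honour thickness, nesting and bulk density", {
  st <- deskParticle()
  expect_identical(addWaterShell(st, waterShellSpec(0)), st)
  counts <- vapply(c(2, 4, 6, 10, 20), function(tw)
    sum(addWaterShell(st, waterShellSpec(tw, seed = 3))@elements == "HOH"),
    numeric(1))
  expect_true(all(diff(counts) > 0))
  # achieved density vs a Monte-Carlo estimate of the shell volume
  hyd <- addWaterShell(st, waterShellSpec(6, seed = 5))
  nw <- sum(hyd@elements == "HOH")
  set.seed(9)
  box <- apply(st@positions, 2, range)
  lo <- box[1, ] - 8.8; hi <- box[2, ] + 8.8
  pts <- cbind(runif(5e4, lo[1], hi[1]), runif(5e4, lo[2], hi[2]),
               runif(5e4, lo[3], hi[3]))
  dmin <- apply(pts, 1, function(p)
    sqrt(min(colSums((t(st@positions) - p)^2))))
  vol <- prod(hi - lo) * mean(dmin >= 2.8 & dmin <= 8.8)
  expect_lt(abs(nw / vol - 0.0334) / 0.0334, 0.15)
})

test_that("spherical shell volume overtakes the particle volume at small T_w", {
  # for a compact particle of radius ~25 A (the production-scale protein),
  # (R + T)^3 - R^3 >= R^3 first happens near T ~ 6.5 A
  R <- 25
  tw <- seq(0, 20, by = 0.5)
  ratio <- ((R + tw)^3 - R^3) / R^3
  crossing <- tw[which(ratio >= 1)[1]]
  expect_gt(crossing, 4)
  expect_lt(crossing, 8)
})

test_that("PDB structures round-trip through the reader", {
  pdb <- file.path(tempdir(), "mini.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  O   ALA A   1       0.000   2.000   0.000  1.00  0.00           O",
    "END"), pdb)
  st <- readPDBStructure(pdb)
  expect_identical(st@elements, c("N", "C", "O"))
  expect_equal(colMeans(st@positions), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(dist(st@positions)[1], 1.5, tolerance = 1e-6)
  # unsupported element handling
  pdb2 <- file.path(tempdir(), "se.pdb")
  writeLines(c(
    "ATOM      1  SE  MSE A   1       0.000   0.000   0.000  1.00  0.00          SE",
    "ATOM      2  CA  MSE A   1       1.500   0.000   0.000  1.00  0.00           C",
    "END"), pdb2)
  expect_warning(st2 <- readPDBStructure(pdb2), "substituting")
  expect_identical(st2@elements[1], "S")
  expect_warning(st3 <- readPDBStructure(pdb2, unsupported = "skip"), "skipping")
  expect_identical(nAtoms(st3), 1L)
  pdb3 <- file.path(tempdir(), "empty.pdb")
  writeLines("END", pdb3)
  expect_error(suppressWarnings(readPDBStructure(pdb3)))
})

test_that("SASE pulses are normalized with the requested envelope duration", {
  p1 <- makeSasePulse(1, 9, seed = 1)
  expect_equal(p1@binFractions, 1)
  for (sd in 1:5)
    expect_equal(sum(makeSasePulse(8, 9, seed = sd)@binFractions), 1,
                 tolerance = 1e-12)
  expect_identical(makeSasePulse(8, 9, seed = 2)@binFractions,
                   makeSasePulse(8, 9, seed = 2)@binFractions)
  # envelope FDHM measured on generated profiles, averaged over 20 seeds
  f <- vapply(1:20, function(sd) pulseFDHM(makeSasePulse(8, 9, seed = sd)),
              numeric(1))
  expect_lt(abs(mean(f) - 9), 2.6)
  expect_equal(makeSasePulse(8, 9, seed = 1)@binWidth, 2.6)
})

test_that("damage trajectories follow the parametric stand-in exactly", {
  st <- deskParticle()
  pulse <- makeSasePulse(8, 9, seed = 2)
  t0 <- makeDamageTrajectory(st, pulse, 0, 0)
  for (b in 1:8)
    expect_equal(t0@snapshots[[b]]@positions, st@positions, tolerance = 1e-12)
  traj <- makeDamageTrajectory(st, pulse, expansionRate = 0.5,
                               ionizationRate = 0.4)
  expect_identical(traj@snapshots[[1]]@positions, st@positions)
  expect_true(all(diff(traj@doses) >= 0))
  expect_equal(sum(traj@fractions), 1, tolerance = 1e-12)
  expect_equal(traj@doses[8], 1 - traj@fractions[8], tolerance = 1e-12)
  # closed-form radius-of-gyration ratio of the final snapshot
  rg <- radiusOfGyration(new("AtomicStructure",
                             elements = traj@snapshots[[8]]@elements,
                             positions = traj@snapshots[[8]]@positions,
                             occupancy = st@occupancy)) / radiusOfGyration(st)
  expect_equal(rg, 1 + 0.5 * traj@doses[8], tolerance = 1e-9)
  expect_error(makeDamageTrajectory(st, pulse, -1, 0))
})
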