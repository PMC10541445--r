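test_that("composition follows the rotation-matrix product", {
  r <- fixedQuats(1)[1, ]
  expect_equal(composeRotations(identityRotation(), r), canonicalizeQuat(r))
  expect_equal(composeRotations(r, invertRotation(r)), identityRotation(),
               tolerance = 1e-12)
  # 90 deg + 90 deg about x = 180 deg about x (matrix oracle)
  q90 <- axisAngle(c(1, 0, 0), pi / 2)
  q180 <- composeRotations(q90, q90)
  expect_equal(quatToMatrix(q180), quatToMatrix(axisAngle(c(1, 0, 0), pi)),
               tolerance = 1e-12)
  # general case: R(a o b) = R(a) R(b)
  ab <- fixedQuats(2, seed = 3)
  expect_equal(quatToMatrix(composeRotations(ab[1, ], ab[2, ])),
               quatToMatrix(ab[1, ]) %*% quatToMatrix(ab[2, ]),
               tolerance = 1e-12)
})

test_that("geodesic angle matches the rotation-matrix trace oracle", {
  expect_equal(geodesicAngle(fixedQuats(1)[1, ], fixedQuats(1)[1, ]), 0)
  a <- axisAngle(c(0, 0, 1), 0.4)
  b <- axisAngle(c(0, 0, 1), 1.5)
  expect_equal(geodesicAngle(a, b), 1.1, tolerance = 1e-12)
  pairs <- fixedQuats(20, seed = 5)
  for (i in seq_len(10)) {
    x <- pairs[2 * i - 1, ]; y <- pairs[2 * i, ]
    Rrel <- crossprod(quatToMatrix(x), quatToMatrix(y))
    expect_equal(geodesicAngle(x, y),
                 acos(min(1, max(-1, (sum(diag(Rrel)) - 1) / 2))),
                 tolerance = 1e-9)
  }
})

test_that("geodesic angle is a bi-invariant metric", {
  q <- fixedQuats(9, seed = 11)
  g <- q[1, ]
  for (i in 1:3) {
    a <- q[3 * i - 1, ]; b <- q[3 * i, ]
    expect_equal(geodesicAngle(composeRotations(g, a), composeRotations(g, b)),
                 geodesicAngle(a, b), tolerance = 1e-10)
  }
  # triangle inequality on random triples
  tr <- fixedQuats(30, seed = 13)
  for (i in seq_len(10)) {
    a <- tr[3 * i - 2, ]; b <- tr[3 * i - 1, ]; cc <- tr[3 * i, ]
    expect_lte(geodesicAngle(a, cc),
               geodesicAngle(a, b) + geodesicAngle(b, cc) + 1e-12)
  }
})

test_that("600-cell sampling count follows 10(5n^3 + n) by construction", {
  for (n in 1:4) {
    rs <- sampleRotations(n)
    expect_identical(nrow(rs@quaternions), as.integer(10 * (5 * n^3 + n)))
    expect_equal(sum(rs@weights), 1, tolerance = 1e-10)
    expect_true(all(rs@weights > 0))
    expect_lt(max(abs(sqrt(rowSums(rs@quaternions^2)) - 1)), 1e-12)
    expect_true(all(rs@quaternions[, 1] >= -1e-12))
  }
  expect_error(sampleRotations(0), "positive")
})

test_that("sampling is near-uniform (nearest-neighbour spread)", {
  for (n in 2:6) {
    rs <- sampleRotations(n)
    q <- rs@quaternions
    idx <- seq_len(min(nrow(q), 300))
    d <- abs(q[idx, , drop = FALSE] %*% t(q))
    nn <- vapply(seq_along(idx), function(i) {
      r <- d[i, ]; r[idx[i]] <- 0
      2 * acos(min(1, max(r)))
    }, numeric(1))
    expect_lt(stats::sd(nn) / mean(nn), 0.3)
  }
})

test_that("symmetry groups contain identity and are closed", {
  for (nm in c("C1", "C2", "friedel_z")) {
    g <- makeGroup(nm)
    el <- g@elements
    expect_true(any(apply(el, 1, function(q) geodesicAngle(q, identityRotation()) < 1e-12)))
    for (i in seq_len(nrow(el))) for (j in seq_len(nrow(el))) {
      prod <- composeRotations(el[i, ], el[j, ])
      expect_lt(min(apply(el, 1, geodesicAngle, b = prod)), 1e-9)
    }
  }
  c2 <- makeGroup("C2", axis = c(0, 0, 1))
  expect_equal(nrow(c2@elements), 2L)
  expect_equal(geodesicAngle(c2@elements[2, ], axisAngle(c(0, 0, 1), pi)), 0,
               tolerance = 1e-12)
  fz <- makeGroup("friedel_z")
  expect_equal(composeRotations(fz@elements[2, ], fz@elements[2, ]),
               identityRotation(), tolerance = 1e-12)
  expect_error(makeGroup("icosahedral"))
})

test_that("quotient distance equals the brute-force group minimum", {
  s <- makeGroup("C2"); z <- makeGroup("friedel_z")
  q <- fixedQuats(20, seed = 17)
  for (i in seq_len(10)) {
    a <- q[2 * i - 1, ]; b <- q[2 * i, ]
    brute <- Inf
    for (si in 1:2) for (zi in 1:2)
      brute <- min(brute, geodesicAngle(
        spiOrient:::quatMultiply(
          spiOrient:::quatMultiply(s@elements[si, ], a), z@elements[zi, ]), b))
    expect_equal(quotientAngle(a, b, s, z), brute, tolerance = 1e-12)
    expect_lte(quotientAngle(a, b, s, z), geodesicAngle(a, b) + 1e-12)
  }
  # symmetry-equivalent orientations collapse to zero (acos is sqrt-
  # accurate near unit dot product, hence the 1e-6 tolerance)
  expect_lt(quotientAngle(axisAngle(c(0, 0, 1), pi), identityRotation(),
                          s = s), 1e-6)
  for (i in 1:5) {
    a <- q[i, ]
    sa <- composeRotations(composeRotations(s@elements[2, ], a),
                           z@elements[2, ])
    expect_lt(quotientAngle(a, sa, s, z), 1e-6)
  }
  expect_equal(quotientAngle(q[1, ], q[2, ]), geodesicAngle(q[1, ], q[2, ]),
               tolerance = 1e-12)
})
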