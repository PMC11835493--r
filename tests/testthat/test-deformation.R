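test_that("identity and rigid motions have exactly zero ground-truth stretch", {
  uv <- cbind(runif(50, -20, 20), runif(50, -15, 15))
  for (m in list(identityModel(),
                 rigidMotionModel(rotationMatrix("z", 25), c(3, -2, 7)),
                 rigidMotionModel(rotationMatrix("x", 40)))) {
    gt <- groundTruthStrain(m, uv)
    expect_identical(unname(max(abs(gt$principal))), 0)
    expect_identical(unname(max(abs(gt$orthogonal))), 0)
  }
})

test_that("uniaxial stretch matches its definition", {
  m <- uniaxialStretch(0.33)
  gt <- groundTruthStrain(m, cbind(c(0, 5, -7), c(0, 2, 3)))
  expect_equal(gt$principal, rep(33, 3))
  expect_equal(gt$orthogonal, rep(0, 3))
  expect_equal(gt$theta, rep(0, 3))
  # zero magnitude is the identity
  m0 <- uniaxialStretch(0)
  uv <- cbind(runif(10, -10, 10), runif(10, -10, 10))
  expect_equal(deformPoints(m0, uv)[, 1:2], unname(uv), ignore_attr = TRUE)
  # a 10 mm segment along u under 10% stretch ends up 11 mm long
  m1 <- uniaxialStretch(0.1)
  ends <- deformPoints(m1, rbind(c(0, 0), c(10, 0)))
  expect_equal(ends[2, 1] - ends[1, 1], 11)
})

test_that("ramp stretch integrates to the stated linear profile", {
  m <- rampStretch(5, base = 0, origin = 0)   # 5 %/cm
  gt <- groundTruthStrain(m, cbind(c(0, 20, 40), c(0, 0, 0)))
  expect_equal(gt$principal, c(0, 10, 20))    # 20% after 4 cm
  # zero gradient is uniform
  g0 <- groundTruthStrain(rampStretch(0, base = 0.1), cbind(-5:5, 0 * (-5:5)))
  expect_equal(g0$principal, rep(10, 11))
  # gradient too steep for the domain
  mneg <- rampStretch(-30, base = 0, origin = 0)
  expect_error(deformPoints(mneg, cbind(40, 0)), "domain")
  # finite-difference gradient of the ground-truth field recovers 5 %/cm
  us <- seq(0, 40, by = 1)
  pr <- groundTruthStrain(m, cbind(us, 0))$principal
  expect_equal(mean(diff(pr)) * 10, 5, tolerance = 1e-9)
})

test_that("bulge ground truth agrees with numerical surface-metric strain", {
  for (amp in c(5, -4)) {
    m <- bulge(amp, radius = 12)
    uv <- cbind(runif(40, -10, 10), runif(40, -8, 8))
    gt <- groundTruthStrain(m, uv)
    h <- 1e-4
    P0 <- deformPoints(m, uv)
    Pu <- (deformPoints(m, cbind(uv[, 1] + h, uv[, 2])) - P0) / h
    Pv <- (deformPoints(m, cbind(uv[, 1], uv[, 2] + h)) - P0) / h
    for (i in seq_len(nrow(uv))) {
      G <- matrix(c(sum(Pu[i, ]^2), sum(Pu[i, ] * Pv[i, ]),
                    sum(Pu[i, ] * Pv[i, ]), sum(Pv[i, ]^2)), 2, 2)
      lam <- sqrt(sort(eigen(G, symmetric = TRUE)$values, decreasing = TRUE))
      expect_lt(abs(100 * (lam[1] - 1) - gt$principal[i]), 0.1)
      expect_lt(abs(100 * (lam[2] - 1) - gt$orthogonal[i]), 0.1)
    }
  }
})

test_that("bulge sign controls expansion versus contraction at the apex", {
  near <- cbind(runif(20, -2, 2), runif(20, -2, 2))
  out <- groundTruthStrain(bulge(6, 12), near)
  expect_true(all(out$principal > 0))
  expect_true(all(out$orthogonal > 0))
  inw <- groundTruthStrain(bulge(-6, 12), near)
  expect_true(all(inw$orthogonal < 0))
  # zero amplitude is the identity
  uv <- cbind(runif(10, -10, 10), runif(10, -8, 8))
  expect_equal(deformPoints(bulge(0, 12), uv),
               cbind(uv, 0), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("composing with a rigid motion leaves ground truth unchanged", {
  m <- uniaxialStretch(0.2)
  mc <- composeRigid(m, rotationMatrix("y", 30), c(5, 1, -3))
  uv <- cbind(runif(10, -10, 10), runif(10, -8, 8))
  expect_equal(groundTruthStrain(mc, uv), groundTruthStrain(m, uv))
  # and the mapped points really are rigidly moved
  a <- deformPoints(m, uv)
  b <- deformPoints(mc, uv)
  d <- as.matrix(dist(rbind(a[1, ], a[5, ])))[1, 2]
  d2 <- as.matrix(dist(rbind(b[1, ], b[5, ])))[1, 2]
  expect_equal(d, d2, tolerance = 1e-10)
})
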