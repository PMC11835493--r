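test_that("closed-form strain identities hold for diagonal stretches", {
  refT <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  defT <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(0, 1.1, 0))
  s <- triangleStrain(refT, defT)
  expect_equal(s$E11, 0.22, tolerance = 1e-12)
  expect_equal(s$E22, 0.105, tolerance = 1e-12)
  expect_equal(s$E12, 0, tolerance = 1e-12)
  expect_equal(s$principal, 20, tolerance = 1e-9)
  expect_equal(s$orthogonal, 10, tolerance = 1e-9)
  expect_equal(s$areaRatio, 1.32, tolerance = 1e-12)
})

test_that("the 33% uniaxial benchmark triangle reports (33, 0) along the leg", {
  refT <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  defT <- rbind(c(0, 0, 0), c(1.33, 0, 0), c(0, 1, 0))
  s <- triangleStrain(refT, defT)
  expect_equal(s$principal, 33, tolerance = 1e-9)
  expect_equal(s$orthogonal, 0, tolerance = 1e-9)
  expect_equal(abs(s$ox), 1, tolerance = 1e-9)
  expect_equal(s$oy, 0, tolerance = 1e-9)
})

test_that("strain is invariant to rigid motions of the deformed triangle", {
  set.seed(51)
  for (k in 1:20) {
    refT <- matrix(runif(9, -5, 5), 3, 3)
    refT[, 3] <- runif(3, -1, 1)
    R <- rotationMatrix("x", runif(1, 0, 360)) %*%
      rotationMatrix("y", runif(1, 0, 360)) %*%
      rotationMatrix("z", runif(1, 0, 360))
    t <- runif(3, -10, 10)
    defT <- sweep(refT %*% t(R), 2, -t)
    s <- triangleStrain(refT, defT)
    expect_lt(abs(s$principal), 1e-9)
    expect_lt(abs(s$orthogonal), 1e-9)
    expect_lt(abs(s$areaRatio - 1), 1e-9)
  }
})

test_that("rigidly rotating a stretched state rotates the orientation only", {
  refT <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1.5, 0))
  defT <- rbind(c(0, 0, 0), c(2 * 1.25, 0, 0), c(0, 1.5 * 0.9, 0))
  s0 <- triangleStrain(refT, defT)
  R <- rotationMatrix("y", 35) %*% rotationMatrix("z", 20)
  s1 <- triangleStrain(refT, sweep(defT %*% t(R), 2, -c(1, 2, 3)))
  expect_equal(s1$principal, s0$principal, tolerance = 1e-9)
  expect_equal(s1$orthogonal, s0$orthogonal, tolerance = 1e-9)
  expect_equal(s1$areaRatio, s0$areaRatio, tolerance = 1e-9)
  # orientation lives in the reference frame, so it must not move
  expect_equal(c(s1$ox, s1$oy, s1$oz), c(s0$ox, s0$oy, s0$oz),
               tolerance = 1e-9)
})

test_that("cyclic vertex relabeling leaves all outputs unchanged", {
  set.seed(52)
  refT <- matrix(runif(9, -4, 4), 3, 3)
  defT <- refT %*% diag(c(1.15, 0.95, 1)) + matrix(runif(9, -0.1, 0.1), 3, 3)
  s0 <- triangleStrain(refT, defT)
  for (perm in list(c(2, 3, 1), c(3, 1, 2))) {
    s1 <- triangleStrain(refT[perm, ], defT[perm, ])
    expect_equal(s1$principal, s0$principal, tolerance = 1e-9)
    expect_equal(s1$orthogonal, s0$orthogonal, tolerance = 1e-9)
    expect_equal(s1$areaRatio, s0$areaRatio, tolerance = 1e-9)
    expect_equal(abs(c(s1$ox, s1$oy, s1$oz) %*% c(s0$ox, s0$oy, s0$oz))[1], 1,
                 tolerance = 1e-9)
  }
})

test_that("area ratio equals the product of the principal stretch ratios", {
  set.seed(53)
  mesh <- buildMesh(analyticMeshPoints(uniaxialStretch(0.33), nx = 10, ny = 8))
  tri <- strains(strainField(mesh))
  prod <- (1 + tri$principal / 100) * (1 + tri$orthogonal / 100)
  expect_lt(max(abs(tri$areaRatio - prod)), 1e-9)
})

test_that("analytic flat meshes reproduce the ground truth", {
  # uniform models: machine-precision agreement
  m <- uniaxialStretch(0.33)
  mesh <- buildMesh(analyticMeshPoints(m, nx = 12, ny = 9))
  tri <- strains(strainField(mesh))
  expect_lt(max(abs(tri$principal - 33)), 1e-6)
  expect_lt(max(abs(tri$orthogonal)), 1e-6)
  # spatially varying models: agreement at the discretization scale
  mr <- rampStretch(5, base = 0, origin = -10)
  meshr <- buildMesh(analyticMeshPoints(mr, nx = 21, ny = 11))
  fr <- strainField(meshr)
  trir <- strains(fr)
  F <- meshFaces(meshr)
  uvc <- (meshr@material[F[, 1], ] + meshr@material[F[, 2], ] +
          meshr@material[F[, 3], ]) / 3
  gt <- groundTruthStrain(mr, uvc)
  expect_lt(max(abs(trir$principal - gt$principal)), 0.1)
})

test_that("bulge and contraction produce opposite orthogonal stretch", {
  apexTri <- function(amp) {
    mesh <- buildMesh(analyticMeshPoints(bulge(amp, 12), nx = 25, ny = 19))
    f <- strainField(mesh)
    tri <- strains(f)
    near <- sqrt(tri$cx^2 + tri$cy^2) < 3
    tri[near, ]
  }
  puff <- apexTri(6)
  expect_true(all(puff$orthogonal > 0))
  expect_true(all(puff$principal > 0))
  expect_true(all(puff$areaRatio > 1))
  pout <- apexTri(-6)
  expect_true(all(pout$orthogonal < 0))
})

test_that("degenerate deformed triangles are flagged and excluded", {
  pts <- analyticMeshPoints(identityModel(), 4, 4)
  pts[, c("defX", "defY", "defZ")] <- 0  # all collapse
  mesh <- buildMesh(pts)
  f <- strainField(mesh)
  expect_true(all(strains(f)$status == "degenerate"))
  expect_equal(f@summary$nValid, 0)
})

test_that("optional k-ring smoothing only averages neighboring triangles", {
  mesh <- buildMesh(analyticMeshPoints(rampStretch(5, origin = -10), 15, 9))
  f <- strainField(mesh)
  fs <- smoothStrain(f, k = 1)
  expect_equal(mean(strains(fs)$principal), mean(strains(f)$principal),
               tolerance = 0.1)
  expect_lt(stats::sd(strains(fs)$principal),
            stats::sd(strains(f)$principal) + 1e-12)
  # k = 0 is the identity
  expect_identical(strains(smoothStrain(f, 0)), strains(f))
})
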