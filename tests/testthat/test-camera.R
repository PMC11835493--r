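test_that("pinhole projection follows similar triangles", {
  cam <- frontoCamera(focal = 3000, imageSize = c(700, 500), distance = 300)
  # point on the optical axis projects to the principal point
  expect_equal(as.numeric(project(cam, c(0, 0, 0))),
               as.numeric(cam@principalPoint), tolerance = 1e-9)
  # 30 mm off-axis at 300 mm with f = 3000 px -> 300 px off center
  p <- project(cam, c(30, 0, 0))
  expect_equal(p[1, 1] - cam@principalPoint[1], 300, tolerance = 1e-9)
  # behind the camera errors
  expect_error(project(cam, c(0, 0, -400)), "behind")
})

test_that("triangulation inverts projection exactly for noiseless matches", {
  rig <- stereoRig(focal = 3000, imageSize = c(700, 500))
  set.seed(1)
  X <- cbind(runif(40, -20, 20), runif(40, -15, 15), runif(40, -5, 5))
  px1 <- project(rig[[1]], X)
  px2 <- project(rig[[2]], X)
  tri <- triangulatePoints(px1, px2, rig[[1]], rig[[2]])
  expect_lt(max(abs(as.matrix(tri[, 1:3]) - X)), 1e-6)
  expect_lt(max(tri$residual), 1e-6)
  expect_false(any(tri$degenerate))
  # swapping the two views yields identical points
  tri2 <- triangulatePoints(px2, px1, rig[[2]], rig[[1]])
  expect_equal(as.matrix(tri2[, 1:3]), as.matrix(tri[, 1:3]),
               tolerance = 1e-9)
})

test_that("near-parallel rays are flagged degenerate", {
  cam1 <- frontoCamera()
  cam2 <- cam1
  cam2@translation <- cam1@translation + c(0.0001, 0, 0)  # ~zero baseline
  px <- matrix(cam1@principalPoint, 1, 2)
  tri <- triangulatePoints(px, px, cam1, cam2)
  expect_true(tri$degenerate[1])
  # identical centers are an error
  expect_error(triangulatePoints(px, px, cam1, cam1), "distinct")
})

test_that("reconstruction error grows monotonically with pixel noise", {
  rig <- stereoRig(focal = 3000, imageSize = c(700, 500))
  set.seed(7)
  X <- cbind(runif(300, -20, 20), runif(300, -15, 15), runif(300, -3, 3))
  px1 <- project(rig[[1]], X)
  px2 <- project(rig[[2]], X)
  errs <- vapply(c(0.2, 0.5, 1, 2), function(s) {
    set.seed(100 + round(10 * s))
    n1 <- px1 + matrix(rnorm(length(px1), 0, s), ncol = 2)
    n2 <- px2 + matrix(rnorm(length(px2), 0, s), ncol = 2)
    tri <- triangulatePoints(n1, n2, rig[[1]], rig[[2]])
    mean(sqrt(rowSums((as.matrix(tri[, 1:3]) - X)^2)))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
  # and the scaling is near-linear: quadrupling the noise at least triples
  # the error
  expect_gt(errs[4] / errs[1], 3)
})

test_that("reprojection residual stays commensurate with matching noise", {
  rig <- stereoRig(focal = 3000, imageSize = c(700, 500))
  set.seed(9)
  X <- cbind(runif(200, -15, 15), runif(200, -10, 10), 0)
  s <- 1.5
  px1 <- project(rig[[1]], X) + matrix(rnorm(400, 0, s), ncol = 2)
  px2 <- project(rig[[2]], X) + matrix(rnorm(400, 0, s), ncol = 2)
  tri <- triangulatePoints(px1, px2, rig[[1]], rig[[2]])
  expect_lt(mean(tri$residual), 2 * s)
})

test_that("rig perturbation reaches the requested reprojection regime", {
  rig <- stereoRig()
  set.seed(3)
  X <- cbind(runif(100, -15, 15), runif(100, -10, 10), 0)
  pert <- perturbRig(rig, X, targetRMS = 3)
  expect_lt(abs(pert$rms - 3), 0.15 * 3)
})

test_that("camera YAML serialization round-trips", {
  rig <- stereoRig()
  rig[[2]]@distortion <- c(-0.05, 0.01)
  path <- tempfile(fileext = ".yaml")
  writeCameraYAML(rig, path)
  back <- readCameraYAML(path)
  for (i in 1:2) {
    expect_equal(back[[i]]@rotation, rig[[i]]@rotation, tolerance = 1e-8)
    expect_equal(back[[i]]@translation, rig[[i]]@translation,
                 tolerance = 1e-8)
    expect_equal(back[[i]]@focal, rig[[i]]@focal)
    expect_equal(back[[i]]@distortion, rig[[i]]@distortion)
  }
  unlink(path)
})
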