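test_that("integer matching equals the exhaustive brute-force ZNCC oracle", {
  img <- makeSpeckleImage(seed = 31, widthMM = 12, heightMM = 10, scale = 8)
  img <- img[1:64, 1:64]
  # integer shift with wrap-free crop
  sh <- c(4, 3)
  tgt <- matrix(mean(img), 64, 64)
  tgt[(1 + sh[2]):64, (1 + sh[1]):64] <- img[1:(64 - sh[2]), 1:(64 - sh[1])]
  centers <- as.matrix(expand.grid(x = c(20, 30, 40), y = c(24, 34, 44)))
  grid <- new("SubsetGrid", centers = centers,
              index = as.matrix(expand.grid(1:3, 1:3)),
              dims = c(3L, 3L), radius = 8, spacing = 8)
  field <- matchInteger(img, tgt, grid, searchRadius = 7)
  oracle <- bruteForceZNCC(img, tgt, centers, radius = 8, search = 7)
  cc <- correspondences(field)
  expect_equal(cc$tgt_x - cc$ref_x, oracle$dx)
  expect_equal(cc$tgt_y - cc$ref_y, oracle$dy)
  expect_equal(cc$score, oracle$score, tolerance = 1e-10)
})

test_that("tie-breaking picks the smallest displacement deterministically", {
  # a periodic target makes several displacements exactly equivalent
  base <- matrix(0, 60, 60)
  base[, seq(1, 60, by = 6)] <- 1
  base[seq(1, 60, by = 6), ] <- 1
  centers <- matrix(c(30, 30), 1, 2)
  grid <- new("SubsetGrid", centers = centers, index = matrix(1L, 1, 2),
              dims = c(1L, 1L), radius = 9, spacing = 9)
  field <- matchInteger(base, base, grid, searchRadius = 8)
  oracle <- bruteForceZNCC(base, base, centers, radius = 9, search = 8)
  cc <- correspondences(field)
  expect_equal(c(cc$tgt_x - cc$ref_x, cc$tgt_y - cc$ref_y), c(0, 0))
  expect_equal(c(oracle$dx, oracle$dy), c(0, 0))
})

test_that("identical images match at zero displacement with score one", {
  img <- makeSpeckleImage(seed = 32)
  grid <- subsetGrid(dim(img)[2:1], radius = 12, spacing = 12)
  field <- matchInteger(img, img, grid, searchRadius = 5)
  cc <- correspondences(field)
  expect_true(all(cc$status == "matched"))
  expect_true(all(cc$tgt_x == cc$ref_x & cc$tgt_y == cc$ref_y))
  expect_true(all(abs(cc$score - 1) < 1e-12))
})

test_that("pure integer translations are recovered exactly (shift equivariance)", {
  img <- makeSpeckleImage(seed = 33)
  h <- nrow(img); w <- ncol(img)
  sh <- c(7, -3)
  tgt <- matrix(mean(img), h, w)
  tgt[1:(h + sh[2]), (1 + sh[1]):w] <- img[(1 - sh[2]):h, 1:(w - sh[1])]
  grid <- subsetGrid(c(w, h), radius = 12, spacing = 12, margin = 25)
  field <- matchInteger(img, tgt, grid, searchRadius = 10)
  cc <- correspondences(field)
  m <- cc$status == "matched"
  expect_gt(mean(m), 0.9)
  expect_true(all(cc$tgt_x[m] - cc$ref_x[m] == sh[1]))
  expect_true(all(cc$tgt_y[m] - cc$ref_y[m] == sh[2]))
})

test_that("ZNCC matching is invariant to affine intensity changes", {
  img <- makeSpeckleImage(seed = 34)
  tgt <- 0.6 * img + 0.25
  grid <- subsetGrid(dim(img)[2:1], radius = 12, spacing = 12)
  f1 <- matchInteger(img, img, grid, searchRadius = 4)
  f2 <- matchInteger(img, tgt, grid, searchRadius = 4)
  c1 <- correspondences(f1); c2 <- correspondences(f2)
  expect_equal(c2$tgt_x, c1$tgt_x)
  expect_equal(c2$tgt_y, c1$tgt_y)
  expect_equal(c2$score, c1$score, tolerance = 1e-9)
})

test_that("flat subsets are flagged low_score with zero score", {
  img <- matrix(0.5, 100, 100)
  img[40:60, 40:60] <- makeSpeckleImage(seed = 35)[1:21, 1:21]
  grid <- new("SubsetGrid",
              centers = rbind(c(50, 50), c(15, 15)),
              index = rbind(c(1L, 1L), c(2L, 1L)),
              dims = c(2L, 1L), radius = 8, spacing = 8)
  field <- matchInteger(img, img, grid, searchRadius = 3)
  cc <- correspondences(field)
  expect_equal(cc$status, c("matched", "low_score"))
  expect_equal(cc$score[2], 0)
})

test_that("subpixel refinement recovers fractional translations", {
  img <- makeSpeckleImage(seed = 36)
  shift <- c(0.5, -0.3)
  tgt <- warpImage(img, function(xy) cbind(xy[, 1] - shift[1],
                                           xy[, 2] - shift[2]))
  grid <- subsetGrid(dim(img)[2:1], radius = 14, spacing = 14, margin = 20)
  field <- matchInteger(img, tgt, grid, searchRadius = 3)
  field <- refineSubpixel(field, img, tgt)
  cc <- correspondences(field)
  m <- cc$status == "matched"
  expect_gt(sum(m), 5)
  dx <- cc$tgt_x[m] - cc$ref_x[m]
  dy <- cc$tgt_y[m] - cc$ref_y[m]
  expect_lt(max(abs(dx - shift[1])), 0.05)
  expect_lt(max(abs(dy - shift[2])), 0.05)
  # agreement with an upsampled-correlation brute-force oracle on one subset
  i <- which(m)[1]
  cx <- cc$ref_x[i]; cy <- cc$ref_y[i]
  offs <- as.matrix(expand.grid(dx = seq(0.3, 0.7, by = 0.01),
                                dy = seq(-0.5, -0.1, by = 0.01)))
  r <- 14
  dxs <- rep(-r:r, times = 2 * r + 1)
  dys <- rep(-r:r, each = 2 * r + 1)
  f <- dermastretch:::interpBicubicCpp(img, cx + dxs, cy + dys)
  f <- f - mean(f)
  zn <- apply(offs, 1, function(o) {
    g <- dermastretch:::interpBicubicCpp(tgt, cx + o[1] + dxs, cy + o[2] + dys)
    g <- g - mean(g)
    sum(f * g) / sqrt(sum(f^2) * sum(g^2))
  })
  best <- offs[which.max(zn), ]
  expect_lt(abs(dx[1] - best[1]), 0.05)
  expect_lt(abs(dy[1] - best[2]), 0.05)
})

test_that("affine-warped subsets converge to the known warp", {
  img <- makeSpeckleImage(seed = 37)
  h <- nrow(img); w <- ncol(img)
  cx0 <- (w - 1) / 2; cy0 <- (h - 1) / 2
  # 10% uniaxial stretch about the image center
  tgt <- warpImage(img, function(xy) cbind((xy[, 1] - cx0) / 1.1 + cx0,
                                           xy[, 2]))
  grid <- subsetGrid(c(w, h), radius = 14, spacing = 14, margin = 22)
  field <- matchInteger(img, tgt, grid, searchRadius = 8)
  field <- refineSubpixel(field, img, tgt)
  cc <- correspondences(field)
  m <- cc$status == "matched"
  expect_gt(sum(m), 5)
  predX <- (cc$ref_x[m] - cx0) * 1.1 + cx0
  expect_lt(max(abs(cc$tgt_x[m] - predX)), 0.1)
  expect_lt(max(abs(cc$tgt_y[m] - cc$ref_y[m])), 0.1)
  expect_lt(max(abs(cc$ux[m] - 0.1)), 0.02)
})

test_that("refinement is a no-op on an already-perfect match", {
  img <- makeSpeckleImage(seed = 38)
  grid <- subsetGrid(dim(img)[2:1], radius = 12, spacing = 12)
  field <- matchInteger(img, img, grid, searchRadius = 2)
  ref <- refineSubpixel(field, img, img)
  cc <- correspondences(ref)
  m <- cc$status == "matched"
  expect_lt(max(abs(cc$tgt_x[m] - cc$ref_x[m])), 1e-3)
  expect_lt(max(abs(cc$tgt_y[m] - cc$ref_y[m])), 1e-3)
})

test_that("analytic warp displacement fields are recovered below 0.1 px RMS", {
  img <- makeSpeckleImage(seed = 39, widthMM = 18, heightMM = 14)
  h <- nrow(img); w <- ncol(img)
  cx0 <- (w - 1) / 2; cy0 <- (h - 1) / 2
  tgt <- warpImage(img, function(xy)
    cbind((xy[, 1] - cx0) / 1.05 + cx0, (xy[, 2] - cy0) / 0.98 + cy0))
  grid <- subsetGrid(c(w, h), radius = 14, spacing = 10, margin = 24)
  field <- matchImages(img, tgt, grid, searchRadius = 12, coarseFactor = 2L,
                       intRadius = 10)
  cc <- correspondences(field)
  m <- cc$status == "matched"
  expect_gt(mean(m), 0.8)
  errX <- cc$tgt_x[m] - ((cc$ref_x[m] - cx0) * 1.05 + cx0)
  errY <- cc$tgt_y[m] - ((cc$ref_y[m] - cy0) * 0.98 + cy0)
  expect_lt(sqrt(mean(errX^2 + errY^2)), 0.1)
})

test_that("a smudged stripe is flagged without disturbing its surroundings", {
  img <- makeSpeckleImage(seed = 40)
  h <- nrow(img); w <- ncol(img)
  tgt <- img
  stripe <- 45:70
  # heavy box blur inside the stripe wipes out the speckle detail
  sm <- tgt[, stripe]
  for (k in 1:6) {
    sm <- (sm + rbind(sm[-1, ], sm[nrow(sm), ]) + rbind(sm[1, ], sm[-nrow(sm), ]) +
             cbind(sm[, -1], sm[, ncol(sm)]) + cbind(sm[, 1], sm[, -ncol(sm)])) / 5
  }
  tgt[, stripe] <- matrix(mean(sm), h, length(stripe)) +
    0.02 * (sm - mean(sm))
  grid <- subsetGrid(c(w, h), radius = 10, spacing = 10, margin = 14)
  field <- matchInteger(img, tgt, grid, searchRadius = 3)
  field <- refineSubpixel(field, img, tgt)
  cc <- correspondences(field)
  insideStripe <- cc$ref_x >= 48 & cc$ref_x <= 66
  outside <- cc$ref_x < 30 | cc$ref_x > 85
  expect_true(all(cc$status[insideStripe] != "matched"))
  expect_true(all(cc$status[outside] == "matched"))
  expect_true(all(abs(cc$tgt_x[outside] - cc$ref_x[outside]) < 0.05))
})

test_that("DIC displacements in mm are unchanged when resolution doubles", {
  # rigid in-plane translation viewed fronto-parallel at two raster/camera
  # resolutions; the recovered physical displacement must agree
  shift <- c(0.4, 0.25)  # mm
  model <- rigidMotionModel(translation = c(shift, 0))
  surf <- flatPatch(16, 12)
  res <- lapply(1:2, function(s) {
    p <- speckleParams(canvasSize = c(18, 14), rasterScale = 6 * s, seed = 44)
    tex <- generateSpeckle(p)
    cam <- frontoCamera(focal = 1800 * s, imageSize = c(150 * s, 120 * s))
    footprint <- pixelFootprint(cam, 300)
    ref <- renderView(surf, tex, identityModel(), cam)
    def <- renderView(surf, tex, model, cam)
    grid <- subsetGrid(c(150 * s, 120 * s), radius = 10 * s, spacing = 10 * s)
    field <- matchInteger(ref, def, grid, searchRadius = 6 * s)
    field <- refineSubpixel(field, ref, def)
    cc <- correspondences(field)
    m <- cc$status == "matched"
    c(mean(cc$tgt_x[m] - cc$ref_x[m]), mean(cc$tgt_y[m] - cc$ref_y[m])) *
      footprint
  })
  expect_lt(max(abs(res[[1]] - res[[2]])), 0.05)
  expect_lt(max(abs(res[[2]] - shift)), 0.05)
})
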