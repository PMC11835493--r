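test_that("weighted percentiles match brute-force expansion by area", {
  # brute-force oracle: expand each value by its integer area and take the
  # midpoint-position sample quantile of the expanded data
  oracle <- function(vals, wts, p) {
    xs <- sort(rep(vals, times = wts))
    pos <- (seq_along(xs) - 0.5) / length(xs)
    if (p <= pos[1]) return(xs[1])
    if (p >= pos[length(pos)]) return(xs[length(xs)])
    stats::approx(pos, xs, xout = p)$y
  }
  # 10 triangles of equal area: every probability agrees with the expansion
  vals <- c(5, 12, 7, 30, 18, 22, 9, 14, 26, 11)
  for (p in c(0.05, 0.25, 0.5, 0.75, 0.95))
    expect_equal(weightedQuantile(vals, rep(2, 10), p),
                 oracle(vals, rep(2, 10), p), tolerance = 1e-9)
  # unequal areas: probe at the weighted midpoint positions, where the
  # interpolated weighted quantile and the expansion coincide exactly (the
  # expansion is piecewise flat inside a value's area block, so between
  # probes the two can differ by design)
  wts <- c(3, 2, 4, 2, 5, 2, 2, 3, 2, 4)
  o <- order(vals)
  sw <- wts[o]; sv <- vals[o]
  pos <- (cumsum(sw) - sw / 2) / sum(sw)
  for (i in c(1, 2, 5, 9, 10)) {
    expect_equal(weightedQuantile(vals, wts, pos[i]), sv[i],
                 tolerance = 1e-9)
    expect_equal(oracle(vals, wts, pos[i]), sv[i], tolerance = 1e-9)
  }
  # equal weights reduce to the unweighted midpoint quantile
  expect_equal(weightedQuantile(vals, rep(1, 10), 0.5),
               stats::quantile(vals, 0.5, type = 5)[[1]], tolerance = 1e-9)
})

test_that("percentile summaries are area-weighted", {
  # two-value field with equal areas averages to the midpoint
  pts <- analyticMeshPoints(identityModel(), 3, 3)
  mesh <- buildMesh(pts)
  f <- strainField(mesh)
  f@triangles$principal <- rep(c(10, 30), length.out = nrow(f@triangles))
  f@triangles$refArea <- rep(1, nrow(f@triangles))
  s <- percentileSummary(f)
  expect_equal(s$meanPrincipal, 20)
  # constant field: mean = p5 = p95
  f@triangles$principal <- rep(22, nrow(f@triangles))
  s2 <- percentileSummary(f)
  expect_equal(s2$meanPrincipal, 22)
  expect_equal(s2$p5Principal, 22)
  expect_equal(s2$p95Principal, 22)
})

test_that("plane fitting is exact and equivariant for planar patches", {
  mesh <- buildMesh(analyticMeshPoints(uniaxialStretch(0.2), nx = 10, ny = 8))
  f <- strainField(mesh)
  pl <- fitPlane(f)
  expect_equal(pl@inPlaneFraction, 1, tolerance = 1e-12)
  d <- sweep(vertices(mesh), 2, pl@point) %*% pl@normal
  expect_lt(max(abs(d)), 1e-9)
  # tilt the whole scene by 30 degrees: the fitted plane tilts with it
  R <- rotationMatrix("x", 30)
  pts <- analyticMeshPoints(uniaxialStretch(0.2), nx = 10, ny = 8)
  vr <- as.matrix(pts[, c("refX", "refY", "refZ")]) %*% t(R)
  vd <- as.matrix(pts[, c("defX", "defY", "defZ")]) %*% t(R)
  pts[, c("refX", "refY", "refZ")] <- vr
  pts[, c("defX", "defY", "defZ")] <- vd
  plt <- fitPlane(strainField(buildMesh(pts)))
  expect_equal(abs(sum(plt@normal * (R %*% c(0, 0, 1)))), 1,
               tolerance = 1e-9)
  expect_equal(plt@inPlaneFraction, 1, tolerance = 1e-9)
})

test_that("curved patches lose in-plane fraction but keep the symmetry plane", {
  # spherical cap inflated radially: principal directions are tangent to the
  # cap, so part of their magnitude leaves the best-fitting plane
  R0 <- 30
  gi <- rep(1:21, times = 21); gj <- rep(1:21, each = 21)
  u <- (gi - 11) * 1.2; v <- (gj - 11) * 1.2
  zc <- sqrt(R0^2 - u^2 - v^2)
  ref <- cbind(u, v, zc - min(zc))
  def <- ref * 1.05
  pts <- data.frame(gi = gi, gj = gj, refX = ref[, 1], refY = ref[, 2],
                    refZ = ref[, 3], defX = def[, 1], defY = def[, 2],
                    defZ = def[, 3], score = 1)
  pl <- fitPlane(strainField(buildMesh(pts)))
  expect_lt(pl@inPlaneFraction, 1)
  expect_gt(pl@inPlaneFraction, 0.8)
  expect_gt(abs(pl@normal[3]), 0.999)  # symmetry axis
})

test_that("grid resampling reproduces constant fields and conserves means", {
  mesh <- buildMesh(analyticMeshPoints(uniaxialStretch(0.33), 25, 19))
  f <- strainField(mesh)
  pl <- fitPlane(f)
  map <- resampleGrid(f, pl, resolution = 1)
  vals <- gridValues(map)[gridMask(map)]
  expect_lt(max(abs(vals - 33)), 1e-6)
  # conservation on a spatially varying field
  meshr <- buildMesh(analyticMeshPoints(rampStretch(5, origin = -12), 25, 19))
  fr <- strainField(meshr)
  plr <- fitPlane(fr)
  mapr <- resampleGrid(fr, plr, resolution = 1)
  tri <- strains(fr)
  ok <- tri$status == "ok"
  meshMean <- sum(tri$refArea[ok] * tri$principal[ok]) / sum(tri$refArea[ok])
  gridMean <- mean(gridValues(mapr)[gridMask(mapr)])
  expect_lt(abs(gridMean - meshMean), 0.5)
})

test_that("cells mix triangles by area weight", {
  # two triangles of equal area with values 10 and 30 in one cell -> 20
  pts <- data.frame(gi = c(1, 2, 1, 2), gj = c(1, 1, 2, 2),
                    refX = c(0, 0.9, 0, 0.9), refY = c(0, 0, 0.9, 0.9),
                    refZ = 0,
                    defX = c(0, 0.9, 0, 0.9), defY = c(0, 0, 0.9, 0.9),
                    defZ = 0, score = 1)
  mesh <- buildMesh(pts)
  f <- strainField(mesh)
  f@triangles$principal <- c(10, 30)
  pl <- fitPlane(f)
  map <- resampleGrid(f, pl, resolution = 2)
  expect_equal(gridValues(map)[1, 1], 20, tolerance = 1e-9)
})

test_that("masked cells stay masked and resolution must be positive", {
  mesh <- buildMesh(analyticMeshPoints(identityModel(), 12, 10))
  f <- strainField(mesh)
  pl <- fitPlane(f)
  expect_error(resampleGrid(f, pl, resolution = 0), "resolution")
  map <- resampleGrid(f, pl, resolution = 1)
  expect_true(all(is.na(gridValues(map)[!gridMask(map)])))
})

test_that("the stretch gradient statistic behaves like a derivative", {
  fieldOf <- function(model) {
    mesh <- buildMesh(analyticMeshPoints(model, 41, 21))
    f <- strainField(mesh)
    resampleGrid(f, fitPlane(f), resolution = 1)
  }
  expect_equal(stretchGradient(fieldOf(uniaxialStretch(0.2))), 0,
               tolerance = 1e-6)
  g5 <- stretchGradient(fieldOf(rampStretch(5, origin = -20)))
  expect_lt(abs(g5 - 5), 0.5)
  g8 <- stretchGradient(fieldOf(rampStretch(8, origin = -20)))
  g4 <- stretchGradient(fieldOf(rampStretch(4, origin = -20)))
  expect_gt(g8, g4)
  expect_lt(abs(g8 - 8) / 8, 0.1)
  expect_lt(abs(g4 - 4) / 4, 0.1)
})

test_that("axial statistics recover dispersion and respect axial symmetry", {
  expect_equal(axialStats(rep(37, 50))@angularSD, 0)
  # orthogonal axes cancel: maximal axial dispersion
  s <- axialStats(c(0, 90), weights = c(1, 1))
  expect_false(is.finite(s@angularSD) && s@angularSD < 45)
  # wrapped-normal recovery
  set.seed(61)
  draws <- (rnorm(1e4, mean = 40, sd = 6)) %% 180
  r <- axialStats(draws)
  expect_lt(abs(r@angularSD - 6), 0.5)
  expect_lt(abs(r@axialMean - 40), 1)
  # flipping any subset by 180 changes nothing
  flip <- draws + ifelse(seq_along(draws) %% 3 == 0, 180, 0)
  r2 <- axialStats(flip)
  expect_equal(r2@angularSD, r@angularSD, tolerance = 1e-9)
  expect_equal(r2@axialMean, r@axialMean, tolerance = 1e-9)
  # adding a constant shifts the mean, not the SD
  r3 <- axialStats(draws + 25)
  expect_equal(r3@angularSD, r@angularSD, tolerance = 1e-9)
  # histogram is a distribution
  expect_equal(sum(r@histogram$freq), 1, tolerance = 1e-12)
  expect_error(axialStats(numeric(0)), "at least one")
  expect_error(axialStats(c(1, 2), weights = c(0, 0)), "zero total weight")
  # histogram round-trips through its CSV export
  path <- tempfile(fileext = ".csv")
  writeOrientationCSV(r, path)
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$freq, r@histogram$freq, tolerance = 1e-12)
  unlink(path)
})

test_that("profiles along an axis reproduce ramps and flat fields", {
  mapOf <- function(model) {
    mesh <- buildMesh(analyticMeshPoints(model, 41, 21))
    f <- strainField(mesh)
    resampleGrid(f, fitPlane(f), resolution = 1)
  }
  anchors <- rbind(c(-18, 0), c(18, 0))
  ramp <- profileAlongAxis(mapOf(rampStretch(5, origin = -20)), anchors,
                           binCm = 0.5)
  filled <- !is.na(ramp$mean)
  expect_true(all(diff(ramp$mean[filled]) > 0))
  # slope ~5% per cm
  fit <- stats::lm(mean ~ binCenter, data = ramp[filled, ])
  expect_lt(abs(stats::coef(fit)[2] - 5) / 5, 0.1)
  flat <- profileAlongAxis(mapOf(uniaxialStretch(0.15)), anchors, binCm = 1)
  expect_lt(max(abs(flat$mean[!is.na(flat$mean)] - 15)), 1e-6)
  expect_error(profileAlongAxis(mapOf(uniaxialStretch(0.1)),
                                rbind(c(0, 0), c(0, 0))), "distinct")
})

test_that("a stretch field decaying along the axis gives decreasing bins", {
  # knee-flexion-like preset: high stretch at one end, decaying along u
  mdl <- rampStretch(-4, base = 0.25, origin = -20)
  mesh <- buildMesh(analyticMeshPoints(mdl, 41, 21))
  f <- strainField(mesh)
  map <- resampleGrid(f, fitPlane(f), resolution = 1)
  pr <- profileAlongAxis(map, rbind(c(-18, 0), c(18, 0)), binCm = 1)
  m <- pr$mean[!is.na(pr$mean)]
  expect_true(all(diff(m) < 0))
})
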