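# shared fixtures, all generated in code

# small speckle raster for DIC unit tests
makeSpeckleImage <- function(seed = 1, widthMM = 14, heightMM = 11,
                             scale = 8) {
  p <- speckleParams(canvasSize = c(widthMM, heightMM), rasterScale = scale,
                     seed = seed)
  patternImage(generateSpeckle(p))
}

# independent R oracle for integer ZNCC matching, same tie-break rules as the
# implementation (score within 1e-12 -> smaller displacement magnitude, then
# lexicographic on (dx, dy))
bruteForceZNCC <- function(ref, tgt, centers, radius, search, init = NULL) {
  n <- nrow(centers)
  if (is.null(init)) init <- matrix(0, n, 2)
  out <- data.frame(dx = numeric(n), dy = numeric(n), score = numeric(n),
                    status = integer(n))
  hR <- nrow(ref); wR <- ncol(ref); hT <- nrow(tgt); wT <- ncol(tgt)
  for (p in seq_len(n)) {
    x0 <- round(centers[p, 1]); y0 <- round(centers[p, 2])
    idx0 <- round(init[p, 1]); idy0 <- round(init[p, 2])
    out$dx[p] <- idx0; out$dy[p] <- idy0
    if (x0 - radius < 0 || x0 + radius >= wR ||
        y0 - radius < 0 || y0 + radius >= hR) { out$status[p] <- 2; next }
    f <- ref[(y0 - radius):(y0 + radius) + 1, (x0 - radius):(x0 + radius) + 1]
    f <- f - mean(f)
    fn <- sqrt(sum(f^2))
    if (fn < 1e-12) { out$status[p] <- 1; next }
    best <- -2; bmag <- Inf; bdx <- 0; bdy <- 0; anyc <- FALSE
    for (sy in -search:search) for (sx in -search:search) {
      tx <- x0 + idx0 + sx; ty <- y0 + idy0 + sy
      if (tx - radius < 0 || tx + radius >= wT ||
          ty - radius < 0 || ty + radius >= hT) next
      g <- tgt[(ty - radius):(ty + radius) + 1,
               (tx - radius):(tx + radius) + 1]
      gc <- g - mean(g)
      gn2 <- sum(gc^2)
      z <- if (gn2 < 1e-20) 0 else sum(f * gc) / (fn * sqrt(gn2))
      tdx <- idx0 + sx; tdy <- idy0 + sy
      mag <- tdx^2 + tdy^2
      better <- if (!anyc) TRUE
      else if (z > best + 1e-12) TRUE
      else if (z < best - 1e-12) FALSE
      else if (mag < bmag - 1e-9) TRUE
      else if (mag > bmag + 1e-9) FALSE
      else if (tdx != bdx) tdx < bdx
      else tdy < bdy
      if (better) { best <- z; bmag <- mag; bdx <- tdx; bdy <- tdy
                    anyc <- TRUE }
    }
    if (!anyc) { out$status[p] <- 2; next }
    out$dx[p] <- bdx; out$dy[p] <- bdy; out$score[p] <- best
  }
  out
}

# grid of tracked points deformed analytically (no imaging), ready for
# buildMesh; material spacing in mm
analyticMeshPoints <- function(model, nx = 21, ny = 16, spacing = 1,
                               centerAt = c(0, 0)) {
  gi <- rep(seq_len(nx), times = ny)
  gj <- rep(seq_len(ny), each = nx)
  u <- (gi - (nx + 1) / 2) * spacing + centerAt[1]
  v <- (gj - (ny + 1) / 2) * spacing + centerAt[2]
  def <- deformPoints(model, cbind(u, v))
  data.frame(gi = gi, gj = gj, refX = u, refY = v, refZ = 0,
             defX = def[, 1], defY = def[, 2], defZ = def[, 3],
             score = 1, matU = u, matV = v)
}

# fronto-parallel camera looking at the origin from -z
frontoCamera <- function(focal = 1800, imageSize = c(240, 180),
                         distance = 300) {
  lookAtCamera(cameraModel(focal, imageSize), c(0, 0, -distance))
}

# reduced-size pipeline configuration for fast end-to-end tests
smallConfig <- function(preset = "identity", seed = 1L, ...) {
  runConfig(preset, seed = seed, patchSize = c(20, 15),
            imageSize = c(420, 320), dicRadius = 30, dicSpacing = 10,
            intRadius = 12, ...)
}

# bicubic resampling of an image at a translated/warped grid (test fixture
# generator for subpixel ground-truth displacements)
warpImage <- function(img, mapFun) {
  h <- nrow(img); w <- ncol(img)
  xy <- cbind(rep(seq_len(w) - 1, times = h), rep(seq_len(h) - 1, each = w))
  src <- mapFun(xy)
  val <- dermastretch:::interpBicubicCpp(img, src[, 1], src[, 2])
  val[is.na(val)] <- mean(img)
  matrix(val, h, w, byrow = TRUE)
}
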