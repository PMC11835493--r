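#' Checkerboard specification
#'
#' @param rows,cols number of inner corners per column / row.
#' @param squareSize square edge length in mm.
#' @return a plain list used by the calibration functions.
#' @export
checkerboardSpec <- function(rows = 6L, cols = 7L, squareSize = 10) {
  list(rows = as.integer(rows), cols = as.integer(cols),
       squareSize = squareSize)
}

# board coordinates (mm) of the inner corners, ordered column-major in i
.boardCorners <- function(spec) {
  cbind(rep(seq_len(spec$cols), times = spec$rows) * spec$squareSize,
        rep(seq_len(spec$rows), each = spec$cols) * spec$squareSize)
}

#' Render a synthetic checkerboard view
#'
#' The board has \code{(cols + 1) x (rows + 1)} squares on a white surround;
#' ray casting onto the board plane with analytic anti-aliasing (linear
#' intensity ramps of half-width \code{aaWidth} mm across the edges), which
#' keeps subpixel corner positions free of raster quantization.
#'
#' @param camera a [CameraModel-class].
#' @param rotation,translation board pose: world point = R p_board + t.
#' @param spec a [checkerboardSpec()].
#' @param noiseSD additive Gaussian intensity noise.
#' @param aaWidth edge transition half-width in mm (about one pixel footprint).
#' @return list: \code{image} (matrix) and \code{corners} (ground-truth
#'   pixel positions of the inner corners, for testing).
#' @export
renderCheckerboard <- function(camera, rotation, translation, spec,
                               noiseSD = 0, aaWidth = 0.12) {
  w <- camera@imageSize[1]; h <- camera@imageSize[2]
  sq <- spec$squareSize
  bw <- (spec$cols + 1) * sq; bh <- (spec$rows + 1) * sq
  px <- cbind(rep(seq_len(w) - 1, times = h),
              rep(seq_len(h) - 1, each = w))
  rays <- pixelRays(camera, px)
  n <- rotation[, 3]
  denom <- as.numeric(rays$dir %*% n)
  tt <- as.numeric((translation - rays$origin) %*% n) / denom
  p <- sweep(rays$dir * tt, 2, -rays$origin)
  lb <- sweep(p, 2, translation) %*% rotation
  bu <- lb[, 1]; bv <- lb[, 2]
  inside <- bu >= 0 & bu <= bw & bv >= 0 & bv <= bh & tt > 0
  # smooth square wave in [-1, 1] with linear edge ramps
  sqw <- function(t) {
    tau <- (t / sq) %% 2
    s <- ifelse(tau < 1, 1, -1)
    d <- pmin(tau %% 1, 1 - tau %% 1)        # distance to nearest edge
    s * pmin(1, d / (aaWidth / sq))
  }
  val <- ifelse(inside, 0.525 + 0.425 * sqw(bu) * sqw(bv), 0.95)
  img <- matrix(val, nrow = h, ncol = w, byrow = TRUE)
  if (noiseSD > 0)
    img <- pmin(pmax(img + matrix(stats::rnorm(length(img), 0, noiseSD),
                                  h, w), 0), 1)
  bc <- .boardCorners(spec)
  world <- cbind(bc, 0) %*% t(rotation)
  world <- sweep(world, 2, -translation)
  corners <- project(camera, world, allowBehind = TRUE)
  list(image = img, corners = corners)
}

# separable Gaussian blur with replicated edges
.blur2d <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) rbind(m[rep(1, n), , drop = FALSE], m,
                              m[rep(nrow(m), n), , drop = FALSE])
  conv1 <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

# Foerstner-style subpixel corner refinement on image gradients
.refineCorner <- function(gx, gy, x, y, win = 5L, iters = 3L) {
  h <- nrow(gx); w <- ncol(gx)
  for (it in seq_len(iters)) {
    xs <- round(x) + (-win:win); ys <- round(y) + (-win:win)
    if (min(xs) < 0 || min(ys) < 0 || max(xs) >= w || max(ys) >= h)
      return(c(x, y))
    sub_gx <- gx[ys + 1, xs + 1]
    sub_gy <- gy[ys + 1, xs + 1]
    X <- rep(xs, each = length(ys)); Y <- rep(ys, times = length(xs))
    gxx <- sum(sub_gx^2); gyy <- sum(sub_gy^2); gxy <- sum(sub_gx * sub_gy)
    bx <- sum(sub_gx^2 * X + sub_gx * sub_gy * Y)
    by <- sum(sub_gx * sub_gy * X + sub_gy^2 * Y)
    det <- gxx * gyy - gxy^2
    if (abs(det) < 1e-12) return(c(x, y))
    nx <- (gyy * bx - gxy * by) / det
    ny <- (gxx * by - gxy * bx) / det
    if (abs(nx - x) < 1e-4 && abs(ny - y) < 1e-4) { x <- nx; y <- ny; break }
    x <- nx; y <- ny
  }
  c(x, y)
}

#' Detect checkerboard inner corners
#'
#' Saddle points of the blurred intensity (negative Hessian determinant
#' response) are located, refined to subpixel with a gradient-based
#' (Foerstner) iteration, and ordered into the board grid through a
#' homography fitted to the four extreme corners. Assumes the full board is
#' visible and the camera roughly upright (board x axis within 90 degrees of
#' image x).
#'
#' @param image grayscale matrix.
#' @param spec a [checkerboardSpec()].
#' @return list with \code{px} (n x 2 subpixel corner positions ordered
#'   column-major in board x) and \code{board} (n x 2 board coordinates,
#'   mm), or NULL if detection fails.
#' @export
detectCheckerboardCorners <- function(image, spec) {
  nWant <- spec$rows * spec$cols
  S <- .blur2d(image, 2)
  h <- nrow(S); w <- ncol(S)
  Sx <- matrix(0, h, w); Sy <- matrix(0, h, w)
  Sx[, 2:(w - 1)] <- (S[, 3:w] - S[, 1:(w - 2)]) / 2
  Sy[2:(h - 1), ] <- (S[3:h, ] - S[1:(h - 2), ]) / 2
  Sxx <- matrix(0, h, w); Syy <- matrix(0, h, w); Sxy <- matrix(0, h, w)
  Sxx[, 2:(w - 1)] <- S[, 3:w] - 2 * S[, 2:(w - 1)] + S[, 1:(w - 2)]
  Syy[2:(h - 1), ] <- S[3:h, ] - 2 * S[2:(h - 1), ] + S[1:(h - 2), ]
  Sxy[2:(h - 1), 2:(w - 1)] <-
    (S[3:h, 3:w] - S[3:h, 1:(w - 2)] - S[1:(h - 2), 3:w] +
     S[1:(h - 2), 1:(w - 2)]) / 4
  resp <- -(Sxx * Syy - Sxy^2)
  resp[resp < 0] <- 0
  # 3x3 local maxima above threshold
  thr <- 0.2 * max(resp)
  isMax <- resp >= thr
  sh <- function(m, dy, dx) {
    out <- matrix(-Inf, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & (resp >= sh(resp, dy, dx))
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) < nWant) return(NULL)
  ord <- order(resp[idx], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1) # (x, y), 0-based
  # dedupe peaks closer than a few pixels, keep strongest
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      later <- (i + 1):nrow(pts)
      d2 <- (pts[later, 1] - pts[i, 1])^2 + (pts[later, 2] - pts[i, 2])^2
      keep[later[d2 < 25]] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < nWant) return(NULL)
  # inner corners (four dark quadrant-contrast) outrank boundary saddles;
  # keep exactly the strongest board-sized set
  pts <- pts[seq_len(nWant), , drop = FALSE]
  ref <- t(apply(pts, 1, function(p) .refineCorner(Sx, Sy, p[1], p[2])))
  # order through a homography from the four extreme hull corners
  hull <- grDevices::chull(ref)
  if (length(hull) < 4) return(NULL)
  combs <- utils::combn(hull, 4)
  areas <- apply(combs, 2, function(q) {
    q <- q[order(match(q, hull))]
    x <- ref[q, 1]; y <- ref[q, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  })
  q <- combs[, which.max(areas)]
  q <- q[order(match(q, hull))]
  Wb <- (spec$cols - 1); Hb <- (spec$rows - 1)
  targets <- rbind(c(0, 0), c(Wb, 0), c(Wb, Hb), c(0, Hb))
  best <- NULL
  for (rev_ in c(FALSE, TRUE)) {
    qq <- if (rev_) rev(q) else q
    for (rot in 0:3) {
      qr <- if (rot == 0) qq else c(qq[-seq_len(rot)], qq[seq_len(rot)])
      H <- tryCatch(.homographyDLT(ref[qr, , drop = FALSE], targets),
                    error = function(e) NULL)
      if (is.null(H) || !all(is.finite(H))) next
      bc <- .applyHomography(H, ref)
      if (!all(is.finite(bc))) next
      snap <- round(bc)
      resid <- sqrt(rowSums((bc - snap)^2))
      okpts <- snap[, 1] >= 0 & snap[, 1] <= Wb & snap[, 2] >= 0 &
        snap[, 2] <= Hb & resid < 0.25
      if (sum(okpts) < nWant) next
      # keep board x roughly aligned with image x and the labeling
      # right-handed in image coordinates (rejects mirrored labelings)
      Hinv <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(Hinv)) next
      c0 <- c(Wb / 2, Hb / 2)
      pr <- .applyHomography(Hinv, rbind(c0, c0 + c(1, 0), c0 + c(0, 1)))
      e1 <- pr[2, ] - pr[1, ]
      e2 <- pr[3, ] - pr[1, ]
      if (e1[1] <= 0) next
      if (e1[1] * e2[2] - e1[2] * e2[1] <= 0) next
      key <- snap[okpts, 1] + snap[okpts, 2] * spec$cols
      if (anyDuplicated(key)) next
      totResid <- mean(resid[okpts])
      if (is.null(best) || totResid < best$resid)
        best <- list(resid = totResid, px = ref[okpts, , drop = FALSE],
                     key = key)
    }
  }
  if (is.null(best)) return(NULL)
  ordk <- order(best$key)
  px <- best$px[ordk, , drop = FALSE]
  if (nrow(px) != nWant) return(NULL)
  list(px = px, board = .boardCorners(spec))
}

# normalized DLT homography: maps src (n x 2) to dst (n x 2)
.homographyDLT <- function(src, dst) {
  norm2d <- function(p) {
    ctr <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
    T <- diag(c(sc, sc, 1))
    T[1:2, 3] <- -sc * ctr
    list(T = T, p = cbind(p, 1) %*% t(T))
  }
  ns <- norm2d(src); nd <- norm2d(dst)
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- ns$p[i, ]; x <- nd$p[i, 1]; y <- nd$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, x * X)
    A[2 * i, ] <- c(0, 0, 0, -X, y * X)
  }
  if (nrow(A) < 9) A <- rbind(A, matrix(0, 9 - nrow(A), 9))
  hvec <- svd(A)$v[, 9]
  H <- matrix(hvec, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  H / H[3, 3]
}

.applyHomography <- function(H, p) {
  q <- cbind(p, 1) %*% t(H)
  q[, 1:2] / q[, 3]
}

.rvecToR <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  ax <- r / th
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

.RToRvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  th <- acos(pmin(1, pmax(-1, ct)))
  if (th < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  ax * th
}

# closest rotation matrix (polar decomposition)
.orthonormalize <- function(M) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R <- sv$u %*% diag(c(1, 1, -1)) %*% t(sv$v)
  R
}

# Zhang closed-form intrinsics from a list of homographies
.intrinsicsFromH <- function(Hs) {
  vij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H)
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))))
  b <- svd(V)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  v0 <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lam <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  fx <- sqrt(abs(lam / B11))
  fy <- sqrt(abs(lam * B11 / (B11 * B22 - B12^2)))
  u0 <- -B13 * fx^2 / lam
  c(fx = fx, fy = fy, cx = u0, cy = v0)
}

.extrinsicsFromH <- function(H, K) {
  Kinv <- solve(K)
  h1 <- Kinv %*% H[, 1]; h2 <- Kinv %*% H[, 2]; h3 <- Kinv %*% H[, 3]
  lam <- 1 / sqrt(sum(h1^2))
  r1 <- lam * h1; r2 <- lam * h2
  R <- .orthonormalize(cbind(r1, r2, .cross3(as.numeric(r1), as.numeric(r2))))
  t <- as.numeric(lam * h3)
  if (t[3] < 0) { R <- .orthonormalize(cbind(-r1, -r2,
                                             .cross3(as.numeric(-r1), as.numeric(-r2))))
                  t <- -t }
  list(R = R, t = t)
}

.projectSimple <- function(intr, R, t, board, dist = numeric()) {
  pc <- cbind(board, 0) %*% t(R)
  pc <- sweep(pc, 2, -t)
  xn <- pc[, 1] / pc[, 3]; yn <- pc[, 2] / pc[, 3]
  if (length(dist)) {
    r2 <- xn^2 + yn^2
    fac <- 1 + dist[1] * r2 + if (length(dist) > 1) dist[2] * r2^2 else 0
    xn <- xn * fac; yn <- yn * fac
  }
  cbind(intr[1] * xn + intr[3], intr[2] * yn + intr[4])
}

#' Stereo calibration from checkerboard views
#'
#' Per-camera Zhang calibration (normalized DLT homographies, closed-form
#' intrinsics, per-view extrinsics) followed by a joint Levenberg-Marquardt
#' refinement of both cameras' intrinsics, the shared relative pose and the
#' per-view board poses, minimizing reprojection error in both cameras.
#' Views where corner detection fails are excluded with a warning; at least
#' three usable views are required.
#'
#' @param views list of views; each view is a list of two elements, one per
#'   camera, each either a grayscale image matrix or a precomputed corner
#'   set (list with \code{px}, \code{board}) as returned by
#'   [detectCheckerboardCorners()].
#' @param spec a [checkerboardSpec()].
#' @param imageSize (width, height) in px of the cameras.
#' @param estimateDistortion estimate two radial terms per camera.
#' @return a [CalibrationResult-class]; camera 1 defines the world frame.
#' @export
calibrateStereo <- function(views, spec, imageSize,
                            estimateDistortion = FALSE) {
  getCorners <- function(v) {
    if (is.matrix(v)) detectCheckerboardCorners(v, spec) else v
  }
  usable <- list()
  for (i in seq_along(views)) {
    c1 <- getCorners(views[[i]][[1]])
    c2 <- getCorners(views[[i]][[2]])
    if (is.null(c1) || is.null(c2)) {
      warning("corner detection failed in view ", i, "; view excluded")
      next
    }
    usable[[length(usable) + 1]] <- list(c1 = c1, c2 = c2)
  }
  nv <- length(usable)
  if (nv < 3) stop("calibration needs at least 3 usable views (got ", nv, ")")
  board <- usable[[1]]$c1$board
  H1 <- lapply(usable, function(v) .homographyDLT(board, v$c1$px))
  H2 <- lapply(usable, function(v) .homographyDLT(board, v$c2$px))
  intr1 <- .intrinsicsFromH(H1)
  intr2 <- .intrinsicsFromH(H2)
  Kof <- function(i) matrix(c(i[1], 0, 0, 0, i[2], 0, i[3], i[4], 1), 3, 3)
  ex1 <- lapply(H1, .extrinsicsFromH, K = Kof(intr1))
  ex2 <- lapply(H2, .extrinsicsFromH, K = Kof(intr2))
  # relative pose averaged over views
  rel <- lapply(seq_len(nv), function(i) {
    R <- ex2[[i]]$R %*% t(ex1[[i]]$R)
    list(R = R, t = ex2[[i]]$t - R %*% ex1[[i]]$t)
  })
  Rrel <- .orthonormalize(Reduce(`+`, lapply(rel, `[[`, "R")) / nv)
  trel <- Reduce(`+`, lapply(rel, function(r) as.numeric(r$t))) / nv
  nd <- if (estimateDistortion) 2L else 0L
  pack <- function() {
    c(intr1, if (nd) c(0, 0), intr2, if (nd) c(0, 0),
      .RToRvec(Rrel), trel,
      unlist(lapply(ex1, function(e) c(.RToRvec(e$R), e$t))))
  }
  resid <- function(par) {
    i1 <- par[1:4]; o <- 4
    d1 <- if (nd) par[o + 1:2] else numeric(); o <- o + nd
    i2 <- par[o + 1:4]; o <- o + 4
    d2 <- if (nd) par[o + 1:2] else numeric(); o <- o + nd
    Rr <- .rvecToR(par[o + 1:3]); tr <- par[o + 4:6]; o <- o + 6
    out <- numeric(0)
    for (i in seq_len(nv)) {
      Rv <- .rvecToR(par[o + 1:3]); tv <- par[o + 4:6]; o <- o + 6
      p1 <- .projectSimple(i1, Rv, tv, board, d1)
      p2 <- .projectSimple(i2, Rr %*% Rv, as.numeric(Rr %*% tv) + tr, board, d2)
      out <- c(out, as.numeric(p1 - usable[[i]]$c1$px),
               as.numeric(p2 - usable[[i]]$c2$px))
    }
    out
  }
  fit <- minpack.lm::nls.lm(par = pack(), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ptol = 1e-12, ftol = 1e-12))
  par <- fit$par
  i1 <- par[1:4]; o <- 4
  d1 <- if (nd) par[o + 1:2] else numeric(); o <- o + nd
  i2 <- par[o + 1:4]; o <- o + 4
  d2 <- if (nd) par[o + 1:2] else numeric(); o <- o + nd
  Rr <- .rvecToR(par[o + 1:3]); tr <- par[o + 4:6]
  rms <- {
    r <- resid(par)
    m <- matrix(r^2, nrow = 2) # (dx, dy) per observed corner
    sqrt(mean(colSums(m)))
  }
  perView <- data.frame(view = seq_len(nv))
  cam1 <- cameraModel(i1[1:2], imageSize, principalPoint = i1[3:4],
                      distortion = d1)
  cam2 <- cameraModel(i2[1:2], imageSize, principalPoint = i2[3:4],
                      rotation = Rr, translation = as.numeric(tr),
                      distortion = d2)
  new("CalibrationResult", cameras = list(cam1, cam2),
      reprojectionError = rms, nViews = as.integer(nv), perView = perView)
}

#' Baseline length of a calibrated pair
#'
#' @param calib a [CalibrationResult-class].
#' @return distance between the two camera centers in mm.
#' @export
calibrationBaseline <- function(calib) {
  sqrt(sum((cameraCenter(calib@cameras[[1]]) -
            cameraCenter(calib@cameras[[2]]))^2))
}
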