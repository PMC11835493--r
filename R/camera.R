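#' Construct a pinhole camera
#'
#' @param focal focal length in pixels; scalar or (fx, fy).
#' @param principalPoint (cx, cy) in pixels; defaults to the image center.
#' @param imageSize (width, height) in pixels.
#' @param rotation 3 x 3 world-to-camera rotation.
#' @param translation length-3 vector t in \code{p_cam = R X + t} (mm).
#' @param distortion radial distortion coefficients (k1, k2, ...).
#' @return a [CameraModel-class].
#' @export
cameraModel <- function(focal, imageSize, principalPoint = (imageSize - 1) / 2,
                        rotation = diag(3), translation = c(0, 0, 0),
                        distortion = numeric()) {
  if (length(focal) == 1) focal <- c(focal, focal)
  new("CameraModel", focal = as.numeric(focal),
      principalPoint = as.numeric(principalPoint),
      imageSize = as.numeric(imageSize), rotation = rotation,
      translation = as.numeric(translation),
      distortion = as.numeric(distortion))
}

#' Aim a camera at a target point
#'
#' Positions the camera at \code{center} looking toward \code{target} with
#' the image x axis roughly aligned with world x (world +y maps toward image
#' +y, i.e. downward in the image).
#'
#' @param camera a [CameraModel-class] providing intrinsics.
#' @param center camera center in world coordinates (mm).
#' @param target point the optical axis passes through (mm).
#' @return the camera with its pose set.
#' @export
lookAtCamera <- function(camera, center, target = c(0, 0, 0)) {
  r3 <- target - center
  r3 <- r3 / sqrt(sum(r3^2))
  r1 <- .cross3(c(0, 1, 0), r3)
  n1 <- sqrt(sum(r1^2))
  if (n1 < 1e-9) stop("camera looks along the vertical; choose another up axis")
  r1 <- r1 / n1
  r2 <- .cross3(r3, r1)
  R <- rbind(r1, r2, r3)
  dimnames(R) <- NULL
  camera@rotation <- R
  camera@translation <- as.numeric(-R %*% center)
  validObject(camera)
  camera
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project world points to pixel coordinates
#'
#' Standard pinhole projection with optional radial distortion. Points at or
#' behind the camera plane are an error unless \code{allowBehind} is set (then
#' returned as NA rows).
#'
#' @param camera a [CameraModel-class].
#' @param points n x 3 matrix (or length-3 vector) of world positions (mm).
#' @param allowBehind return NA instead of erroring for points behind the
#'   camera.
#' @return n x 2 matrix of (x, y) pixel coordinates (0-based).
#' @export
project <- function(camera, points, allowBehind = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  pc <- points %*% t(camera@rotation)
  pc <- sweep(pc, 2, -camera@translation)
  behind <- pc[, 3] <= 1e-9
  if (any(behind) && !allowBehind)
    stop("point at or behind the camera plane cannot be projected")
  xn <- pc[, 1] / pc[, 3]
  yn <- pc[, 2] / pc[, 3]
  if (length(camera@distortion)) {
    r2 <- xn^2 + yn^2
    fac <- 1
    rp <- r2
    for (k in camera@distortion) {
      fac <- fac + k * rp
      rp <- rp * r2
    }
    xn <- xn * fac
    yn <- yn * fac
  }
  out <- cbind(camera@focal[1] * xn + camera@principalPoint[1],
               camera@focal[2] * yn + camera@principalPoint[2])
  out[behind, ] <- NA_real_
  out
}

#' Back-project pixels to world rays
#'
#' @param camera a [CameraModel-class].
#' @param px n x 2 matrix of pixel coordinates (0-based).
#' @return list with \code{origin} (camera center) and \code{dir} (n x 3 unit
#'   direction matrix in world coordinates).
#' @export
pixelRays <- function(camera, px) {
  if (is.null(dim(px))) px <- matrix(px, ncol = 2)
  xn <- (px[, 1] - camera@principalPoint[1]) / camera@focal[1]
  yn <- (px[, 2] - camera@principalPoint[2]) / camera@focal[2]
  if (length(camera@distortion)) {
    # invert the radial model by fixed-point iteration
    xd <- xn; yd <- yn
    for (i in 1:20) {
      r2 <- xn^2 + yn^2
      fac <- 1
      rp <- r2
      for (k in camera@distortion) {
        fac <- fac + k * rp
        rp <- rp * r2
      }
      xn <- xd / fac
      yn <- yd / fac
    }
  }
  d <- cbind(xn, yn, 1) %*% camera@rotation  # = t(R) %*% d_cam per row
  d <- d / sqrt(rowSums(d^2))
  list(origin = cameraCenter(camera), dir = d)
}

#' Triangulate matched pixel coordinates into 3-D points
#'
#' Midpoint (linear least squares) triangulation: each match yields the point
#' minimizing the summed squared distance to the two back-projected rays.
#' The per-point residual is the mean reprojection distance over the two
#' views. Matches whose rays subtend less than \code{minAngle} degrees are
#' flagged degenerate.
#'
#' @param px1,px2 n x 2 matrices of matched pixel coordinates in each camera.
#' @param cam1,cam2 the two [CameraModel-class] objects (distinct centers).
#' @param minAngle degeneracy threshold on the ray angle, degrees.
#' @return data.frame with columns X, Y, Z (mm), residual (px) and degenerate
#'   (logical).
#' @export
triangulatePoints <- function(px1, px2, cam1, cam2, minAngle = 0.1) {
  if (is.null(dim(px1))) px1 <- matrix(px1, ncol = 2)
  if (is.null(dim(px2))) px2 <- matrix(px2, ncol = 2)
  stopifnot(nrow(px1) == nrow(px2))
  c1 <- cameraCenter(cam1); c2 <- cameraCenter(cam2)
  if (sqrt(sum((c1 - c2)^2)) < 1e-9)
    stop("cameras must have distinct centers")
  r1 <- pixelRays(cam1, px1)
  r2 <- pixelRays(cam2, px2)
  n <- nrow(px1)
  X <- matrix(NA_real_, n, 3)
  # solve (sum_i (I - d_i d_i^T)) X = sum_i (I - d_i d_i^T) o_i per point
  for (i in seq_len(n)) {
    if (anyNA(r1$dir[i, ]) || anyNA(r2$dir[i, ])) next
    P1 <- diag(3) - tcrossprod(r1$dir[i, ])
    P2 <- diag(3) - tcrossprod(r2$dir[i, ])
    A <- P1 + P2
    b <- P1 %*% c1 + P2 %*% c2
    X[i, ] <- tryCatch(as.numeric(solve(A, b)), error = function(e) NA_real_)
  }
  cosang <- rowSums(r1$dir * r2$dir)
  degenerate <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi < minAngle
  p1 <- project(cam1, X, allowBehind = TRUE)
  p2 <- project(cam2, X, allowBehind = TRUE)
  res <- 0.5 * (sqrt(rowSums((p1 - px1)^2)) + sqrt(rowSums((p2 - px2)^2)))
  data.frame(X = X[, 1], Y = X[, 2], Z = X[, 3], residual = res,
             degenerate = degenerate)
}

#' Build a verged two-camera rig
#'
#' Two cameras separated horizontally by \code{baseline} mm at a working
#' distance \code{distance} mm from the origin, both aimed at the origin.
#' This reproduces one calibrated pair of the four-camera acquisition square
#' (cameras at the corners of a 20 x 20 cm square roughly 30 cm from the
#' skin).
#'
#' @param focal focal length in pixels.
#' @param imageSize (width, height) in pixels.
#' @param baseline camera separation in mm.
#' @param distance working distance in mm.
#' @return list of two [CameraModel-class] objects.
#' @export
stereoRig <- function(focal = 3000, imageSize = c(700, 500), baseline = 200,
                      distance = 300) {
  proto <- cameraModel(focal, imageSize)
  list(lookAtCamera(proto, c(-baseline / 2, 0, -distance)),
       lookAtCamera(proto, c(baseline / 2, 0, -distance)))
}

#' Rotate a camera rig about an axis through the origin
#'
#' Used for the changed-viewing-angle validation conditions: the whole rig is
#' rotated rigidly about an in-plane axis through the patch center.
#'
#' @param rig list of [CameraModel-class] objects.
#' @param axis "x", "y" or "z".
#' @param angleDeg rotation angle in degrees.
#' @return the rotated rig.
#' @export
rotateRig <- function(rig, axis = "x", angleDeg = 15) {
  Q <- rotationMatrix(axis, angleDeg)
  lapply(rig, function(cam) {
    # world transforms by Q; camera pose follows: R' = R Q^T, t unchanged
    cam@rotation <- cam@rotation %*% t(Q)
    validObject(cam)
    cam
  })
}

#' Central pixel footprint of a camera
#'
#' @param camera a [CameraModel-class].
#' @param distance working distance along the optical axis in mm.
#' @return mm covered by one central pixel.
#' @export
pixelFootprint <- function(camera, distance) {
  distance / mean(camera@focal)
}

#' Perturb a stereo rig to a target reprojection-error regime
#'
#' Emulates imperfect calibration: a random perturbation direction of each
#' camera's rotation, translation and principal point is drawn and scaled
#' (secant search on a linear predictor) so that triangulating exact
#' correspondences of \code{refPoints} with the perturbed rig yields the
#' requested RMS reprojection error.
#'
#' @param rig list of two [CameraModel-class] objects (ground truth).
#' @param refPoints n x 3 matrix of scene points used to gauge the error.
#' @param targetRMS target RMS reprojection error in pixels.
#' @return list with \code{rig} (perturbed cameras), \code{rms} (achieved
#'   reprojection RMS in px).
#' @export
perturbRig <- function(rig, refPoints, targetRMS = 3) {
  dir1 <- list(rot = stats::rnorm(3), t = stats::rnorm(3), pp = stats::rnorm(2))
  dir2 <- list(rot = stats::rnorm(3), t = stats::rnorm(3), pp = stats::rnorm(2))
  px1 <- project(rig[[1]], refPoints)
  px2 <- project(rig[[2]], refPoints)
  apply_s <- function(s) {
    pert <- function(cam, d) {
      ax <- d$rot / sqrt(sum(d$rot^2))
      ang <- s * 0.002 * sqrt(sum(d$rot^2))  # radians
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
      dR <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      cam@rotation <- dR %*% cam@rotation
      cam@translation <- cam@translation + s * 0.5 * d$t
      cam@principalPoint <- cam@principalPoint + s * 2 * d$pp
      cam
    }
    list(pert(rig[[1]], dir1), pert(rig[[2]], dir2))
  }
  rmsOf <- function(s) {
    pr <- apply_s(s)
    tri <- triangulatePoints(px1, px2, pr[[1]], pr[[2]])
    sqrt(mean(tri$residual^2))
  }
  # secant iteration on the (near-linear) error-vs-scale curve
  s1 <- 1; e1 <- rmsOf(s1)
  s2 <- targetRMS / e1; e2 <- rmsOf(s2)
  for (i in 1:10) {
    if (abs(e2 - targetRMS) <= 0.05 * targetRMS || abs(e2 - e1) < 1e-12) break
    s3 <- s2 + (targetRMS - e2) * (s2 - s1) / (e2 - e1)
    s1 <- s2; e1 <- e2
    s2 <- s3; e2 <- rmsOf(s2)
  }
  list(rig = apply_s(s2), rms = e2)
}
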