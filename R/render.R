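#' Render a deformed, textured surface through a camera
#'
#' Inverse-mapped rendering: every pixel's ray is intersected with the
#' deformed surface by a vectorized Newton iteration on (u, v, t), the
#' recovered material coordinate is looked up in the speckle texture with
#' bicubic interpolation, and optional additive Gaussian intensity noise is
#' applied. There is no lighting model: the patterns are high-contrast ink
#' and the validation protocol images flat printouts.
#'
#' @param surface a [SurfacePatch-class] giving the material domain.
#' @param texture a [SpecklePattern-class] covering the domain.
#' @param model a [DeformationModel-class] mapping material coordinates to
#'   deformed positions.
#' @param camera a [CameraModel-class].
#' @param noiseSD standard deviation of additive Gaussian noise (intensity
#'   units; the image range is [0, 1]). Noise draws come from the R RNG, so
#'   seed the session for reproducible images.
#' @param background intensity of pixels that see no part of the patch.
#' @param maxIter Newton iterations for the ray-surface intersection.
#' @return numeric matrix (rows = y, cols = x) of intensities in [0, 1].
#' @export
renderView <- function(surface, texture, model, camera, noiseSD = 0,
                       background = 0.85, maxIter = 8) {
  w <- camera@imageSize[1]; h <- camera@imageSize[2]
  px <- cbind(rep(seq_len(w) - 1, times = h), rep(seq_len(h) - 1, each = w))
  rays <- pixelRays(camera, px)
  o <- rays$origin
  d <- rays$dir
  # initialize on the z = 0 plane
  tt <- (0 - o[3]) / d[, 3]
  u <- o[1] + tt * d[, 1]
  v <- o[2] + tt * d[, 2]
  hstep <- 1e-4
  for (it in seq_len(maxIter)) {
    P <- model@map(cbind(u, v))
    rx <- o[1] + tt * d[, 1] - P[, 1]
    ry <- o[2] + tt * d[, 2] - P[, 2]
    rz <- o[3] + tt * d[, 3] - P[, 3]
    if (max(abs(rx), abs(ry), abs(rz)) < 1e-9) break
    Pu <- (model@map(cbind(u + hstep, v)) - P) / hstep
    Pv <- (model@map(cbind(u, v + hstep)) - P) / hstep
    # solve [d, -Pu, -Pv] (dt, du, dv)^T = -r per pixel (3x3, closed form)
    a11 <- d[, 1]; a12 <- -Pu[, 1]; a13 <- -Pv[, 1]
    a21 <- d[, 2]; a22 <- -Pu[, 2]; a23 <- -Pv[, 2]
    a31 <- d[, 3]; a32 <- -Pu[, 3]; a33 <- -Pv[, 3]
    det <- a11 * (a22 * a33 - a23 * a32) -
           a12 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * a32 - a22 * a31)
    det[abs(det) < 1e-14] <- NA
    b1 <- -rx; b2 <- -ry; b3 <- -rz
    dt <- (b1 * (a22 * a33 - a23 * a32) -
           a12 * (b2 * a33 - a23 * b3) +
           a13 * (b2 * a32 - a22 * b3)) / det
    du <- (a11 * (b2 * a33 - a23 * b3) -
           b1 * (a21 * a33 - a23 * a31) +
           a13 * (a21 * b3 - b2 * a31)) / det
    dv <- (a11 * (a22 * b3 - b2 * a32) -
           a12 * (a21 * b3 - b2 * a31) +
           b1 * (a21 * a32 - a22 * a31)) / det
    bad <- !is.finite(dt) | !is.finite(du) | !is.finite(dv)
    dt[bad] <- 0; du[bad] <- 0; dv[bad] <- 0
    tt <- tt + dt; u <- u + du; v <- v + dv
    if (max(abs(du), abs(dv)) < 1e-10) break
  }
  dom <- surface@domain
  inside <- u >= dom["umin"] & u <= dom["umax"] &
            v >= dom["vmin"] & v <= dom["vmax"]
  tx <- materialToPixel(texture, cbind(u, v))
  val <- interpBicubicCpp(texture@image, tx[, 1], tx[, 2])
  val[!inside | is.na(val)] <- background
  if (!any(inside)) stop("patch fully outside the camera frustum: empty view")
  img <- matrix(val, nrow = h, ncol = w, byrow = TRUE)
  if (noiseSD > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noiseSD), h, w)
  img <- pmin(pmax(img, 0), 1)
  img
}
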