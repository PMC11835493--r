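#' Flat rectangular surface patch
#'
#' Reference embedding (u, v) -> (u, v, 0) on a centered rectangular domain.
#'
#' @param width,height patch extent in mm.
#' @param center (u, v) of the patch center in mm.
#' @return a [SurfacePatch-class].
#' @export
flatPatch <- function(width = 40, height = 30, center = c(0, 0)) {
  dom <- c(umin = center[1] - width / 2, umax = center[1] + width / 2,
           vmin = center[2] - height / 2, vmax = center[2] + height / 2)
  new("SurfacePatch",
      mapping = function(uv) cbind(uv[, 1], uv[, 2], 0),
      domain = dom)
}

.strainFrame <- function(principal, orthogonal, theta) {
  data.frame(principal = principal, orthogonal = orthogonal, theta = theta)
}

# principal/orthogonal/theta from two orthogonal engineering stretches
# su along u, sv along v (fractions)
.axisStrainGT <- function(su, sv) {
  principal <- 100 * pmax(su, sv)
  orthogonal <- 100 * pmin(su, sv)
  theta <- ifelse(su >= sv, 0, 90)
  theta[abs(su - sv) < 1e-15] <- 0
  .strainFrame(principal, orthogonal, theta)
}

#' Identity deformation
#'
#' @return a [DeformationModel-class] with zero ground-truth stretch.
#' @export
identityModel <- function() {
  new("DeformationModel", name = "identity",
      map = function(uv) cbind(uv[, 1], uv[, 2], 0),
      strain = function(uv) .axisStrainGT(rep(0, nrow(uv)), rep(0, nrow(uv))),
      params = list())
}

#' Rigid motion of the flat patch
#'
#' Rotation followed by translation; ground-truth stretch is exactly zero.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @return a [DeformationModel-class].
#' @export
rigidMotionModel <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)),
            max(abs(crossprod(rotation) - diag(3))) < 1e-8)
  force(rotation); force(translation)
  new("DeformationModel", name = "rigid",
      map = function(uv) {
        p <- cbind(uv[, 1], uv[, 2], 0)
        sweep(p %*% t(rotation), 2, -translation)
      },
      strain = function(uv) .axisStrainGT(rep(0, nrow(uv)), rep(0, nrow(uv))),
      params = list(rotation = rotation, translation = translation))
}

#' Uniform uniaxial stretch
#'
#' \code{(u, v) -> ((1 + magnitude) u, v, 0)}: ground-truth principal stretch
#' is \code{100 * magnitude} percent along u, orthogonal stretch zero.
#'
#' @param magnitude stretch as a fraction (> -1); 0.33 is the 33% validation
#'   condition.
#' @return a [DeformationModel-class].
#' @export
uniaxialStretch <- function(magnitude) {
  stopifnot(magnitude > -1)
  force(magnitude)
  new("DeformationModel", name = "uniaxial",
      map = function(uv) cbind((1 + magnitude) * uv[, 1], uv[, 2], 0),
      strain = function(uv) .axisStrainGT(rep(magnitude, nrow(uv)),
                                          rep(0, nrow(uv))),
      params = list(magnitude = magnitude))
}

#' Linear stretch ramp along the u axis
#'
#' Local engineering stretch grows linearly along u:
#' \code{s(u) = base + gradient/1000 * (u - origin)} (gradient in percent per
#' cm, u in mm). Positions integrate the local stretch so the ground-truth
#' stretch field is exactly linear with the stated gradient.
#'
#' @param gradient stretch gradient in percent per cm.
#' @param base stretch fraction at \code{u = origin}.
#' @param origin u coordinate (mm) where the ramp starts.
#' @return a [DeformationModel-class]. Evaluating it where the local stretch
#'   would reach -100% is a domain error.
#' @export
rampStretch <- function(gradient, base = 0, origin = 0) {
  g <- gradient / 1000  # fraction per mm
  force(base); force(origin)
  localS <- function(u) base + g * (u - origin)
  new("DeformationModel", name = "ramp",
      map = function(uv) {
        u <- uv[, 1]
        s <- localS(u)
        if (any(s <= -1))
          stop("domain too large for ramp gradient: local stretch reaches -100%")
        d <- u - origin
        cbind(origin + d + base * d + g * d^2 / 2, uv[, 2], 0)
      },
      strain = function(uv) {
        s <- localS(uv[, 1])
        if (any(s <= -1))
          stop("domain too large for ramp gradient: local stretch reaches -100%")
        .axisStrainGT(s, rep(0, nrow(uv)))
      },
      params = list(gradient = gradient, base = base, origin = origin))
}

#' Out-of-plane bulge or contraction
#'
#' A smooth radial Gaussian bump emulating cheek puffing (positive amplitude)
#' or pouting (negative amplitude). The apex also expands (or contracts)
#' in-plane, as an inflating membrane does, so the orthogonal
#' (circumferential) stretch is positive near the apex of an outward bulge
#' and negative for an inward contraction.
#'
#' With radial profile \code{g(r) = exp(-r^2 / (2 sigma^2))}, \code{sigma =
#' radius / 2}, the map is \code{rho(r) = r (1 + beta g(r))}, \code{z(r) =
#' amplitude * g(r)}, \code{beta = kappa * amplitude / radius}. Ground-truth
#' stretches follow from the surface metric: circumferential stretch
#' \code{rho / r} and radial stretch \code{sqrt(rho'(r)^2 + z'(r)^2)}.
#'
#' @param amplitude apex height in mm (negative for an inward contraction).
#' @param radius bump radius scale in mm (> 0).
#' @param center (u, v) of the apex.
#' @param kappa in-plane coupling of the apex expansion (dimensionless).
#' @return a [DeformationModel-class].
#' @export
bulge <- function(amplitude, radius, center = c(0, 0), kappa = 0.3) {
  stopifnot(radius > 0)
  sigma <- radius / 2
  beta <- kappa * amplitude / radius
  force(center)
  gfun <- function(r) exp(-r^2 / (2 * sigma^2))
  new("DeformationModel", name = "bulge",
      map = function(uv) {
        du <- uv[, 1] - center[1]; dv <- uv[, 2] - center[2]
        r <- sqrt(du^2 + dv^2)
        fac <- 1 + beta * gfun(r)
        cbind(center[1] + du * fac, center[2] + dv * fac, amplitude * gfun(r))
      },
      strain = function(uv) {
        du <- uv[, 1] - center[1]; dv <- uv[, 2] - center[2]
        r <- sqrt(du^2 + dv^2)
        g <- gfun(r)
        gp <- -r / sigma^2 * g            # g'(r)
        lamC <- 1 + beta * g              # circumferential
        rhop <- 1 + beta * g + beta * r * gp
        zp <- amplitude * gp
        lamR <- sqrt(rhop^2 + zp^2)       # radial
        thR <- atan2(dv, du) * 180 / pi   # radial direction (axial angle)
        prin <- 100 * (pmax(lamR, lamC) - 1)
        orth <- 100 * (pmin(lamR, lamC) - 1)
        theta <- ifelse(lamR >= lamC, thR, thR + 90)
        theta <- theta %% 180
        # at the apex the deformation is isotropic; pick theta = 0
        theta[r < 1e-12] <- 0
        .strainFrame(prin, orth, theta)
      },
      params = list(amplitude = amplitude, radius = radius, center = center,
                    kappa = kappa))
}

#' Compose a deformation with a subsequent rigid motion
#'
#' Post-multiplying by a rigid motion leaves the ground-truth stretch
#' magnitudes and the material-frame orientation unchanged.
#'
#' @param model a [DeformationModel-class].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @return a [DeformationModel-class].
#' @export
composeRigid <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is(model, "DeformationModel"))
  innerMap <- model@map
  force(rotation); force(translation)
  new("DeformationModel", name = paste0(model@name, "+rigid"),
      map = function(uv) sweep(innerMap(uv) %*% t(rotation), 2, -translation),
      strain = model@strain,
      params = c(model@params, list(postRotation = rotation,
                                    postTranslation = translation)))
}

#' Evaluate a deformation model
#'
#' @param model a [DeformationModel-class].
#' @param uv n x 2 matrix (or length-2 vector) of material coordinates (mm).
#' @return n x 3 matrix of deformed positions.
#' @export
deformPoints <- function(model, uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2)
  model@map(uv)
}

#' Ground-truth strain of a deformation model
#'
#' @inheritParams deformPoints
#' @return data.frame with columns \code{principal}, \code{orthogonal}
#'   (percent) and \code{theta} (degrees, axial).
#' @export
groundTruthStrain <- function(model, uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, ncol = 2)
  model@strain(uv)
}

#' Rotation matrix about a coordinate axis
#'
#' @param axis "x", "y" or "z".
#' @param angleDeg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotationMatrix <- function(axis = c("x", "y", "z"), angleDeg) {
  axis <- match.arg(axis)
  a <- angleDeg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3))
}
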