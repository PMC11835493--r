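#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib dermastretch, .registration = TRUE
NULL

#' Speckle pattern generation parameters
#'
#' Physical parameters of an ink speckle texture: nominal dot diameter (mm),
#' target ink area fraction, per-dot diameter jitter fraction, canvas size
#' (mm), raster scale (px/mm) and the RNG seed that makes the pattern
#' reproducible.
#'
#' @slot dotDiameter nominal dot diameter in mm.
#' @slot dotDensity target ink-covered area fraction in (0, 1).
#' @slot dotVariation per-dot diameter jitter fraction in [0, 1]; each dot's
#'   diameter is drawn uniformly from \code{dotDiameter * [1 - dotVariation, 1]}.
#' @slot canvasSize width and height of the canvas in mm.
#' @slot rasterScale pixels per mm of the rendered texture.
#' @slot seed integer RNG seed.
#' @exportClass SpeckleParams
setClass("SpeckleParams",
  representation(dotDiameter = "numeric", dotDensity = "numeric",
                 dotVariation = "numeric", canvasSize = "numeric",
                 rasterScale = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@dotDiameter <= 0) msg <- c(msg, "dotDiameter must be > 0")
    if (object@dotDensity <= 0 || object@dotDensity >= 1)
      msg <- c(msg, "dotDensity must be in (0, 1)")
    if (object@dotVariation < 0 || object@dotVariation > 1)
      msg <- c(msg, "dotVariation must be in [0, 1]")
    if (length(object@canvasSize) != 2 || any(object@canvasSize <= 0))
      msg <- c(msg, "canvasSize must be two positive lengths (mm)")
    if (object@rasterScale <= 0) msg <- c(msg, "rasterScale must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Rasterized speckle pattern
#'
#' A grayscale raster texture in [0, 1] (ink dark, background bright) with a
#' physical scale and the material coordinate of pixel (0, 0).
#'
#' @slot image numeric matrix, rows = y, columns = x, intensities in [0, 1].
#' @slot scale pixels per mm.
#' @slot origin material (u, v) coordinate (mm) of pixel (0, 0).
#' @slot params the generating [SpeckleParams-class].
#' @exportClass SpecklePattern
setClass("SpecklePattern",
  representation(image = "matrix", scale = "numeric", origin = "numeric",
                 params = "SpeckleParams"),
  validity = function(object) {
    msg <- character()
    rng <- range(object@image)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      msg <- c(msg, "intensities must be normalized to [0, 1]")
    if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
    if (length(object@origin) != 2) msg <- c(msg, "origin must be length 2")
    if (length(msg)) msg else TRUE
  })

#' Parametric reference surface patch
#'
#' Maps material coordinates (u, v) in mm to reference 3-D positions in mm.
#' The flat patch maps (u, v) to (u, v, 0).
#'
#' @slot mapping function taking an n x 2 matrix of (u, v) and returning an
#'   n x 3 matrix of positions.
#' @slot domain named numeric: umin, umax, vmin, vmax (mm).
#' @exportClass SurfacePatch
setClass("SurfacePatch",
  representation(mapping = "function", domain = "numeric"))

#' Analytic deformation model with closed-form ground-truth strain
#'
#' A map from material coordinates to deformed 3-D positions together with
#' the analytic principal/orthogonal stretch and principal orientation it
#' induces, used as simulation ground truth.
#'
#' @slot name preset name.
#' @slot map function: n x 2 material (u, v) -> n x 3 deformed position (mm).
#' @slot strain function: n x 2 material (u, v) -> data.frame with columns
#'   \code{principal}, \code{orthogonal} (engineering stretch in percent) and
#'   \code{theta} (axial principal direction in degrees from the u axis).
#' @slot params list of model parameters.
#' @exportClass DeformationModel
setClass("DeformationModel",
  representation(name = "character", map = "function", strain = "function",
                 params = "list"))

#' Pinhole camera
#'
#' Intrinsics, pose and optional radial distortion. Convention: right-handed
#' coordinates, the camera looks down its +z axis, pixel (0, 0) is top-left
#' and pixel centers sit at integer coordinates. A world point X projects via
#' p_cam = R X + t.
#'
#' @slot focal (fx, fy) in pixels.
#' @slot principalPoint (cx, cy) in pixels.
#' @slot imageSize (width, height) in pixels.
#' @slot rotation 3 x 3 rotation matrix (world to camera).
#' @slot translation length-3 vector (mm).
#' @slot distortion radial coefficients (k1, k2, ...); empty means none.
#' @exportClass CameraModel
setClass("CameraModel",
  representation(focal = "numeric", principalPoint = "numeric",
                 imageSize = "numeric", rotation = "matrix",
                 translation = "numeric", distortion = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(object@focal <= 0)) msg <- c(msg, "focal must be > 0")
    R <- object@rotation
    if (!all(dim(R) == c(3, 3)) ||
        max(abs(crossprod(R) - diag(3))) > 1e-6 ||
        abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal with determinant +1")
    if (length(object@translation) != 3) msg <- c(msg, "translation must be length 3")
    if (length(msg)) msg else TRUE
  })

#' Stereo calibration result
#'
#' @slot cameras list of two [CameraModel-class] objects (camera 1 frame is
#'   the reference).
#' @slot reprojectionError RMS reprojection error in pixels over all views.
#' @slot nViews number of checkerboard views used.
#' @slot perView data.frame of per-view diagnostics.
#' @exportClass CalibrationResult
setClass("CalibrationResult",
  representation(cameras = "list", reprojectionError = "numeric",
                 nViews = "integer", perView = "data.frame"),
  validity = function(object) {
    if (object@reprojectionError < 0) "reprojectionError must be >= 0" else TRUE
  })

#' Regular grid of DIC subset centers
#'
#' @slot centers n x 2 matrix of (x, y) pixel coordinates (0-based).
#' @slot index n x 2 integer matrix of grid (column, row) indices.
#' @slot dims (ncol, nrow) of the grid.
#' @slot radius subset half-width in pixels.
#' @slot spacing grid spacing in pixels.
#' @exportClass SubsetGrid
setClass("SubsetGrid",
  representation(centers = "matrix", index = "matrix", dims = "integer",
                 radius = "numeric", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@spacing < 1) msg <- c(msg, "spacing must be >= 1")
    if (object@radius < object@spacing)
      msg <- c(msg, "radius must be >= spacing (subsets must overlap)")
    if (length(msg)) msg else TRUE
  })

#' Field of subset correspondences between two images
#'
#' One correspondence per grid center with subpixel target position, local
#' affine warp, ZNCC score and a status flag
#' (matched / low_score / out_of_bounds / diverged).
#'
#' @slot grid the [SubsetGrid-class] the field is defined on.
#' @slot correspondences data.frame with columns ref_x, ref_y, tgt_x, tgt_y,
#'   ux, uy, vx, vy, score, status.
#' @slot pairing label of the image pair, e.g. "cam1_ref->cam2_ref".
#' @exportClass MatchField
setClass("MatchField",
  representation(grid = "SubsetGrid", correspondences = "data.frame",
                 pairing = "character"))

#' Triangulated mesh of tracked points with paired reference/deformed positions
#'
#' @slot verticesRef n x 3 reference 3-D positions (mm).
#' @slot verticesDef n x 3 deformed 3-D positions (mm), same indexing.
#' @slot faces m x 3 integer matrix of vertex index triples (1-based).
#' @slot scores per-vertex DIC provenance scores.
#' @slot gridIndex n x 2 grid (column, row) indices of the originating subsets.
#' @slot material n x 2 material (u, v) coordinates when known (synthetic
#'   scenes), otherwise a 0-row matrix.
#' @exportClass TrackedMesh
setClass("TrackedMesh",
  representation(verticesRef = "matrix", verticesDef = "matrix",
                 faces = "matrix", scores = "numeric", gridIndex = "matrix",
                 material = "matrix"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@verticesRef)
    if (!identical(dim(object@verticesRef), dim(object@verticesDef)))
      msg <- c(msg, "reference and deformed vertices must have identical dimensions")
    if (nrow(object@faces) > 0 &&
        (min(object@faces) < 1 || max(object@faces) > n))
      msg <- c(msg, "faces must reference valid vertices")
    if (length(msg)) msg else TRUE
  })

#' Per-triangle membrane strain field
#'
#' @slot mesh the [TrackedMesh-class] the strains were computed on.
#' @slot triangles data.frame with one row per face: in-plane Green-Lagrange
#'   components (E11, E12, E22), principal and orthogonal engineering stretch
#'   in percent, 3-D principal orientation (unit vector, canonical sign),
#'   reference area (mm^2), area ratio and a status flag.
#' @slot summary list of summary statistics.
#' @exportClass StrainField
setClass("StrainField",
  representation(mesh = "TrackedMesh", triangles = "data.frame",
                 summary = "list"))

#' Best-fitting plane of a tracked patch
#'
#' @slot point a point on the plane (mm).
#' @slot normal unit normal.
#' @slot axes 3 x 2 matrix of orthonormal in-plane axes.
#' @slot inPlaneFraction strain-weighted fraction of principal-direction
#'   magnitude lying in the plane (1 for planar scenes).
#' @exportClass FittedPlane
setClass("FittedPlane",
  representation(point = "numeric", normal = "numeric", axes = "matrix",
                 inPlaneFraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(sum(object@normal^2) - 1) > 1e-6) msg <- c(msg, "normal must be unit")
    A <- object@axes
    if (max(abs(crossprod(A) - diag(2))) > 1e-6)
      msg <- c(msg, "in-plane axes must be orthonormal")
    if (max(abs(crossprod(A, object@normal))) > 1e-6)
      msg <- c(msg, "axes must be orthogonal to the normal")
    if (length(msg)) msg else TRUE
  })

#' Plane-projected stretch map on a regular grid
#'
#' @slot resolution cell size in mm.
#' @slot origin plane coordinates (mm) of the center of cell (1, 1).
#' @slot values matrix of stretch magnitudes (percent); NA where masked.
#' @slot orientations matrix of axial angles (degrees in [0, 180)); NA where
#'   masked.
#' @slot mask logical matrix; TRUE where the cell is inside the projected patch.
#' @slot plane the [FittedPlane-class] defining the projection.
#' @exportClass GridMap
setClass("GridMap",
  representation(resolution = "numeric", origin = "numeric",
                 values = "matrix", orientations = "matrix", mask = "matrix",
                 plane = "FittedPlane"),
  validity = function(object) {
    msg <- character()
    if (object@resolution <= 0) msg <- c(msg, "resolution must be > 0")
    if (!identical(dim(object@values), dim(object@mask)))
      msg <- c(msg, "values and mask must have identical dimensions")
    if (any(!is.na(object@values[!object@mask])))
      msg <- c(msg, "cells outside the patch must be masked (NA)")
    if (length(msg)) msg else TRUE
  })

#' Axial orientation statistics
#'
#' Circular statistics of axial (mod 180 degrees) orientation data computed
#' on doubled angles.
#'
#' @slot axialMean mean orientation in degrees, in [0, 180).
#' @slot angularSD circular standard deviation on the axial scale (degrees).
#' @slot histogram data.frame with columns \code{binCenter} (degrees) and
#'   \code{freq} (relative frequency, sums to 1).
#' @slot n number of observations.
#' @exportClass OrientationStats
setClass("OrientationStats",
  representation(axialMean = "numeric", angularSD = "numeric",
                 histogram = "data.frame", n = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@angularSD < 0) msg <- c(msg, "angularSD must be >= 0")
    if (nrow(object@histogram) &&
        abs(sum(object@histogram$freq) - 1) > 1e-9)
      msg <- c(msg, "histogram must sum to 1")
    if (length(msg)) msg else TRUE
  })
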