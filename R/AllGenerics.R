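#' Accessors for dermastretch objects
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patternImage", function(x) standardGeneric("patternImage"))

#' @rdname accessors
#' @export
setGeneric("patternScale", function(x) standardGeneric("patternScale"))

#' @rdname accessors
#' @export
setGeneric("vertices", function(x, ...) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname accessors
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))

#' @rdname accessors
#' @export
setGeneric("correspondences", function(x) standardGeneric("correspondences"))

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' @rdname accessors
#' @export
setGeneric("cameraCenter", function(x) standardGeneric("cameraCenter"))

setMethod("patternImage", "SpecklePattern", function(x) x@image)
setMethod("patternScale", "SpecklePattern", function(x) x@scale)

setMethod("vertices", "TrackedMesh", function(x, pose = c("reference", "deformed")) {
  pose <- match.arg(pose)
  if (pose == "reference") x@verticesRef else x@verticesDef
})
setMethod("meshFaces", "TrackedMesh", function(x) x@faces)
setMethod("strains", "StrainField", function(x) x@triangles)
setMethod("correspondences", "MatchField", function(x) x@correspondences)
setMethod("gridValues", "GridMap", function(x) x@values)
setMethod("gridMask", "GridMap", function(x) x@mask)
setMethod("cameraCenter", "CameraModel",
          function(x) as.numeric(-crossprod(x@rotation, x@translation)))

setMethod("show", "SpecklePattern", function(object) {
  d <- dim(object@image)
  cat(sprintf("SpecklePattern: %d x %d px (%.1f x %.1f mm at %g px/mm)\n",
              d[2], d[1], d[2] / object@scale, d[1] / object@scale,
              object@scale))
  cat(sprintf("  measured ink fraction: %.3f (target %.3f)\n",
              inkFraction(object), object@params@dotDensity))
})

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel: %d x %d px, f = (%.1f, %.1f) px\n",
              object@imageSize[1], object@imageSize[2],
              object@focal[1], object@focal[2]))
  cc <- cameraCenter(object)
  cat(sprintf("  center: (%.1f, %.1f, %.1f) mm; distortion: %s\n",
              cc[1], cc[2], cc[3],
              if (length(object@distortion)) paste(signif(object@distortion, 3),
                                                   collapse = ", ") else "none"))
})

setMethod("show", "SubsetGrid", function(object) {
  cat(sprintf("SubsetGrid: %d centers (%d x %d), radius %g px, spacing %g px\n",
              nrow(object@centers), object@dims[1], object@dims[2],
              object@radius, object@spacing))
})

setMethod("show", "MatchField", function(object) {
  st <- table(object@correspondences$status)
  cat(sprintf("MatchField [%s]: %d subsets\n", object@pairing,
              nrow(object@correspondences)))
  cat("  ", paste(names(st), as.integer(st), sep = ": ", collapse = ", "), "\n")
})

setMethod("show", "TrackedMesh", function(object) {
  cat(sprintf("TrackedMesh: %d vertices, %d faces\n",
              nrow(object@verticesRef), nrow(object@faces)))
})

setMethod("show", "StrainField", function(object) {
  s <- object@summary
  cat(sprintf("StrainField: %d triangles (%d valid)\n",
              nrow(object@triangles), s$nValid))
  cat(sprintf("  principal stretch: mean %.2f%% [p5 %.2f, p95 %.2f]; orthogonal mean %.2f%%\n",
              s$meanPrincipal, s$p5Principal, s$p95Principal, s$meanOrthogonal))
})

setMethod("show", "FittedPlane", function(object) {
  cat(sprintf("FittedPlane: normal (%.3f, %.3f, %.3f), in-plane strain fraction %.3f\n",
              object@normal[1], object@normal[2], object@normal[3],
              object@inPlaneFraction))
})

setMethod("show", "GridMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridMap: %d x %d cells at %g mm (%d unmasked)\n",
              d[2], d[1], object@resolution, sum(object@mask)))
})

setMethod("show", "OrientationStats", function(object) {
  cat(sprintf("OrientationStats: n = %d, axial mean %.1f deg, angular SD %.2f deg\n",
              object@n, object@axialMean, object@angularSD))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: %d views, RMS reprojection error %.3f px\n",
              object@nViews, object@reprojectionError))
})

setMethod("show", "DeformationModel", function(object) {
  cat(sprintf("DeformationModel '%s'\n", object@name))
  if (length(object@params))
    cat("  ", paste(names(object@params),
                    vapply(object@params, function(p) paste(signif(unlist(p), 4), collapse = ","), ""),
                    sep = "=", collapse = ", "), "\n")
})
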