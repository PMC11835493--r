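#' Write a grayscale image as PNG
#'
#' @param img matrix of intensities in [0, 1].
#' @param path output path.
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

.RToQuat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s, s / 4)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[i] <- s / 4
    q[j] <- (R[j, i] + R[i, j]) / s
    q[k] <- (R[k, i] + R[i, k]) / s
    q[4] <- (R[k, j] - R[j, k]) / s
  }
  q / sqrt(sum(q^2)) # (x, y, z, w)
}

.quatToR <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + z * w), 2 * (x * z - y * w),
           2 * (x * y - z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z + x * w),
           2 * (x * z + y * w), 2 * (y * z - x * w), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Serialize cameras to a YAML file
#'
#' Stores, per camera, the intrinsic matrix, rotation as a quaternion
#' (x, y, z, w), translation (mm) and radial distortion list.
#'
#' @param cameras list of [CameraModel-class] objects.
#' @param path output YAML path.
#' @param reprojectionError optional RMS reprojection error (px) to record.
#' @export
writeCameraYAML <- function(cameras, path, reprojectionError = NULL) {
  enc <- lapply(cameras, function(cam) {
    list(intrinsics = list(fx = cam@focal[1], fy = cam@focal[2],
                           cx = cam@principalPoint[1],
                           cy = cam@principalPoint[2]),
         image_size = as.numeric(cam@imageSize),
         rotation_quaternion = as.numeric(.RToQuat(cam@rotation)),
         translation_mm = as.numeric(cam@translation),
         distortion = as.numeric(cam@distortion))
  })
  out <- list(cameras = enc)
  if (!is.null(reprojectionError))
    out$reprojection_error_px <- reprojectionError
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname writeCameraYAML
#' @export
readCameraYAML <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y$cameras, function(e) {
    cameraModel(c(e$intrinsics$fx, e$intrinsics$fy),
                imageSize = unlist(e$image_size),
                principalPoint = c(e$intrinsics$cx, e$intrinsics$cy),
                rotation = .quatToR(unlist(e$rotation_quaternion)),
                translation = unlist(e$translation_mm),
                distortion = as.numeric(unlist(e$distortion)))
  })
}

#' Write a match field as CSV
#'
#' Columns: ref_x, ref_y, tgt_x, tgt_y, score, status, pairing.
#'
#' @param field a [MatchField-class].
#' @param path output CSV path.
#' @export
writeMatchField <- function(field, path) {
  cor <- field@correspondences
  out <- data.frame(ref_x = cor$ref_x, ref_y = cor$ref_y,
                    tgt_x = cor$tgt_x, tgt_y = cor$tgt_y,
                    score = cor$score, status = cor$status,
                    pairing = field@pairing)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a grid map as plain text with a YAML header
#'
#' The matrix (rows = plane y, NA for masked cells) is written to
#' \code{path}; origin, resolution and the plane definition go to
#' \code{<path>.yaml}.
#'
#' @param map a [GridMap-class].
#' @param path output path of the matrix file.
#' @export
writeGridMap <- function(map, path) {
  utils::write.table(map@values, path, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(
    resolution_mm = map@resolution,
    origin_mm = as.numeric(map@origin),
    plane = list(point = as.numeric(map@plane@point),
                 normal = as.numeric(map@plane@normal),
                 axes = lapply(1:2, function(i) as.numeric(map@plane@axes[, i])),
                 in_plane_fraction = map@plane@inPlaneFraction)),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Write per-triangle strains as CSV
#'
#' @param field a [StrainField-class].
#' @param path output CSV path.
#' @export
writeStrainCSV <- function(field, path) {
  utils::write.csv(field@triangles, path, row.names = FALSE)
  invisible(path)
}

#' Write an axial orientation histogram as CSV
#'
#' Columns: bin center (degrees) and relative frequency; the axial mean and
#' angular SD are recorded as comment header lines.
#'
#' @param stats an [OrientationStats-class].
#' @param path output CSV path.
#' @export
writeOrientationCSV <- function(stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axial_mean_deg: %.6f", stats@axialMean), con)
  writeLines(sprintf("# angular_sd_deg: %.6f", stats@angularSD), con)
  utils::write.csv(stats@histogram, con, row.names = FALSE)
  invisible(path)
}
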