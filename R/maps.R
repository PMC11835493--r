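#' Area-weighted quantile with linear interpolation
#'
#' Values are sorted and assigned plotting positions at the midpoints of
#' their cumulative weights, \code{(cum_i - w_i/2) / W}; quantiles
#' interpolate linearly between adjacent order statistics and clamp at the
#' extremes. With equal weights this reduces to the usual midpoint
#' (type-5-like) sample quantile.
#'
#' @param x numeric values.
#' @param w nonnegative weights.
#' @param p probabilities in [0, 1].
#' @return quantile(s) of the weighted distribution.
#' @export
weightedQuantile <- function(x, w, p) {
  stopifnot(length(x) == length(w), all(w >= 0))
  keep <- is.finite(x) & w > 0
  x <- x[keep]; w <- w[keep]
  if (!length(x)) return(rep(NA_real_, length(p)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  W <- sum(w)
  pos <- (cumsum(w) - w / 2) / W
  vapply(p, function(pp) {
    if (pp <= pos[1]) return(x[1])
    if (pp >= pos[length(pos)]) return(x[length(x)])
    stats::approx(pos, x, xout = pp, ties = "ordered")$y
  }, numeric(1))
}

#' Fit the best plane to a tracked patch
#'
#' Principal-axes fit minimizing squared orthogonal distance to the
#' reference vertices. When given a [StrainField-class] the in-plane strain
#' fraction is also computed: each triangle's principal direction is
#' decomposed into plane-parallel and plane-normal parts, weighted by the
#' magnitude of its principal stretch, and the fraction is the weighted mean
#' in-plane component. Exactly planar patches give fraction 1.
#'
#' @param x a [StrainField-class] or [TrackedMesh-class] (for a mesh the
#'   strain field is computed first).
#' @return a [FittedPlane-class].
#' @export
fitPlane <- function(x) {
  if (is(x, "TrackedMesh")) x <- strainField(x)
  stopifnot(is(x, "StrainField"))
  v <- x@mesh@verticesRef
  if (.collinear3d(v)) stop("vertices collinear: cannot fit a plane")
  ctr <- colMeans(v)
  sv <- svd(sweep(v, 2, ctr))
  axes <- sv$v[, 1:2, drop = FALSE]
  normal <- sv$v[, 3]
  # deterministic signs
  fix <- function(a) {
    i <- which.max(abs(a))
    if (a[i] < 0) -a else a
  }
  normal <- fix(normal)
  axes[, 1] <- fix(axes[, 1])
  axes[, 2] <- .cross3(normal, axes[, 1])
  tri <- x@triangles
  ok <- tri$status == "ok"
  w <- abs(tri$principal[ok])
  d <- as.matrix(tri[ok, c("ox", "oy", "oz")])
  if (sum(w) > 0) {
    dn <- as.numeric(d %*% normal)
    inplane <- sqrt(pmax(0, 1 - dn^2))
    frac <- sum(w * inplane) / sum(w)
  } else frac <- 1
  new("FittedPlane", point = as.numeric(ctr), normal = as.numeric(normal),
      axes = axes, inPlaneFraction = frac)
}

#' Project points to plane coordinates
#'
#' @param plane a [FittedPlane-class].
#' @param points n x 3 matrix (mm).
#' @return n x 2 matrix of in-plane coordinates (mm).
#' @export
planeCoordinates <- function(plane, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(points, 2, plane@point) %*% plane@axes
}

#' Resample a strain field onto a regular plane grid
#'
#' Triangle centroids are projected onto the fitted plane; each grid cell
#' takes the area-weighted mean of the triangles whose centroid falls in it.
#' Orientations are averaged axially (doubled-angle vector mean). Empty
#' cells within two cells of an occupied one are filled from their nearest
#' occupied neighbor; everything else stays masked.
#'
#' @param field a [StrainField-class].
#' @param plane a [FittedPlane-class] fitted to the same mesh.
#' @param resolution cell size in mm (default 1, the mapping resolution used
#'   throughout).
#' @param value which stretch to map: "principal", "orthogonal" or
#'   "areaChange" (percent area change, 100 (areaRatio - 1)).
#' @return a [GridMap-class].
#' @export
resampleGrid <- function(field, plane, resolution = 1,
                         value = c("principal", "orthogonal", "areaChange")) {
  value <- match.arg(value)
  if (resolution <= 0) stop("resolution must be > 0")
  tri <- field@triangles
  ok <- tri$status == "ok"
  tri <- tri[ok, , drop = FALSE]
  if (!nrow(tri)) stop("no valid triangles to resample")
  s <- planeCoordinates(plane, as.matrix(tri[, c("cx", "cy", "cz")]))
  val <- switch(value,
                principal = tri$principal,
                orthogonal = tri$orthogonal,
                areaChange = 100 * (tri$areaRatio - 1))
  # axial orientation angle in plane coordinates
  d <- as.matrix(tri[, c("ox", "oy", "oz")])
  ang <- atan2(d %*% plane@axes[, 2], d %*% plane@axes[, 1]) * 180 / pi
  ang <- ang %% 180
  w <- tri$refArea
  x0 <- min(s[, 1]); y0 <- min(s[, 2])
  ci <- floor((s[, 1] - x0) / resolution) + 1L
  cj <- floor((s[, 2] - y0) / resolution) + 1L
  nx <- max(ci); ny <- max(cj)
  acc <- function(z) {
    m <- matrix(0, ny, nx)
    mm <- matrix(0, ny, nx)
    for (k in seq_along(z)) {
      m[cj[k], ci[k]] <- m[cj[k], ci[k]] + w[k] * z[k]
      mm[cj[k], ci[k]] <- mm[cj[k], ci[k]] + w[k]
    }
    list(sum = m, w = mm)
  }
  av <- acc(val)
  ac <- acc(cos(2 * ang * pi / 180))
  as_ <- acc(sin(2 * ang * pi / 180))
  occupied <- av$w > 0
  values <- ifelse(occupied, av$sum / pmax(av$w, 1e-300), NA_real_)
  orient <- ifelse(occupied,
                   (atan2(as_$sum, ac$sum) / 2 * 180 / pi) %% 180, NA_real_)
  # nearest-neighbor fill within 2 cells
  mask <- occupied
  if (any(!occupied) && any(occupied)) {
    occIdx <- which(occupied, arr.ind = TRUE)
    empty <- which(!occupied, arr.ind = TRUE)
    for (k in seq_len(nrow(empty))) {
      d2 <- (occIdx[, 1] - empty[k, 1])^2 + (occIdx[, 2] - empty[k, 2])^2
      j <- which.min(d2)
      if (d2[j] <= 4) {
        values[empty[k, 1], empty[k, 2]] <- values[occIdx[j, , drop = FALSE]]
        orient[empty[k, 1], empty[k, 2]] <- orient[occIdx[j, , drop = FALSE]]
        mask[empty[k, 1], empty[k, 2]] <- TRUE
      }
    }
  }
  origin <- c(x0 + resolution / 2, y0 + resolution / 2)
  new("GridMap", resolution = resolution, origin = origin, values = values,
      orientations = orient, mask = mask, plane = plane)
}

# plane coordinates of every cell center; rows of values are y (j), cols x (i)
.cellCenters <- function(map) {
  ny <- nrow(map@values); nx <- ncol(map@values)
  xs <- map@origin[1] + (seq_len(nx) - 1) * map@resolution
  ys <- map@origin[2] + (seq_len(ny) - 1) * map@resolution
  list(x = xs, y = ys)
}

#' Mean spatial stretch gradient of a grid map
#'
#' Central-difference gradient of the stretch field; the statistic is the
#' mean gradient magnitude over cells where both components exist, in
#' percent per cm.
#'
#' @param map a [GridMap-class].
#' @return mean |gradient| in percent/cm, or NA (with a message) when fewer
#'   than a 2 x 2 block of unmasked cells is available.
#' @export
stretchGradient <- function(map) {
  v <- map@values
  ny <- nrow(v); nx <- ncol(v)
  if (sum(map@mask) < 4 || ny < 2 || nx < 2) {
    message("too few unmasked cells: stretch gradient undefined")
    return(NA_real_)
  }
  res <- map@resolution
  gx <- matrix(NA_real_, ny, nx)
  gy <- matrix(NA_real_, ny, nx)
  if (nx >= 3)
    gx[, 2:(nx - 1)] <- (v[, 3:nx] - v[, 1:(nx - 2)]) / (2 * res)
  if (ny >= 3)
    gy[2:(ny - 1), ] <- (v[3:ny, ] - v[1:(ny - 2), ]) / (2 * res)
  mag <- sqrt(gx^2 + gy^2)
  m <- mean(mag[is.finite(mag)])
  if (!is.finite(m)) {
    message("too few unmasked cells: stretch gradient undefined")
    return(NA_real_)
  }
  10 * m  # percent/mm -> percent/cm
}

#' Axial orientation statistics
#'
#' Circular statistics for axial data (angles modulo 180 degrees): angles
#' are doubled, the weighted circular mean and circular standard deviation
#' (sqrt(-2 ln R), in radians) are computed, and both are halved back to the
#' axial scale. The histogram covers [0, 180) or, when \code{center} is
#' TRUE, [-90, 90) after subtracting the axial mean.
#'
#' @param angles orientations in degrees (any representative of the axial
#'   class).
#' @param weights optional nonnegative weights.
#' @param bins number of histogram bins.
#' @param center center the histogram on the axial mean.
#' @return an [OrientationStats-class].
#' @export
axialStats <- function(angles, weights = NULL, bins = 36L, center = FALSE) {
  if (!length(angles)) stop("need at least one angle")
  if (is.null(weights)) weights <- rep(1, length(angles))
  keep <- is.finite(angles) & is.finite(weights)
  angles <- angles[keep]; weights <- weights[keep]
  W <- sum(weights)
  if (W <= 0) stop("zero total weight")
  th2 <- 2 * angles * pi / 180
  C <- sum(weights * cos(th2)) / W
  S <- sum(weights * sin(th2)) / W
  R <- sqrt(C^2 + S^2)
  axialMean <- (atan2(S, C) / 2 * 180 / pi) %% 180
  angularSD <- if (R <= 0) Inf else 0.5 * sqrt(-2 * log(R)) * 180 / pi
  if (center) {
    rel <- ((angles - axialMean + 90) %% 180) - 90
    edges <- seq(-90, 90, length.out = bins + 1)
  } else {
    rel <- angles %% 180
    edges <- seq(0, 180, length.out = bins + 1)
  }
  bi <- pmin(bins, pmax(1L, findInterval(rel, edges, rightmost.closed = TRUE)))
  freq <- vapply(seq_len(bins), function(b) sum(weights[bi == b]) / W,
                 numeric(1))
  hist <- data.frame(binCenter = (edges[-1] + edges[-(bins + 1)]) / 2,
                     freq = freq)
  new("OrientationStats", axialMean = axialMean, angularSD = angularSD,
      histogram = hist, n = length(angles))
}

#' Stretch profile along an axis in plane coordinates
#'
#' Every unmasked cell's plane coordinate is projected onto the straight
#' line through the two anchors; cells are binned by projected distance and
#' per-bin means and counts are reported. Distances are straight-line plane
#' distances, an approximation to geodesic distance on strongly curved
#' patches.
#'
#' @param map a [GridMap-class].
#' @param anchors 2 x 2 matrix of plane coordinates (mm), one anchor per
#'   row; distance is measured from the first anchor along the direction of
#'   the second.
#' @param binCm bin width in cm.
#' @return data.frame with columns \code{binCenter} (cm), \code{mean}
#'   (percent; NA for empty bins) and \code{count}.
#' @export
profileAlongAxis <- function(map, anchors, binCm = 1) {
  stopifnot(all(dim(anchors) == c(2, 2)))
  u <- anchors[2, ] - anchors[1, ]
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) stop("anchors must be distinct")
  u <- u / nu
  cc <- .cellCenters(map)
  X <- cbind(rep(cc$x, each = nrow(map@values)),
             rep(cc$y, times = ncol(map@values)))
  keep <- as.vector(map@mask) & is.finite(as.vector(map@values))
  t_cm <- ((X[, 1] - anchors[1, 1]) * u[1] +
           (X[, 2] - anchors[1, 2]) * u[2]) / 10
  t_cm <- t_cm[keep]
  vals <- as.vector(map@values)[keep]
  edges <- seq(floor(min(t_cm) / binCm) * binCm,
               ceiling(max(t_cm) / binCm) * binCm + 1e-9, by = binCm)
  bi <- findInterval(t_cm, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  out <- data.frame(
    binCenter = (edges[-1] + edges[-length(edges)]) / 2,
    mean = vapply(seq_len(nb), function(b)
      if (any(bi == b)) mean(vals[bi == b]) else NA_real_, numeric(1)),
    count = vapply(seq_len(nb), function(b) sum(bi == b), numeric(1)))
  out
}

#' Area-weighted summary of a strain field
#'
#' Mean, 5th and 95th percentile of principal stretch plus mean orthogonal
#' stretch, all area-weighted over valid triangles.
#'
#' @param field a [StrainField-class].
#' @return named list: meanPrincipal, p5Principal, p95Principal,
#'   meanOrthogonal (percent).
#' @export
percentileSummary <- function(field) {
  tri <- field@triangles
  ok <- tri$status == "ok"
  if (!any(ok)) stop("no valid triangles")
  w <- tri$refArea[ok]
  list(meanPrincipal = sum(w * tri$principal[ok]) / sum(w),
       p5Principal = weightedQuantile(tri$principal[ok], w, 0.05),
       p95Principal = weightedQuantile(tri$principal[ok], w, 0.95),
       meanOrthogonal = sum(w * tri$orthogonal[ok]) / sum(w))
}

#' Axial orientation statistics of a grid map or strain field
#'
#' Convenience wrapper: orientations are taken from the resampled grid (the
#' default path) or from raw triangles, weighted by cell occupancy or
#' triangle area respectively.
#'
#' @param x a [GridMap-class] or [StrainField-class].
#' @param ... passed to [axialStats()].
#' @return an [OrientationStats-class].
#' @export
orientationStats <- function(x, ...) {
  if (is(x, "GridMap")) {
    keep <- x@mask & is.finite(x@orientations)
    return(axialStats(x@orientations[keep], ...))
  }
  stopifnot(is(x, "StrainField"))
  tri <- x@triangles
  ok <- tri$status == "ok"
  plane <- fitPlane(x)
  d <- as.matrix(tri[ok, c("ox", "oy", "oz")])
  ang <- (atan2(d %*% plane@axes[, 2], d %*% plane@axes[, 1]) * 180 / pi) %% 180
  axialStats(as.numeric(ang), weights = tri$refArea[ok], ...)
}
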