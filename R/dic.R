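#' Regular grid of subset centers
#'
#' Centers are laid out on a regular lattice leaving enough margin for the
#' subset and the interpolation stencil. Defaults follow the full-scale
#' processing settings: subset half-width 60 px, spacing 10 px, so that
#' neighboring subsets overlap heavily.
#'
#' @param imageSize (width, height) in pixels.
#' @param radius subset half-width in pixels.
#' @param spacing center spacing in pixels (>= 1; must not exceed radius).
#' @param margin border kept free of centers; defaults to \code{radius + 2}.
#' @param region optional region of interest \code{c(xmin, xmax, ymin, ymax)}
#'   in pixels restricting the centers, e.g. the projection of the speckled
#'   patch so that every subset sees only tracked material.
#' @return a [SubsetGrid-class].
#' @export
subsetGrid <- function(imageSize, radius = 60, spacing = 10,
                       margin = radius + 2, region = NULL) {
  xs <- seq(margin, imageSize[1] - 1 - margin, by = spacing)
  ys <- seq(margin, imageSize[2] - 1 - margin, by = spacing)
  if (!is.null(region)) {
    xs <- xs[xs >= region[1] & xs <= region[2]]
    ys <- ys[ys >= region[3] & ys <= region[4]]
  }
  if (!length(xs) || !length(ys))
    stop("image too small for the requested subset radius/margin")
  centers <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  index <- cbind(rep(seq_along(xs), times = length(ys)),
                 rep(seq_along(ys), each = length(xs)))
  new("SubsetGrid", centers = centers, index = index,
      dims = c(length(xs), length(ys)), radius = radius, spacing = spacing)
}

.statusLabels <- c("matched", "low_score", "out_of_bounds", "diverged")

.statusFromCode <- function(code) .statusLabels[code + 1L]

#' Integer-displacement subset matching by ZNCC
#'
#' For every subset center the zero-normalized cross-correlation is maximized
#' over integer displacements within the search window; ties break toward the
#' smallest displacement magnitude, then lexicographically. Flat
#' (zero-variance) subsets are flagged \code{low_score} with score 0.
#'
#' @param ref,target grayscale image matrices (rows = y).
#' @param grid a [SubsetGrid-class].
#' @param searchRadius half-width of the integer search window in pixels.
#' @param init optional n x 2 matrix of initial integer displacements.
#' @param radius optional override of the subset half-width used for the
#'   search (defaults to the grid radius).
#' @return a [MatchField-class]; the ZNCC values around each peak are kept in
#'   \code{attr(correspondences(field), "nbhd")} for subpixel refinement.
#' @export
matchInteger <- function(ref, target, grid, searchRadius = 10, init = NULL,
                         radius = grid@radius) {
  n <- nrow(grid@centers)
  if (is.null(init)) init <- matrix(0, n, 2)
  res <- matchIntegerCpp(ref, target, grid@centers[, 1], grid@centers[, 2],
                         as.integer(radius), as.integer(searchRadius),
                         init[, 1], init[, 2])
  cor <- data.frame(
    ref_x = grid@centers[, 1], ref_y = grid@centers[, 2],
    tgt_x = grid@centers[, 1] + res$dx, tgt_y = grid@centers[, 2] + res$dy,
    ux = 0, uy = 0, vx = 0, vy = 0,
    score = res$score, status = .statusFromCode(res$status),
    stringsAsFactors = FALSE)
  attr(cor, "nbhd") <- res$nbhd
  new("MatchField", grid = grid, correspondences = cor,
      pairing = "unlabelled")
}

# 1-D parabola subpixel offset from 3 samples, clamped to half a pixel
.parabolaOffset <- function(sm, s0, sp) {
  den <- sm - 2 * s0 + sp
  off <- ifelse(is.na(den) | abs(den) < 1e-15, 0, 0.5 * (sm - sp) / den)
  pmin(0.5, pmax(-0.5, ifelse(is.na(off), 0, off)))
}

# local affine seeding: least-squares plane fit of the integer displacement
# field over neighboring grid points
.affineSeeds <- function(grid, dx, dy, good, window = 2L) {
  n <- nrow(grid@centers)
  p <- matrix(0, n, 6)
  idx <- grid@index
  dims <- grid@dims
  lut <- matrix(NA_integer_, dims[1], dims[2])
  lut[cbind(idx[, 1], idx[, 2])] <- seq_len(n)
  sp <- grid@spacing
  for (i in seq_len(n)) {
    if (!good[i]) next
    ci <- idx[i, 1]; ri <- idx[i, 2]
    cs <- max(1, ci - window):min(dims[1], ci + window)
    rs <- max(1, ri - window):min(dims[2], ri + window)
    nb <- lut[cs, rs]
    nb <- nb[!is.na(nb)]
    nb <- nb[good[nb]]
    p[i, 1] <- dx[i]
    p[i, 4] <- dy[i]
    if (length(nb) >= 4) {
      X <- cbind(1, grid@centers[nb, 1] - grid@centers[i, 1],
                 grid@centers[nb, 2] - grid@centers[i, 2])
      fit <- tryCatch(qr.coef(qr(X), cbind(dx[nb], dy[nb])),
                      error = function(e) NULL)
      if (!is.null(fit) && !anyNA(fit)) {
        p[i, 1] <- fit[1, 1]; p[i, 2] <- fit[2, 1]; p[i, 3] <- fit[3, 1]
        p[i, 4] <- fit[1, 2]; p[i, 5] <- fit[2, 2]; p[i, 6] <- fit[3, 2]
        # keep the measured displacement at the point itself
        p[i, 1] <- dx[i]; p[i, 4] <- dy[i]
      }
    }
  }
  p
}

#' Subpixel refinement of an integer match field
#'
#' Two-stage refinement: a quadratic fit of the ZNCC surface around the
#' integer peak seeds an iterative inverse-compositional Gauss-Newton
#' optimization with a first-order (affine) subset shape function and bicubic
#' interpolation. Convergence requires the parameter update norm to drop
#' below \code{tol} px within \code{maxIter} iterations, else the point is
#' flagged \code{diverged}. The affine terms are seeded from a local plane
#' fit of the neighboring integer displacements, which lets the optimization
#' start inside its convergence basin even under large strains.
#'
#' @param field a [MatchField-class] from [matchInteger()].
#' @param ref,target the images the field was computed on.
#' @param mode \code{"icgn"} (default) or \code{"quadratic"} (stop after the
#'   quadratic stage).
#' @param scoreThreshold matches below this final ZNCC are flagged
#'   \code{low_score}.
#' @param maxIter,tol Gauss-Newton iteration cap and convergence tolerance.
#' @param minIntegerScore integer-stage ZNCC below which a subset is flagged
#'   \code{low_score} without attempting refinement (a peak at noise level
#'   has no convergence basin).
#' @return the refined [MatchField-class].
#' @export
refineSubpixel <- function(field, ref, target, mode = c("icgn", "quadratic"),
                           scoreThreshold = 0.8, maxIter = 50L, tol = 1e-4,
                           minIntegerScore = 0.3) {
  mode <- match.arg(mode)
  grid <- field@grid
  cor <- field@correspondences
  nbhd <- attr(cor, "nbhd")
  n <- nrow(cor)
  dx <- cor$tgt_x - cor$ref_x
  dy <- cor$tgt_y - cor$ref_y
  qx <- qy <- rep(0, n)
  if (!is.null(nbhd)) {
    qx <- .parabolaOffset(nbhd[, 4], nbhd[, 5], nbhd[, 6])
    qy <- .parabolaOffset(nbhd[, 2], nbhd[, 5], nbhd[, 8])
  }
  # subsets whose integer peak is already down at noise level cannot converge;
  # flag them without spending Gauss-Newton iterations on them
  hopeless <- cor$status == "matched" & cor$score < minIntegerScore
  cor$status[hopeless] <- "low_score"
  good <- cor$status == "matched"
  if (mode == "quadratic") {
    cor$tgt_x <- cor$ref_x + dx + ifelse(good, qx, 0)
    cor$tgt_y <- cor$ref_y + dy + ifelse(good, qy, 0)
    attr(cor, "nbhd") <- nbhd
    field@correspondences <- cor
    return(field)
  }
  seeds <- .affineSeeds(grid, dx, dy, good)
  seeds[, 1] <- seeds[, 1] + ifelse(good, qx, 0)
  seeds[, 4] <- seeds[, 4] + ifelse(good, qy, 0)
  res <- list(p = seeds, score = cor$score, iters = rep(0L, n),
              status = rep(1L, n))
  if (any(good)) {
    sub <- refineICGNCpp(ref, target, cor$ref_x[good], cor$ref_y[good],
                         seeds[good, , drop = FALSE],
                         as.integer(grid@radius), as.integer(maxIter), tol)
    res$p[good, ] <- sub$p
    res$score[good] <- sub$score
    res$status[good] <- sub$status
  }
  upd <- good & res$status == 0L
  cor$tgt_x[upd] <- cor$ref_x[upd] + res$p[upd, 1]
  cor$tgt_y[upd] <- cor$ref_y[upd] + res$p[upd, 4]
  cor$ux[upd] <- res$p[upd, 2]; cor$uy[upd] <- res$p[upd, 3]
  cor$vx[upd] <- res$p[upd, 5]; cor$vy[upd] <- res$p[upd, 6]
  cor$score[upd] <- res$score[upd]
  newStatus <- cor$status
  newStatus[good & res$status == 2L] <- "out_of_bounds"
  newStatus[good & res$status == 3L] <- "diverged"
  low <- upd & cor$score < scoreThreshold
  newStatus[low] <- "low_score"
  cor$status <- newStatus
  attr(cor, "nbhd") <- NULL
  field@correspondences <- cor
  field
}

# block-mean downsampling by an integer factor (crops the remainder)
.blockMean <- function(img, f) {
  h2 <- nrow(img) %/% f; w2 <- ncol(img) %/% f
  arr <- array(img[seq_len(h2 * f), seq_len(w2 * f)], c(f, h2, f, w2))
  colMeans(aperm(arr, c(1, 3, 2, 4)), dims = 2)
}

# bilinear interpolation of a displacement component sampled on the coarse
# subgrid of grid indices; invalid coarse samples are filled from their
# nearest valid neighbor first
.interpCoarse <- function(coarseIdx, val, dims, queryIdx) {
  grd <- matrix(NA_real_, max(coarseIdx[, 1]), max(coarseIdx[, 2]))
  grd[coarseIdx] <- val
  if (anyNA(grd)) {
    ok <- which(!is.na(grd), arr.ind = TRUE)
    if (!nrow(ok)) return(rep(0, nrow(queryIdx)))
    bad <- which(is.na(grd), arr.ind = TRUE)
    for (k in seq_len(nrow(bad))) {
      d2 <- (ok[, 1] - bad[k, 1])^2 + (ok[, 2] - bad[k, 2])^2
      grd[bad[k, 1], bad[k, 2]] <- grd[ok[which.min(d2), , drop = FALSE]]
    }
  }
  qx <- pmin(pmax(queryIdx[, 1], 1), nrow(grd))
  qy <- pmin(pmax(queryIdx[, 2], 1), ncol(grd))
  x0 <- pmin(floor(qx), nrow(grd) - 1); y0 <- pmin(floor(qy), ncol(grd) - 1)
  if (nrow(grd) == 1) x0 <- rep(1, length(qx))
  if (ncol(grd) == 1) y0 <- rep(1, length(qy))
  fx <- qx - x0; fy <- qy - y0
  x1 <- pmin(x0 + 1, nrow(grd)); y1 <- pmin(y0 + 1, ncol(grd))
  grd[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    grd[cbind(x1, y0)] * fx * (1 - fy) +
    grd[cbind(x0, y1)] * (1 - fx) * fy +
    grd[cbind(x1, y1)] * fx * fy
}

#' Match two images coarse-to-fine with subpixel refinement
#'
#' Full matching strategy for production image pairs: an integer ZNCC pass on
#' block-averaged images seeds the dense integer pass (small residual search,
#' reduced subset), which in turn seeds the affine Gauss-Newton refinement at
#' the full subset radius. Large inter-camera or inter-pose displacements are
#' absorbed by the coarse pass, so no epipolar geometry is needed.
#'
#' @param ref,target grayscale image matrices.
#' @param grid a [SubsetGrid-class].
#' @param searchRadius full-resolution search half-width in px; defaults to a
#'   quarter of the image width.
#' @param coarseFactor block-mean downsampling factor of the coarse pass.
#' @param intRadius subset half-width of the dense integer pass.
#' @param fineSearch residual integer search around the coarse prediction.
#' @param scoreThreshold ZNCC below which a subset is flagged.
#' @param pairing label stored on the returned field.
#' @return a [MatchField-class].
#' @export
matchImages <- function(ref, target, grid,
                        searchRadius = round(0.25 * ncol(ref)),
                        coarseFactor = 4L, intRadius = min(15, grid@radius),
                        fineSearch = 10L, scoreThreshold = 0.8,
                        pairing = "pair") {
  refC <- .blockMean(ref, coarseFactor)
  tgtC <- .blockMean(target, coarseFactor)
  # coarse subgrid: at most ~200 textured points
  n <- nrow(grid@centers)
  k <- max(1L, ceiling(sqrt(n / 200)))
  sel <- (grid@index[, 1] - 1L) %% k == 0 & (grid@index[, 2] - 1L) %% k == 0
  cc <- grid@centers[sel, , drop = FALSE] / coarseFactor
  # a small coarse subset stays correlated even at large strains (a 33%
  # stretch shifts the edge of a half-width-8 subset by less than a coarse
  # dot diameter); wrong isolated peaks are then removed by median filtering
  # rather than by a score gate, which would also discard strained content
  rC <- max(6L, min(8L, (min(dim(refC)) - 4L) %/% 4L))
  sC <- as.integer(ceiling(searchRadius / coarseFactor))
  resC <- matchIntegerCpp(refC, tgtC, cc[, 1], cc[, 2], rC, sC,
                          rep(0, nrow(cc)), rep(0, nrow(cc)))
  okC <- resC$status == 0L & resC$score > 0.2
  ci <- cbind((grid@index[sel, 1] - 1L) %/% k + 1L,
              (grid@index[sel, 2] - 1L) %/% k + 1L)
  qi <- cbind((grid@index[, 1] - 1) / k + 1, (grid@index[, 2] - 1) / k + 1)
  if (any(okC)) {
    # 3x3 median filtering of the coarse displacement field (consensus of
    # the neighborhood replaces isolated outliers)
    dxg <- matrix(NA_real_, max(ci[, 1]), max(ci[, 2]))
    dyg <- dxg
    dxg[ci[okC, , drop = FALSE]] <- resC$dx[okC]
    dyg[ci[okC, , drop = FALSE]] <- resC$dy[okC]
    medfilt <- function(g) {
      out <- g
      for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
        nb <- g[max(1, i - 1):min(nrow(g), i + 1),
                max(1, j - 1):min(ncol(g), j + 1)]
        nb <- nb[!is.na(nb)]
        if (length(nb) >= 3) out[i, j] <- stats::median(nb)
      }
      out
    }
    dxg <- medfilt(dxg)
    dyg <- medfilt(dyg)
    valid <- which(!is.na(dxg), arr.ind = TRUE)
    initx <- .interpCoarse(valid, dxg[valid] * coarseFactor, NULL, qi)
    inity <- .interpCoarse(valid, dyg[valid] * coarseFactor, NULL, qi)
  } else {
    initx <- inity <- rep(0, n)
  }
  field <- matchInteger(ref, target, grid, searchRadius = fineSearch,
                        init = cbind(round(initx), round(inity)),
                        radius = intRadius)
  field <- refineSubpixel(field, ref, target, scoreThreshold = scoreThreshold)
  field@pairing <- pairing
  field
}

# subset texture mask: reference subsets with enough intensity variation
.texturedMask <- function(img, grid, radius = grid@radius, minSD = 0.02) {
  vapply(seq_len(nrow(grid@centers)), function(i) {
    x0 <- grid@centers[i, 1]; y0 <- grid@centers[i, 2]
    xs <- (x0 - radius):(x0 + radius) + 1
    ys <- (y0 - radius):(y0 + radius) + 1
    if (min(xs) < 1 || min(ys) < 1 || max(xs) > ncol(img) || max(ys) > nrow(img))
      return(FALSE)
    stats::sd(img[ys, xs]) > minSD
  }, logical(1))
}

#' Track subsets across cameras and poses
#'
#' Anchors every tracked point on the grid of camera 1's reference image and
#' matches it (i) into camera 2 at the reference pose, (ii) into camera 1 at
#' the deformed pose and (iii) into camera 2 at the deformed pose. Points
#' matched in all three fields are triangulated in both poses, yielding
#' paired 3-D positions per tracked point; the rest are dropped with their
#' failure reason kept in the match fields.
#'
#' @param refImages,defImages lists of two image matrices (cameras 1 and 2).
#' @param camerasRef,camerasDef lists of two [CameraModel-class] objects used
#'   for triangulation in each pose.
#' @param grid a [SubsetGrid-class] on camera 1's reference image.
#' @param searchRadius,scoreThreshold,coarseFactor passed to [matchImages()].
#' @param minMatchedFraction abort threshold: if fewer than this fraction of
#'   textured subsets survive all three matches the pipeline fails, mirroring
#'   acquisitions where reliable image correlations could not be found.
#' @return list with \code{points} (data.frame: grid indices, reference and
#'   deformed 3-D positions, scores, residuals) and \code{fields} (the three
#'   [MatchField-class] objects).
#' @export
trackPoseChain <- function(refImages, defImages, camerasRef, camerasDef, grid,
                           searchRadius = round(0.25 * ncol(refImages[[1]])),
                           scoreThreshold = 0.8, coarseFactor = 4L,
                           minMatchedFraction = 0.5) {
  fS <- matchImages(refImages[[1]], refImages[[2]], grid, searchRadius,
                    coarseFactor, scoreThreshold = scoreThreshold,
                    pairing = "cam1_ref->cam2_ref")
  fP <- matchImages(refImages[[1]], defImages[[1]], grid, searchRadius,
                    coarseFactor, scoreThreshold = scoreThreshold,
                    pairing = "cam1_ref->cam1_def")
  fQ <- matchImages(refImages[[1]], defImages[[2]], grid, searchRadius,
                    coarseFactor, scoreThreshold = scoreThreshold,
                    pairing = "cam1_ref->cam2_def")
  cS <- fS@correspondences; cP <- fP@correspondences; cQ <- fQ@correspondences
  ok <- cS$status == "matched" & cP$status == "matched" & cQ$status == "matched"
  textured <- .texturedMask(refImages[[1]], grid)
  if (sum(textured) == 0 || sum(ok) / max(1, sum(textured)) < minMatchedFraction)
    stop("reliable image correlations could not be found for most subsets (",
         sum(ok), "/", sum(textured), " textured subsets matched)")
  triRef <- triangulatePoints(grid@centers[ok, , drop = FALSE],
                              cbind(cS$tgt_x, cS$tgt_y)[ok, , drop = FALSE],
                              camerasRef[[1]], camerasRef[[2]])
  triDef <- triangulatePoints(cbind(cP$tgt_x, cP$tgt_y)[ok, , drop = FALSE],
                              cbind(cQ$tgt_x, cQ$tgt_y)[ok, , drop = FALSE],
                              camerasDef[[1]], camerasDef[[2]])
  pts <- data.frame(
    gi = grid@index[ok, 1], gj = grid@index[ok, 2],
    refX = triRef$X, refY = triRef$Y, refZ = triRef$Z,
    defX = triDef$X, defY = triDef$Y, defZ = triDef$Z,
    score = pmin(cS$score[ok], cP$score[ok], cQ$score[ok]),
    residRef = triRef$residual, residDef = triDef$residual)
  keep <- stats::complete.cases(pts) & !triRef$degenerate & !triDef$degenerate
  list(points = pts[keep, , drop = FALSE], fields = list(fS, fP, fQ),
       grid = grid)
}
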