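#' Construct speckle generation parameters
#'
#' Defaults follow the speckle patterns used on skin: 1.27 mm dots at 65%
#' target density with 75% per-dot diameter variation.
#'
#' @param dotDiameter nominal dot diameter in mm.
#' @param dotDensity target ink area fraction in (0, 1).
#' @param dotVariation per-dot diameter jitter fraction in [0, 1].
#' @param canvasSize canvas (width, height) in mm.
#' @param rasterScale pixels per mm.
#' @param seed integer seed; the same seed and parameters give a bit-identical
#'   pattern.
#' @return a [SpeckleParams-class] object.
#' @export
speckleParams <- function(dotDiameter = 1.27, dotDensity = 0.65,
                          dotVariation = 0.75, canvasSize = c(44, 34),
                          rasterScale = 8, seed = 1L) {
  new("SpeckleParams", dotDiameter = dotDiameter, dotDensity = dotDensity,
      dotVariation = dotVariation, canvasSize = as.numeric(canvasSize),
      rasterScale = rasterScale, seed = as.integer(seed))
}

#' Generate a random ink speckle pattern
#'
#' Dots are placed by seeded rejection-free uniform sampling (overlap is
#' allowed) until the measured ink-covered raster fraction reaches the target
#' density. Each dot's diameter is drawn uniformly from
#' \code{dotDiameter * [1 - dotVariation, 1]} and rendered anti-aliased at the
#' raster scale. Ink is dark (0) on a bright background (1).
#'
#' Densities of 0.9 and above are refused: with overlapping dots the covered
#' fraction approaches its target exponentially slowly and such densities are
#' unreachable in bounded time.
#'
#' @param params a [SpeckleParams-class] object.
#' @param maxBatches safety cap on placement batches.
#' @return a [SpecklePattern-class]; pixel (0, 0) center sits at material
#'   coordinate \code{origin = -canvasSize / 2} (canvas centered on the
#'   material origin).
#' @export
generateSpeckle <- function(params, maxBatches = 400L) {
  stopifnot(is(params, "SpeckleParams"))
  validObject(params)
  if (params@dotDensity >= 0.9)
    stop("requested dot density ", params@dotDensity,
         " is unreachable with overlapping dots (must be < 0.9)")
  sc <- params@rasterScale
  w <- max(4L, as.integer(round(params@canvasSize[1] * sc)))
  h <- max(4L, as.integer(round(params@canvasSize[2] * sc)))
  cover <- matrix(0, h, w)                    # ink coverage in [0, 1]
  # pixel center material coordinates
  origin <- -params@canvasSize / 2
  rmaxPx <- params@dotDiameter / 2 * sc
  target <- params@dotDensity
  # expected dots for the target density under random overlap:
  # covered = 1 - exp(-n * pi E[r^2] / A)
  dlo <- 1 - params@dotVariation
  meanR2 <- (params@dotDiameter / 2)^2 * (dlo^2 + dlo + 1) / 3
  nExpect <- ceiling(-log(1 - target) * (w * h / sc^2) / (pi * meanR2))
  batch <- max(8L, ceiling(nExpect / 20))
  oldseed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv()))
  set.seed(params@seed)
  placed <- 0L
  for (b in seq_len(maxBatches)) {
    frac <- mean(cover >= 0.5)
    if (frac >= target) break
    if (b == maxBatches)
      stop("density ", target, " not reached after bounded attempts ",
           "(reached ", round(frac, 3), ")")
    # place a batch of dots
    nb <- if (placed < nExpect) batch else max(4L, batch %/% 4L)
    cxs <- runif(nb, 0, w - 1)
    cys <- runif(nb, 0, h - 1)
    rads <- params@dotDiameter / 2 * runif(nb, 1 - params@dotVariation, 1) * sc
    for (i in seq_len(nb)) {
      cover <- .stampDot(cover, cxs[i], cys[i], rads[i])
    }
    placed <- placed + nb
  }
  img <- 1 - pmin(cover, 1)
  new("SpecklePattern", image = img, scale = sc, origin = as.numeric(origin),
      params = params)
}

# Anti-aliased disk: coverage ramps linearly across a one-pixel band at the rim.
.stampDot <- function(cover, cx, cy, r) {
  h <- nrow(cover); w <- ncol(cover)
  x0 <- max(0L, floor(cx - r - 1)); x1 <- min(w - 1L, ceiling(cx + r + 1))
  y0 <- max(0L, floor(cy - r - 1)); y1 <- min(h - 1L, ceiling(cy + r + 1))
  if (x0 > x1 || y0 > y1) return(cover)
  xs <- x0:x1; ys <- y0:y1
  dx <- xs - cx; dy <- ys - cy
  d <- sqrt(outer(dy^2, dx^2, "+"))
  a <- pmin(1, pmax(0, r + 0.5 - d))
  sub <- cover[ys + 1L, xs + 1L, drop = FALSE]
  cover[ys + 1L, xs + 1L] <- pmax(sub, a)
  cover
}

#' Place a single dot on an otherwise empty canvas
#'
#' Degenerate limit of the generator used for testing: one dot of the nominal
#' diameter at the canvas center.
#'
#' @inheritParams generateSpeckle
#' @return a [SpecklePattern-class] containing exactly one dot.
#' @export
singleDotPattern <- function(params) {
  stopifnot(is(params, "SpeckleParams"))
  sc <- params@rasterScale
  w <- as.integer(round(params@canvasSize[1] * sc))
  h <- as.integer(round(params@canvasSize[2] * sc))
  cover <- .stampDot(matrix(0, h, w), (w - 1) / 2, (h - 1) / 2,
                     params@dotDiameter / 2 * sc)
  new("SpecklePattern", image = 1 - pmin(cover, 1), scale = sc,
      origin = as.numeric(-params@canvasSize / 2), params = params)
}

#' Measured ink area fraction of a pattern
#'
#' Fraction of raster pixels whose ink coverage exceeds one half (intensity
#' below 0.5).
#'
#' @param pattern a [SpecklePattern-class].
#' @return scalar in [0, 1].
#' @export
inkFraction <- function(pattern) {
  stopifnot(is(pattern, "SpecklePattern"))
  mean(pattern@image <= 0.5)
}

#' Material coordinates of texture pixels
#'
#' @param pattern a [SpecklePattern-class].
#' @param px n x 2 matrix of (x, y) pixel coordinates (0-based).
#' @return n x 2 matrix of material (u, v) in mm.
#' @export
pixelToMaterial <- function(pattern, px) {
  cbind(px[, 1] / pattern@scale + pattern@origin[1],
        px[, 2] / pattern@scale + pattern@origin[2])
}

#' @rdname pixelToMaterial
#' @param uv n x 2 matrix of material coordinates (mm).
#' @export
materialToPixel <- function(pattern, uv) {
  cbind((uv[, 1] - pattern@origin[1]) * pattern@scale,
        (uv[, 2] - pattern@origin[2]) * pattern@scale)
}
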