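#' Build a triangulated mesh over grid-indexed tracked points
#'
#' Tracked points carry their DIC grid index, so the triangulation of the
#' reference-image grid is formed directly: each grid quad present in the
#' data is split into two triangles along a fixed diagonal (on a regular
#' lattice this coincides with a Delaunay triangulation up to cocircular
#' ties). Quads with any dropped vertex are omitted, and triangles with an
#' edge longer than three times the median reference edge length are removed,
#' which cuts bridges across holes in the tracked region.
#'
#' @param points data.frame with columns \code{gi}, \code{gj} (grid column /
#'   row), \code{refX/Y/Z}, \code{defX/Y/Z} and optionally \code{score},
#'   \code{matU}, \code{matV} (material coordinates, kept for synthetic
#'   ground-truth lookups).
#' @param maxEdgeFactor edge-length pruning factor.
#' @param minArea triangles with smaller reference area (mm^2) are dropped as
#'   degenerate.
#' @return a [TrackedMesh-class].
#' @export
buildMesh <- function(points, maxEdgeFactor = 3, minArea = 1e-6) {
  stopifnot(all(c("gi", "gj", "refX", "refY", "refZ",
                  "defX", "defY", "defZ") %in% names(points)))
  n <- nrow(points)
  if (n < 3) stop("need at least 3 tracked points to mesh")
  vref <- as.matrix(points[, c("refX", "refY", "refZ")])
  vdef <- as.matrix(points[, c("defX", "defY", "defZ")])
  if (.collinear3d(vref)) stop("all points collinear: cannot triangulate")
  gi <- points$gi; gj <- points$gj
  lut <- matrix(NA_integer_, max(gi), max(gj))
  lut[cbind(gi, gj)] <- seq_len(n)
  faces <- list()
  for (j in seq_len(max(gj) - 1)) {
    for (i in seq_len(max(gi) - 1)) {
      a <- lut[i, j]; b <- lut[i + 1, j]
      c_ <- lut[i, j + 1]; d <- lut[i + 1, j + 1]
      if (is.na(a) || is.na(b) || is.na(c_) || is.na(d)) next
      faces[[length(faces) + 1]] <- c(a, b, d)
      faces[[length(faces) + 1]] <- c(a, d, c_)
    }
  }
  if (!length(faces)) stop("no complete grid quads: cannot triangulate")
  F <- do.call(rbind, faces)
  # prune long edges and degenerate triangles (reference geometry)
  e1 <- sqrt(rowSums((vref[F[, 2], ] - vref[F[, 1], ])^2))
  e2 <- sqrt(rowSums((vref[F[, 3], ] - vref[F[, 2], ])^2))
  e3 <- sqrt(rowSums((vref[F[, 1], ] - vref[F[, 3], ])^2))
  medEdge <- stats::median(c(e1, e2, e3))
  keep <- pmax(e1, e2, e3) <= maxEdgeFactor * medEdge
  area <- .triArea3d(vref, F)
  keep <- keep & area > minArea
  F <- F[keep, , drop = FALSE]
  if (!nrow(F)) stop("all triangles degenerate after pruning")
  scores <- if ("score" %in% names(points)) points$score else rep(NA_real_, n)
  material <- if (all(c("matU", "matV") %in% names(points)))
    as.matrix(points[, c("matU", "matV")]) else matrix(numeric(), 0, 2)
  new("TrackedMesh", verticesRef = vref, verticesDef = vdef,
      faces = F, scores = scores, gridIndex = cbind(gi, gj),
      material = material)
}

.collinear3d <- function(v) {
  if (nrow(v) < 3) return(TRUE)
  v0 <- sweep(v, 2, colMeans(v))
  sv <- svd(v0, nu = 0, nv = 0)$d
  sv[2] < 1e-9 * max(sv[1], 1e-12)
}

.triArea3d <- function(v, F) {
  a <- v[F[, 2], , drop = FALSE] - v[F[, 1], , drop = FALSE]
  b <- v[F[, 3], , drop = FALSE] - v[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Mean reference triangle area of a mesh
#'
#' @param mesh a [TrackedMesh-class].
#' @return mean area in mm^2.
#' @export
meanTriangleArea <- function(mesh) {
  mean(.triArea3d(mesh@verticesRef, mesh@faces))
}

#' Export a tracked mesh as a pair of ASCII PLY files
#'
#' Reference and deformed vertex positions are written to two PLY files
#' sharing the face list.
#'
#' @param mesh a [TrackedMesh-class].
#' @param pathRef,pathDef output file paths.
#' @export
exportMeshPLY <- function(mesh, pathRef, pathDef) {
  .writePLY(mesh@verticesRef, mesh@faces, pathRef)
  .writePLY(mesh@verticesDef, mesh@faces, pathDef)
  invisible(c(pathRef, pathDef))
}

.writePLY <- function(v, F, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(F)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
}

.readPLY <- function(path) {
  lines <- readLines(path)
  endH <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1]))
  v <- do.call(rbind, lapply(lines[endH + seq_len(nv)],
                             function(l) as.numeric(strsplit(l, " ")[[1]])))
  F <- do.call(rbind, lapply(lines[endH + nv + seq_len(nf)], function(l) {
    x <- as.integer(strsplit(l, " ")[[1]])
    x[2:4] + 1L
  }))
  list(vertices = v, faces = F)
}

#' Import tracked point pairs from disk
#'
#' Two formats are supported: a CSV of grid-indexed point pairs (columns
#' \code{gi, gj, refX, refY, refZ, defX, defY, defZ} and optionally
#' \code{score}) or a pair of PLY meshes sharing a face list (reference and
#' deformed positions).
#'
#' @param path CSV path, or for \code{format = "ply"} a character vector of
#'   the two PLY paths (reference, deformed).
#' @param format "csv" or "ply".
#' @return a [TrackedMesh-class].
#' @export
importTrackedPoints <- function(path, format = c("csv", "ply")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop("file not found: ", path)
    pts <- utils::read.csv(path)
    need <- c("gi", "gj", "refX", "refY", "refZ", "defX", "defY", "defZ")
    missing <- setdiff(need, names(pts))
    if (length(missing))
      stop("schema error: missing columns ", paste(missing, collapse = ", "))
    bad <- which(!stats::complete.cases(pts[, need]))
    if (length(bad))
      stop("schema error: incomplete row(s) ", paste(bad, collapse = ", "))
    return(buildMesh(pts))
  }
  stopifnot(length(path) == 2, all(file.exists(path)))
  mref <- .readPLY(path[1])
  mdef <- .readPLY(path[2])
  if (nrow(mref$vertices) != nrow(mdef$vertices))
    stop("schema error: mismatched vertex counts between poses (",
         nrow(mref$vertices), " vs ", nrow(mdef$vertices), ")")
  if (!identical(mref$faces, mdef$faces))
    stop("schema error: the two PLY files must share one face list")
  new("TrackedMesh", verticesRef = mref$vertices, verticesDef = mdef$vertices,
      faces = mref$faces, scores = rep(NA_real_, nrow(mref$vertices)),
      gridIndex = matrix(NA_integer_, nrow(mref$vertices), 2),
      material = matrix(numeric(), 0, 2))
}

#' Export tracked points as CSV
#'
#' @param mesh a [TrackedMesh-class].
#' @param path output CSV path.
#' @export
exportTrackedPoints <- function(mesh, path) {
  df <- data.frame(gi = mesh@gridIndex[, 1], gj = mesh@gridIndex[, 2],
                   refX = mesh@verticesRef[, 1], refY = mesh@verticesRef[, 2],
                   refZ = mesh@verticesRef[, 3],
                   defX = mesh@verticesDef[, 1], defY = mesh@verticesDef[, 2],
                   defZ = mesh@verticesDef[, 3],
                   score = mesh@scores)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
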