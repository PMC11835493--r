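#' Green-Lagrange membrane strain of a single triangle
#'
#' Both triangles are expressed in their own orthonormal in-plane frames; the
#' 2 x 2 in-plane deformation gradient F maps reference edge vectors to
#' deformed edge vectors, E = (F'F - I)/2, and the principal engineering
#' stretches follow from the eigenvalues e1 >= e2 of E via
#' lambda_i = sqrt(1 + 2 e_i), reported as 100 (lambda_i - 1) percent.
#' The principal orientation is the e1 eigenvector rotated back into the 3-D
#' reference-surface frame, stored axially with canonical sign (positive
#' first nonzero component). The area ratio is |det F|.
#'
#' @param refTri,defTri 3 x 3 matrices, one vertex per row (mm).
#' @param minArea triangles below this area (mm^2) are degenerate.
#' @return one-row data.frame: E11, E12, E22 (reference in-plane frame),
#'   principal, orthogonal (percent), orientation (ox, oy, oz), areaRatio,
#'   refArea, status.
#' @export
triangleStrain <- function(refTri, defTri, minArea = 1e-6) {
  out <- .triangleStrainRows(
    list(refTri[1, ], refTri[2, ], refTri[3, ]),
    list(defTri[1, ], defTri[2, ], defTri[3, ]), minArea)
  out
}

# vectorized core: p1..p3 / q1..q3 are lists of n x 3 matrices (or vectors)
.triangleStrainRows <- function(refPts, defPts, minArea = 1e-6) {
  asM <- function(x) if (is.null(dim(x))) matrix(x, ncol = 3) else x
  p1 <- asM(refPts[[1]]); p2 <- asM(refPts[[2]]); p3 <- asM(refPts[[3]])
  q1 <- asM(defPts[[1]]); q2 <- asM(defPts[[2]]); q3 <- asM(defPts[[3]])
  n <- nrow(p1)
  a <- p2 - p1; b <- p3 - p1
  f <- q2 - q1; g <- q3 - q1
  frame <- function(a, b) {
    # orthonormal in-plane frame (e1 along a, e2 in-plane) and the 2D edge
    # coordinates of a and b
    na <- sqrt(rowSums(a^2))
    e1 <- a / na
    nx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
    ny <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
    nz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    area <- nn / 2
    nrm <- cbind(nx, ny, nz) / nn
    e2 <- cbind(nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
                nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
                nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1])
    list(e1 = e1, e2 = e2, area = area,
         D = cbind(na, rowSums(b * e1), rep(0, length(na)), rowSums(b * e2)))
    # D columns: a1, b1, a2 (= 0), b2 of the 2x2 edge matrix [a | b]
  }
  fr <- frame(a, b)
  fd <- frame(f, g)
  refArea <- fr$area
  defArea <- fd$area
  bad <- !is.finite(refArea) | refArea < minArea |
         !is.finite(defArea) | defArea < minArea
  # F = Ddef %*% solve(Dref); Dref = [a1 b1; 0 b2]
  a1 <- fr$D[, 1]; b1 <- fr$D[, 2]; b2 <- fr$D[, 4]
  c1 <- fd$D[, 1]; d1 <- fd$D[, 2]; d2 <- fd$D[, 4]
  # solve(Dref) = [1/a1, -b1/(a1 b2); 0, 1/b2]
  # F = [c1 d1; 0 d2] %*% inv([a1 b1; 0 b2]); inv = [1/a1, -b1/(a1 b2); 0, 1/b2]
  F11 <- c1 / a1
  F12 <- (d1 - c1 * b1 / a1) / b2
  F21 <- rep(0, n)
  F22 <- d2 / b2
  E11 <- (F11^2 + F21^2 - 1) / 2
  E12 <- (F11 * F12 + F21 * F22) / 2
  E22 <- (F12^2 + F22^2 - 1) / 2
  tr <- E11 + E22
  dd <- sqrt(((E11 - E22) / 2)^2 + E12^2)
  eMax <- tr / 2 + dd
  eMin <- tr / 2 - dd
  lam1 <- sqrt(pmax(0, 1 + 2 * eMax))
  lam2 <- sqrt(pmax(0, 1 + 2 * eMin))
  areaRatio <- abs(F11 * F22 - F12 * F21)
  # eigenvector of eMax in the reference in-plane frame
  wx <- ifelse(abs(E12) > 1e-15, eMax - E22, ifelse(E11 >= E22, 1, 0))
  wy <- ifelse(abs(E12) > 1e-15, E12, ifelse(E11 >= E22, 0, 1))
  wn <- sqrt(wx^2 + wy^2)
  wx <- wx / wn; wy <- wy / wn
  o3 <- fr$e1 * wx + fr$e2 * wy
  # canonical axial sign: first component of largest magnitude positive
  sgn <- sign(ifelse(abs(o3[, 1]) > 1e-9, o3[, 1],
                     ifelse(abs(o3[, 2]) > 1e-9, o3[, 2], o3[, 3])))
  sgn[sgn == 0] <- 1
  o3 <- o3 * sgn
  data.frame(E11 = E11, E12 = E12, E22 = E22,
             principal = 100 * (lam1 - 1), orthogonal = 100 * (lam2 - 1),
             ox = o3[, 1], oy = o3[, 2], oz = o3[, 3],
             areaRatio = areaRatio, refArea = refArea,
             status = ifelse(bad, "degenerate", "ok"),
             stringsAsFactors = FALSE)
}

#' Per-triangle strain field of a tracked mesh
#'
#' Computes [triangleStrain()] for every face (strain lives in each
#' triangle's own plane: a membrane assumption, with no bending penalty) and
#' attaches area-weighted summary statistics.
#'
#' @param mesh a [TrackedMesh-class].
#' @return a [StrainField-class]. Degenerate deformed triangles are flagged
#'   and excluded from summaries and maps.
#' @export
strainField <- function(mesh) {
  F <- mesh@faces
  vr <- mesh@verticesRef; vd <- mesh@verticesDef
  tri <- .triangleStrainRows(
    list(vr[F[, 1], , drop = FALSE], vr[F[, 2], , drop = FALSE],
         vr[F[, 3], , drop = FALSE]),
    list(vd[F[, 1], , drop = FALSE], vd[F[, 2], , drop = FALSE],
         vd[F[, 3], , drop = FALSE]))
  cen <- (vr[F[, 1], , drop = FALSE] + vr[F[, 2], , drop = FALSE] +
          vr[F[, 3], , drop = FALSE]) / 3
  tri <- cbind(data.frame(face = seq_len(nrow(F)),
                          cx = cen[, 1], cy = cen[, 2], cz = cen[, 3]), tri)
  ok <- tri$status == "ok"
  s <- list(nValid = sum(ok))
  if (any(ok)) {
    w <- tri$refArea[ok]
    s$meanPrincipal <- sum(w * tri$principal[ok]) / sum(w)
    s$meanOrthogonal <- sum(w * tri$orthogonal[ok]) / sum(w)
    s$p5Principal <- weightedQuantile(tri$principal[ok], w, 0.05)
    s$p95Principal <- weightedQuantile(tri$principal[ok], w, 0.95)
    s$meanAbsPrincipal <- sum(w * abs(tri$principal[ok])) / sum(w)
  } else {
    s[c("meanPrincipal", "meanOrthogonal", "p5Principal", "p95Principal",
        "meanAbsPrincipal")] <- NA_real_
  }
  new("StrainField", mesh = mesh, triangles = tri, summary = s)
}

#' Optional k-ring smoothing of a strain field
#'
#' Averages principal/orthogonal stretch and area ratio over each triangle
#' and its edge-adjacent neighbors, repeated \code{k} times. Off by default
#' throughout the package: raw per-triangle values are reported.
#'
#' @param field a [StrainField-class].
#' @param k number of smoothing rings (0 returns the field untouched).
#' @return the smoothed [StrainField-class].
#' @export
smoothStrain <- function(field, k = 0L) {
  if (k <= 0) return(field)
  F <- field@mesh@faces
  tri <- field@triangles
  # adjacency via shared edges
  edges <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  edges <- t(apply(edges, 1, sort))
  key <- paste(edges[, 1], edges[, 2])
  faceId <- rep(seq_len(nrow(F)), 3)
  adj <- split(faceId, key)
  adj <- adj[lengths(adj) == 2]
  nb <- lapply(seq_len(nrow(F)), function(i) i)
  for (pr in adj) {
    nb[[pr[1]]] <- c(nb[[pr[1]]], pr[2])
    nb[[pr[2]]] <- c(nb[[pr[2]]], pr[1])
  }
  for (it in seq_len(k)) {
    for (colname in c("principal", "orthogonal", "areaRatio")) {
      v <- tri[[colname]]
      tri[[colname]] <- vapply(nb, function(ix) mean(v[ix], na.rm = TRUE),
                               numeric(1))
    }
  }
  field@triangles <- tri
  field
}
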