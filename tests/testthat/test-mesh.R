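test_that("a full regular grid triangulates into 2(n-1)(m-1) faces", {
  pts <- analyticMeshPoints(identityModel(), nx = 7, ny = 5)
  mesh <- buildMesh(pts)
  expect_equal(nrow(meshFaces(mesh)), 2 * (7 - 1) * (5 - 1))
  expect_equal(nrow(vertices(mesh)), 35)
})

test_that("full-scale synthetic patches have plausible triangle areas", {
  # 1 mm grid spacing, the full-scale tracking geometry
  pts <- analyticMeshPoints(identityModel(), nx = 40, ny = 30, spacing = 1)
  mesh <- buildMesh(pts)
  expect_gte(meanTriangleArea(mesh), 0.5)
  expect_lte(meanTriangleArea(mesh), 2.4)
})

test_that("removing an interior vertex removes its faces but keeps the mesh connected", {
  pts <- analyticMeshPoints(identityModel(), nx = 7, ny = 5)
  drop <- which(pts$gi == 4 & pts$gj == 3)
  mesh <- buildMesh(pts[-drop, ])
  # 6 incident faces disappear (all quads touching the vertex)
  expect_equal(nrow(meshFaces(mesh)), 2 * 24 - 8)
  # connectivity via undirected edge graph
  F <- meshFaces(mesh)
  n <- nrow(vertices(mesh))
  adj <- vector("list", n)
  for (r in seq_len(nrow(F))) {
    tr <- F[r, ]
    for (a in 1:3) for (b in 1:3) if (a != b)
      adj[[tr[a]]] <- c(adj[[tr[a]]], tr[b])
  }
  seen <- logical(n)
  inFaces <- sort(unique(as.vector(F)))
  queue <- inFaces[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE
    queue <- c(queue, unique(nb))
  }
  expect_true(all(seen[inFaces]))
})

test_that("degenerate inputs are refused", {
  pts <- analyticMeshPoints(identityModel(), nx = 5, ny = 1)
  expect_error(buildMesh(pts), "collinear")
  expect_error(buildMesh(analyticMeshPoints(identityModel(), 3, 3)[1:2, ]),
               "at least 3")
})

test_that("long bridging edges are pruned", {
  pts <- analyticMeshPoints(identityModel(), nx = 8, ny = 5)
  # tear one column far away: its quads' edges become > 3x median
  far <- pts$gi == 5
  pts$refX[far] <- pts$refX[far] + 40
  pts$defX[far] <- pts$defX[far] + 40
  mesh <- buildMesh(pts)
  F <- meshFaces(mesh)
  v <- vertices(mesh)
  e <- rbind(v[F[, 2], ] - v[F[, 1], ], v[F[, 3], ] - v[F[, 2], ],
             v[F[, 1], ] - v[F[, 3], ])
  expect_lt(max(sqrt(rowSums(e^2))), 10)
})

test_that("tracked points round-trip through CSV with identical strains", {
  model <- uniaxialStretch(0.15)
  mesh <- buildMesh(analyticMeshPoints(model, nx = 9, ny = 7))
  f1 <- strainField(mesh)
  path <- tempfile(fileext = ".csv")
  exportTrackedPoints(mesh, path)
  mesh2 <- importTrackedPoints(path, "csv")
  f2 <- strainField(mesh2)
  expect_equal(strains(f2)$principal, strains(f1)$principal,
               tolerance = 1e-9)
  expect_equal(strains(f2)$orthogonal, strains(f1)$orthogonal,
               tolerance = 1e-9)
  unlink(path)
})

test_that("schema violations are reported with the offending location", {
  path <- tempfile(fileext = ".csv")
  pts <- analyticMeshPoints(identityModel(), 4, 4)
  bad <- pts
  bad$defZ[7] <- NA
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(importTrackedPoints(path, "csv"), "row.*7")
  utils::write.csv(pts[, setdiff(names(pts), "defY")], path,
                   row.names = FALSE)
  expect_error(importTrackedPoints(path, "csv"), "defY")
  expect_error(importTrackedPoints(tempfile(), "csv"), "not found")
  unlink(path)
})

test_that("PLY mesh pairs round-trip", {
  model <- bulge(4, 10)
  mesh <- buildMesh(analyticMeshPoints(model, nx = 8, ny = 6))
  p1 <- tempfile(fileext = ".ply"); p2 <- tempfile(fileext = ".ply")
  exportMeshPLY(mesh, p1, p2)
  back <- importTrackedPoints(c(p1, p2), "ply")
  expect_equal(vertices(back), unname(vertices(mesh)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(vertices(back, "deformed"), unname(vertices(mesh, "deformed")),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(meshFaces(back), meshFaces(mesh), ignore_attr = TRUE)
  # mismatched vertex counts across poses
  mesh3 <- buildMesh(analyticMeshPoints(model, nx = 7, ny = 6))
  p3 <- tempfile(fileext = ".ply")
  exportMeshPLY(mesh3, p3, tempfile(fileext = ".ply"))
  expect_error(importTrackedPoints(c(p1, p3), "ply"), "mismatched")
  unlink(c(p1, p2, p3))
})
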