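#' Configuration of a synthetic pipeline run
#'
#' Desk-scale defaults: a 40 x 30 mm flat patch textured at 8 px/mm with
#' 1.27 mm dots at 65% density, viewed by a two-camera rig (baseline 200 mm
#' at 300 mm, focal 3000 px, image 700 x 500 px) whose central pixel covers
#' roughly 0.1 x 0.1 mm; DIC subset half-width 60 px and spacing 10 px. The
#' DIC settings equal the full-scale processing settings because the pixel
#' footprint matches full scale; only the patch and the frame are smaller.
#'
#' @param preset one of "identity" (re-imaged, cameras unmoved),
#'   "view_change" (undeformed, rig rotated), "uniaxial_33" (33% uniaxial
#'   stretch, same view), "ramp", "bulge" or "custom".
#' @param seed integer seed driving every random draw of the run.
#' @param outDir optional output directory for artifacts.
#' @param patchSize (width, height) of the patch in mm.
#' @param canvasMargin extra texture border in mm.
#' @param rasterScale texture raster scale, px/mm.
#' @param dotDiameter,dotDensity,dotVariation speckle parameters.
#' @param imageSize camera image (width, height) px.
#' @param focal focal length in px.
#' @param baseline,distance rig geometry in mm.
#' @param viewRotation rig rotation (degrees, about the in-plane x axis) for
#'   rotated-view conditions.
#' @param rotateView rotate the rig for the deformed acquisition (set by the
#'   presets; for "custom" choose freely).
#' @param noiseSD additive image noise sd (intensity units).
#' @param dicRadius,dicSpacing subset half-width and grid spacing, px.
#' @param intRadius subset half-width of the integer search stage, px.
#' @param searchRadius full-resolution search half-width, px.
#' @param scoreThreshold ZNCC acceptance threshold.
#' @param stretch uniaxial stretch fraction for the stretch presets.
#' @param gradient ramp gradient, percent/cm.
#' @param bulgeAmplitude,bulgeRadius bulge preset geometry, mm.
#' @param model a [DeformationModel-class] for \code{preset = "custom"}.
#' @return a validated config (named list, class "dermastretchConfig").
#' @export
runConfig <- function(preset = c("identity", "view_change", "uniaxial_33",
                                 "ramp", "bulge", "custom"),
                      seed = 1L, outDir = NULL,
                      patchSize = c(40, 30), canvasMargin = 2,
                      rasterScale = 8,
                      dotDiameter = 1.27, dotDensity = 0.65,
                      dotVariation = 0.75,
                      imageSize = c(700, 500), focal = 3000,
                      baseline = 200, distance = 300,
                      viewRotation = 15, rotateView = NULL,
                      noiseSD = 0.01,
                      dicRadius = 60, dicSpacing = 10, intRadius = 15,
                      searchRadius = NULL, scoreThreshold = 0.8,
                      stretch = 0.33, gradient = 5,
                      bulgeAmplitude = 5, bulgeRadius = 20,
                      model = NULL) {
  preset <- match.arg(preset)
  if (is.null(rotateView)) rotateView <- preset == "view_change"
  if (is.null(searchRadius)) searchRadius <- round(0.25 * imageSize[1])
  cfg <- list(preset = preset, seed = as.integer(seed), outDir = outDir,
              patchSize = patchSize, canvasMargin = canvasMargin,
              rasterScale = rasterScale, dotDiameter = dotDiameter,
              dotDensity = dotDensity, dotVariation = dotVariation,
              imageSize = imageSize, focal = focal, baseline = baseline,
              distance = distance, viewRotation = viewRotation,
              rotateView = rotateView, noiseSD = noiseSD,
              dicRadius = dicRadius, dicSpacing = dicSpacing,
              intRadius = intRadius, searchRadius = searchRadius,
              scoreThreshold = scoreThreshold, stretch = stretch,
              gradient = gradient, bulgeAmplitude = bulgeAmplitude,
              bulgeRadius = bulgeRadius, model = model)
  stopifnot(cfg$noiseSD >= 0, cfg$dicSpacing >= 1,
            cfg$dicRadius >= cfg$dicSpacing,
            cfg$stretch > -1, all(cfg$patchSize > 0),
            cfg$focal > 0, cfg$scoreThreshold > 0, cfg$scoreThreshold <= 1)
  class(cfg) <- "dermastretchConfig"
  cfg
}

#' Round-trip a run configuration through YAML
#'
#' @param config a [runConfig()] (the deformation model of "custom" presets
#'   is not serialized).
#' @param path YAML path.
#' @export
writeRunConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$model <- NULL
  cfg$outDir <- if (is.null(cfg$outDir)) "" else cfg$outDir
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  y$outDir <- if (identical(y$outDir, "")) NULL else y$outDir
  num <- function(x) if (is.list(x)) unlist(x) else x
  for (f in c("patchSize", "imageSize")) y[[f]] <- num(y[[f]])
  do.call(runConfig, y)
}

.sceneModel <- function(config) {
  switch(config$preset,
    identity = identityModel(),
    view_change = identityModel(),
    uniaxial_33 = uniaxialStretch(config$stretch),
    ramp = rampStretch(config$gradient, base = 0,
                       origin = -config$patchSize[1] / 2),
    bulge = bulge(config$bulgeAmplitude, config$bulgeRadius),
    custom = {
      if (is.null(config$model)) stop("custom preset needs a model")
      config$model
    })
}

#' Assemble the synthetic scene of a run
#'
#' @param config a [runConfig()].
#' @return list: surface, texture, model, rigRef, rigDef, grid.
#' @export
buildScene <- function(config) {
  surface <- flatPatch(config$patchSize[1], config$patchSize[2])
  params <- speckleParams(config$dotDiameter, config$dotDensity,
                          config$dotVariation,
                          canvasSize = config$patchSize + 2 * config$canvasMargin,
                          rasterScale = config$rasterScale,
                          seed = config$seed)
  texture <- generateSpeckle(params)
  rigRef <- stereoRig(config$focal, config$imageSize, config$baseline,
                      config$distance)
  rigDef <- if (config$rotateView)
    rotateRig(rigRef, "x", config$viewRotation) else rigRef
  # region of interest: subsets fully inside the projected patch, so every
  # tracked subset sees only speckled material (patch-boundary subsets mix
  # moving material with static background and cannot correspond)
  w2 <- config$patchSize[1] / 2; h2 <- config$patchSize[2] / 2
  corners <- rbind(c(-w2, -h2, 0), c(w2, -h2, 0), c(w2, h2, 0),
                   c(-w2, h2, 0))
  cpx <- project(rigRef[[1]], corners)
  region <- c(min(cpx[, 1]) + config$dicRadius,
              max(cpx[, 1]) - config$dicRadius,
              min(cpx[, 2]) + config$dicRadius,
              max(cpx[, 2]) - config$dicRadius)
  grid <- subsetGrid(config$imageSize, config$dicRadius, config$dicSpacing,
                     region = region)
  list(surface = surface, texture = texture, model = .sceneModel(config),
       rigRef = rigRef, rigDef = rigDef, grid = grid)
}

# material coordinates of camera-1 reference pixels (flat reference patch at
# z = 0); exact scene geometry, used only for ground-truth bookkeeping
.materialOfPixels <- function(camera, px) {
  rays <- pixelRays(camera, px)
  tt <- -rays$origin[3] / rays$dir[, 3]
  cbind(rays$origin[1] + tt * rays$dir[, 1],
        rays$origin[2] + tt * rays$dir[, 2])
}

# best-fit rigid (Kabsch) alignment of A onto B; returns aligned A
.rigidAlign <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  R <- sv$v %*% t(sv$u)
  if (det(R) < 0) R <- sv$v %*% diag(c(1, 1, -1)) %*% t(sv$u)
  sweep(sweep(A, 2, ca) %*% t(R), 2, -cb)
}

#' Run the full synthetic measurement chain
#'
#' Scene generation, multi-view rendering, DIC tracking across cameras and
#' poses, stereo triangulation, meshing, per-triangle strain, plane-projected
#' maps and (because ground truth is known) a validation report. Fully
#' deterministic given the config seed.
#'
#' @param config a [runConfig()].
#' @param outDir output directory for artifacts (images, match CSVs, PLY
#'   meshes, strain CSV, grid maps, config and run log); overrides
#'   \code{config$outDir}. NULL writes nothing.
#' @return list with elements \code{scene}, \code{chain}, \code{mesh},
#'   \code{field} ([StrainField-class]), \code{plane}, \code{map}
#'   ([GridMap-class]), \code{summary}, \code{report} (one-row data.frame:
#'   mean absolute principal/orthogonal stretch error in percentage points,
#'   mean 3-D point error in mm, counts).
#' @export
runPipeline <- function(config, outDir = config$outDir) {
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)
  scene <- buildScene(config)
  idm <- identityModel()
  refImages <- lapply(scene$rigRef, function(cam)
    renderView(scene$surface, scene$texture, idm, cam, config$noiseSD))
  defImages <- lapply(scene$rigDef, function(cam)
    renderView(scene$surface, scene$texture, scene$model, cam, config$noiseSD))
  chain <- trackPoseChain(refImages, defImages, scene$rigRef, scene$rigDef,
                          scene$grid, searchRadius = config$searchRadius,
                          scoreThreshold = config$scoreThreshold)
  pts <- chain$points
  # ground-truth bookkeeping from the known scene
  gridLut <- scene$grid
  centers <- gridLut@centers[match(paste(pts$gi, pts$gj),
                                   paste(gridLut@index[, 1],
                                         gridLut@index[, 2])), , drop = FALSE]
  uv <- .materialOfPixels(scene$rigRef[[1]], centers)
  pts$matU <- uv[, 1]; pts$matV <- uv[, 2]
  mesh <- buildMesh(pts)
  field <- strainField(mesh)
  plane <- fitPlane(field)
  map <- resampleGrid(field, plane, resolution = 1)
  summ <- percentileSummary(field)
  report <- .validationReport(config, scene, mesh, field)
  out <- list(scene = scene, images = list(ref = refImages, def = defImages),
              chain = chain, mesh = mesh, field = field, plane = plane,
              map = map, summary = summ, report = report)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeImagePNG(refImages[[1]], file.path(outDir, "ref_cam1.png"))
    writeImagePNG(refImages[[2]], file.path(outDir, "ref_cam2.png"))
    writeImagePNG(defImages[[1]], file.path(outDir, "def_cam1.png"))
    writeImagePNG(defImages[[2]], file.path(outDir, "def_cam2.png"))
    writeCameraYAML(c(scene$rigRef, scene$rigDef),
                    file.path(outDir, "cameras.yaml"))
    for (f in chain$fields)
      writeMatchField(f, file.path(outDir, paste0(
        "matches_", gsub("[^a-z0-9_]+", "_", f@pairing), ".csv")))
    exportMeshPLY(mesh, file.path(outDir, "mesh_ref.ply"),
                  file.path(outDir, "mesh_def.ply"))
    exportTrackedPoints(mesh, file.path(outDir, "tracked_points.csv"))
    writeStrainCSV(field, file.path(outDir, "strain.csv"))
    writeGridMap(map, file.path(outDir, "stretch_map.txt"))
    writeRunConfig(config, file.path(outDir, "config.yaml"))
    utils::write.csv(report, file.path(outDir, "validation.csv"),
                     row.names = FALSE)
    log <- c(sprintf("dermastretch %s", as.character(utils::packageVersion("dermastretch"))),
             sprintf("preset: %s  seed: %d", config$preset, config$seed),
             sprintf("tracked points: %d  faces: %d", nrow(pts),
                     nrow(mesh@faces)),
             sprintf("matched fractions: %s",
                     paste(vapply(chain$fields, function(f)
                       sprintf("%s %.2f", f@pairing,
                               mean(f@correspondences$status == "matched")),
                       ""), collapse = "; ")),
             sprintf("elapsed: %.1f s", proc.time()[["elapsed"]] - t0))
    writeLines(log, file.path(outDir, "run_log.txt"))
  }
  out
}

.validationReport <- function(config, scene, mesh, field) {
  tri <- field@triangles
  ok <- tri$status == "ok"
  F <- mesh@faces
  uvc <- (mesh@material[F[, 1], , drop = FALSE] +
          mesh@material[F[, 2], , drop = FALSE] +
          mesh@material[F[, 3], , drop = FALSE]) / 3
  gt <- groundTruthStrain(scene$model, uvc)
  ePrin <- abs(tri$principal - gt$principal)[ok]
  eOrth <- abs(tri$orthogonal - gt$orthogonal)[ok]
  gtDef <- deformPoints(scene$model, mesh@material)
  ePoint <- sqrt(rowSums((mesh@verticesDef - gtDef)^2))
  gtRef <- cbind(mesh@material, 0)
  ePointRef <- sqrt(rowSums((mesh@verticesRef - gtRef)^2))
  data.frame(condition = paste0(config$preset,
                                if (config$rotateView &&
                                    config$preset != "view_change")
                                  "_rotated" else ""),
             seed = config$seed,
             meanAbsPrincipalErr = mean(ePrin),
             meanAbsOrthogonalErr = mean(eOrth),
             meanPointErr = mean(ePoint),
             meanPointErrRef = mean(ePointRef),
             nPoints = nrow(mesh@verticesRef),
             nTriangles = sum(ok))
}

#' Reproduce the validation table over seeds and conditions
#'
#' Four conditions: undeformed/same view, undeformed/rotated view, 33%
#' uniaxial stretch/same view and 33% stretch/rotated view; each yields the
#' mean absolute principal- and orthogonal-stretch errors (percentage
#' points) and the mean 3-D point error (mm) against the analytic ground
#' truth.
#'
#' @param seeds integer vector of seeds.
#' @param config base [runConfig()]; preset and seed are overridden.
#' @param conditions subset of the four condition names.
#' @return data.frame, one row per condition x seed.
#' @export
runValidationSuite <- function(seeds = 1:3, config = runConfig(),
                               conditions = c("identity", "view_change",
                                              "uniaxial_33",
                                              "uniaxial_33_rotated")) {
  rows <- list()
  for (cond in conditions) {
    for (s in seeds) {
      cfg <- config
      cfg$seed <- as.integer(s)
      if (cond == "uniaxial_33_rotated") {
        cfg$preset <- "custom"
        cfg$model <- uniaxialStretch(cfg$stretch)
        cfg$rotateView <- TRUE
      } else {
        cfg$preset <- cond
        cfg$model <- NULL
        cfg$rotateView <- cond == "view_change"
      }
      run <- runPipeline(cfg, outDir = NULL)
      row <- run$report
      row$condition <- cond
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Synthetic stereo checkerboard views with corner noise
#'
#' Projects checkerboard corners through both cameras of a rig for a set of
#' randomized board poses (tilted and shifted around the working plane) and
#' adds Gaussian pixel noise, emulating real corner observations whose noise
#' level sets the calibration reprojection-error regime.
#'
#' @param rig list of two [CameraModel-class] objects.
#' @param spec a [checkerboardSpec()].
#' @param nViews number of board poses.
#' @param cornerNoise corner observation noise sd in px.
#' @param distance working distance of the rig in mm.
#' @return list of views consumable by [calibrateStereo()].
#' @export
makeCalibrationViews <- function(rig, spec, nViews = 8, cornerNoise = 2.1,
                                 distance = 300) {
  bc <- .boardCorners(spec)
  bw <- (spec$cols + 1) * spec$squareSize
  bh <- (spec$rows + 1) * spec$squareSize
  lapply(seq_len(nViews), function(i) {
    Rb <- rotationMatrix("x", stats::runif(1, -20, 20)) %*%
      rotationMatrix("y", stats::runif(1, -20, 20)) %*%
      rotationMatrix("z", stats::runif(1, -15, 15))
    tb <- c(stats::runif(1, -5, 5) - bw / 2, stats::runif(1, -4, 4) - bh / 2,
            stats::runif(1, -0.15, 0.15) * distance)
    world <- sweep(cbind(bc, 0) %*% t(Rb), 2, -tb)
    lapply(rig, function(cam) {
      px <- project(cam, world)
      list(px = px + matrix(stats::rnorm(length(px), 0, cornerNoise),
                            ncol = 2),
           board = bc)
    })
  })
}

#' Reconstruction accuracy in the calibrated-camera regime
#'
#' Emulates the full measurement protocol of the study: the stereo pair is
#' calibrated from checkerboard views whose corner noise puts the
#' calibration reprojection RMS at roughly 3 px, the DIC chain runs on
#' synthetic acquisitions (undeformed, 33% stretch, and an undeformed
#' rotated view), tracked points are triangulated with the *fitted* cameras,
#' and the mean Euclidean distance to ground truth is reported after
#' best-fit rigid alignment (the calibrated frame is defined only up to a
#' rigid motion of the true world frame).
#'
#' @param seeds integer seeds.
#' @param config base [runConfig()].
#' @param cornerNoise checkerboard corner noise sd in px (sets the
#'   reprojection-error regime).
#' @param nViews checkerboard views per calibration.
#' @return data.frame per condition x seed with \code{meanPointErr} (mm) and
#'   the calibration \code{reprojRMS} (px).
#' @export
runReconstructionStudy <- function(seeds = 1:3, config = runConfig(),
                                   cornerNoise = 2.1, nViews = 8) {
  conds <- c("identity", "uniaxial_33", "view_change")
  spec <- checkerboardSpec(rows = 7L, cols = 8L, squareSize = 6)
  rows <- list()
  for (s in seeds) {
    set.seed(s + 20000L)
    rigTrue <- stereoRig(config$focal, config$imageSize, config$baseline,
                         config$distance)
    views <- makeCalibrationViews(rigTrue, spec, nViews, cornerNoise,
                                  config$distance)
    calib <- calibrateStereo(views, spec, config$imageSize)
    for (cond in conds) {
      cfg <- config
      cfg$seed <- as.integer(s)
      cfg$preset <- cond
      cfg$rotateView <- cond == "view_change"
      run <- runPipeline(cfg, outDir = NULL)
      mesh <- run$mesh
      gtRef <- cbind(mesh@material, 0)
      # matched pixel coordinates of the mesh vertices in the reference pair
      pts <- run$chain$points
      keyAll <- paste(run$chain$grid@index[, 1], run$chain$grid@index[, 2])
      sel <- match(paste(pts$gi, pts$gj), keyAll)
      inMesh <- match(paste(mesh@gridIndex[, 1], mesh@gridIndex[, 2]),
                      paste(pts$gi, pts$gj))
      fS <- run$chain$fields[[1]]@correspondences
      fP <- run$chain$fields[[2]]@correspondences
      fQ <- run$chain$fields[[3]]@correspondences
      pick <- function(m) m[sel, , drop = FALSE][inMesh, , drop = FALSE]
      # both poses are reconstructed with the *fitted* pair; the relative
      # stereo geometry is unchanged when the whole rig moves, so the
      # rotated-view acquisition reuses the same calibration, and each
      # reconstruction lives in its own camera-1 frame (hence the per-pose
      # rigid alignment)
      poseErr <- function(pxa, pxb, gt) {
        tri <- triangulatePoints(pxa, pxb, calib@cameras[[1]],
                                 calib@cameras[[2]])
        rec <- as.matrix(tri[, c("X", "Y", "Z")])
        good <- stats::complete.cases(rec)
        aligned <- .rigidAlign(rec[good, , drop = FALSE],
                               gt[good, , drop = FALSE])
        sqrt(rowSums((aligned - gt[good, , drop = FALSE])^2))
      }
      gtDef <- deformPoints(run$scene$model, mesh@material)
      errRef <- poseErr(pick(run$chain$grid@centers),
                        pick(cbind(fS$tgt_x, fS$tgt_y)), gtRef)
      errDef <- poseErr(pick(cbind(fP$tgt_x, fP$tgt_y)),
                        pick(cbind(fQ$tgt_x, fQ$tgt_y)), gtDef)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, seed = s,
        meanPointErr = mean(c(errRef, errDef)),
        reprojRMS = calib@reprojectionError,
        n = length(errRef) + length(errDef))
    }
  }
  do.call(rbind, rows)
}
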