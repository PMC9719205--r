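# End-to-end phantom pipeline -------------------------------------------
#
# Orchestrates phantom generation -> segmentation -> masked ICP
# registration -> coordinate frame -> drift metrics for one synthetic
# subject, and a cohort simulator for the statistics layer.

#' Tag crest, window and boundary zones on a phantom surface model
#'
#' Zone tags stand in for the operator's manual selection of the
#' alignment area: bone vertices within \code{crestMarginMm} below the
#' cortical top form the alveolar-crest zone; vertices within the apical
#' window sphere (plus a small guard band) form the window zone; vertices
#' near the volume bounding box form the boundary zone (their surface is
#' an artefact of volume cropping, and after a jaw motion the two
#' timepoints are cropped at different anatomical positions, so the
#' boundary margin must exceed the expected jaw displacement). For a
#' follow-up model the inverse jaw transform maps vertices back to the
#' canonical frame first; the boundary test is applied in both frames.
#'
#' @param model a \code{SurfaceModel} from \code{\link{extractMesh}}.
#' @param phantom the list returned by \code{\link{generatePhantom}}.
#' @param timepoint "To" or "Tn".
#' @param crestMarginMm crest-zone depth below the local bone top, mm.
#' @param windowRadiusMm radius of the opened apical window, mm.
#' @param boundaryMarginMm thickness of the boundary zone, mm.
#' @return The model with its zone labels filled in.
#' @export
labelPhantomZones <- function(model, phantom, timepoint = "To",
                              crestMarginMm = 2, windowRadiusMm = 0,
                              boundaryMarginMm = 1) {
  g <- phantom$geometry
  V <- model@vertices
  canonical <- if (timepoint == "Tn")
    .apply_rigid(V, invertTransform(phantom$jawT)) else V
  zone <- rep("none", nrow(V))
  isBone <- model@labels$structure == "bone"
  topZ <- .bone_top_z(canonical[, 1], canonical[, 2], g$boneBase, g$boneAmp)
  zone[isBone & canonical[, 3] > topZ - crestMarginMm] <- "crest"
  if (windowRadiusMm > 0) {
    # the tooth moves between timepoints, so the two windows sit at
    # different anatomical positions; after superimposition both window
    # areas are unstable and each model excludes both
    wcTo <- phantom$baseline$windowCenterMm
    wcTn <- phantom$followup$windowCenterMm
    centers <- if (timepoint == "Tn")
      rbind(applyTransform(wcTo, phantom$jawT), wcTn)
    else
      rbind(wcTo, applyTransform(wcTn, invertTransform(phantom$jawT)))
    for (i in seq_len(nrow(centers))) {
      wc <- centers[i, ]
      d2 <- (V[, 1] - wc[1])^2 + (V[, 2] - wc[2])^2 + (V[, 3] - wc[3])^2
      zone[d2 <= (windowRadiusMm + 0.6)^2] <- "window"
    }
  }
  lo <- g$bbox["lo", ]
  hi <- g$bbox["hi", ]
  nearEdge <- rep(FALSE, nrow(V))
  for (a in 1:3)
    nearEdge <- nearEdge |
      V[, a] < lo[a] + boundaryMarginMm |
      V[, a] > hi[a] - boundaryMarginMm |
      canonical[, a] < lo[a] + boundaryMarginMm |
      canonical[, a] > hi[a] - boundaryMarginMm
  zone[nearEdge] <- "boundary"
  model@labels$zone <- zone
  model
}

.subsample_rows <- function(m, nmax, seed) {
  if (nrow(m) <= nmax) return(m)
  idx <- .with_seed(seed, sample.int(nrow(m), nmax))
  m[idx, , drop = FALSE]
}

#' Run the full measurement pipeline on one phantom subject
#'
#' Generates the two-timepoint phantom, segments both volumes
#' (crown/root/bone thresholds, apical window, union, labelled mesh),
#' superimposes the follow-up onto the baseline by masked ICP, maps the
#' (optionally jittered) follow-up landmarks into the baseline frame with
#' the recovered transform, builds the baseline tooth frame and measures
#' the drift outcome.
#'
#' @param spec a \code{PhantomSpec}.
#' @param motion a \code{GroundTruthMotion}.
#' @param thresholds a \code{ThresholdConfig} or NULL for the phantom
#'   defaults with an apical window of \code{windowRadiusMm}.
#' @param alignMask an \code{AlignmentMask}.
#' @param windowRadiusMm apical window radius when \code{thresholds} is
#'   NULL.
#' @param jitterSdMm landmark jitter SD applied to both timepoints'
#'   landmark sets (operator error), mm.
#' @param icpMaxPoints moving/fixed point budgets for ICP, length-2.
#' @param seed integer seed for jitter and subsampling.
#' @param keepModels keep the segmented surface models in the result.
#' @return A list: \code{drift} (a \code{DriftResult}), \code{frame},
#'   \code{icp} (the full ICP result), \code{jawRecoveryError}
#'   (rotation/translation error of the recovered superimposition against
#'   the inverse jaw transform), \code{expected} (ground-truth outcome
#'   from \code{\link{expectedDrift}}), \code{phantom} (landmarks and
#'   truth; volumes dropped), and optionally \code{models}.
#' @export
runPhantomPipeline <- function(spec, motion, thresholds = NULL,
                               alignMask = AlignmentMask(),
                               windowRadiusMm = 4.5, jitterSdMm = 0,
                               icpMaxPoints = c(6000L, 100000L),
                               seed = 1L, keepModels = FALSE) {
  phantom <- generatePhantom(spec, motion)
  if (is.null(thresholds))
    thresholds <- defaultThresholds(spec, phantom$baseline$windowCenterMm,
                                    windowRadiusMm)
  thrTn <- thresholds
  thrTn@windowCenterMm <- phantom$followup$windowCenterMm

  segTo <- segmentVolume(phantom$baseline$volume, thresholds,
                         phantom$baseline$labelVolume)
  segTn <- segmentVolume(phantom$followup$volume, thrTn,
                         phantom$followup$labelVolume)
  modTo <- labelPhantomZones(segTo$model, phantom, "To",
                             alignMask@crestMarginMm,
                             thresholds@windowRadiusMm)
  modTn <- labelPhantomZones(segTn$model, phantom, "Tn",
                             alignMask@crestMarginMm,
                             thrTn@windowRadiusMm)

  fixedPts <- .subsample_rows(selectAlignmentPoints(modTo, alignMask),
                              icpMaxPoints[2], seed + 11L)
  movingPts <- .subsample_rows(selectAlignmentPoints(modTn, alignMask),
                               icpMaxPoints[1], seed + 13L)
  icp <- icpAlignRobust(movingPts, fixedPts)
  jawErr <- transformError(icp$transform, invertTransform(phantom$jawT))

  lmTo <- jitterLandmarks(phantom$baseline$landmarks, jitterSdMm,
                          seed + 17L)
  lmTn <- jitterLandmarks(phantom$followup$landmarks, jitterSdMm,
                          seed + 19L)
  lmTnReg <- applyTransform(lmTn, icp$transform)
  frame <- buildFrame(lmTo)
  drift <- measureDrift(lmTo, lmTnReg, frame, icp$finalRmsMm)

  out <- list(drift = drift, frame = frame, icp = icp,
              jawRecoveryError = jawErr,
              expected = expectedDrift(phantom$baseline$landmarks, motion),
              truth = motion,
              landmarks = list(To = phantom$baseline$landmarks,
                               Tn = phantom$followup$landmarks))
  if (keepModels) out$models <- list(To = modTo, Tn = modTn)
  out
}

#' Landmark-exact drift measurement for one phantom subject
#'
#' The fast path used for recovery and repeatability studies: no volume
#' is rasterised; the phantom's analytic landmarks (optionally jittered)
#' feed the frame construction and metrics directly, with the jaw
#' transform undone exactly.
#'
#' @param spec a \code{PhantomSpec}.
#' @param motion a \code{GroundTruthMotion}.
#' @param jitterSdMm landmark jitter SD, mm.
#' @param seed integer seed for the jitter.
#' @return A list with \code{drift}, \code{expected} and \code{frame}.
#' @export
measurePhantomExact <- function(spec, motion, jitterSdMm = 0, seed = 1L) {
  phantom <- generatePhantom(spec, motion, voxelize = FALSE)
  lmTo <- jitterLandmarks(phantom$baseline$landmarks, jitterSdMm,
                          seed + 17L)
  lmTn <- jitterLandmarks(phantom$followup$landmarks, jitterSdMm,
                          seed + 19L)
  lmTnReg <- applyTransform(lmTn, invertTransform(phantom$jawT))
  frame <- buildFrame(lmTo)
  list(drift = measureDrift(lmTo, lmTnReg, frame),
       expected = expectedDrift(phantom$baseline$landmarks, motion),
       frame = frame)
}

.MOLAR_TYPES <- data.frame(
  molar_type = c("upper-first", "upper-second", "lower-first",
                 "lower-second"),
  arch = c("maxilla", "maxilla", "mandible", "mandible"),
  quadrant = c("upper-right", "upper-left", "lower-right", "lower-left"),
  stringsAsFactors = FALSE)

#' Simulate a cohort of unopposed molars (landmark-exact)
#'
#' Draws per-tooth ground-truth motions, measures each with the
#' landmark-exact pipeline, and assembles the cohort table used by the
#' statistics layer.
#'
#' @param nTeeth number of teeth.
#' @param seed integer seed.
#' @param eruptionRangeMm range of true eruption, mm.
#' @param tipSdDeg SD of the true tipping angles, degrees.
#' @param jitterSdMm landmark jitter SD, mm.
#' @return A cohort data.frame (see \code{\link{validateCohortTable}}).
#' @export
simulateCohort <- function(nTeeth = 30L, seed = 1L,
                           eruptionRangeMm = c(-0.4, 1.9),
                           tipSdDeg = 2.5, jitterSdMm = 0.05) {
  draws <- .with_seed(seed, {
    data.frame(
      eruption = stats::runif(nTeeth, eruptionRangeMm[1], eruptionRangeMm[2]),
      bl = pmax(-12, pmin(12, rnorm(nTeeth, 0, tipSdDeg))),
      md = pmax(-12, pmin(12, rnorm(nTeeth, 0, tipSdDeg))),
      type = sample.int(4L, nTeeth, replace = TRUE),
      sex = sample(c("male", "female"), nTeeth, replace = TRUE,
                   prob = c(0.7, 0.3)),
      age = round(stats::runif(nTeeth, 30, 78)),
      tn = round(pmax(3, rnorm(nTeeth, 9.1, 4.3)), 1))
  })
  rows <- vector("list", nTeeth)
  for (i in seq_len(nTeeth)) {
    ty <- .MOLAR_TYPES[draws$type[i], ]
    spec <- PhantomSpec(quadrant = ty$quadrant, seed = seed + i)
    motion <- GroundTruthMotion(eruptionMm = draws$eruption[i],
                                blTipDeg = draws$bl[i],
                                mdTipDeg = draws$md[i])
    m <- measurePhantomExact(spec, motion, jitterSdMm, seed = seed + 100L + i)
    rows[[i]] <- driftRow(m$drift, toothId = i, arch = ty$arch,
                          molarType = ty$molar_type, tnMonths = draws$tn[i],
                          patientId = i, sex = draws$sex[i],
                          ageYears = draws$age[i])
  }
  cohort <- do.call(rbind, rows)
  validateCohortTable(cohort)
  cohort
}

#' In-silico method-error protocol
#'
#' Repeats the landmark-exact measurement twice per phantom subject with
#' independent landmark jitter (two digitisation sessions), then computes
#' the Dahlberg combined method error and the two-way mixed single-measure
#' consistency ICC for each outcome parameter.
#'
#' @param nSubjects number of phantom subjects.
#' @param eruptionRangeMm range of true eruption spanned by the subjects.
#' @param tipSdDeg SD of true tipping.
#' @param jitterSdMm per-coordinate landmark jitter SD per session, mm.
#' @param seed integer seed.
#' @return A list of per-parameter \code{dahlberg} and \code{icc} values
#'   plus the measurement pairs.
#' @export
methodErrorStudy <- function(nSubjects = 10L,
                             eruptionRangeMm = c(-0.41, 1.92),
                             tipSdDeg = 3, jitterSdMm = 0.1,
                             seed = 1L) {
  truths <- .with_seed(seed, {
    data.frame(eruption = seq(eruptionRangeMm[1], eruptionRangeMm[2],
                              length.out = nSubjects),
               bl = rnorm(nSubjects, 0, tipSdDeg),
               md = rnorm(nSubjects, 0, tipSdDeg))
  })
  params <- c("OE_mean", "OE_max", "cBLT", "cMDT")
  m1 <- m2 <- matrix(NA_real_, nSubjects, length(params),
                     dimnames = list(NULL, params))
  for (i in seq_len(nSubjects)) {
    spec <- PhantomSpec(seed = seed + i)
    motion <- GroundTruthMotion(eruptionMm = truths$eruption[i],
                                blTipDeg = truths$bl[i],
                                mdTipDeg = truths$md[i])
    a <- measurePhantomExact(spec, motion, jitterSdMm,
                             seed = seed + 1000L + 100L * i)$drift
    b <- measurePhantomExact(spec, motion, jitterSdMm,
                             seed = seed + 5000L + 100L * i)$drift
    m1[i, ] <- c(a@oeMeanMm, a@oeMaxMm, a@cBLTDeg, a@cMDTDeg)
    m2[i, ] <- c(b@oeMeanMm, b@oeMaxMm, b@cBLTDeg, b@cMDTDeg)
  }
  list(
    dahlberg = vapply(params, function(p)
      dahlbergError(cbind(m1[, p], m2[, p])), numeric(1)),
    icc = vapply(params, function(p)
      iccTwoWayMixed(cbind(m1[, p], m2[, p])), numeric(1)),
    pairs = list(first = m1, second = m2))
}

#' One-shot demonstration of the full chain
#'
#' Runs the voxel pipeline on a built-in phantom and prints the drift
#' table next to ground truth.
#'
#' @param eruptionMm,blTipDeg,mdTipDeg true tooth motion.
#' @param seed integer seed.
#' @param voxelSpacingMm phantom voxel spacing, mm.
#' @param quiet suppress printing.
#' @return Invisibly, the \code{\link{runPhantomPipeline}} result.
#' @export
runDemo <- function(eruptionMm = 0.5, blTipDeg = -2, mdTipDeg = 0,
                    seed = 1L, voxelSpacingMm = 0.3, quiet = FALSE) {
  spec <- PhantomSpec(voxelSpacingMm = voxelSpacingMm, seed = seed)
  motion <- GroundTruthMotion(
    eruptionMm = eruptionMm, blTipDeg = blTipDeg, mdTipDeg = mdTipDeg,
    jawRotation = axisAngleRotation(c(0.2, 1, 0.5), 2),
    jawTranslationMm = c(1, -0.5, 0.8))
  res <- runPhantomPipeline(spec, motion, jitterSdMm = 0.05, seed = seed)
  if (!quiet) {
    cat("Demo phantom: eruption", eruptionMm, "mm, BL tip", blTipDeg,
        "deg, MD tip", mdTipDeg, "deg, jaw moved 2 deg / ~1.4 mm\n\n")
    show(res$drift)
    cat(sprintf("\nGround truth: OE_mean %.3f mm, OE_max %.3f mm (%s), cBLT %.3f deg, cMDT %.3f deg\n",
                res$expected$oeMeanMm, res$expected$oeMaxMm,
                res$expected$oeMaxCusp, res$expected$cBLTDeg,
                res$expected$cMDTDeg))
    cat(sprintf("Jaw recovery error: %.4f deg / %.4f mm; ICP RMS %.4f mm (%d iterations)\n",
                res$jawRecoveryError$rotationDeg,
                res$jawRecoveryError$translationMm,
                res$icp$finalRmsMm, res$icp$iterations))
  }
  invisible(res)
}

#' Write a run manifest
#'
#' Records inputs, configuration (with an md5 of its canonical JSON),
#' seed and package version next to a pipeline output.
#'
#' @param path manifest JSON path.
#' @param config named list of configuration values.
#' @param seed integer seed of the run.
#' @param inputs character vector of input paths.
#' @param outputs character vector of output paths.
#' @return Invisibly, \code{path}.
#' @export
writeManifest <- function(path, config, seed, inputs = character(),
                          outputs = character()) {
  cfgPath <- paste0(path, ".config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed,
         config = config,
         config_md5 = unname(tools::md5sum(cfgPath)),
         inputs = inputs, outputs = outputs,
         package = "molarDrift",
         package_version = as.character(packageVersion("molarDrift")),
         r_version = R.version.string),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
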