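#' @import methods
#' @importFrom stats rnorm sd aov anova pt pf qf setNames complete.cases
#' @importFrom utils write.csv read.csv packageVersion
#' @useDynLib molarDrift, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.unit_tol <- 1e-9

.is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

# VoxelVolume -----------------------------------------------------------

#' VoxelVolume: a 3D intensity array with physical voxel spacing
#'
#' The in-memory stand-in for a CBCT scan: a 3D array of intensities plus
#' voxel spacing (mm) and the physical position of the first voxel centre.
#' Voxel `[i, j, k]` has its centre at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @slot intensities 3D numeric array.
#' @slot spacingMm positive length-3 numeric, voxel spacing in mm (x, y, z).
#' @slot originMm length-3 numeric, mm position of voxel `[1, 1, 1]`.
#' @exportClass VoxelVolume
setClass("VoxelVolume",
  representation(intensities = "array", spacingMm = "numeric",
                 originMm = "numeric"))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  if (length(object@intensities) == 0L)
    msg <- c(msg, "intensities must be non-empty")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be 3 strictly positive values")
  if (length(object@originMm) != 3L)
    msg <- c(msg, "originMm must have length 3")
  if (length(msg)) msg else TRUE
})

#' @param intensities 3D numeric array.
#' @param spacingMm voxel spacing in mm; a scalar is recycled to 3.
#' @param originMm mm coordinates of the first voxel centre.
#' @return A \code{VoxelVolume}.
#' @rdname VoxelVolume-class
#' @export
VoxelVolume <- function(intensities, spacingMm, originMm = c(0, 0, 0)) {
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  new("VoxelVolume", intensities = intensities,
      spacingMm = as.numeric(spacingMm), originMm = as.numeric(originMm))
}

# SurfaceModel ----------------------------------------------------------

#' SurfaceModel: a triangle mesh with per-vertex region labels
#'
#' Triangle surface in mm coordinates. Each vertex carries the tissue
#' structure that produced it (target crown/root, neighbour crown, alveolar
#' bone) and a zone tag used to restrict the registration alignment area
#' (alveolar crest, apical window, volume boundary).
#'
#' @slot vertices n x 3 numeric matrix, mm.
#' @slot faces m x 3 integer matrix of 1-based vertex indices.
#' @slot labels data.frame with n rows and columns \code{structure} and
#'   \code{zone} (character).
#' @exportClass SurfaceModel
setClass("SurfaceModel",
  representation(vertices = "matrix", faces = "matrix", labels = "data.frame"))

setValidity("SurfaceModel", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  if (nrow(object@faces) &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (nrow(object@labels) != nrow(object@vertices))
    msg <- c(msg, "labels must have one row per vertex")
  if (!all(c("structure", "zone") %in% names(object@labels)))
    msg <- c(msg, "labels needs columns 'structure' and 'zone'")
  if (length(msg)) msg else TRUE
})

#' @param vertices n x 3 numeric matrix of mm coordinates.
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param structure character vector (length n) of structure labels;
#'   recycled if scalar.
#' @param zone character vector (length n) of zone labels; default "none".
#' @return A \code{SurfaceModel}.
#' @rdname SurfaceModel-class
#' @export
SurfaceModel <- function(vertices, faces, structure = "unknown", zone = "none") {
  n <- nrow(vertices)
  labels <- data.frame(structure = rep_len(as.character(structure), n),
                       zone = rep_len(as.character(zone), n),
                       stringsAsFactors = FALSE)
  storage.mode(faces) <- "integer"
  new("SurfaceModel", vertices = unname(vertices), faces = unname(faces),
      labels = labels)
}

# LandmarkSet -----------------------------------------------------------

#' LandmarkSet: labelled reference points of one tooth at one timepoint
#'
#' Cusp tips are labelled with the field's cusp nomenclature (MB, DB, ML,
#' DL, B, L: mesio-/disto- buccal/lingual); labels ending in "B" are read
#' as buccal, labels ending in "L" as lingual. \code{Mm}/\code{Md} are the
#' midpoints of the mesial and distal marginal crests. \code{quadrantTips}
#' are the cusp tips of all posterior teeth in the quadrant, used for the
#' occlusal-plane fit.
#'
#' @slot cuspTips k x 3 numeric matrix with cusp labels as rownames.
#' @slot apexes r x 3 numeric matrix of root apex points.
#' @slot Mm,Md length-3 numeric, marginal-crest midpoints (mm).
#' @slot quadrantTips q x 3 numeric matrix (q >= 3, non-collinear).
#' @exportClass LandmarkSet
setClass("LandmarkSet",
  representation(cuspTips = "matrix", apexes = "matrix",
                 Mm = "numeric", Md = "numeric", quadrantTips = "matrix"))

.is_buccal <- function(labels) grepl("B$", labels)
.is_lingual <- function(labels) grepl("L$", labels)

.collinear <- function(pts, tol = 1e-9) {
  if (nrow(pts) < 3L) return(TRUE)
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  sv[2] < tol * max(sv[1], 1)
}

setValidity("LandmarkSet", function(object) {
  msg <- character()
  labs <- rownames(object@cuspTips)
  if (nrow(object@cuspTips) < 2L || is.null(labs))
    msg <- c(msg, "need >= 2 labelled cusp tips")
  else if (!any(.is_buccal(labs)) || !any(.is_lingual(labs)))
    msg <- c(msg, "need at least one buccal- and one lingual-labelled cusp")
  if (nrow(object@apexes) < 1L) msg <- c(msg, "need >= 1 root apex")
  if (length(object@Mm) != 3L || length(object@Md) != 3L)
    msg <- c(msg, "Mm and Md must be 3-vectors")
  else if (sqrt(sum((object@Mm - object@Md)^2)) < 1e-12)
    msg <- c(msg, "Mm and Md must be distinct")
  if (nrow(object@quadrantTips) < 3L || .collinear(object@quadrantTips))
    msg <- c(msg, "need >= 3 non-collinear quadrant cusp tips")
  if (length(msg)) msg else TRUE
})

#' @param cuspTips k x 3 matrix with rownames giving cusp labels.
#' @param apexes r x 3 matrix of apex points.
#' @param Mm,Md marginal-crest midpoints (length-3).
#' @param quadrantTips q x 3 matrix of quadrant cusp tips.
#' @return A \code{LandmarkSet}.
#' @rdname LandmarkSet-class
#' @export
LandmarkSet <- function(cuspTips, apexes, Mm, Md, quadrantTips) {
  if (is.null(dim(apexes))) apexes <- matrix(apexes, ncol = 3)
  new("LandmarkSet", cuspTips = as.matrix(cuspTips),
      apexes = as.matrix(apexes), Mm = as.numeric(Mm), Md = as.numeric(Md),
      quadrantTips = as.matrix(quadrantTips))
}

# ToothFrame ------------------------------------------------------------

#' ToothFrame: tooth-local coordinate frame and reference planes
#'
#' Origin at the intersection of the z-axis with the occlusal plane; unit
#' axes x (mesial), y (lingual), z (occlusal). The three reference planes
#' all pass through the origin: the occlusal plane (normal z), the
#' mesio-distal plane (normal y, contains the z-axis and Md) and the
#' bucco-lingual plane (normal x).
#'
#' @slot originMm length-3 numeric.
#' @slot axes 3 x 3 matrix whose columns are the unit x, y, z axes.
#' @slot handedness "right" or "left" (sign of det(axes)).
#' @exportClass ToothFrame
setClass("ToothFrame",
  representation(originMm = "numeric", axes = "matrix",
                 handedness = "character"))

setValidity("ToothFrame", function(object) {
  msg <- character()
  A <- object@axes
  if (!all(dim(A) == c(3L, 3L))) msg <- c(msg, "axes must be 3 x 3")
  else {
    if (max(abs(crossprod(A) - diag(3))) > .unit_tol)
      msg <- c(msg, "axes must be orthonormal within 1e-9")
    if (abs(abs(det(A)) - 1) > 1e-8)
      msg <- c(msg, "axes must form a basis")
  }
  if (length(object@originMm) != 3L) msg <- c(msg, "origin must be length 3")
  if (length(msg)) msg else TRUE
})

# RigidTransform --------------------------------------------------------

#' RigidTransform: proper rigid transform (rotation + translation)
#'
#' Maps a point p to \code{rotation \%*\% p + translationMm}.
#'
#' @slot rotation 3 x 3 proper orthogonal matrix (det +1, R'R = I within
#'   1e-9).
#' @slot translationMm length-3 numeric, mm.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translationMm = "numeric"))

setValidity("RigidTransform", function(object) {
  msg <- character()
  if (!.is_rotation(object@rotation))
    msg <- c(msg, "rotation must be proper orthogonal within 1e-9")
  if (length(object@translationMm) != 3L)
    msg <- c(msg, "translationMm must have length 3")
  if (length(msg)) msg else TRUE
})

#' @param rotation 3 x 3 proper rotation matrix.
#' @param translationMm length-3 translation, mm.
#' @return A \code{RigidTransform}.
#' @rdname RigidTransform-class
#' @export
RigidTransform <- function(rotation = diag(3), translationMm = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translationMm = as.numeric(translationMm))
}

# DriftResult -----------------------------------------------------------

#' DriftResult: positional-change outcome parameters for one tooth
#'
#' Mean and maximum cusp overeruption (mm, signed along the baseline
#' occlusal axis), the cusp attaining the maximum, bucco-lingual and
#' mesio-distal tipping angles at both timepoints and their changes
#' (degrees; positive = lingual / mesial), per-cusp occlusal displacements,
#' and the registration residual when the follow-up model was superimposed.
#'
#' @slot oeMeanMm,oeMaxMm mean / signed maximum cusp overeruption, mm.
#' @slot oeMaxCusp label of the cusp attaining the maximum.
#' @slot cBLTDeg,cMDTDeg tipping changes, degrees.
#' @slot bltToDeg,bltTnDeg,mdtToDeg,mdtTnDeg tipping angles per timepoint.
#' @slot perCuspDzMm named numeric, per-cusp occlusal displacement.
#' @slot registrationRmsMm final ICP RMS (NA when landmark-exact).
#' @exportClass DriftResult
setClass("DriftResult",
  representation(oeMeanMm = "numeric", oeMaxMm = "numeric",
                 oeMaxCusp = "character", cBLTDeg = "numeric",
                 cMDTDeg = "numeric", bltToDeg = "numeric",
                 bltTnDeg = "numeric", mdtToDeg = "numeric",
                 mdtTnDeg = "numeric", perCuspDzMm = "numeric",
                 registrationRmsMm = "numeric"))

setValidity("DriftResult", function(object) {
  msg <- character()
  if (length(object@perCuspDzMm)) {
    if (abs(object@oeMaxMm - max(object@perCuspDzMm)) > 1e-9)
      msg <- c(msg, "oeMaxMm must equal the maximum per-cusp displacement")
    if (object@oeMaxMm < object@oeMeanMm - 1e-9)
      msg <- c(msg, "max of per-cusp dz cannot be below their mean")
  }
  if (abs(object@cBLTDeg - (object@bltTnDeg - object@bltToDeg)) > 1e-9)
    msg <- c(msg, "cBLT must equal BLT(Tn) - BLT(To)")
  if (abs(object@cMDTDeg - (object@mdtTnDeg - object@mdtToDeg)) > 1e-9)
    msg <- c(msg, "cMDT must equal MDT(Tn) - MDT(To)")
  if (length(msg)) msg else TRUE
})

# PhantomSpec -----------------------------------------------------------

#' PhantomSpec: geometry and imaging parameters of the synthetic phantom
#'
#' Describes a two-timepoint molar phantom: a superellipsoid crown bearing
#' 2-5 spherical-cap cusps, 1-3 tapered-cone roots, an undulating alveolar
#' bone slab, and two stable neighbour crowns in the same quadrant. Tissue
#' classes carry distinct mean intensities (strictly ordered background <
#' bone < root < crown) so single thresholds separate adjacent classes.
#'
#' @slot quadrant one of "upper-left", "upper-right", "lower-left",
#'   "lower-right" (metadata; the phantom always uses its own right-handed
#'   mm frame with x mesial, y lingual, z occlusal).
#' @slot nCusps integer 2-5.
#' @slot nRoots integer 1-3.
#' @slot cuspRadiusMm,crownHeightMm,rootLengthMm geometry, mm.
#' @slot voxelSpacingMm positive length-3, mm.
#' @slot intensityMeans named numeric for background, bone, root, crown.
#' @slot noiseSd intensity noise SD (0 = noise-free).
#' @slot seed integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(quadrant = "character", nCusps = "integer",
                 nRoots = "integer", cuspRadiusMm = "numeric",
                 crownHeightMm = "numeric", rootLengthMm = "numeric",
                 voxelSpacingMm = "numeric", intensityMeans = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@quadrant %in%
      c("upper-left", "upper-right", "lower-left", "lower-right"))
    msg <- c(msg, "invalid quadrant")
  if (object@nCusps < 2L || object@nCusps > 5L)
    msg <- c(msg, "nCusps must be 2-5")
  if (object@nRoots < 1L || object@nRoots > 3L)
    msg <- c(msg, "nRoots must be 1-3")
  if (any(c(object@cuspRadiusMm, object@crownHeightMm,
            object@rootLengthMm) <= 0))
    msg <- c(msg, "geometry sizes must be positive")
  if (length(object@voxelSpacingMm) != 3L || any(object@voxelSpacingMm <= 0))
    msg <- c(msg, "voxelSpacingMm must be 3 positive values")
  im <- object@intensityMeans
  need <- c("background", "bone", "root", "crown")
  if (!all(need %in% names(im)))
    msg <- c(msg, "intensityMeans needs background, bone, root, crown")
  else if (!(im["background"] < im["bone"] && im["bone"] < im["root"] &&
             im["root"] < im["crown"]))
    msg <- c(msg, "intensityMeans must be strictly ordered background < bone < root < crown")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param quadrant quadrant label (metadata).
#' @param nCusps,nRoots integers (2-5 cusps, 1-3 roots).
#' @param cuspRadiusMm,crownHeightMm,rootLengthMm geometry, mm.
#' @param voxelSpacingMm scalar or length-3 voxel spacing, mm.
#' @param intensityMeans named numeric intensities per tissue class.
#' @param noiseSd Gaussian intensity noise SD.
#' @param seed integer seed for the intensity noise.
#' @return A \code{PhantomSpec}.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(quadrant = "upper-right", nCusps = 4L, nRoots = 3L,
                        cuspRadiusMm = 1.2, crownHeightMm = 7,
                        rootLengthMm = 13, voxelSpacingMm = 0.25,
                        intensityMeans = c(background = 0, bone = 400,
                                           root = 900, crown = 1600),
                        noiseSd = 0, seed = 1L) {
  if (length(voxelSpacingMm) == 1L) voxelSpacingMm <- rep(voxelSpacingMm, 3L)
  new("PhantomSpec", quadrant = quadrant, nCusps = as.integer(nCusps),
      nRoots = as.integer(nRoots), cuspRadiusMm = cuspRadiusMm,
      crownHeightMm = crownHeightMm, rootLengthMm = rootLengthMm,
      voxelSpacingMm = as.numeric(voxelSpacingMm),
      intensityMeans = intensityMeans, noiseSd = noiseSd,
      seed = as.integer(seed))
}

# GroundTruthMotion -----------------------------------------------------

#' GroundTruthMotion: known tooth motion plus global jaw motion
#'
#' The target tooth first rotates about the apex centroid CA (the minimal
#' rotation taking the true occlusal axis z to the tipped direction given
#' by \code{blTipDeg} toward lingual and \code{mdTipDeg} toward mesial),
#' then translates by \code{eruptionMm} along the occlusal axis; finally
#' the whole jaw (tooth and stable structures alike) moves by the rigid
#' \code{jawRotation}/\code{jawTranslationMm}. Tests and recovery bounds
#' depend on this fixed composition order.
#'
#' @slot eruptionMm occlusal translation, mm.
#' @slot blTipDeg rotation toward lingual (about the mesio-distal axis
#'   through CA), degrees.
#' @slot mdTipDeg rotation toward mesial (about the bucco-lingual axis
#'   through CA), degrees.
#' @slot jawRotation 3 x 3 proper rotation.
#' @slot jawTranslationMm length-3 translation, mm.
#' @exportClass GroundTruthMotion
setClass("GroundTruthMotion",
  representation(eruptionMm = "numeric", blTipDeg = "numeric",
                 mdTipDeg = "numeric", jawRotation = "matrix",
                 jawTranslationMm = "numeric"))

setValidity("GroundTruthMotion", function(object) {
  msg <- character()
  if (!.is_rotation(object@jawRotation))
    msg <- c(msg, "jawRotation must be a proper rigid rotation (det +1)")
  if (length(object@jawTranslationMm) != 3L)
    msg <- c(msg, "jawTranslationMm must have length 3")
  if (length(msg)) msg else TRUE
})

#' @param eruptionMm occlusal translation in mm.
#' @param blTipDeg,mdTipDeg tipping angles, degrees (positive = lingual /
#'   mesial).
#' @param jawRotation 3 x 3 proper rotation applied to the whole jaw.
#' @param jawTranslationMm jaw translation, mm.
#' @return A \code{GroundTruthMotion}.
#' @rdname GroundTruthMotion-class
#' @export
GroundTruthMotion <- function(eruptionMm = 0, blTipDeg = 0, mdTipDeg = 0,
                              jawRotation = diag(3),
                              jawTranslationMm = c(0, 0, 0)) {
  new("GroundTruthMotion", eruptionMm = eruptionMm, blTipDeg = blTipDeg,
      mdTipDeg = mdTipDeg, jawRotation = jawRotation,
      jawTranslationMm = as.numeric(jawTranslationMm))
}

# ThresholdConfig -------------------------------------------------------

#' ThresholdConfig: segmentation thresholds and apical window
#'
#' Half-open intensity intervals [lo, hi) per tissue class, and the
#' spherical window opened in the bone mask around the target root apexes.
#'
#' @slot crownRange,rootRange,boneRange length-2 numeric (lo, hi), lo < hi.
#' @slot windowCenterMm length-3 numeric, mm.
#' @slot windowRadiusMm nonnegative radius, mm (0 disables the window).
#' @exportClass ThresholdConfig
setClass("ThresholdConfig",
  representation(crownRange = "numeric", rootRange = "numeric",
                 boneRange = "numeric", windowCenterMm = "numeric",
                 windowRadiusMm = "numeric"))

setValidity("ThresholdConfig", function(object) {
  msg <- character()
  for (nm in c("crownRange", "rootRange", "boneRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || !(r[1] < r[2]))
      msg <- c(msg, paste(nm, "must be (lo, hi) with lo < hi"))
  }
  if (length(object@windowCenterMm) != 3L)
    msg <- c(msg, "windowCenterMm must have length 3")
  if (object@windowRadiusMm < 0)
    msg <- c(msg, "windowRadiusMm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param crownRange,rootRange,boneRange (lo, hi) intensity intervals.
#' @param windowCenterMm centre of the apical window, mm.
#' @param windowRadiusMm radius of the apical window, mm.
#' @return A \code{ThresholdConfig}.
#' @rdname ThresholdConfig-class
#' @export
ThresholdConfig <- function(crownRange, rootRange, boneRange,
                            windowCenterMm = c(0, 0, 0),
                            windowRadiusMm = 0) {
  new("ThresholdConfig", crownRange = as.numeric(crownRange),
      rootRange = as.numeric(rootRange), boneRange = as.numeric(boneRange),
      windowCenterMm = as.numeric(windowCenterMm),
      windowRadiusMm = windowRadiusMm)
}

# AlignmentMask ---------------------------------------------------------

#' AlignmentMask: which surface regions enter the ICP alignment area
#'
#' Mirrors the clinical rule: all crowns of the dentition except the target
#' tooth, plus the stable alveolar bone excluding the alveolar-crest zone
#' and the opened apical window. Target-tooth vertices are never included;
#' vertices in the volume-boundary zone are always dropped.
#'
#' @slot includeCrownsExceptTarget,includeStableBone logical include flags
#'   (at least one must be set).
#' @slot excludeCrestZone,excludeWindowZone logical exclusion flags.
#' @slot crestMarginMm depth of the crest zone below the bone top, mm.
#' @exportClass AlignmentMask
setClass("AlignmentMask",
  representation(includeCrownsExceptTarget = "logical",
                 includeStableBone = "logical",
                 excludeCrestZone = "logical",
                 excludeWindowZone = "logical",
                 crestMarginMm = "numeric"))

setValidity("AlignmentMask", function(object) {
  msg <- character()
  if (!object@includeCrownsExceptTarget && !object@includeStableBone)
    msg <- c(msg, "at least one include flag must be set")
  if (object@crestMarginMm <= 0)
    msg <- c(msg, "crestMarginMm must be positive")
  if (length(msg)) msg else TRUE
})

#' @param includeCrownsExceptTarget,includeStableBone include flags.
#' @param excludeCrestZone,excludeWindowZone exclusion flags.
#' @param crestMarginMm crest-zone depth, mm.
#' @return An \code{AlignmentMask}.
#' @rdname AlignmentMask-class
#' @export
AlignmentMask <- function(includeCrownsExceptTarget = TRUE,
                          includeStableBone = TRUE,
                          excludeCrestZone = TRUE,
                          excludeWindowZone = TRUE,
                          crestMarginMm = 2) {
  new("AlignmentMask",
      includeCrownsExceptTarget = includeCrownsExceptTarget,
      includeStableBone = includeStableBone,
      excludeCrestZone = excludeCrestZone,
      excludeWindowZone = excludeWindowZone,
      crestMarginMm = crestMarginMm)
}
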