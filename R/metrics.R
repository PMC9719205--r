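# Outcome parameters: overeruption and tipping --------------------------
#
# All angles are measured in the baseline (To) frame; the follow-up
# landmark set must already be superimposed into the baseline global
# frame. Signs: overeruption positive toward occlusal; BLT positive
# toward lingual, MDT positive toward mesial, so a negative cBLT is
# buccal tipping and a negative cMDT is distal tipping.

# fixed tie-break order for cusp attribution of the maximum
.CUSP_ORDER <- c("MB", "DB", "ML", "DL", "B", "L")

.argmax_cusp <- function(dz) {
  labs <- names(dz)
  best <- max(dz)
  cand <- labs[dz >= best - 1e-12]
  ord <- c(.CUSP_ORDER, sort(setdiff(labs, .CUSP_ORDER)))
  cand[order(match(cand, ord))][1]
}

#' Centroid of a point set
#'
#' Arithmetic mean per coordinate — used for the centroid of cusp tips
#' (CC) and the centroid of root apexes (CA).
#'
#' @param points n x 3 matrix (n >= 1).
#' @return Length-3 numeric.
#' @export
centroid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("empty point set")
  colMeans(points)
}

#' Tooth axis from apex and cusp centroids
#'
#' The unit vector from CA (apex centroid) to CC (cusp-tip centroid).
#'
#' @param CA,CC length-3 points, mm.
#' @return Unit length-3 vector.
#' @export
toothAxis <- function(CA, CC) {
  d <- CC - CA
  if (sqrt(sum(d^2)) < 1e-12) stop("CA and CC coincide; axis undefined")
  .normalize(d)
}

#' Per-cusp occlusal displacement and overeruption summaries
#'
#' For each cusp label present at both timepoints, dz = z(tip at Tn) -
#' z(tip at To) in the baseline frame. OE_mean is the mean of the dz
#' values (equivalently the occlusal displacement of the cusp-tip
#' centroid); OE_max is their signed maximum (a tooth moving apically
#' yields a negative OE_max), attributed to a cusp with ties broken in
#' the fixed label order MB, DB, ML, DL, B, L.
#'
#' @param lmTo,lmTn baseline and (superimposed) follow-up
#'   \code{LandmarkSet}s with identical cusp label sets.
#' @param frame the baseline \code{ToothFrame}.
#' @return A list: \code{oeMeanMm}, \code{oeMaxMm}, \code{oeMaxCusp},
#'   \code{perCuspDzMm} (named).
#' @export
overeruption <- function(lmTo, lmTn, frame) {
  labsO <- rownames(lmTo@cuspTips)
  labsN <- rownames(lmTn@cuspTips)
  if (!setequal(labsO, labsN) || anyDuplicated(labsO))
    stop("cusp labels differ between timepoints")
  zO <- toToothCoords(lmTo@cuspTips, frame)[, 3]
  zN <- toToothCoords(lmTn@cuspTips[labsO, , drop = FALSE], frame)[, 3]
  dz <- setNames(zN - zO, labsO)
  list(oeMeanMm = mean(dz), oeMaxMm = max(dz),
       oeMaxCusp = .argmax_cusp(dz), perCuspDzMm = dz)
}

#' Tipping angles of a tooth axis
#'
#' BLT is the signed angle between the tooth axis and the mesio-distal
#' plane, \code{asin(axis . y)} in degrees (positive toward lingual); MDT
#' the signed angle to the bucco-lingual plane, \code{asin(axis . x)}
#' (positive toward mesial). Both lie in [-90, 90].
#'
#' @param axis unit length-3 vector.
#' @param frame a \code{ToothFrame}.
#' @return A list with \code{bltDeg} and \code{mdtDeg}.
#' @export
tippingAngles <- function(axis, frame) {
  A <- frame@axes
  clamp <- function(v) min(1, max(-1, v))
  deg <- 180 / pi
  list(bltDeg = asin(clamp(sum(axis * A[, 2]))) * deg,
       mdtDeg = asin(clamp(sum(axis * A[, 1]))) * deg)
}

#' Tipping changes between timepoints
#'
#' cBLT = BLT(Tn) - BLT(To) and cMDT = MDT(Tn) - MDT(To), with both
#' axes' angles measured in the baseline frame. Negative cBLT = buccal
#' tipping; negative cMDT = distal tipping.
#'
#' @inheritParams overeruption
#' @return A list with \code{cBLTDeg}, \code{cMDTDeg}, and the four
#'   per-timepoint angles.
#' @export
tippingChange <- function(lmTo, lmTn, frame) {
  axO <- toothAxis(centroid(lmTo@apexes), centroid(lmTo@cuspTips))
  axN <- toothAxis(centroid(lmTn@apexes), centroid(lmTn@cuspTips))
  aO <- tippingAngles(axO, frame)
  aN <- tippingAngles(axN, frame)
  list(cBLTDeg = aN$bltDeg - aO$bltDeg, cMDTDeg = aN$mdtDeg - aO$mdtDeg,
       bltToDeg = aO$bltDeg, bltTnDeg = aN$bltDeg,
       mdtToDeg = aO$mdtDeg, mdtTnDeg = aN$mdtDeg)
}

#' Full drift outcome for one tooth
#'
#' Combines \code{\link{overeruption}} and \code{\link{tippingChange}}
#' into a \code{DriftResult}.
#'
#' @inheritParams overeruption
#' @param registrationRmsMm final ICP RMS of the superimposition, or NA
#'   for landmark-exact input.
#' @return A \code{DriftResult}.
#' @export
measureDrift <- function(lmTo, lmTn, frame, registrationRmsMm = NA_real_) {
  oe <- overeruption(lmTo, lmTn, frame)
  tp <- tippingChange(lmTo, lmTn, frame)
  new("DriftResult", oeMeanMm = oe$oeMeanMm, oeMaxMm = oe$oeMaxMm,
      oeMaxCusp = oe$oeMaxCusp, cBLTDeg = tp$cBLTDeg, cMDTDeg = tp$cMDTDeg,
      bltToDeg = tp$bltToDeg, bltTnDeg = tp$bltTnDeg,
      mdtToDeg = tp$mdtToDeg, mdtTnDeg = tp$mdtTnDeg,
      perCuspDzMm = oe$perCuspDzMm,
      registrationRmsMm = registrationRmsMm)
}

#' One row of a cohort table from a drift result
#'
#' @param drift a \code{DriftResult}.
#' @param toothId,arch,molarType,tnMonths cohort metadata.
#' @param patientId,sex,ageYears optional patient metadata.
#' @return A one-row data.frame matching the cohort schema.
#' @export
driftRow <- function(drift, toothId, arch, molarType, tnMonths,
                     patientId = NA, sex = NA, ageYears = NA) {
  data.frame(tooth_id = toothId, patient_id = patientId, sex = sex,
             age_years = ageYears, t_n_months = tnMonths, arch = arch,
             molar_type = molarType, OE_mean = drift@oeMeanMm,
             OE_max = drift@oeMaxMm, OE_max_cusp = drift@oeMaxCusp,
             cBLT = drift@cBLTDeg, cMDT = drift@cMDTDeg,
             registration_rms = drift@registrationRmsMm,
             stringsAsFactors = FALSE)
}
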