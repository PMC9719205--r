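# Synthetic two-timepoint molar phantom --------------------------------
#
# The phantom lives in its own right-handed mm coordinate system with
# x = mesial, y = lingual, z = occlusal (its true occlusal axis is fixed
# by construction, so ground truth is unambiguous). Geometry: a
# superellipsoid crown bearing spherical-cap cusps (analytic tip
# positions), tapered-cone roots (analytic apexes), an alveolar bone slab
# with a gently undulating cortical top, and two stable neighbour crowns
# at +/- one tooth pitch along the arch.

.cusp_layout <- function(nCusps) {
  switch(as.character(nCusps),
    "2" = data.frame(label = c("B", "L"),
                     dx = c(0, 0), dy = c(-2.8, 2.8)),
    "3" = data.frame(label = c("MB", "DB", "L"),
                     dx = c(2.2, -2.2, 0), dy = c(-2.8, -2.8, 2.8)),
    "4" = data.frame(label = c("MB", "DB", "ML", "DL"),
                     dx = c(2.2, -2.2, 2.2, -2.2),
                     dy = c(-2.8, -2.8, 2.8, 2.8)),
    "5" = data.frame(label = c("MB", "B", "DB", "ML", "DL"),
                     dx = c(2.4, 0, -2.4, 2.2, -2.2),
                     dy = c(-2.4, -2.4, -2.4, 3.6, 3.6)),
    stop("nCusps must be 2-5"))
}

.root_layout <- function(nRoots) {
  switch(as.character(nRoots),
    "1" = data.frame(cx = 0, cy = 0),
    "2" = data.frame(cx = c(2.0, -2.0), cy = c(0, 0)),
    "3" = data.frame(cx = c(1.9, -1.9, 0), cy = c(-1.5, -1.5, 3.0)),
    stop("nRoots must be 1-3"))
}

# cortical bone top surface; the undulation emulates the non-planar
# cortical contour of real alveolar bone
.bone_top_z <- function(x, y, base = 10, amp = 0.8) {
  base + amp * sin(2 * pi * x / 7) * cos(2 * pi * y / 5)
}

# inferior border of the bone block; undulating like the top so no
# axis-aligned plane survives into the surface model
.bone_bottom_z <- function(x, y, g) {
  g$boneBottom + 0.6 * cos(2 * pi * x / 8.5) * cos(2 * pi * y / 6 + 0.5)
}

# half-width of the alveolar ridge at height z: flares toward the base
# and undulates along the arch like a real buccal/lingual cortical plate
.bone_half_width <- function(x, z, g) {
  g$boneY0 + g$boneFlare * pmax(0, g$boneBase - z) +
    g$boneXAmp * sin(2 * pi * x / g$boneXPeriod + g$boneXPhase)
}

.phantom_geometry <- function(spec) {
  zCervix <- 12
  h <- spec@crownHeightMm
  cusps <- .cusp_layout(spec@nCusps)
  # lingual cusps balanced against buccal so the cusp-tip centroid sits on
  # the phantom midline (tooth axis exactly occlusal at baseline)
  cusps$dy <- cusps$dy - mean(cusps$dy)
  cusps$dx <- cusps$dx - mean(cusps$dx)
  cusps$cz <- zCervix + h - 0.4
  roots <- .root_layout(spec@nRoots)
  roots$cx <- roots$cx - mean(roots$cx)
  roots$cy <- roots$cy - mean(roots$cy)
  zApex <- zCervix - spec@rootLengthMm
  boneBottom <- min(-4, zApex - 3)
  zTip <- zCervix + h - 0.4 + spec@cuspRadiusMm
  list(
    zCervix = zCervix,
    crownCenter = c(0, 0, zCervix + h / 2),
    crownHalf = c(4.3, 5.1, h / 2),
    crownExp = 4,
    # neighbour crowns: a smaller tooth mesially, a larger one distally,
    # each with a small axial inclination as posterior teeth have in a
    # real arch (cusp spheres stay upright so tips remain analytic and
    # the quadrant cusp tips exactly coplanar)
    neighborScale = c(mesial = 0.93, distal = 1.05),
    neighborTilt = list(
      mesial = axisAngleRotation(c(0, 1, 0), 6) %*%
        axisAngleRotation(c(1, 0, 0), 3),
      distal = axisAngleRotation(c(0, 1, 0), -5) %*%
        axisAngleRotation(c(1, 0, 0), -2.5)),
    cusps = cusps,
    cuspR = spec@cuspRadiusMm,
    roots = roots,
    rootR = 1.6,
    zApex = zApex,
    CA = c(0, 0, zApex),
    boneBase = 10, boneAmp = 0.8, boneBottom = boneBottom,
    boneY0 = 5.3, boneFlare = 0.08, boneXAmp = 0.4, boneXPeriod = 9,
    boneXPhase = 0.7,
    pitch = 9.5,
    zTip = zTip,
    Mm = c(4.3, 0, zCervix + h - 1.7),
    Md = c(-4.3, 0, zCervix + h - 1.7),
    bbox = rbind(lo = c(-16, -8.2, boneBottom - 2.2),
                 hi = c(16, 8.2, zTip + 1.7)),
    occlusalAxis = c(0, 0, 1)
  )
}

.in_superellipsoid <- function(P, center, half, expn) {
  out <- rep(FALSE, nrow(P))
  cand <- abs(P[, 1] - center[1]) <= half[1] &
    abs(P[, 2] - center[2]) <= half[2] &
    abs(P[, 3] - center[3]) <= half[3]
  if (any(cand)) {
    Q <- P[cand, , drop = FALSE]
    s <- (abs(Q[, 1] - center[1]) / half[1])^expn +
      (abs(Q[, 2] - center[2]) / half[2])^expn +
      (abs(Q[, 3] - center[3]) / half[3])^expn
    out[cand] <- s <= 1
  }
  out
}

.in_sphere <- function(P, center, r) {
  out <- rep(FALSE, nrow(P))
  cand <- abs(P[, 1] - center[1]) <= r & abs(P[, 2] - center[2]) <= r &
    abs(P[, 3] - center[3]) <= r
  if (any(cand)) {
    Q <- P[cand, , drop = FALSE]
    out[cand] <- (Q[, 1] - center[1])^2 + (Q[, 2] - center[2])^2 +
      (Q[, 3] - center[3])^2 <= r^2
  }
  out
}

# one crown (superellipsoid plus its cusp spheres) centred at xy offset;
# scale shrinks/enlarges the mesio-distal and bucco-lingual footprint and
# tilt rotates the crown body about its centre
.in_crown <- function(P, g, offset = c(0, 0), scale = 1, tilt = NULL) {
  ctr <- g$crownCenter + c(offset, 0)
  half <- c(g$crownHalf[1] * scale, g$crownHalf[2] * scale, g$crownHalf[3])
  if (is.null(tilt)) {
    inside <- .in_superellipsoid(P, ctr, half, g$crownExp)
  } else {
    pad <- 1.2
    cand <- abs(P[, 1] - ctr[1]) <= half[1] + pad &
      abs(P[, 2] - ctr[2]) <= half[2] + pad &
      abs(P[, 3] - ctr[3]) <= half[3] + pad
    inside <- rep(FALSE, nrow(P))
    if (any(cand)) {
      Q <- sweep(P[cand, , drop = FALSE], 2, ctr) %*% tilt
      inside[cand] <- (abs(Q[, 1]) / half[1])^g$crownExp +
        (abs(Q[, 2]) / half[2])^g$crownExp +
        (abs(Q[, 3]) / half[3])^g$crownExp <= 1
    }
  }
  for (i in seq_len(nrow(g$cusps))) {
    cc <- c(offset[1] + scale * g$cusps$dx[i],
            offset[2] + scale * g$cusps$dy[i], g$cusps$cz[i])
    inside <- inside | .in_sphere(P, cc, g$cuspR)
  }
  inside
}

.in_roots <- function(P, g, spec) {
  out <- rep(FALSE, nrow(P))
  zin <- P[, 3] >= g$zApex & P[, 3] <= g$zCervix
  if (!any(zin)) return(out)
  Q <- P[zin, , drop = FALSE]
  frac <- (Q[, 3] - g$zApex) / spec@rootLengthMm
  hit <- rep(FALSE, nrow(Q))
  for (i in seq_len(nrow(g$roots))) {
    rr <- g$rootR * frac
    hit <- hit | ((Q[, 1] - g$roots$cx[i])^2 +
                    (Q[, 2] - g$roots$cy[i])^2 <= rr^2)
  }
  out[zin] <- hit
  out
}

.in_bone_slab <- function(P, g) {
  P[, 3] >= .bone_bottom_z(P[, 1], P[, 2], g) &
    P[, 3] <= .bone_top_z(P[, 1], P[, 2], g$boneBase, g$boneAmp) &
    abs(P[, 2]) <= .bone_half_width(P[, 1], P[, 3], g)
}

# structure codes used in label volumes and meshes
.STRUCT <- c(bone = 1L, target_crown = 2L, target_root = 3L,
             neighbor_crown = 4L)
.STRUCT_NAMES <- c("background", names(.STRUCT))

# classify canonical-frame coordinates for the stable structures and
# tooth-frame coordinates for the target tooth
.classify_points <- function(Pstable, Ptooth, g, spec) {
  lab <- integer(nrow(Pstable))
  bone <- .in_bone_slab(Pstable, g)
  lab[bone] <- .STRUCT[["bone"]]
  nb <- .in_crown(Pstable, g, c(g$pitch, 0), g$neighborScale[["mesial"]],
                  g$neighborTilt$mesial) |
    .in_crown(Pstable, g, c(-g$pitch, 0), g$neighborScale[["distal"]],
              g$neighborTilt$distal)
  lab[nb] <- .STRUCT[["neighbor_crown"]]
  rt <- .in_roots(Ptooth, g, spec)
  lab[rt] <- .STRUCT[["target_root"]]
  cr <- .in_crown(Ptooth, g)
  lab[cr] <- .STRUCT[["target_crown"]]
  lab
}

.tissue_of_structure <- c("background", "bone", "crown", "root", "crown")

#' Rotation implied by a ground-truth motion
#'
#' The tooth rotation of a \code{GroundTruthMotion}: the minimal rotation
#' taking the true occlusal axis z to the tipped axis direction
#' \code{(sin(mdTip), sin(blTip), sqrt(1 - sin^2 - sin^2))}, so that the
#' bucco-lingual and mesio-distal tipping angles of the moved tooth axis
#' are exactly \code{blTipDeg} and \code{mdTipDeg}. For a single nonzero
#' tip this is a rotation about the mesio-distal (or bucco-lingual) axis.
#'
#' @param motion a \code{GroundTruthMotion}.
#' @return A 3 x 3 rotation matrix.
#' @export
motionRotation <- function(motion) {
  sb <- sin(motion@blTipDeg * pi / 180)
  sm <- sin(motion@mdTipDeg * pi / 180)
  s2 <- sb^2 + sm^2
  if (s2 >= 1) stop("tipping angles too large to define an axis direction")
  a <- c(sm, sb, sqrt(1 - s2))
  z <- c(0, 0, 1)
  w <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3],
         z[1] * a[2] - z[2] * a[1])
  nw <- sqrt(sum(w^2))
  if (nw < 1e-15) return(diag(3))
  ang <- atan2(nw, sum(z * a)) * 180 / pi
  axisAngleRotation(w, ang)
}

#' Tooth motion as a rigid transform (jaw coordinates)
#'
#' Rotation about the apex centroid CA followed by the eruption
#' translation along the occlusal axis; the jaw transform is applied
#' afterwards (the composition order every ground-truth comparison relies
#' on).
#'
#' @param motion a \code{GroundTruthMotion}.
#' @param CA apex centroid of the target tooth, length-3.
#' @param occlusalAxis unit occlusal direction (default phantom z).
#' @return A \code{RigidTransform}.
#' @export
toothMotionTransform <- function(motion, CA, occlusalAxis = c(0, 0, 1)) {
  R <- motionRotation(motion)
  RigidTransform(R, as.vector(CA - R %*% CA) +
                   motion@eruptionMm * occlusalAxis)
}

#' Jaw motion as a rigid transform
#'
#' @param motion a \code{GroundTruthMotion}.
#' @return A \code{RigidTransform}.
#' @export
jawTransform <- function(motion) {
  RigidTransform(motion@jawRotation, motion@jawTranslationMm)
}

.phantom_landmarks <- function(g) {
  tips <- as.matrix(cbind(g$cusps$dx, g$cusps$dy, g$cusps$cz + g$cuspR))
  rownames(tips) <- g$cusps$label
  apexes <- as.matrix(cbind(g$roots$cx, g$roots$cy, g$zApex))
  nb4 <- .cusp_layout(4L)
  quad <- tips
  for (s in c(1, -1)) {
    sc <- g$neighborScale[[if (s > 0) "mesial" else "distal"]]
    # neighbour cusp-sphere tips share the target's cusp-tip height
    nt <- cbind(s * g$pitch + sc * nb4$dx, sc * nb4$dy,
                max(g$cusps$cz) + g$cuspR)
    quad <- rbind(quad, nt)
  }
  rownames(quad) <- NULL
  LandmarkSet(tips, apexes, g$Mm, g$Md, quad)
}

.voxel_grid <- function(g, spacing) {
  lo <- g$bbox["lo", ]
  hi <- g$bbox["hi", ]
  n <- pmax(2L, floor((hi - lo) / spacing) + 1L)
  list(x = lo[1] + (seq_len(n[1]) - 1) * spacing[1],
       y = lo[2] + (seq_len(n[2]) - 1) * spacing[2],
       z = lo[3] + (seq_len(n[3]) - 1) * spacing[3],
       dims = n, origin = lo)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.voxelize_phantom <- function(spec, g, toothT, jawT, seed) {
  grid <- .voxel_grid(g, spec@voxelSpacingMm)
  P <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z,
                             KEEP.OUT.ATTRS = FALSE))
  jawInv <- invertTransform(jawT)
  toothInv <- invertTransform(toothT)
  Pstable <- .apply_rigid(P, jawInv)
  Ptooth <- .apply_rigid(Pstable, toothInv)
  lab <- .classify_points(Pstable, Ptooth, g, spec)
  vals <- spec@intensityMeans[c("background", "bone", "crown", "root",
                                "crown")][lab + 1L]
  if (spec@noiseSd > 0)
    vals <- vals + .with_seed(seed, rnorm(length(vals), 0, spec@noiseSd))
  vol <- VoxelVolume(array(vals, dim = grid$dims), spec@voxelSpacingMm,
                     grid$origin)
  labels <- array(lab, dim = grid$dims)
  list(volume = vol, labelVolume = labels)
}

#' Generate a two-timepoint molar phantom with known ground truth
#'
#' Builds baseline (To) and follow-up (Tn) voxel volumes, structure label
#' volumes and labelled landmark sets for a synthetic unopposed molar. The
#' two timepoints share the identical tooth shape; the follow-up differs
#' from baseline by the ground-truth tooth motion (rotation about CA, then
#' eruption) followed by the global jaw transform, both applied exactly,
#' so follow-up landmarks equal transformed baseline landmarks to
#' floating-point precision. Stable structures (neighbour crowns, bone)
#' differ only by the jaw transform.
#'
#' @param spec a \code{PhantomSpec}.
#' @param motion a \code{GroundTruthMotion}; |eruption| <= 5 mm and
#'   |tips| <= 15 degrees.
#' @param voxelize if \code{FALSE}, skip volume rasterisation and return
#'   landmarks and transforms only (fast, landmark-exact studies).
#' @return A list with components \code{baseline} and \code{followup}
#'   (each \code{volume}, \code{labelVolume}, \code{landmarks},
#'   \code{windowCenterMm}), \code{truth} (the motion), \code{toothT} and
#'   \code{jawT} (the component \code{RigidTransform}s), \code{geometry}
#'   and \code{spec}.
#' @examples
#' ph <- generatePhantom(PhantomSpec(voxelSpacingMm = 0.6),
#'                       GroundTruthMotion(eruptionMm = 0.5))
#' ph$baseline$landmarks
#' @export
generatePhantom <- function(spec, motion = GroundTruthMotion(),
                            voxelize = TRUE) {
  validObject(spec)
  validObject(motion)
  if (abs(motion@eruptionMm) > 5)
    stop("|eruptionMm| must be <= 5")
  if (abs(motion@blTipDeg) > 15 || abs(motion@mdTipDeg) > 15)
    stop("tipping angles must be <= 15 degrees in magnitude")
  g <- .phantom_geometry(spec)
  toothT <- toothMotionTransform(motion, g$CA, g$occlusalAxis)
  jawT <- jawTransform(motion)
  identityT <- RigidTransform()

  lmTo <- .phantom_landmarks(g)
  # follow-up: target landmarks move by tooth motion then jaw; the
  # neighbours' quadrant tips move by jaw only
  full <- composeTransforms(jawT, toothT)
  tipsN <- .apply_rigid(lmTo@cuspTips, full)
  rownames(tipsN) <- rownames(lmTo@cuspTips)
  nTarget <- nrow(lmTo@cuspTips)
  quadN <- rbind(
    .apply_rigid(lmTo@quadrantTips[seq_len(nTarget), , drop = FALSE], full),
    .apply_rigid(lmTo@quadrantTips[-seq_len(nTarget), , drop = FALSE], jawT))
  lmTn <- LandmarkSet(tipsN, .apply_rigid(lmTo@apexes, full),
                      applyTransform(lmTo@Mm, full),
                      applyTransform(lmTo@Md, full), quadN)

  baseline <- list(landmarks = lmTo, windowCenterMm = g$CA)
  followup <- list(landmarks = lmTn,
                   windowCenterMm = applyTransform(g$CA, full))
  if (voxelize) {
    vb <- .voxelize_phantom(spec, g, identityT, identityT, spec@seed)
    vf <- .voxelize_phantom(spec, g, toothT, jawT, spec@seed + 1L)
    baseline$volume <- vb$volume
    baseline$labelVolume <- vb$labelVolume
    followup$volume <- vf$volume
    followup$labelVolume <- vf$labelVolume
  }
  list(baseline = baseline, followup = followup, truth = motion,
       toothT = toothT, jawT = jawT, geometry = g, spec = spec)
}

#' Add Gaussian jitter to a landmark set
#'
#' Perturbs every stored point by independent Gaussian noise of the given
#' per-coordinate SD, preserving all labels. Emulates operator
#' landmark-placement error for repeatability (method-error) studies.
#' \code{sdMm = 0} returns the input unchanged; the same seed always
#' yields the same output.
#'
#' @param lm a \code{LandmarkSet}.
#' @param sdMm per-coordinate noise SD, mm (>= 0).
#' @param seed integer seed.
#' @return A jittered \code{LandmarkSet}.
#' @export
jitterLandmarks <- function(lm, sdMm, seed) {
  stopifnot(is(lm, "LandmarkSet"), sdMm >= 0)
  if (sdMm == 0) return(lm)
  .with_seed(seed, {
    jit <- function(p) p + rnorm(length(p), 0, sdMm)
    tips <- jit(lm@cuspTips)
    rownames(tips) <- rownames(lm@cuspTips)
    LandmarkSet(tips, jit(lm@apexes), jit(lm@Mm), jit(lm@Md),
                jit(lm@quadrantTips))
  })
}

#' Expected drift outcome implied by a ground-truth motion
#'
#' Closed-form expected values of the outcome parameters for a tooth whose
#' baseline landmarks are \code{lm} and which then moves by \code{motion}
#' (tooth rotation about CA, then eruption; the jaw transform is assumed
#' undone by superimposition). Used to score recovery of the measurement
#' pipeline against ground truth.
#'
#' @param lm baseline \code{LandmarkSet} in the phantom frame.
#' @param motion a \code{GroundTruthMotion}.
#' @return A list with \code{oeMeanMm}, \code{oeMaxMm}, \code{oeMaxCusp},
#'   \code{cBLTDeg}, \code{cMDTDeg} and \code{perCuspDzMm}.
#' @export
expectedDrift <- function(lm, motion) {
  R <- motionRotation(motion)
  CA <- colMeans(lm@apexes)
  z <- c(0, 0, 1)
  dz <- apply(lm@cuspTips, 1, function(p) {
    moved <- as.vector(R %*% (p - CA)) + CA + motion@eruptionMm * z
    moved[3] - p[3]
  })
  axisO <- .normalize(colMeans(lm@cuspTips) - CA)
  axisN <- as.vector(R %*% axisO)
  deg <- 180 / pi
  list(oeMeanMm = mean(dz),
       oeMaxMm = max(dz),
       oeMaxCusp = .argmax_cusp(dz),
       cBLTDeg = (asin(axisN[2]) - asin(axisO[2])) * deg,
       cMDTDeg = (asin(axisN[1]) - asin(axisO[1])) * deg,
       perCuspDzMm = dz)
}
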