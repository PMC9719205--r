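# Multi-threshold segmentation and surface extraction -------------------
#
# The model-building workflow: one binary mask per tissue class from a
# half-open intensity interval, Boolean union of the masks, a spherical
# window opened in the bone mask around the target apexes to expose the
# root, and isosurface extraction of the union at iso-level 0.5 into a
# labelled triangle mesh.

#' Threshold a volume into a binary mask
#'
#' Voxels with \code{lo <= intensity < hi} (half-open, so adjacent class
#' intervals partition exactly) become TRUE.
#'
#' @param vol a \code{VoxelVolume}.
#' @param range length-2 numeric (lo, hi), lo < hi.
#' @return A logical 3D array of the same dimensions.
#' @export
thresholdMask <- function(vol, range) {
  stopifnot(is(vol, "VoxelVolume"), length(range) == 2L, range[1] < range[2])
  v <- vol@intensities
  mask <- v >= range[1] & v < range[2]
  if (!any(mask))
    warning("threshold range [", range[1], ", ", range[2],
            ") selects no voxels")
  mask
}

#' Voxelwise union of binary masks
#'
#' Logical OR across a list of same-shaped masks (the Boolean "unite"
#' step that merges the crown, root and bone masks into one model).
#'
#' @param masks list of logical arrays with identical dimensions.
#' @return A logical array.
#' @export
unionMasks <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d)) stop("mask dimensions differ")
  Reduce(`|`, masks)
}

#' Open a spherical apical window in a mask
#'
#' Clears all voxels whose centres lie within \code{windowRadiusMm} of
#' \code{windowCenterMm} — applied to the bone mask before the union so
#' the target root apex is exposed in the combined model. A zero radius,
#' or a window sphere that misses the volume entirely (warned), leaves
#' the mask unchanged.
#'
#' @param mask logical 3D array.
#' @param vol the \code{VoxelVolume} the mask came from (for geometry).
#' @param cfg a \code{ThresholdConfig} carrying the window centre/radius,
#'   or a list with \code{windowCenterMm} and \code{windowRadiusMm}.
#' @return The windowed mask.
#' @export
openApicalWindow <- function(mask, vol, cfg) {
  ctr <- if (is(cfg, "ThresholdConfig")) cfg@windowCenterMm else cfg$windowCenterMm
  r <- if (is(cfg, "ThresholdConfig")) cfg@windowRadiusMm else cfg$windowRadiusMm
  if (r <= 0) return(mask)
  d <- dim(mask)
  sp <- vol@spacingMm
  o <- vol@originMm
  lo <- o
  hi <- o + (d - 1L) * sp
  if (any(ctr + r < lo) || any(ctr - r > hi)) {
    warning("apical window lies outside the volume; mask unchanged")
    return(mask)
  }
  # restrict to the bounding sub-grid of the sphere
  i0 <- pmax(1L, ceiling((ctr - r - o) / sp) + 1L)
  i1 <- pmin(d, floor((ctr + r - o) / sp) + 1L)
  xs <- o[1] + (seq(i0[1], i1[1]) - 1) * sp[1]
  ys <- o[2] + (seq(i0[2], i1[2]) - 1) * sp[2]
  zs <- o[3] + (seq(i0[3], i1[3]) - 1) * sp[3]
  dx2 <- (xs - ctr[1])^2
  dy2 <- (ys - ctr[2])^2
  dz2 <- (zs - ctr[3])^2
  inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
  sub <- mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  sub[inside] <- FALSE
  mask[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
  mask
}

#' Extract a labelled triangle mesh from a binary mask
#'
#' Marching-tetrahedra isosurface of the binary mask at iso-level 0.5
#' (meshing is decoupled from how the mask was segmented). The mask is
#' zero-padded so structures touching the volume boundary still produce a
#' closed surface. Vertices are in mm; each vertex is tagged with the
#' structure label of the inside voxel that produced it.
#'
#' @param mask logical 3D array (must contain at least one TRUE voxel).
#' @param vol the \code{VoxelVolume} the mask came from.
#' @param structureLabels optional integer 3D array of structure codes
#'   (see \code{structureNames}); 0 = background.
#' @return A \code{SurfaceModel}.
#' @export
extractMesh <- function(mask, vol, structureLabels = NULL) {
  stopifnot(is(vol, "VoxelVolume"))
  if (!any(mask)) stop("cannot mesh an empty mask")
  d <- dim(mask)
  dp <- d + 2L
  padded <- array(0, dim = dp)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask)
  plab <- array(0L, dim = dp)
  if (!is.null(structureLabels)) {
    stopifnot(identical(dim(structureLabels), d))
    plab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <-
      as.integer(structureLabels)
  }
  res <- .march_tets(as.numeric(padded), dp, vol@spacingMm,
                     vol@originMm - vol@spacingMm, 0.5, as.integer(plab))
  structure_chr <- c("unknown", names(.STRUCT))[res$vertexLabel + 1L]
  SurfaceModel(res$vertices, res$faces, structure = structure_chr)
}

#' Names of the phantom structure codes
#'
#' @return Named integer vector mapping structure names to the codes used
#'   in label volumes.
#' @export
structureCodes <- function() .STRUCT

#' Surface area of a triangle mesh
#'
#' @param model a \code{SurfaceModel}.
#' @return Total triangle area in mm^2.
#' @export
meshArea <- function(model) {
  V <- model@vertices
  F <- model@faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Volume enclosed by a triangle mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; requires consistently
#' oriented, closed surfaces such as those produced by
#' \code{\link{extractMesh}}.
#'
#' @param model a \code{SurfaceModel}.
#' @return Enclosed volume in mm^3.
#' @export
meshVolume <- function(model) {
  V <- model@vertices
  F <- model@faces
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
    p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
    p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det6)) / 6
}

#' Segment a phantom timepoint into its combined surface model
#'
#' Convenience wrapper running the full model-building chain on one
#' timepoint: crown/root/bone threshold masks, apical window on the bone
#' mask, Boolean union, and labelled mesh extraction.
#'
#' @param volume a \code{VoxelVolume}.
#' @param cfg a \code{ThresholdConfig}.
#' @param structureLabels optional structure-code array for vertex labels.
#' @return A list with the three masks (\code{crown}, \code{root},
#'   \code{bone}), the \code{union} mask and the \code{model}.
#' @export
segmentVolume <- function(volume, cfg, structureLabels = NULL) {
  crown <- thresholdMask(volume, cfg@crownRange)
  root <- thresholdMask(volume, cfg@rootRange)
  bone <- thresholdMask(volume, cfg@boneRange)
  bone <- openApicalWindow(bone, volume, cfg)
  u <- unionMasks(list(crown, root, bone))
  model <- extractMesh(u, volume, structureLabels)
  list(crown = crown, root = root, bone = bone, union = u, model = model)
}

#' Default threshold configuration for a phantom
#'
#' Class boundaries at the midpoints between adjacent class mean
#' intensities (the phantom stand-in for scanner-specific "experience
#' thresholds").
#'
#' @param spec a \code{PhantomSpec}.
#' @param windowCenterMm apical window centre (default: none).
#' @param windowRadiusMm apical window radius, mm.
#' @return A \code{ThresholdConfig}.
#' @export
defaultThresholds <- function(spec, windowCenterMm = c(0, 0, 0),
                              windowRadiusMm = 0) {
  m <- spec@intensityMeans
  cutBgBone <- (m[["background"]] + m[["bone"]]) / 2
  cutBoneRoot <- (m[["bone"]] + m[["root"]]) / 2
  cutRootCrown <- (m[["root"]] + m[["crown"]]) / 2
  hi <- m[["crown"]] + 10 * (m[["crown"]] - m[["background"]])
  ThresholdConfig(crownRange = c(cutRootCrown, hi),
                  rootRange = c(cutBoneRoot, cutRootCrown),
                  boneRange = c(cutBgBone, cutBoneRoot),
                  windowCenterMm = windowCenterMm,
                  windowRadiusMm = windowRadiusMm)
}
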