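# Masked best-fit rigid superimposition (ICP) ---------------------------
#
# The follow-up model is superimposed onto the baseline model by
# point-to-point iterative closest point with the closed-form (Kabsch/SVD)
# update, restricted to the clinically stable alignment area: all crowns
# except the target tooth plus the stable alveolar bone, excluding the
# alveolar-crest zone, the opened apical window and the volume boundary.

#' Select the alignment-area points of a surface model
#'
#' Applies an \code{AlignmentMask} to the vertex labels: neighbour crowns
#' and/or stable bone are included; target-tooth vertices are never
#' included; crest-zone and window-zone vertices are dropped when the
#' corresponding flags are set; boundary-zone vertices are always
#' dropped. Fewer than 100 surviving points is an error (the rigid fit
#' would be under-constrained).
#'
#' @param model a \code{SurfaceModel} with structure/zone labels.
#' @param mask an \code{AlignmentMask}.
#' @return An n x 3 matrix of vertex coordinates (n >= 100).
#' @export
selectAlignmentPoints <- function(model, mask) {
  stopifnot(is(model, "SurfaceModel"), is(mask, "AlignmentMask"))
  lab <- model@labels
  keep <- rep(FALSE, nrow(lab))
  if (mask@includeCrownsExceptTarget)
    keep <- keep | lab$structure == "neighbor_crown"
  if (mask@includeStableBone)
    keep <- keep | lab$structure == "bone"
  keep <- keep & !(lab$structure %in% c("target_crown", "target_root"))
  if (mask@excludeCrestZone) keep <- keep & lab$zone != "crest"
  if (mask@excludeWindowZone) keep <- keep & lab$zone != "window"
  keep <- keep & lab$zone != "boundary"
  n <- sum(keep)
  if (n < 100L)
    stop("alignment area has only ", n,
         " points (< 100); registration would be under-constrained")
  model@vertices[keep, , drop = FALSE]
}

# closed-form least-squares rigid fit of moving onto fixed (paired rows)
.kabsch <- function(moving, fixed) {
  mbar <- colMeans(moving)
  fbar <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, mbar), sweep(fixed, 2, fbar))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  RigidTransform(R, fbar - as.vector(R %*% mbar))
}

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP: nearest-neighbour correspondences from the moving
#' set into the fixed set, closed-form SVD (Kabsch) update, iterated until
#' the RMS correspondence distance changes by less than \code{tol} or
#' \code{maxIter} is reached. Non-convergence is flagged, not an error.
#' Optional centroid pre-alignment and distance-percentile trimming.
#'
#' @param moving,fixed n x 3 / m x 3 point matrices (both >= 100 rows).
#' @param tol convergence tolerance on the RMS change, mm.
#' @param maxIter maximum number of iterations.
#' @param init initial \code{RigidTransform} (default identity).
#' @param preAlign if TRUE, initialise the translation so the centroids
#'   coincide.
#' @param trim NULL for no trimming, or a fraction in (0, 1] — each
#'   iteration keeps only correspondences below that distance percentile
#'   (e.g. 0.95).
#' @param nnCell bin size (mm) of the uniform grid used for exact
#'   nearest-neighbour lookup.
#' @return A list: \code{transform} (a \code{RigidTransform} mapping
#'   moving into the fixed frame), \code{rms} (per-iteration RMS),
#'   \code{finalRmsMm}, \code{iterations}, \code{converged}.
#' @export
icpAlign <- function(moving, fixed, tol = 1e-6, maxIter = 200L,
                     init = RigidTransform(), preAlign = FALSE,
                     trim = NULL, nnCell = 1) {
  stopifnot(is.matrix(moving), is.matrix(fixed),
            ncol(moving) == 3L, ncol(fixed) == 3L)
  if (nrow(moving) < 100L || nrow(fixed) < 100L)
    stop("both point sets must have >= 100 points")
  if (!is.null(trim)) stopifnot(trim > 0, trim <= 1)
  current <- init
  if (preAlign) {
    shift <- colMeans(fixed) -
      colMeans(.apply_rigid(moving, current))
    current <- composeTransforms(RigidTransform(diag(3), shift), current)
  }
  rmsTrace <- numeric(0)
  converged <- FALSE
  lastRms <- Inf
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    m <- .apply_rigid(moving, current)
    nn <- .nn_grid(m, fixed, nnCell)
    keep <- seq_len(nrow(m))
    if (!is.null(trim) && trim < 1)
      keep <- which(nn$distance <= stats::quantile(nn$distance, trim))
    rms <- sqrt(mean(nn$distance[keep]^2))
    rmsTrace <- c(rmsTrace, rms)
    if (abs(lastRms - rms) < tol) {
      converged <- TRUE
      break
    }
    lastRms <- rms
    step <- .kabsch(m[keep, , drop = FALSE],
                    fixed[nn$index[keep], , drop = FALSE])
    current <- composeTransforms(step, current)
  }
  list(transform = current, rms = rmsTrace,
       finalRmsMm = rmsTrace[length(rmsTrace)],
       iterations = iter, converged = converged)
}

#' Registration error against a known rigid transform
#'
#' Rotation-angle and translation differences between a recovered
#' transform and a reference (for ground-truth recovery checks the
#' recovered moving-to-fixed transform is compared with the inverse of
#' the applied transform).
#'
#' @param recovered,reference \code{RigidTransform}s.
#' @return A list with \code{rotationDeg} and \code{translationMm}.
#' @export
transformError <- function(recovered, reference) {
  dR <- crossprod(reference@rotation, recovered@rotation)
  list(rotationDeg = rotationAngleDeg(dR),
       translationMm = sqrt(sum((recovered@translationMm -
                                   reference@translationMm)^2)))
}

#' ICP with perturbation restarts
#'
#' Point-to-point ICP on vertex-sampled surfaces can settle in shallow
#' local minima a fraction of a degree away from the global best fit.
#' This wrapper first converges normally, then re-initialises from small
#' rotations of the converged solution (about the fixed-set centroid) and
#' keeps the basin with the lowest final RMS.
#'
#' @inheritParams icpAlign
#' @param perturbDeg magnitude of the restart rotations, degrees.
#' @param probePoints number of moving points used during the probe
#'   restarts (the winning basin is refined with all moving points).
#' @return As \code{\link{icpAlign}}.
#' @export
icpAlignRobust <- function(moving, fixed, tol = 1e-6, maxIter = 200L,
                           preAlign = TRUE, perturbDeg = 0.4,
                           probePoints = 2500L, nnCell = 0.75) {
  base <- icpAlign(moving, fixed, tol = tol, maxIter = maxIter,
                   preAlign = preAlign, nnCell = nnCell)
  probeTol <- max(tol, 1e-4)  # probes only need to identify the basin
  probe <- if (nrow(moving) > probePoints)
    moving[round(seq(1, nrow(moving), length.out = probePoints)), ,
           drop = FALSE]
  else moving
  ctr <- colMeans(fixed)
  bestInit <- base$transform
  bestRms <- base$finalRmsMm
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    for (sgn in c(-1, 1)) {
      R <- axisAngleRotation(axis, sgn * perturbDeg)
      pert <- composeTransforms(
        RigidTransform(R, ctr - as.vector(R %*% ctr)), base$transform)
      r <- icpAlign(probe, fixed, tol = probeTol, maxIter = maxIter,
                    init = pert, nnCell = nnCell)
      if (r$finalRmsMm < bestRms - 1e-9) {
        bestRms <- r$finalRmsMm
        bestInit <- r$transform
      }
    }
  }
  if (identical(bestInit, base$transform)) return(base)
  icpAlign(moving, fixed, tol = tol, maxIter = maxIter, init = bestInit,
           nnCell = nnCell)
}
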