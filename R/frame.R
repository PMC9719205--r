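# Tooth-local coordinate frame ------------------------------------------
#
# Frame of the baseline model: the occlusal plane is a total-least-squares
# fit through the cusp tips of the posterior teeth of the quadrant; the
# z-axis is the perpendicular to that plane through the midpoint of the
# Mm-Md segment; the origin is where the z-axis meets the plane; x points
# mesial (away from Md), y lingual, z occlusal.

#' Total-least-squares plane fit
#'
#' Orthogonal-distance regression plane through >= 3 non-collinear
#' points: passes through the centroid, normal along the smallest
#' singular vector of the centred point matrix.
#'
#' @param points n x 3 matrix (n >= 3).
#' @return A list with \code{point} (the centroid) and unit
#'   \code{normal}.
#' @export
fitOcclusalPlane <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 3L) stop("need at least 3 points")
  ctr <- colMeans(points)
  s <- svd(sweep(points, 2, ctr))
  if (s$d[2] < 1e-9 * max(s$d[1], 1))
    stop("points are collinear; plane is undetermined")
  list(point = ctr, normal = .normalize(s$v[, 3]))
}

#' Build the tooth coordinate frame from landmarks
#'
#' Constructs origin and axes per the measurement convention: z is the
#' occlusal-plane normal signed along \code{occlusalHint} (default: the
#' apex-centroid-to-cusp-centroid direction, i.e. root to crown); the
#' origin is the orthogonal projection of the Mm-Md midpoint onto the
#' occlusal plane; x is the in-plane direction away from Md (mesial);
#' y = +/- z x x with the sign making the lingual cusp centroid lie on
#' the +y side.
#'
#' @param lm a \code{LandmarkSet}.
#' @param occlusalHint optional rough occlusal direction used only to
#'   sign the plane normal.
#' @param includeTargetTips if FALSE, the target tooth's own cusp tips
#'   are dropped from the occlusal-plane fit (the default keeps them).
#' @return A \code{ToothFrame}.
#' @export
buildFrame <- function(lm, occlusalHint = NULL, includeTargetTips = TRUE) {
  stopifnot(is(lm, "LandmarkSet"))
  validObject(lm)
  if (is.null(occlusalHint)) {
    occlusalHint <- colMeans(lm@cuspTips) - colMeans(lm@apexes)
  }
  occlusalHint <- .normalize(occlusalHint)

  pts <- lm@quadrantTips
  if (!includeTargetTips) {
    # quadrantTips conventionally start with the target's own tips
    n <- nrow(lm@cuspTips)
    if (nrow(pts) - n >= 3L) pts <- pts[-seq_len(n), , drop = FALSE]
  }
  plane <- fitOcclusalPlane(pts)
  zhat <- plane$normal
  if (sum(zhat * occlusalHint) < 0) zhat <- -zhat

  M0 <- (lm@Mm + lm@Md) / 2
  origin <- M0 + sum((plane$point - M0) * zhat) * zhat

  xcand <- lm@Md - origin
  xin <- xcand - sum(xcand * zhat) * zhat
  if (sqrt(sum(xin^2)) < 1e-9)
    stop("Md projects onto the origin; mesial direction undefined")
  xhat <- -.normalize(xin)

  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  labs <- rownames(lm@cuspTips)
  lin <- colMeans(lm@cuspTips[.is_lingual(labs), , drop = FALSE])
  buc <- colMeans(lm@cuspTips[.is_buccal(labs), , drop = FALSE])
  ind <- lin - buc
  if (sqrt(sum(ind^2)) < 1e-9)
    stop("lingual and buccal cusp centroids coincide; y sign ambiguous")
  hand <- "right"
  if (sum(ind * yhat) < 0) {
    yhat <- -yhat
    hand <- "left"
  }
  axes <- cbind(xhat, yhat, zhat)
  colnames(axes) <- c("x", "y", "z")
  new("ToothFrame", originMm = origin, axes = axes, handedness = hand)
}

#' Express points in tooth coordinates
#'
#' \code{(p - origin)} projected on the frame axes; the origin maps to
#' (0, 0, 0). x is mm toward mesial, y toward lingual, z toward occlusal.
#'
#' @param p a length-3 point or an n x 3 matrix.
#' @param frame a \code{ToothFrame}.
#' @return Coordinates with the shape of the input.
#' @export
toToothCoords <- function(p, frame) {
  stopifnot(is(frame, "ToothFrame"))
  if (is.matrix(p)) {
    sweep(p, 2, frame@originMm) %*% frame@axes
  } else {
    as.vector((p - frame@originMm) %*% frame@axes)
  }
}

#' Inverse of \code{toToothCoords}
#'
#' @param q tooth-frame coordinates (length-3 or n x 3).
#' @param frame a \code{ToothFrame}.
#' @return World (mm) coordinates.
#' @export
fromToothCoords <- function(q, frame) {
  stopifnot(is(frame, "ToothFrame"))
  if (is.matrix(q)) {
    sweep(q %*% t(frame@axes), 2, frame@originMm, "+")
  } else {
    as.vector(frame@axes %*% q) + frame@originMm
  }
}
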