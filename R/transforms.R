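# Rigid-transform utilities ---------------------------------------------

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula for the proper rotation by \code{angleDeg} degrees
#' about the (not necessarily unit) axis.
#'
#' @param axis length-3 numeric, rotation axis.
#' @param angleDeg rotation angle in degrees.
#' @return A 3 x 3 rotation matrix.
#' @export
axisAngleRotation <- function(axis, angleDeg) {
  th <- angleDeg * pi / 180
  if (abs(th) < 1e-300) return(diag(3))
  u <- .normalize(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3 x 3 rotation matrix.
#' @return The rotation angle in degrees, in [0, 180].
#' @export
rotationAngleDeg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}

#' Invert a rigid transform
#'
#' @param t a \code{RigidTransform}.
#' @return The inverse \code{RigidTransform}.
#' @export
invertTransform <- function(t) {
  Rt <- t(t@rotation)
  RigidTransform(Rt, -as.vector(Rt %*% t@translationMm))
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{b} first, then
#' \code{a}.
#'
#' @param a,b \code{RigidTransform}s.
#' @return A \code{RigidTransform}.
#' @export
composeTransforms <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.vector(a@rotation %*% b@translationMm) + a@translationMm)
}

.apply_rigid <- function(pts, t) {
  # pts: n x 3 matrix, rows are points
  sweep(pts %*% t(t@rotation), 2, t@translationMm, "+")
}

#' Apply a rigid transform
#'
#' Applies a \code{RigidTransform} to a point matrix, a
#' \code{SurfaceModel} (vertices; labels preserved) or a
#' \code{LandmarkSet} (every stored point). Pairwise distances are
#' preserved to floating-point precision.
#'
#' @param x an n x 3 matrix, a length-3 numeric, a \code{SurfaceModel} or
#'   a \code{LandmarkSet}.
#' @param t a \code{RigidTransform}.
#' @return The transformed copy of \code{x}.
#' @export
setGeneric("applyTransform", function(x, t) standardGeneric("applyTransform"))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("matrix", "RigidTransform"),
  function(x, t) .apply_rigid(x, t))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("numeric", "RigidTransform"),
  function(x, t) as.vector(t@rotation %*% x) + t@translationMm)

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("SurfaceModel", "RigidTransform"),
  function(x, t) {
    x@vertices <- .apply_rigid(x@vertices, t)
    x
  })

#' @rdname applyTransform
#' @export
setMethod("applyTransform", signature("LandmarkSet", "RigidTransform"),
  function(x, t) {
    tips <- .apply_rigid(x@cuspTips, t)
    rownames(tips) <- rownames(x@cuspTips)
    LandmarkSet(tips, .apply_rigid(x@apexes, t),
                applyTransform(x@Mm, t), applyTransform(x@Md, t),
                .apply_rigid(x@quadrantTips, t))
  })
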