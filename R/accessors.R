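# Accessor generics and show methods -----------------------------------

#' @name accessors
#' @title Accessors for molarDrift data classes
#' @description Slot accessors for the core S4 classes; use these instead
#'   of `@`.
#' @param object an object of the documented class.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "VoxelVolume", function(object) object@intensities)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(object) object@spacingMm)

#' @rdname accessors
#' @export
setGeneric("volumeOrigin", function(object) standardGeneric("volumeOrigin"))
#' @rdname accessors
#' @export
setMethod("volumeOrigin", "VoxelVolume", function(object) object@originMm)

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceModel", function(object) object@vertices)

#' @rdname accessors
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))
#' @rdname accessors
#' @export
setMethod("faces", "SurfaceModel", function(object) object@faces)

#' @rdname accessors
#' @export
setGeneric("vertexLabels", function(object) standardGeneric("vertexLabels"))
#' @rdname accessors
#' @export
setMethod("vertexLabels", "SurfaceModel", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("cuspTips", function(object) standardGeneric("cuspTips"))
#' @rdname accessors
#' @export
setMethod("cuspTips", "LandmarkSet", function(object) object@cuspTips)

#' @rdname accessors
#' @export
setGeneric("apexes", function(object) standardGeneric("apexes"))
#' @rdname accessors
#' @export
setMethod("apexes", "LandmarkSet", function(object) object@apexes)

#' @rdname accessors
#' @export
setGeneric("quadrantTips", function(object) standardGeneric("quadrantTips"))
#' @rdname accessors
#' @export
setMethod("quadrantTips", "LandmarkSet", function(object) object@quadrantTips)

#' @rdname accessors
#' @export
setGeneric("marginalCrestMidpoints",
           function(object) standardGeneric("marginalCrestMidpoints"))
#' @rdname accessors
#' @export
setMethod("marginalCrestMidpoints", "LandmarkSet",
          function(object) list(Mm = object@Mm, Md = object@Md))

#' @rdname accessors
#' @export
setGeneric("frameOrigin", function(object) standardGeneric("frameOrigin"))
#' @rdname accessors
#' @export
setMethod("frameOrigin", "ToothFrame", function(object) object@originMm)

#' @rdname accessors
#' @export
setGeneric("frameAxes", function(object) standardGeneric("frameAxes"))
#' @rdname accessors
#' @export
setMethod("frameAxes", "ToothFrame", function(object) object@axes)

#' Reference planes of a tooth frame
#'
#' Returns the occlusal, mesio-distal and bucco-lingual reference planes,
#' each as a list with a point (the frame origin) and a unit normal.
#'
#' @param frame a \code{ToothFrame}.
#' @return A list with components \code{occlusal}, \code{mesioDistal},
#'   \code{buccoLingual}.
#' @export
referencePlanes <- function(frame) {
  stopifnot(is(frame, "ToothFrame"))
  A <- frame@axes
  o <- frame@originMm
  list(occlusal = list(point = o, normal = A[, 3]),
       mesioDistal = list(point = o, normal = A[, 2]),
       buccoLingual = list(point = o, normal = A[, 1]))
}

#' @rdname accessors
#' @export
setGeneric("rotation", function(object) standardGeneric("rotation"))
#' @rdname accessors
#' @export
setMethod("rotation", "RigidTransform", function(object) object@rotation)

#' @rdname accessors
#' @export
setGeneric("translation", function(object) standardGeneric("translation"))
#' @rdname accessors
#' @export
setMethod("translation", "RigidTransform",
          function(object) object@translationMm)

# show ------------------------------------------------------------------

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@intensities)
  cat("VoxelVolume:", paste(d, collapse = " x "), "voxels, spacing",
      paste(format(object@spacingMm, digits = 4), collapse = "/"), "mm\n")
  cat("  intensity range:",
      paste(format(range(object@intensities), digits = 5), collapse = " .. "),
      "\n")
})

setMethod("show", "SurfaceModel", function(object) {
  cat("SurfaceModel:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "triangles\n")
  tab <- table(object@labels$structure)
  cat("  structures:",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet:", nrow(object@cuspTips), "cusp tips (",
      paste(rownames(object@cuspTips), collapse = ", "), "),",
      nrow(object@apexes), "apexes,",
      nrow(object@quadrantTips), "quadrant tips\n")
})

setMethod("show", "ToothFrame", function(object) {
  cat("ToothFrame (", object@handedness, "-handed)\n", sep = "")
  cat("  origin:", paste(format(object@originMm, digits = 5), collapse = ", "),
      "mm\n")
  ax <- format(t(object@axes), digits = 4)
  cat("  x (mesial): ", paste(ax[1, ], collapse = ", "), "\n")
  cat("  y (lingual):", paste(ax[2, ], collapse = ", "), "\n")
  cat("  z (occlusal):", paste(ax[3, ], collapse = ", "), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngleDeg(object@rotation)
  cat("RigidTransform: rotation", format(ang, digits = 5), "deg, translation",
      paste(format(object@translationMm, digits = 5), collapse = ", "),
      "mm\n")
})

setMethod("show", "DriftResult", function(object) {
  cat("DriftResult\n")
  cat(sprintf("  OE_mean: %8.4f mm\n", object@oeMeanMm))
  cat(sprintf("  OE_max:  %8.4f mm (cusp %s)\n", object@oeMaxMm,
              object@oeMaxCusp))
  cat(sprintf("  cBLT:    %8.4f deg (BLT %0.4f -> %0.4f)\n", object@cBLTDeg,
              object@bltToDeg, object@bltTnDeg))
  cat(sprintf("  cMDT:    %8.4f deg (MDT %0.4f -> %0.4f)\n", object@cMDTDeg,
              object@mdtToDeg, object@mdtTnDeg))
  if (!is.na(object@registrationRmsMm))
    cat(sprintf("  registration RMS: %.4f mm\n", object@registrationRmsMm))
})
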