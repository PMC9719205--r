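# File formats ----------------------------------------------------------
#
# STL carries no per-vertex attributes, so region labels travel in a CSV
# sidecar (one row per vertex). Volumes are written as NIfTI with a JSON
# sidecar recording origin and spacing; landmarks as a flat CSV shared
# with the phantom generator; rigid transforms as row-major JSON.

#' Write a surface model as binary STL (+ label sidecar)
#'
#' @param model a \code{SurfaceModel}.
#' @param path output .stl path; the vertex-label sidecar goes to
#'   \code{<path>.labels.csv}.
#' @param sidecar write the per-vertex label sidecar (default TRUE).
#' @return Invisibly, \code{path}.
#' @export
writeSTL <- function(model, path, sidecar = TRUE) {
  V <- model@vertices
  F <- model@faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  p1 <- V[F[, 1], , drop = FALSE]
  p2 <- V[F[, 2], , drop = FALSE]
  p3 <- V[F[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  # 12 floats + 2-byte attribute per facet
  block <- t(cbind(nrm, p1, p2, p3))
  for (i in seq_len(nrow(F))) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  if (sidecar)
    write.csv(cbind(vertex = seq_len(nrow(V)), model@labels),
              paste0(path, ".labels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a binary STL file
#'
#' Facet vertices are welded on exact coordinate equality; if a label
#' sidecar written by \code{\link{writeSTL}} sits next to the file it is
#' reattached.
#'
#' @param path .stl path.
#' @return A \code{SurfaceModel}.
#' @export
readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  # each facet record is 12 little-endian floats + a uint16 attribute
  verts <- matrix(0, 3 * nf, 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
    verts[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
  }
  key <- apply(verts, 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  side <- paste0(path, ".labels.csv")
  if (file.exists(side)) {
    lab <- read.csv(side, stringsAsFactors = FALSE)
    if (nrow(lab) == nrow(uverts))
      return(SurfaceModel(uverts, faces, lab$structure, lab$zone))
  }
  SurfaceModel(uverts, faces)
}

#' Write a voxel volume as NIfTI with a JSON sidecar
#'
#' @param vol a \code{VoxelVolume}.
#' @param path output .nii(.gz) path; the sidecar goes to
#'   \code{<path>.json}.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@intensities, pixdim = vol@spacingMm)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(shape = dim(vol@intensities), spacing_mm = vol@spacingMm,
         origin_mm = vol@originMm,
         coordinate_frame = "phantom right-handed mm: x mesial, y lingual, z occlusal"),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a voxel volume written by \code{\link{writeVolume}}
#'
#' @param path .nii(.gz) path.
#' @return A \code{VoxelVolume}.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    VoxelVolume(array(as.numeric(img), dim = dim(img)),
                meta$spacing_mm, meta$origin_mm)
  } else {
    VoxelVolume(array(as.numeric(img), dim = dim(img)),
                RNifti::pixdim(img))
  }
}

#' Write landmark sets to CSV
#'
#' Flat schema shared with the phantom generator: columns tooth_id,
#' timepoint, label, x_mm, y_mm, z_mm. Cusp tips keep their cusp labels;
#' apexes are labelled apex1..k; marginal-crest midpoints Mm and Md;
#' quadrant tips quadrant1..q.
#'
#' @param lm a \code{LandmarkSet}.
#' @param path output CSV path.
#' @param toothId,timepoint identifiers written into each row.
#' @param append append to an existing file.
#' @return Invisibly, \code{path}.
#' @export
writeLandmarks <- function(lm, path, toothId = "target", timepoint = "To",
                           append = FALSE) {
  rowsOf <- function(pts, labels) {
    data.frame(tooth_id = toothId, timepoint = timepoint, label = labels,
               x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3],
               stringsAsFactors = FALSE)
  }
  df <- rbind(
    rowsOf(lm@cuspTips, paste0("cusp_", rownames(lm@cuspTips))),
    rowsOf(lm@apexes, paste0("apex", seq_len(nrow(lm@apexes)))),
    rowsOf(rbind(lm@Mm, lm@Md), c("Mm", "Md")),
    rowsOf(lm@quadrantTips,
           paste0("quadrant", seq_len(nrow(lm@quadrantTips)))))
  df$x_mm <- sprintf("%.9f", df$x_mm)
  df$y_mm <- sprintf("%.9f", df$y_mm)
  df$z_mm <- sprintf("%.9f", df$z_mm)
  if (append && file.exists(path)) {
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, append = TRUE, quote = TRUE)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read one landmark set from a landmarks CSV
#'
#' @param path CSV path written by \code{\link{writeLandmarks}}.
#' @param toothId,timepoint which set to read.
#' @return A \code{LandmarkSet}.
#' @export
readLandmarks <- function(path, toothId = "target", timepoint = "To") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$tooth_id == toothId & df$timepoint == timepoint, ]
  if (!nrow(df)) stop("no landmarks for ", toothId, "/", timepoint)
  pts <- cbind(as.numeric(df$x_mm), as.numeric(df$y_mm),
               as.numeric(df$z_mm))
  isCusp <- grepl("^cusp_", df$label)
  tips <- pts[isCusp, , drop = FALSE]
  rownames(tips) <- sub("^cusp_", "", df$label[isCusp])
  LandmarkSet(tips,
              pts[grepl("^apex", df$label), , drop = FALSE],
              pts[df$label == "Mm", ],
              pts[df$label == "Md", ],
              pts[grepl("^quadrant", df$label), , drop = FALSE])
}

#' Write a rigid transform as JSON
#'
#' Row-major 3 x 3 rotation plus translation.
#'
#' @param t a \code{RigidTransform}.
#' @param path output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeTransform <- function(t, path) {
  jsonlite::write_json(
    list(rotation_row_major = as.vector(t(t@rotation)),
         translation_mm = t@translationMm),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a rigid transform written by \code{\link{writeTransform}}
#'
#' @param path JSON path.
#' @return A \code{RigidTransform}.
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  RigidTransform(matrix(x$rotation_row_major, 3, 3, byrow = TRUE),
                 x$translation_mm)
}
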