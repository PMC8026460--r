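#' @import methods
NULL

#' VoxelVolume: a CT-like 3D scalar grid
#'
#' Container for a 3D intensity grid with voxel spacing and patient-frame
#' origin. Array index `(i, j, k)` maps to the patient-frame point
#' `origin + (c(i, j, k) - 1) * spacing`, with axes ordered
#' (L, P, S) in the internal left-posterior-superior (LPS) millimetre frame.
#' Axial slices are the third array index.
#'
#' @slot intensities 3D numeric array of voxel intensities (arbitrary units;
#'   CT-like attenuation maps in practice).
#' @slot spacing numeric length-3, millimetres per voxel along each axis.
#' @slot origin numeric length-3, patient-frame position (mm) of voxel (1,1,1).
#' @slot frame character frame label; always "LPS" for objects built here.
#' @export
setClass("VoxelVolume",
  representation(intensities = "array", spacing = "numeric",
                 origin = "numeric", frame = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), frame = "LPS"))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 3L) msg <- c(msg, "intensities must be a 3D array")
  else if (any(d < 2L)) msg <- c(msg, "grid dimensions must be >= 2 on all axes")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a segmentation result aligned to a VoxelVolume
#'
#' @slot mask 3D logical array, congruent with the source volume.
#' @slot spacing,origin geometry copied from the source volume (mm).
#' @slot provenance list recording per-slice seeds, tolerances and warnings.
#' @export
setClass("BinaryMask",
  representation(mask = "array", spacing = "numeric", origin = "numeric",
                 provenance = "list"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), provenance = list()))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L) msg <- c(msg, "mask must be a 3D array")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' TracedRegion: one slice-level level-tracing result
#'
#' The filled mask is the 4-connected region of pixels within the intensity
#' tolerance of the seed; the boundary is the closed crack contour of that
#' region (vertices at pixel corners, first vertex repeated last).
#'
#' @slot slice integer axial slice index (1-based).
#' @slot seed integer length-2 pixel (row, col), 1-based.
#' @slot boundary numeric matrix, n x 2 of (row, col) corner coordinates on
#'   the half-integer pixel-corner lattice; closed (first row == last row).
#' @slot filled logical matrix, the traced region.
#' @slot tolerance numeric intensity half-width used.
#' @export
setClass("TracedRegion",
  representation(slice = "integer", seed = "integer", boundary = "matrix",
                 filled = "matrix", tolerance = "numeric"))

setValidity("TracedRegion", function(object) {
  msg <- character()
  if (!is.logical(object@filled)) msg <- c(msg, "filled must be logical")
  if (length(object@seed) != 2L) msg <- c(msg, "seed must be (row, col)")
  else if (!object@filled[object@seed[1L], object@seed[2L]])
    msg <- c(msg, "seed pixel must be filled")
  b <- object@boundary
  if (nrow(b) < 4L || any(b[1L, ] != b[nrow(b), ]))
    msg <- c(msg, "boundary must be a closed contour (first vertex == last)")
  if (length(msg)) msg else TRUE
})

#' TriangleMesh: a surface model in patient millimetre coordinates
#'
#' @slot vertices numeric n x 3 matrix of vertex positions (mm).
#' @slot faces integer m x 3 matrix of 1-based vertex indices; consistent
#'   outward orientation (positive signed volume) for watertight meshes.
#' @slot provenance list (source geometry, smoothing parameters, realized
#'   volume change).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix", provenance = "list"),
  prototype(provenance = list()))

setValidity("TriangleMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be m x 3")
  f <- object@faces
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(object@vertices))
      msg <- c(msg, "face indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' LandmarkSet: named anatomical fiducials in patient coordinates
#'
#' Coordinates are millimetres in a right-handed LPS
#' (left-posterior-superior) patient frame. See [landmarkSchema()] for the
#' 19-name schema.
#'
#' @slot subject character subject identifier.
#' @slot frame character frame label ("LPS").
#' @slot coords numeric matrix, one named row per landmark, 3 columns (mm).
#' @export
setClass("LandmarkSet",
  representation(subject = "character", frame = "character", coords = "matrix"),
  prototype(subject = "unknown", frame = "LPS"))

setValidity("LandmarkSet", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be n x 3")
  if (nrow(object@coords) > 0L && is.null(rownames(object@coords)))
    msg <- c(msg, "coords rows must be named")
  if (any(!is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
  if (anyDuplicated(rownames(object@coords)))
    msg <- c(msg, "duplicate landmark names")
  if (length(msg)) msg else TRUE
})

#' PelvimetryRecord: the 21 scalar pelvimetric measures for one subject
#'
#' Distances in millimetres, angles in degrees, the inlet/depth ratio
#' dimensionless. The measure names and their order are fixed by
#' [measureRegistry()].
#'
#' @slot subject character subject identifier.
#' @slot measures named numeric vector of length 21 in registry order.
#' @export
setClass("PelvimetryRecord",
  representation(subject = "character", measures = "numeric"),
  prototype(subject = "unknown"))

setValidity("PelvimetryRecord", function(object) {
  msg <- character()
  reg <- measureRegistry()
  if (length(object@measures) != nrow(reg) ||
      !identical(names(object@measures), reg$measure))
    msg <- c(msg, "measures must be the 21 registry measures in order")
  else {
    if (any(!is.finite(object@measures))) msg <- c(msg, "measures must be finite")
    d <- object@measures[reg$type == "distance"]
    if (any(d <= 0)) msg <- c(msg, "distances must be > 0")
    a <- object@measures[reg$type == "angle"]
    if (any(a <= 0 | a >= 180)) msg <- c(msg, "angles must lie in (0, 180)")
    if (object@measures["inlet_depth_ratio"] <= 0)
      msg <- c(msg, "ratio must be > 0")
  }
  if (length(msg)) msg else TRUE
})

## ---- accessors & show -------------------------------------------------

#' @describeIn VoxelVolume-class voxel intensity array
#' @param object,x a package object
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @export
setMethod("intensities", "VoxelVolume", function(object) object@intensities)

#' Voxel spacing in millimetres
#' @param object a `VoxelVolume` or `BinaryMask`
#' @return numeric length-3 (mm per voxel).
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @export
setMethod("voxelSpacing", "VoxelVolume", function(object) object@spacing)
#' @export
setMethod("voxelSpacing", "BinaryMask", function(object) object@spacing)

#' Patient-frame origin of voxel (1,1,1)
#' @param object a `VoxelVolume` or `BinaryMask`
#' @return numeric length-3 (mm).
#' @export
setGeneric("volumeOrigin", function(object) standardGeneric("volumeOrigin"))
#' @export
setMethod("volumeOrigin", "VoxelVolume", function(object) object@origin)
#' @export
setMethod("volumeOrigin", "BinaryMask", function(object) object@origin)

#' Logical mask array of a BinaryMask
#' @param object a `BinaryMask`
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @export
setMethod("maskArray", "BinaryMask", function(object) object@mask)

#' Provenance metadata
#' @param object a `BinaryMask` or `TriangleMesh`
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @export
setMethod("provenance", "BinaryMask", function(object) object@provenance)
#' @export
setMethod("provenance", "TriangleMesh", function(object) object@provenance)

#' Mesh vertices (mm)
#' @param object a `TriangleMesh`
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))
#' @export
setMethod("meshVertices", "TriangleMesh", function(object) object@vertices)

#' Mesh faces (1-based vertex index triples)
#' @param object a `TriangleMesh`
#' @export
setGeneric("meshFaces", function(object) standardGeneric("meshFaces"))
#' @export
setMethod("meshFaces", "TriangleMesh", function(object) object@faces)

#' Landmark coordinate matrix (named rows, mm, LPS)
#' @param object a `LandmarkSet`
#' @export
setGeneric("landmarkCoords", function(object) standardGeneric("landmarkCoords"))
#' @export
setMethod("landmarkCoords", "LandmarkSet", function(object) object@coords)

#' Measures of a PelvimetryRecord as a named numeric vector
#' @param object a `PelvimetryRecord`
#' @export
setGeneric("measures", function(object) standardGeneric("measures"))
#' @export
setMethod("measures", "PelvimetryRecord", function(object) object@measures)

#' Subject identifier
#' @param object a `LandmarkSet` or `PelvimetryRecord`
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @export
setMethod("subjectId", "LandmarkSet", function(object) object@subject)
#' @export
setMethod("subjectId", "PelvimetryRecord", function(object) object@subject)

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, spacing %s mm (%s)\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x "),
              object@frame))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask: %d x %d x %d voxels, %d foreground (%.2f%%)\n",
              d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  if (!is.null(object@provenance$volume_change_percent))
    cat(sprintf("  smoothed; |volume change| = %.4f%%\n",
                abs(object@provenance$volume_change_percent)))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet '%s': %d landmarks (%s frame, mm)\n",
              object@subject, nrow(object@coords), object@frame))
})

setMethod("show", "PelvimetryRecord", function(object) {
  cat(sprintf("PelvimetryRecord '%s' (21 measures)\n", object@subject))
  print(round(object@measures, 2))
})
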