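#' @title Accessors for cctMotion classes
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots.
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "ImageVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "DisplacementField", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))
#' @rdname accessors
#' @export
setMethod("worldOrigin", "ImageVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("worldOrigin", "DisplacementField", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("worldOrigin", "ControlPointGrid", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setMethod("frameIndex", "ImageVolume", function(x) x@frame)
#' @rdname accessors
#' @export
setMethod("frameIndex", "LandmarkSet", function(x) x@frame)

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))
#' @rdname accessors
#' @export
setMethod("meshTriangles", "SurfaceMesh", function(x) x@triangles)

#' @rdname accessors
#' @export
setGeneric("ahaLabels", function(x) standardGeneric("ahaLabels"))
#' @rdname accessors
#' @export
setMethod("ahaLabels", "SurfaceMesh", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("landmarkPoints", function(x) standardGeneric("landmarkPoints"))
#' @rdname accessors
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(x) x@points)

#' @rdname accessors
#' @export
setGeneric("controlPoints", function(x) standardGeneric("controlPoints"))
#' @rdname accessors
#' @export
setMethod("controlPoints", "ControlPointGrid", function(x) x@phi)

#' @rdname accessors
#' @export
setGeneric("fieldArray", function(x) standardGeneric("fieldArray"))
#' @rdname accessors
#' @export
setMethod("fieldArray", "DisplacementField", function(x) x@field)

#' @rdname accessors
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))
#' @rdname accessors
#' @export
setMethod("curveTable", "StrainCurveSet", function(x) x@curves)

#' @export
#' @rdname accessors
#' @param row.names,optional,... passed on (as.data.frame interface).
setMethod("as.data.frame", "StrainCurveSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@curves)

## --- coordinate helpers ----------------------------------------------------

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 1-based; \code{world = origin + (index - 1) * spacing}.
#' Continuous (fractional) indices are allowed.
#'
#' @param x an \linkS4class{ImageVolume} or \linkS4class{DisplacementField}.
#' @param ijk n x 3 matrix of (possibly fractional) 1-based voxel indices.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix.
#' @export
voxelToWorld <- function(x, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, voxelSpacing(x), "*"), 2, worldOrigin(x), "+")
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(x, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, worldOrigin(x), "-"), 2, voxelSpacing(x), "/") + 1
}
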