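#' @import methods
#' @importFrom stats rnorm sd cor lm t.test setNames quantile
#' @importFrom utils head tail read.csv write.csv
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' ImageVolume: a 3D scalar image with world geometry
#'
#' Container for one frame of a gated CT sequence: a 3D array of intensities
#' (Hounsfield units for clinical data), the voxel spacing in mm, the world
#' position of the centre of voxel (1,1,1), and the frame index within the
#' cardiac cycle (0-based; frame 0 is the end-diastolic reference).
#'
#' World coordinates follow the convention
#' \code{world = origin + (index - 1) * spacing} with 1-based voxel indices
#' and no direction cosines beyond the identity.
#'
#' @slot data 3D numeric array of intensities.
#' @slot spacing numeric(3), mm per voxel along each axis (> 0).
#' @slot origin numeric(3), world mm of the first voxel centre.
#' @slot frame integer(1), 0-based frame index.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 frame = "integer"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), frame = 0L))

setValidity("ImageVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing mm per voxel (length 1 or 3).
#' @param origin world mm of the first voxel centre.
#' @param frame 0-based frame index.
#' @return An \linkS4class{ImageVolume}.
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        frame = 0L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), frame = as.integer(frame))
}

#' BinaryMask: a segmentation aligned with an ImageVolume
#'
#' Same geometry as \linkS4class{ImageVolume}, with logical voxel values.
#'
#' @slot data 3D logical array.
#' @export
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@data)) return("mask data must be logical")
  TRUE
})

#' Construct a BinaryMask
#' @param data 3D logical array.
#' @inheritParams ImageVolume
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       frame = 0L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("BinaryMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), frame = as.integer(frame))
}

#' SurfaceMesh: a triangulated endocardial surface
#'
#' Vertices in world mm and counter-clockwise triangles (outward normals for
#' a closed surface enclosing the blood pool). An optional per-triangle AHA
#' segment label (1-16) can be attached.
#'
#' @slot vertices numeric matrix, n x 3, mm.
#' @slot triangles integer matrix, m x 3, 1-based vertex indices.
#' @slot labels integer per-triangle AHA label or NULL.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 labels = "integerOrNULL"),
  prototype(labels = NULL))

setValidity("SurfaceMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@triangles) != 3L) return("triangles must be m x 3")
  tri <- object@triangles
  if (nrow(tri) > 0 &&
      (min(tri) < 1L || max(tri) > nrow(object@vertices)))
    return("triangle indices out of range")
  if (!is.null(object@labels) && length(object@labels) != nrow(tri))
    return("labels must have one entry per triangle")
  TRUE
})

#' Construct a SurfaceMesh
#' @param vertices n x 3 matrix of mm coordinates.
#' @param triangles m x 3 integer matrix of 1-based, counter-clockwise
#'   vertex indices.
#' @param labels optional integer vector of per-triangle AHA labels.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
SurfaceMesh <- function(vertices, triangles, labels = NULL) {
  storage.mode(triangles) <- "integer"
  new("SurfaceMesh", vertices = as.matrix(vertices), triangles = triangles,
      labels = if (is.null(labels)) NULL else as.integer(labels))
}

#' LandmarkSet: named anatomical points
#'
#' A set of named mm points. The six anatomical landmarks used for AHA
#' labelling are named \code{apex}, \code{mv_1}, \code{mv_2}, \code{mv_3},
#' \code{septum_1}, \code{septum_2}; measurement annotation points use the
#' naming convention documented in \code{\link{computeMeasurements}}.
#'
#' @slot points numeric matrix n x 3 with rownames.
#' @slot frame integer frame index.
#' @export
setClass("LandmarkSet",
  representation(points = "matrix", frame = "integer"),
  prototype(frame = 0L))

setValidity("LandmarkSet", function(object) {
  if (ncol(object@points) != 3L) return("points must be n x 3")
  if (is.null(rownames(object@points))) return("points must be named")
  TRUE
})

#' Construct a LandmarkSet
#' @param points named n x 3 matrix (rownames are landmark names), mm.
#' @param frame 0-based frame index.
#' @return A \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(points, frame = 0L) {
  new("LandmarkSet", points = as.matrix(points), frame = as.integer(frame))
}

#' ControlPointGrid: one level of a B-spline free-form deformation
#'
#' Cubic B-spline transform parametrised by control-point displacements
#' \eqn{\Phi = (U, V, W)} on a regular mm lattice. The lattice extends past
#' the image domain so that every image point has full spline support.
#'
#' @slot phi numeric array (ncx, ncy, ncz, 3), displacements in mm.
#' @slot spacing numeric(3), control-point spacing in mm.
#' @slot origin numeric(3), world mm of control point (1,1,1).
#' @slot level integer resolution level (1 = coarsest).
#' @export
setClass("ControlPointGrid",
  representation(phi = "array", spacing = "numeric", origin = "numeric",
                 level = "integer"),
  prototype(level = 1L))

setValidity("ControlPointGrid", function(object) {
  d <- dim(object@phi)
  if (length(d) != 4L || d[4] != 3L) return("phi must be (nx,ny,nz,3)")
  if (any(d[1:3] < 4L)) return("need at least 4 control points per axis")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  TRUE
})

#' DisplacementField: a dense vector field on a voxel lattice
#'
#' Displacements (mm) sampled on a regular lattice, mapping reference
#' world coordinates to their displacement toward a target frame.
#'
#' @slot field numeric array (nx, ny, nz, 3), mm.
#' @slot spacing numeric(3) sample spacing, mm.
#' @slot origin numeric(3), world mm of sample (1,1,1).
#' @export
setClass("DisplacementField",
  representation(field = "array", spacing = "numeric", origin = "numeric"))

setValidity("DisplacementField", function(object) {
  d <- dim(object@field)
  if (length(d) != 4L || d[4] != 3L) return("field must be (nx,ny,nz,3)")
  if (any(!is.finite(object@field))) return("field must be finite")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  TRUE
})

#' Construct a DisplacementField
#' @param field numeric array (nx,ny,nz,3) of mm displacements.
#' @param spacing sample spacing, mm (length 1 or 3).
#' @param origin world mm of the first sample.
#' @return A \linkS4class{DisplacementField}.
#' @export
DisplacementField <- function(field, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DisplacementField", field = field, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' StrainCurveSet: regional strain time series
#'
#' Tidy per-segment strain curves: one row per (frame, segment, metric).
#' Metrics are \code{E_cc} (circumferential), \code{E_zz} (longitudinal),
#' \code{area_ratio} and \code{squeez}. \code{time} is the cycle fraction in
#' [0, 1).
#'
#' @slot curves data.frame with columns frame, time, segment, metric, value.
#' @slot nFrames integer number of frames in the cycle.
#' @export
setClass("StrainCurveSet",
  representation(curves = "data.frame", nFrames = "integer"))

setValidity("StrainCurveSet", function(object) {
  need <- c("frame", "time", "segment", "metric", "value")
  if (!all(need %in% names(object@curves)))
    return("curves must have frame, time, segment, metric, value")
  TRUE
})

#' PhantomSpec: parameters of the deforming-ventricle phantom
#'
#' Describes a synthetic contrast-filled LV: a prolate-spheroid blood cavity
#' (bright) inside a myocardial shell on a dark background, undergoing a
#' smooth cyclic axis-aligned stretch with closed-form Green-Lagrange
#' strains. The long axis is the third image axis.
#'
#' @slot gridShape integer(3) voxel counts (>= 32 per axis).
#' @slot voxelSize numeric(1) isotropic voxel size, mm.
#' @slot aShort,aLong cavity semi-axes, mm (aShort in-plane, aLong along z).
#' @slot wall myocardial wall thickness, mm.
#' @slot bloodHu,myoHu,backgroundHu intensities, HU, within [-1024, 3071].
#' @slot noiseSd additive Gaussian noise, HU.
#' @slot nFrames frames per cardiac cycle (>= 2).
#' @slot lambdaC,lambdaL peak circumferential / longitudinal stretch at
#'   end-systole (dimensionless, in (0, 1.5]).
#' @slot seed integer RNG seed for the noise.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 aShort = "numeric", aLong = "numeric", wall = "numeric",
                 bloodHu = "numeric", myoHu = "numeric",
                 backgroundHu = "numeric", noiseSd = "numeric",
                 nFrames = "integer", lambdaC = "numeric",
                 lambdaL = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(object@gridShape < 32L)) return("gridShape must be >= 32 per axis")
  if (object@nFrames < 2L) return("nFrames must be >= 2")
  lam <- c(object@lambdaC, object@lambdaL)
  if (any(lam <= 0) || any(lam > 1.5)) return("stretches must be in (0, 1.5]")
  hu <- c(object@bloodHu, object@myoHu, object@backgroundHu)
  if (any(hu < -1024) || any(hu > 3071))
    return("intensities must lie in [-1024, 3071] HU")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  ext <- c(object@aShort, object@aShort, object@aLong) + object@wall
  half <- (object@gridShape - 1) * object@voxelSize / 2
  if (any(ext >= half)) return("cavity plus wall does not fit in the grid")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults emulate a 64^3, 1 mm isotropic acquisition with 10 frames per
#' cycle and peak stretches \eqn{\lambda_c^*=0.8}, \eqn{\lambda_l^*=0.88},
#' giving peak circumferential strain of -18\% Green-Lagrange (about -20\%
#' engineering shortening, in the healthy range). Blood pool 400 HU,
#' myocardium 50 HU, background -1000 HU, noise sd 20 HU.
#'
#' @param gridShape voxel counts per axis (scalar or length 3).
#' @param voxelSize isotropic voxel size, mm.
#' @param aShort,aLong cavity semi-axes, mm.
#' @param wall wall thickness, mm.
#' @param bloodHu,myoHu,backgroundHu region intensities, HU.
#' @param noiseSd additive noise standard deviation, HU.
#' @param nFrames frames per cycle.
#' @param lambdaC,lambdaL peak stretches at end-systole.
#' @param seed RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = 64L, voxelSize = 1, aShort = 18,
                        aLong = 24, wall = 5, bloodHu = 400, myoHu = 50,
                        backgroundHu = -1000, noiseSd = 20, nFrames = 10L,
                        lambdaC = 0.8, lambdaL = 0.88, seed = 42L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = voxelSize, aShort = aShort, aLong = aLong, wall = wall,
      bloodHu = bloodHu, myoHu = myoHu, backgroundHu = backgroundHu,
      noiseSd = noiseSd, nFrames = as.integer(nFrames), lambdaC = lambdaC,
      lambdaL = lambdaL, seed = as.integer(seed))
}

## --- show methods ----------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s %d x %d x %d, spacing %s mm, frame %d\n",
              class(object), d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = "x"),
              object@frame))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles%s\n",
              nrow(object@vertices), nrow(object@triangles),
              if (is.null(object@labels)) "" else ", AHA-labelled"))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet (frame %d): %s\n", object@frame,
              paste(rownames(object@points), collapse = ", ")))
})

setMethod("show", "ControlPointGrid", function(object) {
  d <- dim(object@phi)
  cat(sprintf("ControlPointGrid level %d: %d x %d x %d points, spacing %s mm\n",
              object@level, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = "x")))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@field)
  cat(sprintf("DisplacementField %d x %d x %d, max |u| = %.3f mm\n",
              d[1], d[2], d[3], max(abs(object@field))))
})

setMethod("show", "StrainCurveSet", function(object) {
  cat(sprintf("StrainCurveSet: %d frames, %d segments, metrics: %s\n",
              object@nFrames, length(unique(object@curves$segment)),
              paste(unique(object@curves$metric), collapse = ", ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %s grid, %.2g mm voxels, %d frames, ",
                     "lambda_c*=%.2f lambda_l*=%.2f\n"),
              paste(object@gridShape, collapse = "x"), object@voxelSize,
              object@nFrames, object@lambdaC, object@lambdaL))
})
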