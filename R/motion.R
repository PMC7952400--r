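#' Interpolate a displacement field at arbitrary points
#'
#' Component-wise trilinear interpolation of the dense field at world
#' points. Points outside the field domain are an error (silent
#' extrapolation would corrupt downstream strains), with the offending
#' point identified.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param points n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of displacements, mm.
#' @export
interpolateDisplacement <- function(field, points) {
  stopifnot(is(field, "DisplacementField"))
  points <- rbind(points)
  d <- dim(fieldArray(field))[1:3]
  vox <- worldToVoxel(field, points) - 1  # 0-based continuous
  out <- cpp_trilinear_field(as.double(fieldArray(field)), d, vox)
  if (anyNA(out)) {
    bad <- which(is.na(out[, 1]))[1]
    stop(sprintf("point (%g, %g, %g) outside field domain",
                 points[bad, 1], points[bad, 2], points[bad, 3]))
  }
  out
}

#' Deform a mesh through a displacement field
#'
#' Moves every vertex \code{m} to \code{m + u(m)} with
#' \code{\link{interpolateDisplacement}}; connectivity and AHA labels are
#' preserved. Triangles that collapse to (near) zero area are flagged with
#' a warning, never silently dropped.
#'
#' @param mesh a \linkS4class{SurfaceMesh} inside the field domain.
#' @param field a \linkS4class{DisplacementField}.
#' @return The deformed \linkS4class{SurfaceMesh}.
#' @export
deformMesh <- function(mesh, field) {
  disp <- interpolateDisplacement(field, meshVertices(mesh))
  out <- SurfaceMesh(meshVertices(mesh) + disp, meshTriangles(mesh),
                     ahaLabels(mesh))
  a <- triangleAreas(out)
  if (any(a < 1e-12))
    warning(sprintf("%d triangle(s) degenerate after deformation",
                    sum(a < 1e-12)))
  out
}

triangleAreas <- function(mesh) {
  v <- meshVertices(mesh); f <- meshTriangles(mesh)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Propagate landmarks through per-frame displacement fields
#'
#' Applies each frame's reference-to-frame field to the landmark points
#' (the same rule as mesh vertices), producing automatic landmark
#' trajectories across the cycle.
#'
#' @param landmarks a \linkS4class{LandmarkSet} on the reference frame.
#' @param fields list of \linkS4class{DisplacementField}, one per frame
#'   (frame 0 should be the zero field).
#' @return list of per-frame \linkS4class{LandmarkSet}.
#' @export
propagateLandmarks <- function(landmarks, fields) {
  pts <- landmarkPoints(landmarks)
  lapply(seq_along(fields), function(i) {
    disp <- interpolateDisplacement(fields[[i]], pts)
    LandmarkSet(pts + disp, frame = i - 1L)
  })
}

#' Compose two displacement fields
#'
#' Returns the field of the composed map "apply f2, then f1":
#' \eqn{u(x) = u_2(x) + u_1(x + u_2(x))}, sampled on f2's lattice.
#'
#' @param f1,f2 \linkS4class{DisplacementField}s.
#' @return A \linkS4class{DisplacementField}.
#' @export
composeFields <- function(f1, f2) {
  d <- dim(fieldArray(f2))[1:3]
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  x <- voxelToWorld(f2, idx)
  u2 <- matrix(fieldArray(f2), ncol = 3)
  # sample positions leaving f1's lattice are clamped to its edge (the
  # composed map is only used inside the domain of interest)
  d1 <- dim(fieldArray(f1))[1:3]
  v1 <- worldToVoxel(f1, x + u2)
  v1 <- pmin(pmax(v1, 1), matrix(d1, nrow(v1), 3, byrow = TRUE))
  disp1 <- interpolateDisplacement(f1, voxelToWorld(f1, v1))
  DisplacementField(array(u2 + disp1, dim = c(d, 3L)),
                    spacing = voxelSpacing(f2), origin = worldOrigin(f2))
}

#' Build the zero (identity) field on an image lattice
#' @param image an \linkS4class{ImageVolume} providing the geometry.
#' @return A \linkS4class{DisplacementField} of zeros.
#' @export
zeroField <- function(image) {
  d <- dim(voxels(image))
  DisplacementField(array(0, dim = c(d, 3L)), spacing = voxelSpacing(image),
                    origin = worldOrigin(image))
}

#' Sample an analytic phantom deformation onto a lattice
#'
#' Rasterises the phantom's closed-form deformation as a dense displacement
#' field on the image lattice, for oracle comparisons with registration
#' output.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param t frame index.
#' @param image an \linkS4class{ImageVolume} providing the geometry
#'   (defaults to the phantom lattice).
#' @return A \linkS4class{DisplacementField}.
#' @export
analyticField <- function(spec, t, image = NULL) {
  if (is.null(image)) {
    d <- spec@gridShape
    vs <- rep(spec@voxelSize, 3L)
    org <- c(0, 0, 0)
  } else {
    d <- dim(voxels(image))
    vs <- voxelSpacing(image)
    org <- worldOrigin(image)
  }
  idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  x <- sweep(sweep(idx - 1, 2, vs, "*"), 2, org, "+")
  u <- analyticDeformation(x, t, spec) - x
  DisplacementField(array(u, dim = c(d, 3L)), spacing = vs, origin = org)
}
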