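#' Crop an image to a voxel bounding box
#'
#' Keeps voxels in half-open index ranges \code{[lo, hi)} (1-based) per axis
#' and shifts the origin so that world coordinates of retained voxels are
#' unchanged.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param box 2 x 3 integer matrix: row 1 = lower indices (inclusive),
#'   row 2 = upper indices (exclusive).
#' @return A cropped \linkS4class{ImageVolume}.
#' @export
cropVolume <- function(image, box) {
  stopifnot(is(image, "ImageVolume"))
  box <- rbind(box)
  d <- dim(voxels(image))
  lo <- as.integer(box[1, ]); hi <- as.integer(box[2, ])
  if (any(lo < 1L) || any(hi > d + 1L) || any(hi <= lo))
    stop("bounding box empty or out of range")
  dat <- voxels(image)[lo[1]:(hi[1] - 1L), lo[2]:(hi[2] - 1L),
                       lo[3]:(hi[3] - 1L), drop = FALSE]
  init <- if (is(image, "BinaryMask")) BinaryMask else ImageVolume
  init(dat, spacing = voxelSpacing(image),
       origin = worldOrigin(image) + (lo - 1) * voxelSpacing(image),
       frame = frameIndex(image))
}

#' Grey-value region growing
#'
#' 6-connected flood fill from the seed voxels, keeping voxels whose
#' intensity lies within \code{[min(seed HU) - margin, max(seed HU) + margin]}
#' and that are connected to a seed. The default margin of 30 HU is the
#' standard setting for a contrast-filled blood pool.
#'
#' @param image an \linkS4class{ImageVolume}.
#' @param seeds n x 3 matrix of 1-based voxel indices.
#' @param margin HU margin (>= 0).
#' @return A \linkS4class{BinaryMask}.
#' @export
regionGrow <- function(image, seeds, margin = 30) {
  stopifnot(is(image, "ImageVolume"), margin >= 0)
  seeds <- rbind(seeds)
  d <- dim(voxels(image))
  if (any(seeds < 1L) || any(sweep(seeds, 2, d, ">")))
    stop("seed outside image")
  hus <- voxels(image)[seeds]
  mk <- cpp_region_grow(as.double(voxels(image)), d,
                        matrix(as.integer(seeds - 1L), ncol = 3L),
                        min(hus) - margin, max(hus) + margin)
  BinaryMask(mk, spacing = voxelSpacing(image), origin = worldOrigin(image),
             frame = frameIndex(image))
}

## signed distance of a 2D slice: negative inside the mask
sliceSignedDistance <- function(m, spacing) {
  d2 <- c(dim(m), 1L)
  din <- cpp_edt(as.logical(m), d2, c(spacing[1:2], 1))
  dout <- cpp_edt(!as.logical(m), d2, c(spacing[1:2], 1))
  array(din - dout, dim = dim(m))
}

#' Interpolate sparse slice segmentations into a 3D mask
#'
#' Annotated 2D slices (along the third axis) are converted to signed
#' distance maps, linearly interpolated between adjacent annotated slices,
#' and thresholded at zero. Annotated slices are reproduced exactly; slices
#' outside the annotated range are empty.
#'
#' @param sliceMasks list of 2D logical matrices.
#' @param sliceIndex integer vector of slice positions (1-based, 3rd axis).
#' @param targetShape integer(3) output mask shape.
#' @param spacing voxel spacing (mm), length 1 or 3.
#' @param origin world origin.
#' @return A \linkS4class{BinaryMask}.
#' @export
interpolateSegmentation <- function(sliceMasks, sliceIndex, targetShape,
                                    spacing = c(1, 1, 1),
                                    origin = c(0, 0, 0)) {
  if (length(sliceMasks) < 2L) stop("need at least 2 annotated slices")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  ord <- order(sliceIndex)
  sliceIndex <- sliceIndex[ord]
  sliceMasks <- sliceMasks[ord]
  sd <- lapply(sliceMasks, sliceSignedDistance, spacing = spacing)
  out <- array(FALSE, dim = targetShape)
  for (a in seq_len(length(sliceMasks) - 1L)) {
    k0 <- sliceIndex[a]; k1 <- sliceIndex[a + 1L]
    for (k in k0:k1) {
      w <- if (k1 > k0) (k - k0) / (k1 - k0) else 0
      interp <- (1 - w) * sd[[a]] + w * sd[[a + 1L]]
      out[, , k] <- interp < 0
    }
  }
  # annotated slices exactly
  for (a in seq_along(sliceMasks)) out[, , sliceIndex[a]] <- sliceMasks[[a]]
  BinaryMask(out, spacing = spacing, origin = origin)
}

#' Extract an endocardial surface by isosurfacing
#'
#' The binary mask is lightly Gaussian-smoothed (so the iso-level 0.5 surface
#' is smooth rather than a voxel staircase, as a marching-cubes surface of a
#' segmentation should be) and triangulated by tetrahedral-decomposition
#' marching cubes. The result is watertight with outward, counter-clockwise
#' triangles, vertices in world mm.
#'
#' @param mask a \linkS4class{BinaryMask} with a closed foreground component.
#' @param iso iso level in the smoothed [0,1] field.
#' @param smoothSigma Gaussian pre-smoothing in voxels.
#' @return A \linkS4class{SurfaceMesh}.
#' @export
extractSurface <- function(mask, iso = 0.5, smoothSigma = 1) {
  stopifnot(is(mask, "BinaryMask"))
  if (!any(voxels(mask))) stop("empty mask")
  fld <- cpp_gaussian_blur(as.double(voxels(mask)), dim(voxels(mask)),
                           smoothSigma)
  res <- cpp_isosurface(fld, dim(voxels(mask)), iso,
                        worldOrigin(mask), voxelSpacing(mask))
  if (nrow(res$vertices) == 0L) stop("no isosurface at this level")
  SurfaceMesh(res$vertices, res$triangles)
}

## --- mesh utilities --------------------------------------------------------

#' Mesh surface area, enclosed volume, and manifoldness
#'
#' \code{meshArea} sums triangle areas; \code{meshVolume} uses the
#' divergence theorem (signed; positive for outward-oriented closed
#' surfaces); \code{isWatertight} checks that every edge is shared by
#' exactly two triangles.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return numeric scalar (or logical for \code{isWatertight}).
#' @export
meshArea <- function(mesh) {
  v <- meshVertices(mesh); f <- meshTriangles(mesh)
  a <- v[f[, 2], ] - v[f[, 1], ]
  b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @rdname meshArea
#' @export
meshVolume <- function(mesh) {
  v <- meshVertices(mesh); f <- meshTriangles(mesh)
  p1 <- v[f[, 1], ]; p2 <- v[f[, 2], ]; p3 <- v[f[, 3], ]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' @rdname meshArea
#' @export
isWatertight <- function(mesh) {
  f <- meshTriangles(mesh)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Taubin mesh smoothing with volume preservation
#'
#' Alternating lambda/mu Laplacian smoothing (uniform weights), followed by
#' an isotropic rescale about the centroid that restores the enclosed volume
#' (for closed meshes), keeping the volume change well under 0.5\%.
#' Topology is untouched.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param iterations number of lambda/mu passes.
#' @param lambda,mu Taubin coefficients.
#' @return A smoothed \linkS4class{SurfaceMesh}.
#' @export
smoothMesh <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  if (iterations == 0L) return(mesh)
  v <- meshVertices(mesh); f <- meshTriangles(mesh)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nrow(v), nrow(v)))
  A <- (A > 0) * 1
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  closed <- isWatertight(mesh)
  v0 <- meshVolume(mesh)
  step <- function(x, w) x + w * (as.matrix(A %*% x) / deg - x)
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  out <- SurfaceMesh(v, f, ahaLabels(mesh))
  if (closed && v0 > 0) {
    v1 <- meshVolume(out)
    if (v1 > 0) {
      ctr <- colMeans(v)
      s <- (v0 / v1)^(1 / 3)
      v <- sweep(sweep(v, 2, ctr, "-") * s, 2, ctr, "+")
      out <- SurfaceMesh(v, f, ahaLabels(mesh))
    }
  }
  out
}

#' Mean distance from mesh vertices to a mask boundary
#'
#' The mask's boundary voxels (foreground voxels 6-adjacent to background)
#' define the discrete segmentation surface; an exact Euclidean distance
#' transform to that boundary is sampled trilinearly at the mesh vertices
#' and averaged. Used to quantify how far a (smoothed) mesh drifts from its
#' source segmentation.
#'
#' @param mesh a \linkS4class{SurfaceMesh} in the same world frame.
#' @param mask a \linkS4class{BinaryMask}.
#' @return mean unsigned distance in mm.
#' @export
surfaceToMaskDistance <- function(mesh, mask) {
  stopifnot(is(mask, "BinaryMask"))
  m <- voxels(mask)
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  pad <- function(a, dx, dy, dz) {
    b <- array(FALSE, dim = d)
    sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
    sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
    sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
    b[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
    b
  }
  neigh_all <- pad(m, 1, 0, 0) & pad(m, -1, 0, 0) &
    pad(m, 0, 1, 0) & pad(m, 0, -1, 0) &
    pad(m, 0, 0, 1) & pad(m, 0, 0, -1)
  boundary <- m & !neigh_all
  edt <- cpp_edt(as.logical(boundary), d, voxelSpacing(mask))
  pts <- worldToVoxel(mask, meshVertices(mesh)) - 1  # 0-based continuous
  dist <- cpp_trilinear(as.double(edt), d, pts)
  if (all(is.na(dist))) stop("mesh outside mask grid")
  mean(dist, na.rm = TRUE)
}
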