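#' SscDescriptorVolume: binarised self-similarity context descriptors
#'
#' Per-voxel 12-bit codes: Gaussian-weighted patch SSDs between the 12
#' orthogonal pairs of the six unit-offset neighbours are turned into
#' self-similarities (exponentiated with the per-voxel mean SSD as the
#' scale, making the code invariant to affine intensity rescaling) and each
#' channel is binarised against the voxel's mean channel value, ties to 0.
#'
#' @slot codes 3D integer array of 12-bit descriptor codes.
#' @slot nBits descriptor length.
#' @export
setClass("SscDescriptorVolume",
  representation(codes = "array", nBits = "integer"),
  prototype(nBits = 12L))

setMethod("show", "SscDescriptorVolume", function(object) {
  d <- dim(object@codes)
  cat(sprintf("SscDescriptorVolume %d x %d x %d (%d-bit)\n",
              d[1], d[2], d[3], object@nBits))
})

#' Compute SSC descriptors for an image
#'
#' @param image an \linkS4class{ImageVolume}, at least 5 voxels per axis.
#' @return An \linkS4class{SscDescriptorVolume}.
#' @export
sscDescriptor <- function(image) {
  d <- dim(voxels(image))
  if (any(d < 5L)) stop("image too small for descriptor support")
  codes <- cpp_ssc(as.double(voxels(image)), d)
  new("SscDescriptorVolume", codes = array(codes, dim = d), nBits = 12L)
}

#' Displacement label space for discrete registration
#'
#' Enumerates the symmetric 3D displacement labels
#' \code{seq(-radius, radius, by = step)^3} in voxels; always contains the
#' zero displacement.
#'
#' @param radius search radius, voxels.
#' @param step quantisation step, voxels.
#' @return L x 3 integer matrix of voxel offsets.
#' @export
displacementLabels <- function(radius, step = 1L) {
  s <- seq(0L, as.integer(radius), by = as.integer(step))
  s <- sort(unique(c(-s, s)))
  as.matrix(expand.grid(u = s, v = s, w = s))
}

#' Unary label costs from descriptor Hamming distances
#'
#' For each control point \code{p} and label \code{f}, the mean Hamming
#' distance (in bits) between reference descriptors in a patch around
#' \code{p} and target descriptors around \code{p + f}; labels whose patch
#' leaves the volume cost \code{Inf}.
#'
#' @param descRef,descTgt \linkS4class{SscDescriptorVolume}s on the same
#'   lattice.
#' @param controlPoints n x 3 matrix of 1-based voxel indices.
#' @param labels L x 3 matrix of voxel offsets
#'   (\code{\link{displacementLabels}}).
#' @param patchHalfwidth patch half-width, voxels.
#' @param patchStep patch sampling stride, voxels.
#' @param targetBase optional n x 3 matrix of 1-based target-side base
#'   positions (defaults to \code{controlPoints}).
#' @return n x L cost matrix.
#' @export
unaryCosts <- function(descRef, descTgt, controlPoints, labels,
                       patchHalfwidth = 2L, patchStep = 2L,
                       targetBase = controlPoints) {
  if (nrow(labels) == 0L) stop("empty label space")
  d <- dim(descRef@codes)
  stopifnot(all(d == dim(descTgt@codes)))
  cpp_unary_costs(as.integer(descRef@codes), as.integer(descTgt@codes), d,
                  matrix(as.integer(rbind(controlPoints) - 1L), ncol = 3L),
                  matrix(as.integer(rbind(targetBase) - 1L), ncol = 3L),
                  matrix(as.integer(labels), ncol = 3L),
                  as.integer(patchHalfwidth), as.integer(patchStep))
}

#' Minimum spanning tree over a control-point lattice
#'
#' Prim's algorithm on the 6-connected control-point lattice with the given
#' edge weights, starting from node 1; ties are broken deterministically by
#' the smallest node index. Edge weights should reflect local intensity
#' differences in the reference frame so the tree avoids crossing tissue
#' boundaries.
#'
#' @param latticeDim integer(3): control points per axis.
#' @param nodeValues numeric vector (one per node, lattice order, x fastest):
#'   local mean intensity at each control point; edge weight is the absolute
#'   difference between its endpoints' values.
#' @return list with \code{parent} (1-based, NA at the root) and
#'   \code{order} (root-first topological order).
#' @export
buildMst <- function(latticeDim, nodeValues) {
  n <- prod(latticeDim)
  stopifnot(length(nodeValues) == n)
  if (n == 1L) return(list(parent = NA_integer_, order = 1L))
  idx <- arrayInd(seq_len(n), latticeDim)
  # neighbour lists on the 6-connected lattice
  nbr <- vector("list", n)
  lin <- function(ijk) (ijk[, 3] - 1L) * latticeDim[1] * latticeDim[2] +
    (ijk[, 2] - 1L) * latticeDim[1] + ijk[, 1]
  for (ax in 1:3) {
    keep <- idx[, ax] < latticeDim[ax]
    a <- which(keep)
    b <- idx[keep, , drop = FALSE]
    b[, ax] <- b[, ax] + 1L
    bb <- lin(b)
    for (k in seq_along(a)) {
      nbr[[a[k]]] <- c(nbr[[a[k]]], bb[k])
      nbr[[bb[k]]] <- c(nbr[[bb[k]]], a[k])
    }
  }
  dist <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  inTree <- rep(FALSE, n)
  dist[1L] <- 0
  ord <- integer(n)
  for (s in seq_len(n)) {
    cand <- which(!inTree & dist < Inf)
    if (length(cand) == 0L) stop("disconnected control-point graph")
    u <- cand[which.min(dist[cand])]   # which.min: first (smallest index) tie
    inTree[u] <- TRUE
    ord[s] <- u
    for (v in nbr[[u]]) {
      if (!inTree[v]) {
        w <- abs(nodeValues[u] - nodeValues[v])
        if (w < dist[v] ||
            (w == dist[v] && (is.na(parent[v]) || u < parent[v]))) {
          dist[v] <- w
          parent[v] <- u
        }
      }
    }
  }
  list(parent = parent, order = ord)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact min-sum inference on a tree
#'
#' Finds the labeling minimising
#' \deqn{\sum_p cost(p, f_p) + \Theta \sum_{(p,q) \in tree} \|u_{f_p} - u_{f_q}\|^2}
#' exactly, by leaf-to-root message passing and root-to-leaf backtracking.
#'
#' @param costs n x L unary cost matrix (finite for at least one label per
#'   node).
#' @param tree list(parent, order) from \code{\link{buildMst}}.
#' @param labels L x 3 label displacement coordinates.
#' @param theta smoothness weight \eqn{\Theta \ge 0}.
#' @return list with \code{labels} (1-based label index per node) and
#'   \code{objective}.
#' @export
mstMinSum <- function(costs, tree, labels, theta) {
  stopifnot(theta >= 0, nrow(labels) == ncol(costs))
  if (any(apply(costs, 1, function(r) all(!is.finite(r)))))
    stop("a node has no finite-cost label")
  parent <- tree$parent
  parent[is.na(parent)] <- 0L
  cpp_mst_minsum(costs, as.integer(parent), as.integer(tree$order),
                 matrix(as.numeric(labels), ncol = 3L), theta)
}

#' Dense displacement sampling registration
#'
#' DEEDS-style discrete registration of a target frame to the reference:
#' SSC descriptors are computed once per image, then a sequence of
#' control-point grids (default spacings 8, 7, 6, 5, 4 voxels, all on the
#' full-resolution image) is solved exactly on a minimum spanning tree. Per
#' level the label search radius equals the grid spacing with quantisation
#' step \code{ceiling(spacing/2)}, except the final level which refines at
#' unit (one-voxel) steps so arbitrary integer displacements are
#' representable; chosen control displacements are
#' interpolated to a dense field with a cubic B-spline and refined by the
#' next level around the current estimate.
#'
#' @param reference,target \linkS4class{ImageVolume}s on the same domain.
#' @param theta smoothness weight \eqn{\Theta} (optimised default 0.5).
#' @param spacings control-point spacings in voxels, one per level.
#' @param iterations number of levels actually run (defaults to all).
#' @return A \linkS4class{DisplacementField} (mm, on the image lattice).
#' @export
registerDEEDS <- function(reference, target, theta = 0.5,
                          spacings = c(8L, 7L, 6L, 5L, 4L),
                          iterations = length(spacings)) {
  d <- dim(voxels(reference))
  stopifnot(all(d == dim(voxels(target))))
  if (any(d < 4L * max(spacings)))
    stop("image smaller than 4x the coarsest control spacing")
  spacings <- as.integer(spacings[seq_len(iterations)])
  if (any(diff(spacings) > 0L)) stop("spacings must be non-increasing")
  descR <- sscDescriptor(reference)
  descT <- sscDescriptor(target)
  vs <- voxelSpacing(reference)
  u <- array(0, dim = c(d, 3L))   # dense field, mm
  ## coarse levels search with quantisation ceil(s/2); the final level
  ## refines at unit (one-voxel) steps so arbitrary integer displacements
  ## are representable
  qsteps <- pmax(1L, as.integer(ceiling(spacings / 2)))
  qsteps[length(qsteps)] <- 1L
  radii <- spacings
  radii[length(radii)] <- min(radii[length(radii)], 4L)
  for (li in seq_along(spacings)) {
    s <- spacings[li]
    ax <- lapply(1:3, function(a) seq(1L + s %/% 2L, d[a] - s %/% 2L, by = s))
    cps <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    latdim <- vapply(ax, length, 1L)
    # current displacement at the control points, rounded to voxels
    ucur <- matrix(0, nrow(cps), 3L)
    for (c3 in 1:3)
      ucur[, c3] <- round(u[cbind(cps, c3)] / vs[c3])
    tgtBase <- cps + ucur
    tgtBase <- pmin(pmax(tgtBase, 1L),
                    matrix(d, nrow(cps), 3, byrow = TRUE))
    labels <- displacementLabels(radii[li], qsteps[li])
    costs <- unaryCosts(descR, descT, cps, labels,
                        patchHalfwidth = max(1L, s %/% 2L),
                        patchStep = max(1L, s %/% 2L), targetBase = tgtBase)
    # keep the zero label finite even at the border so inference is defined
    zi <- which(labels[, 1] == 0L & labels[, 2] == 0L & labels[, 3] == 0L)
    bad <- !is.finite(costs[, zi])
    if (any(bad)) costs[bad, zi] <- 12
    # MST edge weights: local mean intensity at each control point
    blur <- cpp_gaussian_blur(as.double(voxels(reference)), d, s / 3)
    nodeVal <- array(blur, dim = d)[cps]
    tree <- buildMst(latdim, nodeVal)
    sol <- mstMinSum(costs, tree, labels, theta)
    # total displacement at control points (voxels -> mm)
    tot <- (tgtBase - cps + labels[sol$labels, , drop = FALSE])
    tot <- sweep(tot, 2, vs, "*")
    u <- splineInterpolateControls(tot, latdim, cps, s, reference)
  }
  DisplacementField(u, spacing = vs, origin = worldOrigin(reference))
}

## cubic B-spline interpolation of control-point displacements to the image
## lattice; the control lattice is padded by edge replication so the spline
## support covers the whole image
splineInterpolateControls <- function(tot, latdim, cps, s, reference) {
  d <- dim(voxels(reference))
  vs <- voxelSpacing(reference)
  phi <- array(tot, dim = c(latdim, 3L))  # expand.grid order == array order
  padN <- 3L
  pdim <- latdim + 2L * padN
  pphi <- array(0, dim = c(pdim, 3L))
  ix <- pmin(pmax(seq_len(pdim[1]) - padN, 1L), latdim[1])
  iy <- pmin(pmax(seq_len(pdim[2]) - padN, 1L), latdim[2])
  iz <- pmin(pmax(seq_len(pdim[3]) - padN, 1L), latdim[3])
  pphi <- phi[ix, iy, iz, , drop = FALSE]
  first <- cps[1, ]   # world index of first control point
  gsp <- s * vs
  gorigin <- worldOrigin(reference) + (first - 1 - padN * s) * vs
  fld <- cpp_ffd_rasterise(pphi, pdim, gorigin, gsp, d,
                           worldOrigin(reference), vs)
  fld[is.na(fld)] <- 0
  array(fld, dim = c(d, 3L))
}
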