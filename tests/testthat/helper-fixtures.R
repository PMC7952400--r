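# Shared fixtures, built once per test run.

# small phantom for fast tests (32^3, 3 frames)
smallSpec <- function(nFrames = 3L, noiseSd = 0, ...) {
  phantomSpec(gridShape = 32L, voxelSize = 1, aShort = 9, aLong = 11,
              wall = 3, nFrames = nFrames, noiseSd = noiseSd, seed = 7L, ...)
}

# default-condition phantom, cached across tests
.fixtures <- new.env()
defaultPhantom <- function() {
  if (is.null(.fixtures$phantom))
    .fixtures$phantom <- generatePhantom(phantomSpec())
  .fixtures$phantom
}

# voxelised sphere mask of radius r in a cube of side n
sphereMask <- function(n = 48L, r = 15) {
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  d <- sqrt(rowSums(sweep(idx, 2, rep(ctr, 3))^2))
  BinaryMask(array(d <= r, rep(n, 3L)))
}

# random rigid motion (rotation + translation), seeded
randomRigid <- function(seed) {
  withr::with_seed(seed, {
    th <- runif(3, -pi, pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
                c(-sin(th[2]), 0, cos(th[2])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    list(R = Rz %*% Ry %*% Rx, t = runif(3, -10, 10))
  })
}

# apply a rigid motion to a mesh
rigidMesh <- function(mesh, rig) {
  SurfaceMesh(meshVertices(mesh) %*% t(rig$R) +
                matrix(rig$t, nrow(meshVertices(mesh)), 3, byrow = TRUE),
              meshTriangles(mesh), ahaLabels(mesh))
}

# build a 3-voxel x-translated copy of an image (background fill)
translateImage <- function(image, nvox = 3L, fill = -1000) {
  d <- dim(voxels(image))
  arr <- voxels(image)
  out <- array(fill, d)
  out[(nvox + 1):d[1], , ] <- arr[1:(d[1] - nvox), , ]
  ImageVolume(out, spacing = voxelSpacing(image),
              origin = worldOrigin(image), frame = 1L)
}
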