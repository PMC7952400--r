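test_that("cropping preserves world coordinates", {
  img <- ImageVolume(array(rnorm(8 * 9 * 10), c(8, 9, 10)),
                     spacing = c(0.5, 1, 2), origin = c(3, -2, 7))
  full <- cropVolume(img, rbind(c(1, 1, 1), c(9, 10, 11)))
  expect_equal(voxels(full), voxels(img))
  expect_equal(worldOrigin(full), worldOrigin(img))
  one <- cropVolume(img, rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(dim(voxels(one)), c(1L, 1L, 1L))
  expect_equal(worldOrigin(one), worldOrigin(img))
  # world point inside a crop samples the same intensity
  crop <- cropVolume(img, rbind(c(3, 2, 4), c(7, 8, 9)))
  w <- voxelToWorld(img, rbind(c(4, 5, 6)))
  vi <- worldToVoxel(img, w)
  vc <- worldToVoxel(crop, w)
  expect_equal(voxels(img)[vi[1], vi[2], vi[3]],
               voxels(crop)[vc[1], vc[2], vc[3]])
  expect_error(cropVolume(img, rbind(c(1, 1, 1), c(1, 5, 5))), "empty")
  expect_error(cropVolume(img, rbind(c(0, 1, 1), c(5, 5, 5))), "range")
})

test_that("voxel/world round trip is exact", {
  img <- ImageVolume(array(0, c(5, 5, 5)), spacing = c(0.37, 1.2, 2.5),
                     origin = c(-4.2, 0.1, 9))
  ijk <- rbind(c(1, 1, 1), c(2.25, 3.5, 4.75), c(5, 5, 5))
  expect_equal(worldToVoxel(img, voxelToWorld(img, ijk)), ijk,
               tolerance = 1e-9)
})

test_that("region growing fills the connected in-range component", {
  u <- ImageVolume(array(100, c(10, 10, 10)))
  m <- regionGrow(u, rbind(c(5, 5, 5)), margin = 30)
  expect_true(all(voxels(m)))
  # margin 0 in a flat region bordered by different HU
  a <- array(0, c(10, 10, 10)); a[4:7, 4:7, 4:7] <- 50
  img <- ImageVolume(a)
  m2 <- regionGrow(img, rbind(c(5, 5, 5)), margin = 0)
  expect_equal(voxels(m2), a == 50)
  expect_error(regionGrow(img, rbind(c(11, 5, 5))), "outside")
})

test_that("region-grown blood pool matches the analytic cavity volume", {
  spec <- phantomSpec(noiseSd = 20)
  ph <- generatePhantom(phantomSpec(noiseSd = 20, nFrames = 2L))
  ctr <- round(dim(voxels(ph$frames[[1]])) / 2)
  # several seeds, as in the multi-point protocol: the intensity window is
  # min/max over the seeds plus/minus the 30 HU margin
  seeds <- sweep(rbind(c(0, 0, 0), c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0),
                       c(0, -3, 0), c(0, 0, 3), c(0, 0, -3)), 2, ctr, "+")
  m <- regionGrow(ph$frames[[1]], seeds, margin = 30)
  vol <- sum(voxels(m)) * prod(voxelSpacing(m))
  analytic <- 4 / 3 * pi * spec@aShort^2 * spec@aLong
  expect_lt(abs(vol / analytic - 1), 0.05)
  expect_true(voxels(m)[ctr[1], ctr[2], ctr[3]])   # contains its seed
})

test_that("slice interpolation reproduces annotated slices and blends discs", {
  disc <- function(n, r) {
    idx <- as.matrix(expand.grid(1:n, 1:n))
    matrix(sqrt(rowSums(sweep(idx, 2, c((n + 1) / 2, (n + 1) / 2))^2)) <= r,
           n, n)
  }
  # identical slices: all intermediates identical
  m <- interpolateSegmentation(list(disc(21, 6), disc(21, 6)), c(2, 8),
                               c(21, 21, 10))
  for (k in 2:8) expect_equal(m@data[, , k], disc(21, 6))
  expect_false(any(m@data[, , c(1, 9, 10)]))
  # concentric discs radius 4 and 8: midpoint slice is a disc of radius ~6
  m2 <- interpolateSegmentation(list(disc(25, 4), disc(25, 8)), c(1, 9),
                                c(25, 25, 9))
  expect_equal(m2@data[, , 1], disc(25, 4))
  expect_equal(m2@data[, , 9], disc(25, 8))
  mid <- m2@data[, , 5]
  rad <- sqrt(sum(mid) / pi)
  expect_lt(abs(rad - 6), 1)
  expect_error(interpolateSegmentation(list(disc(25, 4)), 1, c(25, 25, 9)),
               "2 annotated")
})

test_that("isosurface of a sphere mask matches analytic area and volume", {
  mask <- sphereMask(48L, 15)
  mesh <- extractSurface(mask)
  expect_lt(abs(meshArea(mesh) / (4 * pi * 15^2) - 1), 0.05)
  expect_lt(abs(meshVolume(mesh) / (4 / 3 * pi * 15^3) - 1), 0.05)
  expect_true(isWatertight(mesh))
  expect_error(extractSurface(BinaryMask(array(FALSE, c(8, 8, 8)))), "empty")
})

test_that("isosurface volume agrees with voxel count for the phantom cavity", {
  ph <- generatePhantom(phantomSpec(noiseSd = 0, nFrames = 2L))
  ctr <- round(dim(voxels(ph$frames[[1]])) / 2)
  mask <- regionGrow(ph$frames[[1]], rbind(ctr), margin = 30)
  mesh <- extractSurface(mask)
  voxVol <- sum(voxels(mask)) * prod(voxelSpacing(mask))
  expect_lt(abs(meshVolume(mesh) / voxVol - 1), 0.05)
})

test_that("Taubin smoothing shrinks noise but preserves volume and topology", {
  mask <- sphereMask(40L, 12)
  mesh <- extractSurface(mask, smoothSigma = 0.5)
  expect_identical(smoothMesh(mesh, 0L), mesh)
  # perturb radially with noise
  v <- meshVertices(mesh)
  ctr <- colMeans(v)
  rel <- sweep(v, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  noisy <- SurfaceMesh(sweep(rel * (1 + withr::with_seed(1, rnorm(length(r),
    0, 0.02))), 2, ctr, "+"), meshTriangles(mesh))
  sm <- smoothMesh(noisy, 20L)
  dev <- function(m) {
    rr <- sqrt(rowSums(sweep(meshVertices(m), 2, ctr)^2))
    max(abs(rr - mean(rr)))
  }
  expect_lt(dev(sm), dev(noisy))
  expect_lt(abs(meshVolume(sm) / meshVolume(noisy) - 1), 0.005)
  expect_identical(meshTriangles(sm), meshTriangles(noisy))
})

test_that("surface-to-mask distance calibrates against a known offset", {
  mask <- sphereMask(48L, 15)
  mesh <- extractSurface(mask)
  expect_lt(surfaceToMaskDistance(mesh, mask), 1)   # < voxel size
  # controlled 2 mm offset: inflate radially so every vertex moves 2 mm
  # along the local surface normal
  v <- meshVertices(mesh)
  ctr <- colMeans(v)
  rel <- sweep(v, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  inflated <- SurfaceMesh(sweep(rel * (1 + 2 / r), 2, ctr, "+"),
                          meshTriangles(mesh))
  expect_lt(abs(surfaceToMaskDistance(inflated, mask) - 2), 0.3)
  expect_error(surfaceToMaskDistance(mesh,
                                     BinaryMask(array(FALSE, c(4, 4, 4)))),
               "empty")
})
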