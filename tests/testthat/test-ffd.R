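makeGrid <- function(dims = c(8, 8, 8), spacing = c(4, 4, 4),
                     origin = c(-4, -4, -4), fill = 0) {
  new("ControlPointGrid", phi = array(fill, c(dims, 3L)),
      spacing = spacing, origin = origin, level = 1L)
}

test_that("B-spline displacement reproduces constants and the basis sum", {
  g <- makeGrid()
  pts <- rbind(c(5.3, 7.1, 9.9), c(12, 8, 6))
  expect_equal(bsplineDisplacement(g, pts), matrix(0, 2, 3))
  gc <- g
  gc@phi[, , , 1] <- 2.5
  gc@phi[, , , 3] <- -1.25
  expect_equal(bsplineDisplacement(gc, pts),
               matrix(rep(c(2.5, 0, -1.25), each = 2), 2, 3),
               tolerance = 1e-12)
  # brute-force tensor basis sum at a random interior point
  gr <- makeGrid(dims = c(9, 8, 7), spacing = c(3, 4, 5),
                 origin = c(-3, -4, -5))
  gr@phi <- withr::with_seed(11, array(rnorm(length(gr@phi)), dim(gr@phi)))
  p <- c(7.7, 9.2, 11.4)
  bsp <- function(u) {
    v <- 1 - u
    c(v^3 / 6, (3 * u^3 - 6 * u^2 + 4) / 6,
      (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6, u^3 / 6)
  }
  gcoord <- (p - gr@origin) / gr@spacing
  i <- floor(gcoord)
  w <- lapply(1:3, function(a) bsp(gcoord[a] - i[a]))
  acc <- c(0, 0, 0)
  for (a in 0:3) for (b in 0:3) for (cc in 0:3)
    acc <- acc + w[[1]][a + 1] * w[[2]][b + 1] * w[[3]][cc + 1] *
      gr@phi[i[1] + a, i[2] + b, i[3] + cc, ]
  expect_equal(drop(bsplineDisplacement(gr, rbind(p))), acc,
               tolerance = 1e-12)
  expect_error(bsplineDisplacement(g, rbind(c(1e3, 0, 0))), "outside")
})

test_that("SSD similarity behaves as a mean of squared differences", {
  a <- ImageVolume(withr::with_seed(4, array(rnorm(16^3), rep(16, 3))))
  expect_equal(ssdSimilarity(a, a), 0)
  b <- ImageVolume(voxels(a) + 3)
  expect_equal(ssdSimilarity(a, b), 9, tolerance = 1e-12)
})

test_that("a transform encoding a known shift drives SSD to near zero", {
  # smooth image so interpolation error is small
  arr <- array(cctMotion:::cpp_gaussian_blur(
    as.double(withr::with_seed(5, array(rnorm(24^3), rep(24, 3)))),
    rep(24L, 3), 2), rep(24, 3))
  a <- ImageVolume(arr)
  b <- ImageVolume(translateImage(a, 3L, fill = 0)@data)
  # reference -> target displacement is +3 voxels in x
  g <- makeGrid(dims = c(11, 11, 11), spacing = c(3, 3, 3),
                origin = c(-6, -6, -6), fill = 0)
  g@phi[, , , 1] <- 3
  base <- ssdSimilarity(a, b)
  expect_lt(ssdSimilarity(a, b, g) / base, 0.05)
})

test_that("bending energy vanishes for affine fields and matches a stencil", {
  g <- makeGrid(dims = c(6, 6, 6))
  expect_equal(bendingEnergy(g), 0)
  aff <- g
  for (i in 1:6) aff@phi[i, , , 1] <- 2 * i + 1   # linear in index
  for (j in 1:6) aff@phi[, j, , 2] <- -3 * j
  expect_equal(bendingEnergy(aff), 0, tolerance = 1e-20)
  # unit spike: per axis the [1,-2,1] stencil hits it 3 times -> 1+4+1
  spike <- g
  spike@phi[3, 3, 3, 1] <- 1
  expect_equal(bendingEnergy(spike), 3 * 6 / prod(6, 6, 6))
  tiny <- new("ControlPointGrid", phi = array(0, c(4, 4, 4, 3)),
              spacing = c(1, 1, 1), origin = c(0, 0, 0), level = 1L)
  expect_silent(bendingEnergy(tiny))
})

test_that("sparsity penalty is a smoothed L1 over levels", {
  g <- makeGrid()
  expect_equal(sparsityPenalty(g), 0)
  one <- g
  one@phi[2, 3, 4, 2] <- 5
  expect_equal(sparsityPenalty(one, eps = 1e-9), 5, tolerance = 1e-6)
  # two levels, direct evaluation
  g2 <- makeGrid(dims = c(5, 5, 5))
  g2@phi[1, 1, 1, 1] <- -2
  eps <- 1e-2
  direct <- (sqrt(25 + eps^2) - eps) + (sqrt(4 + eps^2) - eps)
  expect_equal(sparsityPenalty(list(one, g2), eps = eps), direct)
  expect_error(sparsityPenalty(list()), "at least one")
})

test_that("analytic objective gradient matches central finite differences", {
  d <- rep(12L, 3)
  blur <- function(x) array(cctMotion:::cpp_gaussian_blur(as.double(x), d,
                                                          1.5), d)
  a <- blur(withr::with_seed(21, array(rnorm(prod(d)), d)))
  b <- blur(withr::with_seed(22, array(rnorm(prod(d)), d)))
  nc <- c(6L, 6L, 6L)
  phi <- withr::with_seed(23, array(rnorm(prod(nc) * 3, 0, 0.3), c(nc, 3)))
  gorig <- c(-6, -6, -6); gsp <- c(4.6, 4.6, 4.6)
  obj <- function(p, wg) cctMotion:::cpp_ffd_objective(
    as.double(a), as.double(b), d, c(0, 0, 0), c(1, 1, 1), p, nc,
    gorig, gsp, wg, numeric(0))
  o <- obj(phi, TRUE)
  ids <- withr::with_seed(24, replicate(15, c(sample(6, 2, TRUE),
                                              sample(6, 1), sample(3, 1)),
                                        simplify = FALSE))
  for (id in ids) {
    id <- rbind(id)
    h <- 1e-5
    pp <- phi; pp[id] <- pp[id] + h
    pm <- phi; pm[id] <- pm[id] - h
    fd <- (obj(pp, FALSE)$value - obj(pm, FALSE)$value) / (2 * h)
    an <- o$grad[id]
    expect_lt(abs(fd - an) / max(abs(fd), abs(an), 1e-8), 1e-4)
  }
})

test_that("registering identical frames yields a near-zero transform", {
  ph <- generatePhantom(smallSpec(nFrames = 2L, noiseSd = 5))
  tr <- registerTSFFD(list(ph$frames[[1]], ph$frames[[1]]), levels = 2L,
                      maxIter = 20L)
  fld <- toDisplacementField(tr, 1)
  expect_lt(max(abs(fieldArray(fld))), 0.1)
})

test_that("the objective trace never increases within an optimisation
           stage", {
  ph <- generatePhantom(smallSpec(nFrames = 2L, noiseSd = 5))
  tgt <- translateImage(ph$frames[[1]], 2L)
  tr <- registerTSFFD(list(ph$frames[[1]], tgt), levels = 2L, maxIter = 25L)
  # NA entries mark stage restarts (new level or blur); accepted
  # iterations within a stage are monotone non-increasing
  expect_true(all(diff(tr@trace) <= 1e-12, na.rm = TRUE))
  expect_gt(sum(!is.na(tr@trace)), 3)
})

test_that("TSFFD recovers a small translation to sub-voxel accuracy", {
  ph <- generatePhantom(phantomSpec(gridShape = 48L, aShort = 12,
                                    aLong = 16, wall = 4, noiseSd = 10,
                                    nFrames = 2L))
  ref <- ph$frames[[1]]
  tgt <- translateImage(ref, 2L)
  tr <- registerTSFFD(list(ref, tgt), maxIter = 80L)
  fld <- toDisplacementField(tr, 1)
  lms <- phantomLandmarks(phantomSpec(gridShape = 48L, aShort = 12,
                                      aLong = 16, wall = 4, nFrames = 2L))
  moved <- propagateLandmarks(lms, list(zeroField(ref), fld))[[2]]
  # true motion: +2 mm in x at every landmark
  truthErr <- sqrt(rowSums((landmarkPoints(moved) - landmarkPoints(lms) -
                              matrix(c(2, 0, 0), nrow(landmarkPoints(lms)),
                                     3, byrow = TRUE))^2))
  expect_lt(mean(truthErr), 0.5)
})

test_that("an over-stiff bending weight biases recovered strain toward zero", {
  spec <- smallSpec(nFrames = 3L, noiseSd = 10)
  ph <- generatePhantom(spec)
  ref <- ph$frames[[1]]
  tgt <- ph$frames[[2]]    # lambda_c(1) = 1 - 0.2 sin^2(pi/3)
  mesh <- extractSurface(regionGrow(ref, rbind(round(dim(voxels(ref)) / 2)),
                                    margin = 30))
  lms <- phantomLandmarks(spec)
  pts <- landmarkPoints(lms)
  apex <- pts["apex", ]
  base <- colMeans(pts[c("mv_1", "mv_2", "mv_3"), ])
  meanEcc <- function(bend) {
    tr <- registerTSFFD(list(ref, tgt), bending = bend, maxIter = 40L)
    def <- deformMesh(mesh, toDisplacementField(tr, 1))
    mean(meshStrain(mesh, def, apex, base)$E_cc)
  }
  tuned <- meanEcc(5e-6)
  stiff <- meanEcc(1)
  truth <- unname(analyticStrain(spec, 1)["E_cc"])
  expect_lt(abs(stiff), abs(tuned))    # stiffness pulls strain toward zero
  expect_lt(abs(stiff), abs(truth))
})
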