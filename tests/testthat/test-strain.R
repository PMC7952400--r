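test_that("element basis matches its defining construction", {
  # triangle in the y-z plane with +x normal, long axis +z
  tri <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  b <- elementBasis(tri, apex = c(0, 0, -10), base = c(0, 0, 10))
  expect_equal(b$e_r, c(1, 0, 0))
  expect_equal(b$e_theta, c(0, 1, 0))
  expect_equal(b$e_z, c(0, 0, 1))
  # random triangle: orthonormal right-handed triad, matches the formulas
  withr::with_seed(51, {
    tri <- matrix(rnorm(9), 3, 3)
    axis <- rnorm(3)
  })
  b2 <- elementBasis(tri, apex = c(0, 0, 0), base = axis)
  Q <- rbind(b2$e_r, b2$e_theta, b2$e_z)
  expect_equal(Q %*% t(Q), diag(3), tolerance = 1e-12)
  expect_equal(det(Q), 1, tolerance = 1e-12)
  e21 <- tri[2, ] - tri[1, ]; e31 <- tri[3, ] - tri[1, ]
  nr <- c(e21[2] * e31[3] - e21[3] * e31[2],
          e21[3] * e31[1] - e21[1] * e31[3],
          e21[1] * e31[2] - e21[2] * e31[1])
  expect_equal(b2$e_r, nr / sqrt(sum(nr^2)))
  ezr <- axis - sum(axis * b2$e_r) * b2$e_r
  expect_equal(b2$e_z, ezr / sqrt(sum(ezr^2)))
  expect_error(elementBasis(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                            c(0, 0, 0), c(0, 0, 1)), "degenerate")
  expect_error(elementBasis(tri, c(0, 0, 0), b2$e_r), "parallel")
})

test_that("deformation gradient maps edges and unit normals", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0))
  expect_equal(deformationGradient(tri, tri), diag(3), tolerance = 1e-12)
  # in-plane scaling of a planar triangle: singular values (1.2, 1.2, 1)
  def <- tri * 1.2
  F1 <- deformationGradient(tri, def)
  expect_equal(sort(svd(F1)$d), c(1, 1.2, 1.2), tolerance = 1e-10)
  # random pair: F e21 = e21', F e31 = e31'
  withr::with_seed(52, {
    r <- matrix(rnorm(9), 3, 3)
    s <- matrix(rnorm(9), 3, 3)
  })
  F2 <- deformationGradient(r, s)
  expect_equal(drop(F2 %*% (r[2, ] - r[1, ])), s[2, ] - s[1, ],
               tolerance = 1e-10)
  expect_equal(drop(F2 %*% (r[3, ] - r[1, ])), s[3, ] - s[1, ],
               tolerance = 1e-10)
  expect_error(deformationGradient(rbind(c(0, 0, 0), c(1, 0, 0),
                                         c(2, 0, 0)), tri), "degenerate")
})

test_that("Green-Lagrange strain is zero for rigid motion and diagonal for stretches", {
  expect_equal(greenLagrange(diag(3)), matrix(0, 3, 3))
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(greenLagrange(R), matrix(0, 3, 3), tolerance = 1e-15)
  E <- greenLagrange(diag(c(1.2, 0.9, 1)))
  expect_equal(diag(E), c(0.22, -0.095, 0))
})

test_that("strain rotation extracts circumferential/longitudinal components", {
  basis <- list(e_r = c(1, 0, 0), e_theta = c(0, 1, 0), e_z = c(0, 0, 1))
  E <- diag(c(0.1, -0.18, -0.05))
  rs <- rotateStrain(E, basis)
  expect_equal(rs$E_cc, -0.18)
  expect_equal(rs$E_zz, -0.05)
  # trace is a similarity invariant for any orthonormal Q
  withr::with_seed(53, {
    tri <- matrix(rnorm(9), 3, 3)
    ax <- rnorm(3)
    Esym <- crossprod(matrix(rnorm(9), 3, 3))
  })
  b <- elementBasis(tri, c(0, 0, 0), ax)
  expect_equal(sum(diag(rotateStrain(Esym, b)$E_e)), sum(diag(Esym)),
               tolerance = 1e-12)
  bad <- basis; bad$e_theta <- c(0, 2, 0)
  expect_error(rotateStrain(E, bad), "orthonormal")
})

test_that("area change and SQUEEZ follow the in-plane determinant", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(unname(areaChange(tri, tri)), c(1, 1))
  expect_equal(unname(areaChange(tri, tri * 0.8)), c(0.64, 0.8))
  # random in-plane affine map: ratio equals |det| of the 2D map
  withr::with_seed(54, A <- matrix(rnorm(4), 2, 2))
  def <- cbind(tri[, 1:2] %*% t(A), 0)
  expect_equal(unname(areaChange(tri, def)["area_ratio"]), abs(det(A)),
               tolerance = 1e-12)
  expect_error(areaChange(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), tri),
               "zero")
})

test_that("exact analytic deformation reproduces closed-form strains everywhere", {
  spec <- phantomSpec()      # lambda_c* = 0.8, lambda_l* = 0.88
  tube <- ahaLabel(phantomTubeMesh(spec), phantomTubeLandmarks(spec))
  lms <- landmarkPoints(phantomTubeLandmarks(spec))
  apex <- lms["apex", ]
  base <- colMeans(lms[c("mv_1", "mv_2", "mv_3"), ])
  for (t in c(2, 5)) {
    def <- SurfaceMesh(analyticDeformation(meshVertices(tube), t, spec),
                       meshTriangles(tube))
    es <- meshStrain(tube, def, apex, base)
    truth <- analyticStrain(spec, t)
    expect_lt(max(abs(es$E_cc - truth["E_cc"])), 1e-6)
    expect_lt(max(abs(es$E_zz - truth["E_zz"])), 1e-6)
    expect_lt(max(abs(es$area_ratio - truth["area_ratio"])), 1e-6)
    # the radial strain components vanish by construction
    expect_lt(max(abs(c(es$E_rr, es$E_rc, es$E_rl))), 1e-10)
  }
})

test_that("rigid motions of arbitrary meshes produce zero strain", {
  spec <- smallSpec()
  tube <- phantomTubeMesh(spec, nTheta = 16L, nZ = 8L)
  lms <- landmarkPoints(phantomTubeLandmarks(spec))
  for (seedling in 1:20) {
    rig <- randomRigid(seedling)
    es <- meshStrain(tube, rigidMesh(tube, rig), lms["apex", ],
                     colMeans(lms[c("mv_1", "mv_2", "mv_3"), ]))
    expect_lt(max(abs(c(es$E_cc, es$E_zz))), 1e-9)
    expect_lt(max(abs(es$area_ratio - 1)), 1e-9)
  }
})

test_that("AHA labelling covers 1..16 and respects the septal anchor", {
  spec <- phantomSpec()
  tube <- phantomTubeMesh(spec)
  lms <- phantomTubeLandmarks(spec)
  lab <- ahaLabels(ahaLabel(tube, lms))
  expect_true(all(lab %in% 1:16))
  expect_setequal(unique(lab), 1:16)
  # rotating the septal landmarks by 60 degrees about the long axis
  # permutes the basal and mid ring labels cyclically
  pts <- landmarkPoints(lms)
  ctr <- phantomCentre(spec)
  rot60 <- function(p) {
    rel <- p - ctr
    th <- pi / 3
    ctr + c(cos(th) * rel[1] - sin(th) * rel[2],
            sin(th) * rel[1] + cos(th) * rel[2], rel[3])
  }
  pts2 <- pts
  pts2["septum_1", ] <- rot60(pts["septum_1", ])
  pts2["septum_2", ] <- rot60(pts["septum_2", ])
  lab2 <- ahaLabels(ahaLabel(tube, LandmarkSet(pts2)))
  basal <- lab <= 6
  shift <- unique((lab2[basal] - lab[basal]) %% 6)
  expect_length(shift, 1)            # a single cyclic shift of one sector
  expect_true(shift %in% c(1, 5))
  mid <- lab >= 7 & lab <= 12
  expect_equal(unique((lab2[mid] - lab[mid]) %% 6), shift)
  expect_true(all(lab2[mid] %in% 7:12))
  # axisymmetric mesh: basal sector element counts agree within 10%
  cnt <- table(lab[basal])
  expect_lt(diff(range(cnt)) / mean(cnt), 0.1)
  bad <- LandmarkSet(pts[c("apex", "mv_1"), ])
  expect_error(ahaLabel(tube, bad), "missing landmark")
})

test_that("regional curves are exact for identity and analytic motion", {
  spec <- phantomSpec()
  tube <- ahaLabel(phantomTubeMesh(spec), phantomTubeLandmarks(spec))
  lms <- phantomTubeLandmarks(spec)
  # identity motion: all curves constant at (0, 0, 1)
  meshes <- rep(list(tube), 3)
  cs <- regionalCurves(meshes, lms)
  cv <- curveTable(cs)
  expect_equal(cv$value[cv$metric == "E_cc"], rep(0, 48))
  expect_equal(cv$value[cv$metric == "area_ratio"], rep(1, 48))
  # analytic deformation: every segment hits the closed-form peak
  meshes <- lapply(0:(spec@nFrames - 1), function(t)
    SurfaceMesh(analyticDeformation(meshVertices(tube), t, spec),
                meshTriangles(tube), ahaLabels(tube)))
  cs2 <- regionalCurves(meshes, lms)
  cv2 <- curveTable(cs2)
  pk <- cv2[cv2$frame == 5 & cv2$metric == "E_cc", ]
  expect_equal(pk$value, rep(-0.18, 16), tolerance = 1e-6)
  # mean of segment area ratios tracks the total area ratio
  ar <- cv2[cv2$frame == 5 & cv2$metric == "area_ratio", ]
  total <- meshArea(meshes[[6]]) / meshArea(tube)
  expect_lt(abs(mean(ar$value) - total), 0.01)
  # element count and labels invariant across frames
  expect_identical(ahaLabels(meshes[[6]]), ahaLabels(tube))
})
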