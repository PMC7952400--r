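test_that("annulus midpoint is the centroid and respects rigid motion", {
  pts <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0))
  expect_equal(annulusMidpoint(pts), c(1, 1, 0))
  expect_equal(annulusMidpoint(pts + 5), c(6, 6, 5))
  expect_error(annulusMidpoint(pts[1:2, ]), "3 annulus")
})

test_that("measurements compute distances, perimeter and projected area", {
  sq <- rbind(annulus_1 = c(0, 0, 0), annulus_2 = c(1, 0, 0),
              annulus_3 = c(1, 1, 0), annulus_4 = c(0, 1, 0),
              trigone_1 = c(0, 0, 0), trigone_2 = c(25, 0, 0),
              posterior_1 = c(0, 0, 0), posterior_2 = c(3, 4, 0),
              posterior_3 = c(3, 4, 12))
  m <- computeMeasurements(LandmarkSet(sq))
  expect_equal(unname(m["trigone_to_trigone"]), 25)
  expect_equal(unname(m["mitral_annulus_area"]), 1)
  expect_equal(unname(m["posterior_perimeter"]), 5 + 12)
  expect_true(is.na(m["intercommissural"]))   # missing points flagged NA
  expect_named(m, measurementNames())
})

test_that("measurements are rigid-motion invariant", {
  lms <- phantomLandmarks(phantomSpec())
  m0 <- computeMeasurements(lms)
  rig <- randomRigid(7)
  moved <- LandmarkSet(landmarkPoints(lms) %*% t(rig$R) +
                         matrix(rig$t, nrow(landmarkPoints(lms)), 3,
                                byrow = TRUE))
  m1 <- computeMeasurements(moved)
  expect_equal(m1, m0, tolerance = 1e-9)
})

test_that("phantom measurements scale with the prescribed stretch", {
  spec <- phantomSpec()
  lms <- phantomLandmarks(spec)
  m0 <- computeMeasurements(lms)
  t <- 5L   # peak: lambda_c = 0.8, lambda_l = 0.88
  mt <- computeMeasurements(LandmarkSet(
    analyticDeformation(landmarkPoints(lms), t, spec)))
  # purely in-plane distances scale by lambda_c
  expect_equal(unname(mt["trigone_to_trigone"] / m0["trigone_to_trigone"]),
               0.8, tolerance = 1e-9)
  expect_equal(unname(mt["intercommissural"] / m0["intercommissural"]),
               0.8, tolerance = 1e-9)
  # the annulus plane is normal to the long axis: area scales by lambda_c^2
  expect_equal(unname(mt["mitral_annulus_area"] / m0["mitral_annulus_area"]),
               0.64, tolerance = 1e-9)
})

test_that("tracking cost follows the stated arithmetic", {
  perfect <- trackingCost(list(c(a = 10, b = 20)), list(c(a = 10, b = 20)))
  expect_equal(perfect$J, 0)
  one <- trackingCost(rbind(11), rbind(10))
  expect_equal(one$J, 0.01, tolerance = 1e-12)
  # m = 2 measurements, t = 2 frames, relative errors 0.1, 0.2, 0, 0.1
  est <- rbind(c(1.1, 2.4), c(3.0, 4.4))
  obs <- rbind(c(1.0, 2.0), c(3.0, 4.0))
  got <- trackingCost(est, obs)
  expect_equal(got$J, (0.01 + 0.04 + 0 + 0.01) / 4)
  expect_equal(got$mean_abs_pct, 100 * (0.1 + 0.2 + 0 + 0.1) / 4)
  # observed zeros are excluded and counted
  gz <- trackingCost(rbind(c(1, 2)), rbind(c(0, 2)))
  expect_equal(gz$n_excluded, 1L)
  expect_equal(gz$n, 1L)
})

test_that("grid search enumerates every permutation deterministically", {
  # cheap synthetic engine: error surface is a known function of the hypers
  engine <- function(hyper, set) {
    scale <- 1 + 0.1 * (hyper[[1]] - 0.3)^2 + 0.05 * (hyper[[2]] - 0.7)^2
    lapply(set$observed, function(v) v * scale)
  }
  set <- list(observed = list(c(a = 10, b = 20), c(a = 11, b = 19)))
  g <- list(theta0 = gridSpec(0, 1, 0.1), theta1 = gridSpec(0, 1, 0.1))
  res <- gridSearch(list(set), g, engine)
  expect_equal(res$n_evaluated, 121L)
  expect_equal(nrow(res$surface), 121L)
  expect_equal(res$best$theta0, 0.3)
  expect_equal(res$best$theta1, 0.7)
  # refined search: 2 bending values x 101 sparsity values
  g2 <- list(theta0 = c(1e-6, 1e-5), theta1 = gridSpec(0, 1, 0.01))
  res2 <- gridSearch(list(set), g2, engine)
  expect_equal(res2$n_evaluated, 202L)
  # constant surface: tie resolves to the first enumerated point
  flat <- gridSearch(list(set), g2, function(hyper, set) set$observed)
  expect_equal(unlist(flat$best), c(theta0 = 1e-6, theta1 = 0))
  # engine failures are recorded, not fatal
  bomb <- gridSearch(list(set), list(a = c(0, 1)),
                     function(hyper, set) if (hyper$a > 0.5)
                       stop("boom") else set$observed)
  expect_equal(sum(is.na(bomb$surface$error_pct)), 1L)
})

test_that("agreement statistics reproduce the product-moment formula", {
  manual <- c(10, 12, 15, 18, 21, 24)
  auto <- manual
  # perfect fits are intentional here; lm warns about them
  s <- suppressWarnings(agreementStats(manual, auto))
  expect_equal(s$r, 1)
  expect_equal(s$r_squared, 1)
  aff <- suppressWarnings(agreementStats(manual, 2 * manual + 3))
  expect_equal(aff$r, 1)
  expect_equal(aff$r_squared, 1)
  expect_lt(aff$p_value, 0.05)   # the t-test detects the mean shift
  # hand-computed r on a small fixed table
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(agreementStats(x, y)$r, num / den)
  expect_warning(agreementStats(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})
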