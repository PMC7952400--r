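#' Deforming-ventricle phantom
#'
#' The phantom emulates a contrast-filled left ventricle in gated CT: a
#' bright prolate-spheroid blood pool inside a myocardial shell on an air
#' background, deforming through the cycle by a smooth, cyclic, axis-aligned
#' stretch about the cavity centre. Because the deformation is a closed form,
#' every downstream stage (segmentation, registration, mesh deformation,
#' strain) can be checked against exact ground truth.
#'
#' The stretch profile is \eqn{\lambda(t) = 1 + (\lambda^* - 1)
#' \sin^2(\pi t / n)} for frame \eqn{t} of \eqn{n}: identity at frame 0,
#' peak contraction at mid cycle, cyclic and C1 in time, matching a
#' retrospectively gated acquisition where frame 0 is the R-wave.
#'
#' @name phantom
NULL

## stretch factors at frame t (0-based)
phantomLambda <- function(spec, t) {
  s <- sin(pi * t / spec@nFrames)^2
  c(lambdaC = 1 + (spec@lambdaC - 1) * s,
    lambdaL = 1 + (spec@lambdaL - 1) * s)
}

#' Centre of the phantom cavity in world mm
#' @param spec a \linkS4class{PhantomSpec}.
#' @return numeric(3).
#' @export
phantomCentre <- function(spec) {
  (spec@gridShape - 1) * spec@voxelSize / 2
}

#' Analytic phantom deformation
#'
#' Maps reference world coordinates to their position at frame \code{t}:
#' \code{diag(lc, lc, ll) \%*\% (p - centre) + centre} with the time-varying
#' stretches of the phantom. Frame 0 is the identity.
#'
#' @param points n x 3 matrix of reference mm coordinates (inside the image).
#' @param t frame index, 0-based, in [0, nFrames).
#' @param spec a \linkS4class{PhantomSpec}.
#' @return n x 3 matrix of deformed mm coordinates.
#' @export
analyticDeformation <- function(points, t, spec) {
  stopifnot(is(spec, "PhantomSpec"))
  if (t < 0 || t >= spec@nFrames)
    stop("frame index out of range [0, nFrames)")
  points <- rbind(points)
  half <- (spec@gridShape - 1) * spec@voxelSize
  if (any(points < -1e-9) || any(sweep(points, 2, half, ">")))
    stop("point outside image bounds")
  lam <- phantomLambda(spec, t)
  ctr <- phantomCentre(spec)
  rel <- sweep(points, 2, ctr, "-")
  rel <- sweep(rel, 2, c(lam[1], lam[1], lam[2]), "*")
  sweep(rel, 2, ctr, "+")
}

#' Closed-form phantom strains
#'
#' Green-Lagrange strains and area ratio at frame \code{t} for wall elements
#' whose circumferential / longitudinal basis vectors align with the stretch
#' axes: \eqn{E_{\theta\theta} = (\lambda_c^2 - 1)/2},
#' \eqn{E_{zz} = (\lambda_l^2 - 1)/2}, area ratio
#' \eqn{\lambda_c \lambda_l}.
#'
#' @inheritParams analyticDeformation
#' @return named numeric: \code{E_cc}, \code{E_zz}, \code{area_ratio}.
#' @export
analyticStrain <- function(spec, t) {
  if (t < 0 || t >= spec@nFrames)
    stop("frame index out of range [0, nFrames)")
  lam <- phantomLambda(spec, t)
  c(E_cc = unname((lam[1]^2 - 1) / 2),
    E_zz = unname((lam[2]^2 - 1) / 2),
    area_ratio = unname(lam[1] * lam[2]))
}

## noiseless HU image of frame t: voxel centres pulled back through the
## inverse stretch and classified as cavity / wall / background
phantomFrameClean <- function(spec, t) {
  n <- spec@gridShape
  vs <- spec@voxelSize
  ctr <- phantomCentre(spec)
  lam <- phantomLambda(spec, t)
  x <- ((seq_len(n[1]) - 1) * vs - ctr[1]) / lam[1]
  y <- ((seq_len(n[2]) - 1) * vs - ctr[2]) / lam[1]
  z <- ((seq_len(n[3]) - 1) * vs - ctr[3]) / lam[2]
  r2in <- outer(outer(x^2 / spec@aShort^2, y^2 / spec@aShort^2, "+"),
                z^2 / spec@aLong^2, "+")
  r2out <- outer(outer(x^2 / (spec@aShort + spec@wall)^2,
                       y^2 / (spec@aShort + spec@wall)^2, "+"),
                 z^2 / (spec@aLong + spec@wall)^2, "+")
  img <- array(spec@backgroundHu, dim = n)
  img[r2out <= 1] <- spec@myoHu
  img[r2in <= 1] <- spec@bloodHu
  img
}

#' Generate a phantom 4D image sequence with ground truth
#'
#' Voxelises the phantom at every frame (frame 0 is the reference) and adds
#' seeded i.i.d. Gaussian noise. The ground-truth component carries the
#' analytic deformation, per-frame landmark trajectories, and closed-form
#' strains.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{frames} (list of
#'   \linkS4class{ImageVolume}) and \code{truth} (list with \code{spec},
#'   \code{landmarks} -- a per-frame list of \linkS4class{LandmarkSet} --
#'   and \code{strain}, a data.frame of per-frame analytic strains).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  frames <- vector("list", spec@nFrames)
  for (t in seq_len(spec@nFrames) - 1L) {
    img <- phantomFrameClean(spec, t)
    if (spec@noiseSd > 0) {
      img <- withr::with_seed(spec@seed + t, {
        img + array(rnorm(length(img), 0, spec@noiseSd), dim = dim(img))
      })
    }
    frames[[t + 1L]] <- ImageVolume(img, spacing = spec@voxelSize,
                                    origin = c(0, 0, 0), frame = t)
  }
  lm0 <- phantomLandmarks(spec)
  lms <- lapply(seq_len(spec@nFrames) - 1L, function(t) {
    LandmarkSet(analyticDeformation(landmarkPoints(lm0), t, spec), frame = t)
  })
  strain <- do.call(rbind, lapply(seq_len(spec@nFrames) - 1L, function(t) {
    data.frame(frame = t, as.list(analyticStrain(spec, t)))
  }))
  list(frames = frames,
       truth = list(spec = spec, landmarks = lms, strain = strain))
}

#' Reference landmarks and measurement annotations for the phantom
#'
#' Returns the six anatomical landmarks (\code{apex}, \code{mv_1..3},
#' \code{septum_1..2}) plus the annotation points needed by
#' \code{\link{computeMeasurements}}: an ordered mitral-annulus ring
#' (\code{annulus_1..8}), trigones, commissures, horns, papillary heads,
#' endo/epicardial apex and a left-atrial posterior wall point. All points
#' lie on or inside the phantom geometry at frame 0.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{LandmarkSet} for frame 0.
#' @export
phantomLandmarks <- function(spec) {
  ctr <- phantomCentre(spec)
  a <- spec@aShort
  b <- spec@aLong
  zb <- 0.85 * b                       # annulus height above centre
  rho <- a * sqrt(1 - (zb / b)^2)      # cavity radius at the annulus plane
  ring <- function(angle_deg, r, z) {
    th <- angle_deg * pi / 180
    if (length(th) == 1L)
      c(ctr[1] + r * cos(th), ctr[2] + r * sin(th), ctr[3] + z)
    else
      cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th), ctr[3] + z)
  }
  ann <- ring(seq(0, 315, by = 45), rho, zb)
  rownames(ann) <- paste0("annulus_", 1:8)
  pts <- rbind(
    ann,
    apex      = ctr + c(0, 0, -b),
    mv_1      = ring(0, rho, zb),
    mv_2      = ring(120, rho, zb),
    mv_3      = ring(240, rho, zb),
    septum_1  = ring(150, a, 0),
    septum_2  = ring(210, a, 0),
    trigone_1 = ring(45, rho, zb),
    trigone_2 = ring(315, rho, zb),
    comm_1    = ring(90, rho, zb),
    comm_2    = ring(270, rho, zb),
    horn_ant  = ring(0, rho, zb),
    horn_post = ring(180, rho, zb),
    pm_al     = ring(60, 0.5 * a, -0.3 * b),
    pm_pm     = ring(200, 0.5 * a, -0.3 * b),
    apex_endo = ctr + c(0, 0, -b),
    apex_epi  = ctr + c(0, 0, -(b + spec@wall)),
    la_post   = ctr + c(0, 0.4 * a,
                        min(b + spec@wall + 2,
                            (spec@gridShape[3] - 1) * spec@voxelSize / 2 - 1))
  )
  # posterior perimeter: ordered arc on the posterior half of the annulus
  post <- ring(seq(135, 225, by = 45), rho, zb)
  rownames(post) <- paste0("posterior_", 1:3)
  LandmarkSet(rbind(pts, post), frame = 0L)
}

#' Idealised cylindrical verification mesh
#'
#' An open cylindrical shell (axis along z) triangulated with
#' counter-clockwise elements whose outward normals are radial. Under the
#' phantom's axis-aligned stretch, every element of this surface has its
#' circumferential basis vector perpendicular to the long axis and its
#' longitudinal basis vector along it, so the closed-form strains of
#' \code{\link{analyticStrain}} hold exactly for every element -- the
#' idealised configuration used to verify the strain tensors.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param nTheta circumferential resolution.
#' @param nZ longitudinal resolution.
#' @return A \linkS4class{SurfaceMesh} (open tube).
#' @export
phantomTubeMesh <- function(spec, nTheta = 48L, nZ = 32L) {
  ctr <- phantomCentre(spec)
  r <- spec@aShort
  zlo <- -0.75 * spec@aLong
  zhi <- 0.75 * spec@aLong
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  z <- seq(zlo, zhi, length.out = nZ)
  vid <- function(it, iz) (iz - 1L) * nTheta + ((it - 1L) %% nTheta) + 1L
  verts <- cbind(ctr[1] + r * cos(rep(th, nZ)),
                 ctr[2] + r * sin(rep(th, nZ)),
                 ctr[3] + rep(z, each = nTheta))
  tris <- matrix(0L, 2L * nTheta * (nZ - 1L), 3L)
  k <- 0L
  for (iz in seq_len(nZ - 1L)) {
    for (it in seq_len(nTheta)) {
      v00 <- vid(it, iz); v10 <- vid(it + 1L, iz)
      v01 <- vid(it, iz + 1L); v11 <- vid(it + 1L, iz + 1L)
      tris[k + 1L, ] <- c(v00, v10, v11)
      tris[k + 2L, ] <- c(v00, v11, v01)
      k <- k + 2L
    }
  }
  SurfaceMesh(verts, tris)
}

#' Landmarks consistent with the tube mesh
#'
#' Apex on the axis at the bottom of the tube and a mitral ring at the top,
#' so the AHA longitudinal coordinate spans exactly [0, 1] over the tube.
#'
#' @inheritParams phantomTubeMesh
#' @return A \linkS4class{LandmarkSet}.
#' @export
phantomTubeLandmarks <- function(spec) {
  ctr <- phantomCentre(spec)
  r <- spec@aShort
  zlo <- -0.75 * spec@aLong
  zhi <- 0.75 * spec@aLong
  ring <- function(angle_deg, z) {
    th <- angle_deg * pi / 180
    c(ctr[1] + r * cos(th), ctr[2] + r * sin(th), ctr[3] + z)
  }
  pts <- rbind(apex = ctr + c(0, 0, zlo),
               mv_1 = ring(0, zhi), mv_2 = ring(120, zhi),
               mv_3 = ring(240, zhi),
               septum_1 = ring(150, 0), septum_2 = ring(210, 0))
  LandmarkSet(pts, frame = 0L)
}

#' Simulate per-segment strain curve sets
#'
#' Generates a subject-level \linkS4class{StrainCurveSet} from the phantom's
#' smooth temporal profile with optional per-segment timing offsets and
#' amplitude variability -- synchronous offsets emulate a healthy subject,
#' large timing spread a dyssynchronous one. Used by the group-comparison
#' and frame-rate analyses.
#'
#' @param nFrames frames per cycle.
#' @param peakEcc,peakEzz peak circumferential / longitudinal strains.
#' @param phaseSd sd of per-segment timing offsets (cycle fraction).
#' @param ampSd relative sd of per-segment amplitude.
#' @param noiseSd additive sd on curve samples.
#' @param seed RNG seed.
#' @return A \linkS4class{StrainCurveSet}.
#' @export
simulateStrainCurves <- function(nFrames = 10L, peakEcc = -0.18,
                                 peakEzz = -0.11, phaseSd = 0,
                                 ampSd = 0.05, noiseSd = 0, seed = 1L) {
  withr::with_seed(seed, {
    segs <- 1:16
    phase <- rnorm(16, 0, phaseSd)
    amp <- 1 + rnorm(16, 0, ampSd)
    u <- (seq_len(nFrames) - 1) / nFrames
    rows <- list()
    for (s in segs) {
      prof <- sin(pi * pmin(pmax(u - phase[s], 0), 1))^2
      for (m in c("E_cc", "E_zz", "area_ratio")) {
        peak <- switch(m, E_cc = peakEcc, E_zz = peakEzz,
                       area_ratio = NA_real_)
        if (m == "area_ratio") {
          lc <- sqrt(pmax(2 * peakEcc * amp[s] * prof + 1, 0))
          ll <- sqrt(pmax(2 * peakEzz * amp[s] * prof + 1, 0))
          val <- lc * ll
        } else {
          val <- peak * amp[s] * prof
        }
        val <- val + rnorm(nFrames, 0, noiseSd)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = seq_len(nFrames) - 1L, time = u, segment = s,
          metric = m, value = val)
      }
    }
    new("StrainCurveSet", curves = do.call(rbind, rows),
        nFrames = as.integer(nFrames))
  })
}
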