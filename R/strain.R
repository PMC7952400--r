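#' Element coordinate system for a triangle
#'
#' Defines the per-element cylindrical basis used for strain rotation:
#' \eqn{e_r} is the unit normal of the counter-clockwise reference triangle,
#' \eqn{e_z} the unit projection of the LV long axis (base minus apex)
#' orthogonal to \eqn{e_r}, and \eqn{e_\theta = e_z \times e_r}. The triad
#' is orthonormal and right-handed, and is computed once on the reference
#' configuration (the same basis is reused for every frame).
#'
#' @param triangle 3 x 3 matrix (rows = vertices, counter-clockwise).
#' @param apex,base mm points defining the long axis (apical and basal).
#' @return list with unit vectors \code{e_r}, \code{e_theta}, \code{e_z}.
#' @export
elementBasis <- function(triangle, apex, base) {
  e21 <- triangle[2, ] - triangle[1, ]
  e31 <- triangle[3, ] - triangle[1, ]
  nr <- cross3(e21, e31)
  nn <- sqrt(sum(nr^2))
  if (nn < 1e-12) stop("degenerate triangle")
  er <- nr / nn
  vab <- base - apex
  ezr <- vab - sum(vab * er) * er
  nz <- sqrt(sum(ezr^2))
  if (nz < 1e-12) stop("long axis parallel to element normal")
  ez <- ezr / nz
  eth <- cross3(ez, er)
  list(e_r = er, e_theta = eth, e_z = ez)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Deformation gradient of a triangle pair
#'
#' The surface deformation gradient F maps reference edge vectors to
#' deformed edge vectors and the reference unit normal to the deformed unit
#' normal (no stretch along the normal):
#' \deqn{F = [e'_{21}\ e'_{31}\ n']\,[e_{21}\ e_{31}\ n]^{-1}.}
#' The unit-normal convention is what makes the rotated radial strain
#' components vanish identically.
#'
#' @param refTriangle,defTriangle 3 x 3 matrices (rows = corresponding
#'   vertices).
#' @return 3 x 3 deformation gradient.
#' @export
deformationGradient <- function(refTriangle, defTriangle) {
  a <- refTriangle[2, ] - refTriangle[1, ]
  b <- refTriangle[3, ] - refTriangle[1, ]
  n <- cross3(a, b)
  if (sqrt(sum(n^2)) < 1e-12) stop("degenerate reference triangle")
  n <- n / sqrt(sum(n^2))
  a2 <- defTriangle[2, ] - defTriangle[1, ]
  b2 <- defTriangle[3, ] - defTriangle[1, ]
  n2 <- cross3(a2, b2)
  if (sqrt(sum(n2^2)) < 1e-12) stop("degenerate deformed triangle")
  n2 <- n2 / sqrt(sum(n2^2))
  M <- cbind(a, b, n)
  if (abs(det(M)) < 1e-12) stop("singular edge matrix")
  cbind(a2, b2, n2) %*% solve(M)
}

#' Green-Lagrange strain tensor
#'
#' \eqn{E = (F^T F - I)/2}; zero for any rigid motion.
#'
#' @param F 3 x 3 deformation gradient.
#' @return symmetric 3 x 3 strain tensor.
#' @export
greenLagrange <- function(F) {
  (t(F) %*% F - diag(3)) / 2
}

#' Rotate a strain tensor into the element frame
#'
#' \eqn{E_e = Q E Q^T} with Q rows \eqn{(e_r, e_\theta, e_z)}. Returns the
#' element-frame tensor and its circumferential and longitudinal diagonal
#' entries. With the unit-normal deformation-gradient convention the radial
#' row and column of \eqn{E_e} vanish.
#'
#' @param E 3 x 3 Green-Lagrange tensor (global frame).
#' @param basis an element basis from \code{\link{elementBasis}}.
#' @return list: \code{E_e}, \code{E_cc}, \code{E_zz}.
#' @export
rotateStrain <- function(E, basis) {
  Q <- rbind(basis$e_r, basis$e_theta, basis$e_z)
  if (max(abs(Q %*% t(Q) - diag(3))) > 1e-8)
    stop("basis is not orthonormal")
  Ee <- Q %*% E %*% t(Q)
  list(E_e = Ee, E_cc = Ee[2, 2], E_zz = Ee[3, 3])
}

#' Local area change and SQUEEZ of a triangle pair
#'
#' Area ratio \eqn{A_{def}/A_{ref}} and its square root (the SQUEEZ
#' measure of regional endocardial deformation).
#'
#' @inheritParams deformationGradient
#' @return named numeric: \code{area_ratio}, \code{squeez}.
#' @export
areaChange <- function(refTriangle, defTriangle) {
  aRef <- sqrt(sum(cross3(refTriangle[2, ] - refTriangle[1, ],
                          refTriangle[3, ] - refTriangle[1, ])^2)) / 2
  if (aRef < 1e-12) stop("zero reference area")
  aDef <- sqrt(sum(cross3(defTriangle[2, ] - defTriangle[1, ],
                          defTriangle[3, ] - defTriangle[1, ])^2)) / 2
  c(area_ratio = aDef / aRef, squeez = sqrt(aDef / aRef))
}

#' Per-element strains for a whole mesh pair
#'
#' Vectorised computation of the deformation gradient, Green-Lagrange
#' tensor, element-frame circumferential/longitudinal strains, radial
#' residuals, and area change for every triangle of a reference/deformed
#' mesh pair sharing connectivity.
#'
#' @param refMesh,defMesh \linkS4class{SurfaceMesh}es with identical
#'   connectivity.
#' @param apex,base mm points defining the LV long axis on the reference.
#' @return data.frame with one row per element: \code{E_cc}, \code{E_zz},
#'   \code{area_ratio}, \code{squeez}, and the radial components
#'   \code{E_rr}, \code{E_rc}, \code{E_rl}.
#' @export
meshStrain <- function(refMesh, defMesh, apex, base) {
  f <- meshTriangles(refMesh)
  stopifnot(all(f == meshTriangles(defMesh)))
  v <- meshVertices(refMesh)
  w <- meshVertices(defMesh)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nr <- rowCross(a, b)
  nn <- sqrt(rowSums(nr^2))
  if (any(nn < 1e-12)) stop("degenerate reference triangle")
  n <- nr / nn
  a2 <- w[f[, 2], , drop = FALSE] - w[f[, 1], , drop = FALSE]
  b2 <- w[f[, 3], , drop = FALSE] - w[f[, 1], , drop = FALSE]
  nr2 <- rowCross(a2, b2)
  nn2 <- sqrt(rowSums(nr2^2))
  n2 <- nr2 / pmax(nn2, 1e-300)
  # inverse of M = [a b n] via adjugate rows
  det <- rowSums(a * rowCross(b, n))
  r1 <- rowCross(b, n) / det
  r2 <- rowCross(n, a) / det
  r3 <- rowCross(a, b) / det
  # F[i,j] = a2_i r1_j + b2_i r2_j + n2_i r3_j
  Fm <- vector("list", 3)
  for (i in 1:3)
    Fm[[i]] <- cbind(a2[, i] * r1[, 1] + b2[, i] * r2[, 1] + n2[, i] * r3[, 1],
                     a2[, i] * r1[, 2] + b2[, i] * r2[, 2] + n2[, i] * r3[, 2],
                     a2[, i] * r1[, 3] + b2[, i] * r2[, 3] + n2[, i] * r3[, 3])
  # E = (F^T F - I)/2, symmetric
  Em <- array(0, dim = c(nrow(f), 3, 3))
  for (j in 1:3)
    for (k in j:3) {
      cjk <- Fm[[1]][, j] * Fm[[1]][, k] + Fm[[2]][, j] * Fm[[2]][, k] +
        Fm[[3]][, j] * Fm[[3]][, k]
      Em[, j, k] <- Em[, k, j] <- (cjk - (j == k)) / 2
    }
  basis <- meshElementBasis(refMesh, apex, base)
  quad <- function(d1, d2) {
    s <- 0
    for (j in 1:3)
      for (k in 1:3) s <- s + d1[, j] * Em[, j, k] * d2[, k]
    s
  }
  ratio <- nn2 / nn
  data.frame(
    element = seq_len(nrow(f)),
    E_cc = quad(basis$e_theta, basis$e_theta),
    E_zz = quad(basis$e_z, basis$e_z),
    area_ratio = ratio,
    squeez = sqrt(ratio),
    E_rr = quad(basis$e_r, basis$e_r),
    E_rc = quad(basis$e_r, basis$e_theta),
    E_rl = quad(basis$e_r, basis$e_z))
}

#' Element bases for every triangle of a mesh
#'
#' @inheritParams meshStrain
#' @return list of m x 3 matrices \code{e_r}, \code{e_theta}, \code{e_z}.
#' @export
meshElementBasis <- function(refMesh, apex, base) {
  v <- meshVertices(refMesh)
  f <- meshTriangles(refMesh)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nr <- rowCross(a, b)
  er <- nr / sqrt(rowSums(nr^2))
  vab <- matrix(base - apex, nrow(f), 3, byrow = TRUE)
  ezr <- vab - rowSums(vab * er) * er
  nz <- sqrt(rowSums(ezr^2))
  if (any(nz < 1e-12)) stop("long axis parallel to an element normal")
  ez <- ezr / nz
  list(e_r = er, e_theta = rowCross(ez, er), e_z = ez)
}

#' Label mesh triangles with AHA 16 segments
#'
#' The long axis runs from the apex landmark to the centroid of the three
#' mitral-valve landmarks. Each triangle centroid gets a longitudinal
#' coordinate s in [0,1] (0 apex, 1 base) and a circumferential angle
#' measured from the mean septal direction, counted counter-clockwise
#' viewed from the base. Thirds of s give the apical/mid/basal rings; the
#' basal and mid rings are split into six 60-degree sectors (segments 1-6
#' and 7-12), the apical ring into four 90-degree sectors (13-16). The
#' apical-cap segment 17 is not used.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param landmarks a \linkS4class{LandmarkSet} containing \code{apex},
#'   \code{mv_1..3} and \code{septum_1..2}.
#' @return The mesh with per-triangle labels attached (see
#'   \code{\link{ahaLabels}}).
#' @export
ahaLabel <- function(mesh, landmarks) {
  pts <- landmarkPoints(landmarks)
  need <- c("apex", "mv_1", "mv_2", "mv_3", "septum_1", "septum_2")
  if (!all(need %in% rownames(pts)))
    stop("missing landmark(s): ",
         paste(setdiff(need, rownames(pts)), collapse = ", "))
  apex <- pts["apex", ]
  base <- colMeans(pts[c("mv_1", "mv_2", "mv_3"), ])
  axis <- base - apex
  L <- sqrt(sum(axis^2))
  axis <- axis / L
  v <- meshVertices(mesh); f <- meshTriangles(mesh)
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  rel <- sweep(cen, 2, apex, "-")
  s <- pmin(pmax(rel %*% axis / L, 0), 1)
  # septal anchor direction, orthogonal to the axis
  sep <- colMeans(pts[c("septum_1", "septum_2"), ]) - apex
  d0 <- sep - sum(sep * axis) * axis
  d0 <- d0 / sqrt(sum(d0^2))
  d90 <- cross3(axis, d0)
  proj <- rel - (rel %*% axis) %*% t(axis)
  ang <- atan2(proj %*% d90, proj %*% d0) %% (2 * pi)
  ring <- findInterval(s, c(1 / 3, 2 / 3))  # 0 apical, 1 mid, 2 basal
  lab <- integer(nrow(f))
  sec6 <- pmin(floor(ang / (pi / 3)), 5)
  sec4 <- pmin(floor(ang / (pi / 2)), 3)
  lab[ring == 2] <- 1L + sec6[ring == 2]
  lab[ring == 1] <- 7L + sec6[ring == 1]
  lab[ring == 0] <- 13L + sec4[ring == 0]
  SurfaceMesh(v, f, labels = lab)
}

#' Regional strain curves over a mesh sequence
#'
#' For every frame and AHA segment, the unweighted mean over member
#' elements of circumferential strain, longitudinal strain, area ratio and
#' SQUEEZ. Frame 0 (the reference) is exactly (0, 0, 1, 1). Segments with
#' no elements are flagged missing (NA), never zero.
#'
#' @param meshes list of \linkS4class{SurfaceMesh}; element 1 is the
#'   reference, all frames share its connectivity.
#' @param landmarks a \linkS4class{LandmarkSet} with the six anatomical
#'   landmarks (used for the long axis and, if the reference carries no
#'   labels, for AHA labelling).
#' @return A \linkS4class{StrainCurveSet}.
#' @export
regionalCurves <- function(meshes, landmarks) {
  ref <- meshes[[1]]
  if (is.null(ahaLabels(ref))) ref <- ahaLabel(ref, landmarks)
  lab <- ahaLabels(ref)
  pts <- landmarkPoints(landmarks)
  apex <- pts["apex", ]
  base <- colMeans(pts[c("mv_1", "mv_2", "mv_3"), ])
  nf <- length(meshes)
  rows <- list()
  metrics <- c("E_cc", "E_zz", "area_ratio", "squeez")
  for (t in seq_len(nf) - 1L) {
    if (t == 0L) {
      per <- data.frame(segment = 1:16, E_cc = 0, E_zz = 0, area_ratio = 1,
                        squeez = 1)
      missing <- setdiff(1:16, unique(lab))
      per[per$segment %in% missing, -1] <- NA_real_
    } else {
      es <- meshStrain(ref, meshes[[t + 1L]], apex, base)
      per <- do.call(rbind, lapply(1:16, function(sg) {
        sel <- lab == sg
        if (!any(sel))
          return(data.frame(segment = sg, E_cc = NA_real_, E_zz = NA_real_,
                            area_ratio = NA_real_, squeez = NA_real_))
        data.frame(segment = sg, E_cc = mean(es$E_cc[sel]),
                   E_zz = mean(es$E_zz[sel]),
                   area_ratio = mean(es$area_ratio[sel]),
                   squeez = mean(es$squeez[sel]))
      }))
    }
    for (m in metrics)
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, time = t / nf, segment = per$segment, metric = m,
        value = per[[m]])
  }
  new("StrainCurveSet", curves = do.call(rbind, rows),
      nFrames = as.integer(nf))
}
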