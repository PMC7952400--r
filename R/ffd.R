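#' FfdTransform: a temporal stack of B-spline transforms
#'
#' Result of \code{\link{registerTSFFD}}: one \linkS4class{ControlPointGrid}
#' per frame (frame 0 is the zero/identity transform), each mapping
#' reference-frame coordinates toward that frame, plus the reference image
#' geometry and the hyperparameters used.
#'
#' @slot grids per frame, a list of per-level
#'   \linkS4class{ControlPointGrid}s whose displacements add (the additive
#'   multi-level representation the sparsity penalty couples).
#' @slot domain list: dim, origin, spacing of the reference image.
#' @slot hyper list of hyperparameters.
#' @slot trace numeric objective trace (accepted iterations, all levels).
#' @export
setClass("FfdTransform",
  representation(grids = "list", domain = "list", hyper = "list",
                 trace = "numeric"))

setMethod("show", "FfdTransform", function(object) {
  last <- object@grids[[length(object@grids)]]
  cat(sprintf("FfdTransform: %d frames, %d level(s), finest spacing %s mm\n",
              length(object@grids), length(last),
              paste(signif(last[[length(last)]]@spacing, 3),
                    collapse = "x")))
})

## control lattice covering [origin, origin+extent] with full cubic support
makeControlGrid <- function(origin, extent, spacing, level = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  nc <- as.integer(ceiling(extent / spacing) + 5L)
  new("ControlPointGrid", phi = array(0, dim = c(nc, 3L)),
      spacing = spacing, origin = origin - 2 * spacing,
      level = as.integer(level))
}

#' Evaluate a B-spline free-form deformation
#'
#' Cubic tensor-product B-spline interpolation of the control-point
#' displacements at arbitrary world points. Points outside the spline
#' support are an error.
#'
#' @param grid a \linkS4class{ControlPointGrid}.
#' @param points n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of displacements, mm.
#' @export
bsplineDisplacement <- function(grid, points) {
  stopifnot(is(grid, "ControlPointGrid"))
  points <- rbind(points)
  out <- cpp_ffd_evaluate(controlPoints(grid), dim(controlPoints(grid))[1:3],
                          worldOrigin(grid), grid@spacing, points)
  if (anyNA(out)) {
    bad <- which(is.na(out[, 1]))[1]
    stop(sprintf("point (%g, %g, %g) outside transform domain",
                 points[bad, 1], points[bad, 2], points[bad, 3]))
  }
  out
}

#' Sum-of-squared-differences similarity under a transform
#'
#' Mean over reference voxels of \eqn{(a(x) - b(x + h(x)))^2}, with
#' trilinear sampling of \code{b}; warped samples falling outside \code{b}
#' are excluded from the mean.
#'
#' @param imageA,imageB \linkS4class{ImageVolume}s on the same domain.
#' @param transform optional \linkS4class{ControlPointGrid}; identity if
#'   omitted.
#' @return scalar mean SSD.
#' @export
ssdSimilarity <- function(imageA, imageB, transform = NULL) {
  d <- dim(voxels(imageA))
  stopifnot(all(d == dim(voxels(imageB))))
  if (is.null(transform)) {
    ext <- (d - 1) * voxelSpacing(imageA)
    transform <- makeControlGrid(worldOrigin(imageA), ext, max(ext) / 2)
  }
  res <- cpp_ffd_objective(as.double(voxels(imageA)),
                           as.double(voxels(imageB)), d,
                           worldOrigin(imageA), voxelSpacing(imageA),
                           controlPoints(transform),
                           dim(controlPoints(transform))[1:3],
                           worldOrigin(transform), transform@spacing, FALSE,
                           numeric(0))
  res$value
}

## second differences along one axis of a (n1,n2,n3,3) array
d2Along <- function(phi, axis) {
  p <- aperm(phi, c(axis, setdiff(1:3, axis), 4))
  n <- dim(p)[1]
  d2 <- p[1:(n - 2), , , , drop = FALSE] - 2 * p[2:(n - 1), , , , drop = FALSE] +
    p[3:n, , , , drop = FALSE]
  d2
}

d2AdjointAlong <- function(d2, axis, outdim) {
  out <- array(0, dim = c(outdim[axis], outdim[setdiff(1:3, axis)], 3L))
  n <- dim(out)[1]
  out[1:(n - 2), , , ] <- out[1:(n - 2), , , ] + d2
  out[2:(n - 1), , , ] <- out[2:(n - 1), , , ] - 2 * d2
  out[3:n, , , ] <- out[3:n, , , ] + d2
  aperm(out, order(c(axis, setdiff(1:3, axis), 4)))
}

#' Bending energy of a control-point grid
#'
#' Discrete thin-plate approximation: the sum of squared second finite
#' differences of the control displacements along each lattice axis,
#' normalised by the number of control points. Zero for any affine
#' (linear-in-index) displacement field.
#'
#' @param grid a \linkS4class{ControlPointGrid} (or raw phi array).
#' @return scalar.
#' @export
bendingEnergy <- function(grid) {
  phi <- if (is(grid, "ControlPointGrid")) controlPoints(grid) else grid
  d <- dim(phi)
  if (any(d[1:3] < 3L)) stop("grid smaller than 3 control points per axis")
  ncp <- prod(d[1:3])
  val <- 0
  for (ax in 1:3) val <- val + sum(d2Along(phi, ax)^2)
  val / ncp
}

bendingEnergyGrad <- function(phi) {
  d <- dim(phi)
  ncp <- prod(d[1:3])
  g <- array(0, dim = d)
  for (ax in 1:3) {
    d2 <- d2Along(phi, ax)
    g <- g + d2AdjointAlong(d2, ax, d[1:3])
  }
  2 * g / ncp
}

#' Smoothed L1 sparsity penalty over transform levels
#'
#' \eqn{\sum_i (\sqrt{x_i^2 + \epsilon^2} - \epsilon)} over every
#' control-point displacement component, concatenated across the supplied
#' grids (levels and/or frames). The \eqn{\epsilon}-smoothing (default
#' 0.01 mm) keeps the penalty differentiable at zero; as
#' \eqn{\epsilon \to 0} it converges to the plain L1 norm.
#'
#' @param grids a \linkS4class{ControlPointGrid}, a phi array, or a list of
#'   either.
#' @param eps smoothing constant, mm.
#' @return scalar.
#' @export
sparsityPenalty <- function(grids, eps = 1e-2) {
  if (!is.list(grids)) grids <- list(grids)
  if (length(grids) < 1L) stop("need at least one level")
  val <- 0
  for (g in grids) {
    phi <- if (is(g, "ControlPointGrid")) controlPoints(g) else g
    val <- val + sum(sqrt(phi^2 + eps^2) - eps)
  }
  val
}

sparsityGrad <- function(phi, eps = 1e-2) phi / sqrt(phi^2 + eps^2)

## block-mean pyramid level of an ImageVolume (origin moves to block centres)
downsampleVolume <- function(image, fac) {
  if (fac == 1L) return(image)
  d <- dim(voxels(image))
  keep <- (d %/% fac) * fac
  dat <- voxels(image)[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
                       drop = FALSE]
  ds <- cpp_downsample(as.double(dat), dim(dat), rep(as.integer(fac), 3L))
  ImageVolume(ds, spacing = voxelSpacing(image) * fac,
              origin = worldOrigin(image) +
                (fac - 1) / 2 * voxelSpacing(image),
              frame = frameIndex(image))
}

#' Temporal sparse free-form deformation registration
#'
#' Registers every frame of a gated sequence to the reference (frame 0)
#' with a multi-level cubic B-spline transform, minimising
#' \deqn{\sum_t SSD_t + \Theta_0 (bending + temporal) + \Theta_1 sparsity}
#' by gradient descent with a backtracking line search (only decreasing
#' steps are accepted, so the objective trace is non-increasing). Levels
#' are processed coarse to fine, the coarsest control spacing being a
#' quarter of the domain extent and halving per level; coarse levels run on
#' a block-mean image pyramid, and each level is initialised by evaluating
#' the previous level's transform at the new control points. In temporal
#' mode the per-frame grids are coupled by a cyclic first-difference
#' penalty in time (weight shared with the bending energy), reflecting the
#' cyclic cardiac deformation; the reference frame closes the cycle with
#' the identity transform.
#'
#' @param frames list of \linkS4class{ImageVolume}; frame 1 of the list is
#'   the reference.
#' @param bending bending-energy weight \eqn{\Theta_0} (optimised default
#'   5e-6).
#' @param sparsity sparsity weight \eqn{\Theta_1} (optimised default 0.43).
#' @param levels number of resolution levels.
#' @param maxIter maximum accepted iterations per level.
#' @param tol relative objective-change convergence tolerance.
#' @param temporal couple frames with the cyclic temporal penalty.
#' @param verbose print per-level progress.
#' @return An \linkS4class{FfdTransform}.
#' @export
registerTSFFD <- function(frames, bending = 5e-6, sparsity = 0.43,
                          levels = 4L, maxIter = 200L, tol = 1e-6,
                          temporal = TRUE, verbose = FALSE) {
  if (length(frames) < 2L) stop("need at least 2 frames")
  d <- dim(voxels(frames[[1]]))
  for (f in frames) if (!all(dim(voxels(f)) == d)) stop("frame shape mismatch")
  ## intensity normalisation: SSD is computed on [0,1]-scaled intensities so
  ## the dimensionless penalty weights keep their meaning across modalities
  rng <- range(voxels(frames[[1]]))
  if (diff(rng) == 0) stop("reference image is constant")
  frames <- lapply(frames, function(f)
    ImageVolume((voxels(f) - rng[1]) / diff(rng), spacing = voxelSpacing(f),
                origin = worldOrigin(f), frame = frameIndex(f)))
  ref <- frames[[1]]
  nt <- length(frames) - 1L   # moving frames
  ext <- (d - 1) * voxelSpacing(ref)
  coarsest <- max(ext) / 4
  trace <- numeric(0)
  grids <- NULL
  for (lev in seq_len(levels)) {
    sp <- coarsest / 2^(lev - 1)
    ## image pyramid: keep at least ~4 voxels per control spacing
    fac <- max(1L, min(4L, as.integer(2^round(log2(
      sp / (4 * min(voxelSpacing(ref))))))))
    while (any(d %/% fac < 8L) && fac > 1L) fac <- fac %/% 2L
    refD <- downsampleVolume(ref, fac)
    tgtD <- lapply(frames[-1], downsampleVolume, fac = fac)
    dl <- dim(voxels(refD))
    ## blur continuation within the level: optimise against progressively
    ## less-blurred images. The wide blur gives every tissue edge a broad
    ## attraction basin (so boundary samples stranded in flat regions keep a
    ## usable SSD gradient); re-optimising at smaller blur removes the
    ## localisation bias the wide blur introduces under contraction
    ## the final small-blur stage runs at every level: fine image texture
    ## (including noise that moves with the tissue) is what constrains the
    ## transform inside homogeneous regions, and the wide blurs erase it
    sigmas <- c(2, 1, 0.5)
    proto <- makeControlGrid(worldOrigin(ref), ext, sp, level = lev)
    nc <- dim(controlPoints(proto))
    ## frozen displacement from previous levels (additive multi-level FFD),
    ## sampled on this level's image lattice; the current level optimises an
    ## increment on top of it
    bases <- vector("list", nt)
    for (t in seq_len(nt)) {
      if (is.null(grids)) {
        bases[[t]] <- numeric(0)
      } else {
        acc <- 0
        for (g in grids[[t]]) {
          fld <- cpp_ffd_rasterise(controlPoints(g),
                                   dim(controlPoints(g))[1:3],
                                   worldOrigin(g), g@spacing, dl,
                                   worldOrigin(refD), voxelSpacing(refD))
          fld[is.na(fld)] <- 0
          acc <- acc + fld
        }
        bases[[t]] <- as.double(acc)
      }
    }
    phis <- lapply(seq_len(nt), function(t) array(0, dim = nc))
    ncp <- prod(nc[1:3])
    spm <- mean(proto@spacing)     # penalties act on phi in spacing units
    refL <- refD
    tgtL <- tgtD
    objective <- function(phis, want_grad) {
      val <- 0
      gr <- if (want_grad) vector("list", nt) else NULL
      for (t in seq_len(nt)) {
        res <- cpp_ffd_objective(as.double(voxels(refL)),
                                 as.double(voxels(tgtL[[t]])),
                                 dl, worldOrigin(refL),
                                 voxelSpacing(refL), phis[[t]], nc[1:3],
                                 worldOrigin(proto), proto@spacing, want_grad,
                                 bases[[t]])
        val <- val + res$value
        g <- if (want_grad) res$grad else NULL
        ## the SSD is a mean over voxels, i.e. the sum formulation divided
        ## by the voxel count; the L1 sum over control coefficients (in
        ## control-spacing units) is divided by the same count so the
        ## dimensionless weights keep a scale-free meaning
        nvox <- prod(dl)
        val <- val + bending * bendingEnergy(phis[[t]] / spm) +
          sparsity * sparsityPenalty(phis[[t]] / spm) / (3 * nvox)
        if (want_grad)
          g <- g + bending * bendingEnergyGrad(phis[[t]] / spm) / spm +
            sparsity * sparsityGrad(phis[[t]] / spm) / (3 * nvox * spm)
        if (temporal) {
          nxt <- if (t == nt) array(0, dim = nc) else phis[[t + 1]]
          prv <- if (t == 1L) array(0, dim = nc) else phis[[t - 1]]
          val <- val + bending *
            (sum((phis[[t]] - nxt)^2) + sum((phis[[t]] - prv)^2)) /
            (2 * ncp * spm^2)
          if (want_grad)
            g <- g + 2 * bending * (2 * phis[[t]] - nxt - prv) / (ncp * spm^2)
        }
        if (want_grad) gr[[t]] <- g
      }
      list(value = val, grad = gr)
    }
    blurVol <- function(img, sigma) {
      ImageVolume(array(cpp_gaussian_blur(as.double(voxels(img)),
                                          dim(voxels(img)), sigma),
                        dim(voxels(img))), spacing = voxelSpacing(img),
                  origin = worldOrigin(img), frame = frameIndex(img))
    }
    for (sigma in sigmas) {
      refL <- blurVol(refD, sigma)
      tgtL <- lapply(tgtD, blurVol, sigma = sigma)
      cur <- objective(phis, TRUE)
      trace <- c(trace, NA_real_, cur$value)   # NA marks a stage restart
      ## normalised-gradient descent: the step is a length in mm, so the
      ## most-sensitive control points move by `step` regardless of the
      ## objective's scale; halve on failure, regrow mildly on success.
      ## Converged when the relative decrease over a 20-iteration window
      ## falls below tol per iteration (a single small step is not taken
      ## as convergence: descent routinely stalls briefly while boundary
      ## samples cross flat-intensity plateaus)
      vox <- min(voxelSpacing(ref))
      step <- 2 * vox
      it <- 0L
      recent <- rep(NA_real_, 20L)
      while (it < maxIter && step > 1e-3 * vox) {
        gmax <- max(vapply(cur$grad, function(g) max(abs(g)), 0), 1e-12)
        trial <- lapply(seq_len(nt),
                        function(t) phis[[t]] - (step / gmax) * cur$grad[[t]])
        tr <- objective(trial, TRUE)
        if (tr$value < cur$value) {
          phis <- trial
          cur <- tr
          trace <- c(trace, cur$value)
          step <- min(step * 1.2, 4 * vox)
          it <- it + 1L
          old <- recent[1L + (it %% 20L)]
          recent[1L + (it %% 20L)] <- cur$value
          if (!is.na(old) &&
              (old - cur$value) / max(abs(old), 1e-12) < 20 * tol) break
        } else {
          step <- step / 2
        }
      }
      if (verbose)
        message(sprintf(
          "level %d (spacing %.2f mm, blur %.2g vox): objective %.6g after %d it",
          lev, sp, sigma, cur$value, it))
    }
    if (is.null(grids)) grids <- lapply(seq_len(nt), function(t) list())
    for (t in seq_len(nt))
      grids[[t]] <- c(grids[[t]], list(
        new("ControlPointGrid", phi = phis[[t]], spacing = proto@spacing,
            origin = worldOrigin(proto), level = as.integer(lev))))
  }
  zero <- grids[[1]][[1]]
  zero@phi[] <- 0
  new("FfdTransform",
      grids = c(list(list(zero)), grids),
      domain = list(dim = d, origin = worldOrigin(ref),
                    spacing = voxelSpacing(ref)),
      hyper = list(bending = bending, sparsity = sparsity, levels = levels,
                   maxIter = maxIter, tol = tol, temporal = temporal),
      trace = trace)
}

#' Rasterise a transform frame to a dense displacement field
#'
#' Evaluates the frame's B-spline transform on the reference voxel lattice,
#' producing the dense field used for mesh deformation and landmark
#' propagation.
#'
#' @param transform an \linkS4class{FfdTransform} (or a single
#'   \linkS4class{ControlPointGrid} plus an explicit geometry).
#' @param frame 0-based frame index.
#' @param domain optional list(dim, origin, spacing) overriding the stored
#'   reference geometry.
#' @return A \linkS4class{DisplacementField}.
#' @export
toDisplacementField <- function(transform, frame = NULL, domain = NULL) {
  if (is(transform, "FfdTransform")) {
    dom <- if (is.null(domain)) transform@domain else domain
    levels <- transform@grids[[frame + 1L]]
  } else {
    stopifnot(is(transform, "ControlPointGrid"), !is.null(domain))
    dom <- domain
    levels <- list(transform)
  }
  acc <- 0
  for (grid in levels) {
    fld <- cpp_ffd_rasterise(controlPoints(grid),
                             dim(controlPoints(grid))[1:3],
                             worldOrigin(grid), grid@spacing,
                             dom$dim, dom$origin, dom$spacing)
    fld[is.na(fld)] <- 0
    acc <- acc + fld
  }
  DisplacementField(array(acc, dim = c(dom$dim, 3L)),
                    spacing = dom$spacing, origin = dom$origin)
}
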