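#' Names of the ten anatomical measurements
#'
#' The ten mitral/ventricular measurements used for tracking validation:
#' trigone-to-trigone diameter, posterior perimeter, mitral annulus area,
#' intercommissural diameter, anterior-to-posterior horn diameter, and the
#' distances from the mitral-annulus midpoint to the anterolateral and
#' posteromedial papillary heads, the endocardial and epicardial apex, and
#' the left-atrial posterior wall. Units are mm (area in mm^2).
#'
#' @return character(10).
#' @export
measurementNames <- function() {
  c("trigone_to_trigone", "posterior_perimeter", "mitral_annulus_area",
    "intercommissural", "anterior_posterior_horn", "ma_to_pm_anterolateral",
    "ma_to_pm_posteromedial", "ma_to_apex_endo", "ma_to_apex_epi",
    "ma_to_la_posterior")
}

#' Mitral annulus midpoint
#'
#' Arithmetic centroid of the annulus landmark points; computed
#' automatically rather than annotated, since a free-floating point in the
#' blood pool has no image features to pin it down.
#'
#' @param annulusPoints n x 3 matrix (n >= 3) of annulus mm points.
#' @return numeric(3).
#' @export
annulusMidpoint <- function(annulusPoints) {
  annulusPoints <- rbind(annulusPoints)
  if (nrow(annulusPoints) < 3L) stop("need at least 3 annulus points")
  colMeans(annulusPoints)
}

## polygon area after projection onto its least-squares plane
polygonArea3d <- function(pts) {
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr, "-")
  sv <- svd(rel)
  uv <- rel %*% sv$v[, 1:2]           # in-plane 2D coordinates
  n <- nrow(uv)
  i2 <- c(2:n, 1)
  abs(sum(uv[, 1] * uv[i2, 2] - uv[i2, 1] * uv[, 2])) / 2
}

#' Compute the ten anatomical measurements from annotated landmarks
#'
#' Expects the annotation naming convention of
#' \code{\link{phantomLandmarks}}: an ordered annulus ring
#' (\code{annulus_1..k}), \code{trigone_1/2}, an ordered posterior arc
#' (\code{posterior_1..j}), \code{comm_1/2}, \code{horn_ant/horn_post},
#' \code{pm_al}, \code{pm_pm}, \code{apex_endo}, \code{apex_epi},
#' \code{la_post}. Distances are Euclidean, the posterior perimeter is the
#' ordered polyline length, and the annulus area is the polygon area after
#' projection onto its least-squares plane. Measurements whose annotation
#' points are absent come back NA (flagged missing).
#'
#' @param landmarks a \linkS4class{LandmarkSet} for one frame.
#' @return named numeric(10) (see \code{\link{measurementNames}}).
#' @export
computeMeasurements <- function(landmarks) {
  pts <- landmarkPoints(landmarks)
  nm <- rownames(pts)
  get <- function(name) if (name %in% nm) pts[name, ] else NULL
  dist2 <- function(a, b) {
    if (is.null(a) || is.null(b)) return(NA_real_)
    sqrt(sum((a - b)^2))
  }
  ann <- pts[grep("^annulus_[0-9]+$", nm), , drop = FALSE]
  ann <- ann[order(as.integer(sub("annulus_", "", rownames(ann)))), ,
             drop = FALSE]
  mid <- if (nrow(ann) >= 3) annulusMidpoint(ann) else NULL
  post <- pts[grep("^posterior_[0-9]+$", nm), , drop = FALSE]
  post <- post[order(as.integer(sub("posterior_", "", rownames(post)))), ,
               drop = FALSE]
  perim <- if (nrow(post) >= 2)
    sum(sqrt(rowSums((post[-1, , drop = FALSE] -
                        post[-nrow(post), , drop = FALSE])^2)))
  else NA_real_
  area <- if (nrow(ann) >= 3) polygonArea3d(ann) else NA_real_
  out <- c(
    trigone_to_trigone = dist2(get("trigone_1"), get("trigone_2")),
    posterior_perimeter = perim,
    mitral_annulus_area = area,
    intercommissural = dist2(get("comm_1"), get("comm_2")),
    anterior_posterior_horn = dist2(get("horn_ant"), get("horn_post")),
    ma_to_pm_anterolateral = dist2(mid, get("pm_al")),
    ma_to_pm_posteromedial = dist2(mid, get("pm_pm")),
    ma_to_apex_endo = dist2(mid, get("apex_endo")),
    ma_to_apex_epi = dist2(mid, get("apex_epi")),
    ma_to_la_posterior = dist2(mid, get("la_post")))
  names(out) <- measurementNames()
  out
}

#' Tracking cost over frames and measurements
#'
#' The optimisation cost
#' \deqn{J = \frac{1}{mt} \sum_i \sum_j \left(\frac{h_\Theta(x) - y}{y}\right)^2}
#' over m measurement kinds and t frames, computed on relative differences
#' so that the reported companion quantity, the mean absolute relative
#' error in percent, matches the tracking-error definition. Cells with an
#' observed value of zero are excluded and counted.
#'
#' @param estimated list (over frames) of named measurement vectors, or a
#'   matrix frames x measurements.
#' @param observed same shape as \code{estimated}.
#' @return list: \code{J}, \code{mean_abs_pct} (mean |h-y|/y in percent),
#'   \code{n}, \code{n_excluded}.
#' @export
trackingCost <- function(estimated, observed) {
  toMat <- function(x) if (is.list(x)) do.call(rbind, x) else rbind(x)
  h <- toMat(estimated)
  y <- toMat(observed)
  stopifnot(all(dim(h) == dim(y)))
  excl <- !is.na(y) & y == 0
  ok <- !is.na(h) & !is.na(y) & !excl
  rel <- (h[ok] - y[ok]) / y[ok]
  list(J = mean(rel^2),
       mean_abs_pct = 100 * mean(abs(rel)),
       n = sum(ok), n_excluded = sum(excl))
}

#' Hyperparameter grid specification
#'
#' An inclusive regular grid \code{seq(min, max, by = step)} per
#' hyperparameter; both endpoints are always included.
#'
#' @param min,max span.
#' @param step resolution (> 0).
#' @return numeric vector of grid values.
#' @export
gridSpec <- function(min, max, step) {
  stopifnot(min <= max, step > 0)
  v <- seq(min, max, by = step)
  if (abs(v[length(v)] - max) > 1e-12) v <- c(v, max)
  v
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every permutation of the supplied hyperparameter grids
#' (deterministic enumeration order: the first hyperparameter varies
#' fastest) on the training sets, scoring each by the mean relative
#' tracking error in percent, and returns the error surface together with
#' the arg-min (ties resolved to the first enumerated permutation). Engine
#' failures at a grid point are recorded as NA, not fatal.
#'
#' @param trainSets list of training sets; each element is a list with
#'   components \code{observed} (per-frame measurement vectors) and
#'   whatever inputs the engine needs.
#' @param grid named list of numeric grid vectors (see
#'   \code{\link{gridSpec}}).
#' @param engine function(hyper, set) returning per-frame estimated
#'   measurement vectors.
#' @return list: \code{best} (named hyperparameter values),
#'   \code{surface} (data.frame, one row per permutation with its error),
#'   \code{n_evaluated}.
#' @export
gridSearch <- function(trainSets, grid, engine) {
  stopifnot(length(trainSets) >= 1L, length(grid) >= 1L)
  perms <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  err <- rep(NA_real_, nrow(perms))
  for (i in seq_len(nrow(perms))) {
    hyper <- as.list(perms[i, , drop = FALSE])
    e <- tryCatch({
      vals <- vapply(trainSets, function(set) {
        est <- engine(hyper, set)
        trackingCost(est, set$observed)$mean_abs_pct
      }, 0)
      mean(vals)
    }, error = function(e) NA_real_)
    err[i] <- e
  }
  surface <- cbind(perms, error_pct = err)
  best <- if (all(is.na(err))) NA_integer_ else which.min(err)
  list(best = if (is.na(best)) NULL else as.list(perms[best, , drop = FALSE]),
       surface = surface,
       n_evaluated = nrow(perms))
}

#' Agreement statistics between manual and automatic measurements
#'
#' Pearson correlation, coefficient of determination from the simple
#' linear regression of automatic on manual values, and a Welch two-sample
#' t-test with the 95 percent confidence interval of the mean difference.
#'
#' @param manual,auto numeric vectors of equal length >= 3.
#' @return list: \code{r}, \code{r_squared}, \code{p_value}, \code{conf_int}.
#' @export
agreementStats <- function(manual, auto) {
  stopifnot(length(manual) == length(auto), length(manual) >= 3L)
  if (sd(manual) == 0 || sd(auto) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                conf_int = c(NA_real_, NA_real_)))
  }
  r <- cor(manual, auto)
  r2 <- summary(lm(auto ~ manual))$r.squared
  tt <- t.test(auto, manual)
  list(r = r, r_squared = r2, p_value = tt$p.value,
       conf_int = unname(tt$conf.int))
}
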