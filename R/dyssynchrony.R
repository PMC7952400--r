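#' Timing and magnitude metrics of a strain curve
#'
#' For one per-segment curve over a cycle: \code{mag} is max minus min;
#' the peak is the sample with the largest absolute deviation from the
#' frame-0 value (so negative-going strains and positive-going area curves
#' are treated alike); \code{t2p} is the peak time as a cycle fraction;
#' \code{tos} is the linearly interpolated first time the curve departs
#' from its frame-0 value by at least half the magnitude, moving toward
#' the peak. Onset is frame 0 (the R wave). A constant curve has
#' \code{mag} 0 and undefined (NA) timings.
#'
#' @param values numeric curve samples, frame 0 first (>= 3 samples).
#' @param times optional sample times as cycle fraction; defaults to
#'   \code{(0:(n-1))/(n-1)}.
#' @return named numeric: \code{t2p}, \code{tos}, \code{mag}.
#' @export
curveMetrics <- function(values, times = NULL) {
  n <- length(values)
  if (n < 3L) stop("need at least 3 samples")
  if (is.null(times)) times <- (seq_len(n) - 1) / (n - 1)
  mag <- max(values) - min(values)
  if (mag == 0)
    return(c(t2p = NA_real_, tos = NA_real_, mag = 0))
  dev <- values - values[1]
  ipk <- which.max(abs(dev))
  t2p <- times[ipk]
  thr <- 0.5 * mag * sign(dev[ipk])
  tos <- NA_real_
  for (i in 2:n) {
    if (abs(dev[i]) >= abs(thr) && sign(dev[i]) == sign(thr)) {
      # linear interpolation between i-1 and i
      d0 <- dev[i - 1]; d1 <- dev[i]
      w <- (thr - d0) / (d1 - d0)
      tos <- times[i - 1] + w * (times[i] - times[i - 1])
      break
    }
  }
  c(t2p = t2p, tos = tos, mag = mag)
}

#' Systolic dyssynchrony index
#'
#' Sample standard deviation (n-1 denominator) of a per-segment timing
#' measure over the 16 AHA segments.
#'
#' @param perSegment numeric(16); fewer or more values are rejected.
#' @return scalar SDI.
#' @export
sdi <- function(perSegment) {
  if (length(perSegment) != 16L || anyNA(perSegment))
    stop("SDI requires exactly 16 segment values")
  sd(perSegment)
}

## per-subject: metric (t2p/tos/mag) per segment for one strain metric,
## then its SDI across the 16 segments
subjectSdi <- function(curveSet, strainMetric, which) {
  cv <- curveTable(curveSet)
  cv <- cv[cv$metric == strainMetric, ]
  per <- vapply(1:16, function(sg) {
    v <- cv$value[cv$segment == sg][order(cv$frame[cv$segment == sg])]
    unname(curveMetrics(v)[which])
  }, 0)
  sdi(per)
}

#' Compare healthy and dyssynchronous strain patterns
#'
#' For each of the nine rows (area change, circumferential and
#' longitudinal strain, each summarised by T2P, TOS and MAG), the
#' per-subject value is the SDI of that metric across the 16 segments; the
#' two groups are then compared with a Welch two-sample t-test. Mirrors
#' the standard 16-segment SDI analysis used to separate CRT candidates
#' from controls.
#'
#' @param healthy,crt lists of per-subject \linkS4class{StrainCurveSet}s
#'   (>= 2 subjects per group).
#' @return data.frame with columns \code{strain}, \code{measure},
#'   \code{p_value}, plus the group means.
#' @export
groupComparison <- function(healthy, crt) {
  stopifnot(length(healthy) >= 2L, length(crt) >= 2L)
  strains <- c(area_ratio = "area_ratio", circumferential = "E_cc",
               longitudinal = "E_zz")
  measures <- c("t2p", "tos", "mag")
  rows <- list()
  for (si in seq_along(strains)) {
    for (ms in measures) {
      hv <- vapply(healthy, subjectSdi, 0, strainMetric = strains[[si]],
                   which = ms)
      cv <- vapply(crt, subjectSdi, 0, strainMetric = strains[[si]],
                   which = ms)
      p <- if (sd(hv) == 0 && sd(cv) == 0) NA_real_ else
        tryCatch(t.test(hv, cv)$p.value, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = names(strains)[si], measure = toupper(ms), p_value = p,
        mean_healthy = mean(hv), mean_crt = mean(cv))
    }
  }
  do.call(rbind, rows)
}

#' Effect of temporal frame count on curve metrics
#'
#' Recomputes T2P, TOS and MAG on stride-subsampled curves (e.g. the
#' 10-frame subset of a 20-frame acquisition) and reports per-segment
#' relative differences in percent, with their mean and sd per metric.
#'
#' @param curveSet a \linkS4class{StrainCurveSet} at the full frame count.
#' @param stride subsampling stride (must divide the frame count).
#' @return list: \code{per_segment} (data.frame strain x segment x metric
#'   with \code{rel_diff_pct}), \code{summary} (mean and sd per strain and
#'   metric).
#' @export
frameSubsampleCompare <- function(curveSet, stride = 2L) {
  nf <- curveSet@nFrames
  if (nf %% stride != 0L) stop("stride must divide the frame count")
  cv <- curveTable(curveSet)
  keep <- cv$frame %% stride == 0L
  rows <- list()
  for (m in unique(cv$metric)) {
    for (sg in sort(unique(cv$segment))) {
      sel <- cv$metric == m & cv$segment == sg
      v <- cv$value[sel][order(cv$frame[sel])]
      full <- curveMetrics(v)
      idx <- seq(1, nf, by = stride)
      # the subsampled curve keeps the full acquisition's time axis: cycle
      # fraction is a property of the cycle, not of the sample count
      sub <- curveMetrics(v[idx], times = (idx - 1) / (nf - 1))
      rel <- 100 * (sub - full) / ifelse(full == 0, NA, full)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, segment = sg,
        measure = c("t2p", "tos", "mag"),
        full = unname(full), subsampled = unname(sub),
        rel_diff_pct = unname(rel))
    }
  }
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per, list(per$metric, per$measure)),
    function(d) data.frame(metric = d$metric[1], measure = d$measure[1],
                           mean_abs_pct = mean(abs(d$rel_diff_pct),
                                               na.rm = TRUE),
                           sd_pct = sd(d$rel_diff_pct, na.rm = TRUE))))
  rownames(summ) <- NULL
  list(per_segment = per, summary = summ)
}
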