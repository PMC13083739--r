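#' Construct a displacement series directly
#'
#' Mostly useful for composing motion summaries from externally computed
#' displacements; [probe_displacements()] is the usual route.
#'
#' @param anterior,posterior Per-frame absolute displacements (mm, >= 0).
#' @param timing A [frame_timing()] of matching length.
#' @param reference_index Reference frame; its displacement must be 0.
#' @param offset_mm Probe offset used (mm).
#' @param brain_center Brain centre (mm).
#' @return A `displacement_series`.
#' @export
displacement_series <- function(anterior, posterior, timing,
                                reference_index = 1L, offset_mm = 70,
                                brain_center = c(0, 0, 0)) {
  anterior <- as.numeric(anterior); posterior <- as.numeric(posterior)
  if (length(anterior) != nrow(timing) || length(posterior) != nrow(timing))
    stop("displacements and timing lengths differ")
  if (any(anterior < 0) || any(posterior < 0))
    stop("displacements must be >= 0")
  if (anterior[reference_index] != 0 || posterior[reference_index] != 0)
    stop("displacement at the reference frame must be 0")
  structure(list(anterior = anterior, posterior = posterior, timing = timing,
                 reference_index = as.integer(reference_index),
                 offset_mm = offset_mm, brain_center = brain_center),
            class = "displacement_series")
}

#' Probe-point displacement series
#'
#' Head motion is summarised by the displacement of two virtual points
#' placed 70 mm anterior and 70 mm posterior of the brain centre (the
#' anterior axis is +y in RAS). For every frame, the displacement is the
#' 3-D Euclidean distance between the transform-mapped point and its
#' reference position.
#'
#' @param traj A `motion_trajectory`.
#' @param brain_center Brain centre in world mm.
#' @param offset_mm Probe offset from the brain centre (default 70 mm).
#' @return A `displacement_series`: list with numeric vectors `anterior`
#'   and `posterior` (mm), the frame `timing`, `reference_index`,
#'   `offset_mm` and `brain_center`.
#' @export
probe_displacements <- function(traj, brain_center = NULL, offset_mm = 70) {
  if (length(traj$transforms) < 1L) stop("empty trajectory")
  if (is.null(brain_center)) brain_center <- traj$transforms[[1]]$center
  ant <- brain_center + c(0, offset_mm, 0)
  post <- brain_center - c(0, offset_mm, 0)
  disp <- function(p) vapply(traj$transforms, function(t)
    sqrt(sum((apply_transform(t, p) - p)^2)), 0)
  structure(list(anterior = disp(ant), posterior = disp(post),
                 timing = traj$timing,
                 reference_index = traj$reference_index,
                 offset_mm = offset_mm, brain_center = brain_center),
            class = "displacement_series")
}

#' @export
print.displacement_series <- function(x, ...) {
  cat(sprintf(
    "<displacement_series> %d frames, probes +/-%g mm; median anterior %.3g mm, posterior %.3g mm\n",
    length(x$anterior), x$offset_mm,
    stats::median(x$anterior), stats::median(x$posterior)))
  invisible(x)
}

#' Automatic motion categorization
#'
#' For each probe point the median absolute displacement over frames is
#' computed (unweighted by frame duration); the larger of the two medians
#' decides the category: low motion below 1 mm, high motion above 2 mm,
#' medium motion in the closed interval [1 mm, 2 mm] (medians exactly on a
#' boundary are medium).
#'
#' @param d A `displacement_series`.
#' @param boundaries Category boundaries in mm, `c(low_upper, high_lower)`.
#' @param duration_weighted If `TRUE`, use the duration-weighted median
#'   instead of the plain per-frame median.
#' @return A `motion_category`: list with `category` (`"low"`, `"medium"`
#'   or `"high"`), `deciding_median` (mm) and `deciding_point`
#'   (`"anterior"` or `"posterior"`).
#' @export
categorize_motion <- function(d, boundaries = c(1, 2),
                              duration_weighted = FALSE) {
  med <- function(x) {
    if (!duration_weighted) return(stats::median(x))
    o <- order(x)
    cw <- cumsum(d$timing$duration[o]) / sum(d$timing$duration)
    x[o][which(cw >= 0.5)[1]]
  }
  m_ant <- med(d$anterior)
  m_post <- med(d$posterior)
  deciding <- max(m_ant, m_post)
  point <- if (m_ant >= m_post) "anterior" else "posterior"
  category <- if (deciding < boundaries[1]) "low"
  else if (deciding > boundaries[2]) "high"
  else "medium"
  structure(list(category = category, deciding_median = deciding,
                 deciding_point = point, boundaries = boundaries),
            class = "motion_category")
}

#' @export
print.motion_category <- function(x, ...) {
  cat(sprintf("Motion category: %s (deciding median %.3g mm, %s probe)\n",
              x$category, x$deciding_median, x$deciding_point))
  invisible(x)
}

#' Cumulative displacement-time histogram
#'
#' For each displacement threshold, the fraction of total scan time spent
#' at or below that displacement (non-strict comparison), per probe point.
#' Thresholds run from 0 to the maximum displacement rounded up to the bin
#' width.
#'
#' @param d A `displacement_series`.
#' @param bin_width_mm Threshold spacing in mm (default 0.1).
#' @return A `cdth` object: list with `thresholds_mm` and matrices-free
#'   vectors `anterior` / `posterior` of cumulative time fractions.
#' @export
cdth <- function(d, bin_width_mm = 0.1) {
  if (bin_width_mm <= 0) stop("bin_width_mm must be > 0")
  dmax <- max(d$anterior, d$posterior)
  thresholds <- seq(0, ceiling(dmax / bin_width_mm) * bin_width_mm,
                    by = bin_width_mm)
  w <- d$timing$duration / sum(d$timing$duration)
  frac <- function(x) vapply(thresholds, function(th) sum(w[x <= th + 1e-12]), 0)
  structure(list(thresholds_mm = thresholds,
                 anterior = frac(d$anterior), posterior = frac(d$posterior),
                 bin_width_mm = bin_width_mm),
            class = "cdth")
}

#' @export
print.cdth <- function(x, ...) {
  cat(sprintf("<cdth> %d thresholds up to %g mm (bin %g mm)\n",
              length(x$thresholds_mm), max(x$thresholds_mm), x$bin_width_mm))
  invisible(x)
}

#' @rdname cdth
#' @param x A `cdth` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cdth <- function(x, ...) {
  graphics::matplot(x$thresholds_mm, cbind(x$anterior, x$posterior),
                    type = "s", lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "displacement threshold (mm)",
                    ylab = "fraction of scan time <= threshold",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomright", c("anterior", "posterior"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Motion plot: probe displacement versus time
#'
#' @param x A `displacement_series`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.displacement_series <- function(x, ...) {
  tmid <- x$timing$start + x$timing$duration / 2
  graphics::matplot(tmid, cbind(x$anterior, x$posterior), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "time (s)", ylab = "displacement (mm)", ...)
  graphics::abline(v = tmid[x$reference_index], lty = 3)
  graphics::legend("topleft", c("anterior", "posterior"), lty = 1,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
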