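#' Brain mask from a reference frame
#'
#' The reference frame is Gaussian-filtered (default FWHM 16 mm) and voxels
#' at or above a fraction (default 30%) of the *smoothed* volume's maximum
#' are included.
#'
#' @param reference A `volume_grid` with a positive maximum.
#' @param smooth_fwhm_mm Smoothing FWHM in mm (default 16).
#' @param threshold_frac Inclusion threshold as a fraction of the smoothed
#'   maximum (default 0.30).
#' @return A `brain_mask`: list with logical array `mask`, `n_voxels`, and
#'   the generating parameters.
#' @export
make_brain_mask <- function(reference, smooth_fwhm_mm = 16,
                            threshold_frac = 0.30) {
  if (all(reference$values == 0)) stop("all-zero reference: cannot build mask")
  if (max(reference$values) <= 0) stop("reference must have a positive maximum")
  sm <- gaussian_smooth(reference, smooth_fwhm_mm)
  thr <- threshold_frac * max(sm$values)
  mask <- sm$values >= thr
  if (!any(mask)) stop("empty brain mask")
  structure(list(mask = mask, n_voxels = sum(mask),
                 spacing = reference$spacing, origin = reference$origin,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 threshold_frac = threshold_frac),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d voxels (FWHM %g mm, threshold %g of smoothed max)\n",
              x$n_voxels, x$smooth_fwhm_mm, x$threshold_frac))
  invisible(x)
}

#' Masked normalized cross-correlation of two volumes
#'
#' Both volumes are Gaussian-smoothed (default FWHM 3 mm), then the
#' zero-normalised (Pearson-form) cross-correlation
#' sum((a - mean(a)) (b - mean(b))) / sqrt(sum((a - mean(a))^2) sum((b - mean(b))^2))
#' is computed over the mask voxels. 1 means identical up to a positive
#' affine intensity change; 0 no correlation.
#'
#' @param frame,reference Aligned `volume_grid` objects.
#' @param mask A [make_brain_mask()] result on the same grid.
#' @param smooth_fwhm_mm Smoothing applied to both volumes before
#'   correlation (default 3 mm).
#' @return Scalar in [-1, 1].
#' @export
xc <- function(frame, reference, mask, smooth_fwhm_mm = 3) {
  if (!grids_aligned(frame, reference))
    stop("frame and reference grids are not aligned")
  if (!identical(dim(mask$mask), dim(frame$values)))
    stop("mask does not match the frame grid")
  a <- gaussian_smooth(frame, smooth_fwhm_mm)$values[mask$mask]
  b <- gaussian_smooth(reference, smooth_fwhm_mm)$values[mask$mask]
  zncc(a, b)
}

#' Cross-correlation over time
#'
#' Computes the masked XC of every frame against the reference frame. The
#' reference entry is 1 by construction.
#'
#' @param series A `dynamic_series`.
#' @param reference_index Reference frame index.
#' @param mask A `brain_mask`; built from the reference frame with default
#'   parameters when omitted.
#' @param smooth_fwhm_mm Smoothing FWHM for the correlation (default 3 mm).
#' @return An `xc_series`: list with `values`, `timing`,
#'   `reference_index`, `smooth_fwhm_mm`.
#' @export
xc_series <- function(series, reference_index, mask = NULL,
                      smooth_fwhm_mm = 3) {
  n <- length(series$frames)
  if (reference_index < 1L || reference_index > n)
    stop("reference_index out of range")
  ref <- series$frames[[reference_index]]
  if (is.null(mask)) mask <- make_brain_mask(ref)
  vals <- numeric(n)
  for (f in seq_len(n)) {
    vals[f] <- tryCatch(xc(series$frames[[f]], ref, mask, smooth_fwhm_mm),
                        error = function(e)
                          stop("frame ", f, ": ", conditionMessage(e)))
  }
  structure(list(values = vals, timing = series$timing,
                 reference_index = reference_index,
                 smooth_fwhm_mm = smooth_fwhm_mm),
            class = "xc_series")
}

#' @export
print.xc_series <- function(x, ...) {
  cat(sprintf("<xc_series> %d frames, reference %d, median XC %.4f\n",
              length(x$values), x$reference_index, median_xc(x)))
  invisible(x)
}

#' Median cross-correlation of a series
#'
#' @param s An `xc_series`.
#' @param exclude_reference Drop the reference frame (whose XC is 1 by
#'   construction) before taking the median; default `TRUE`.
#' @return Scalar median XC.
#' @export
median_xc <- function(s, exclude_reference = TRUE) {
  v <- s$values
  if (exclude_reference && length(v) > 1L) v <- v[-s$reference_index]
  stats::median(v)
}

#' @rdname xc_series
#' @param x An `xc_series`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.xc_series <- function(x, ...) {
  tmid <- x$timing$start + x$timing$duration / 2
  graphics::plot(tmid, x$values, type = "b", pch = 16,
                 xlab = "time (s)", ylab = "XC", ylim = c(min(x$values), 1),
                 ...)
  graphics::abline(v = tmid[x$reference_index], lty = 3)
  invisible(x)
}
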