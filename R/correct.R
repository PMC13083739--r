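#' Motion-correct a dynamic frame series
#'
#' Pull-back correction: frame f is resampled through its trajectory
#' transform T_f (which maps reference-space coordinates into frame-f
#' space), bringing every frame into the reference frame's anatomy. The
#' reference frame is returned unchanged.
#'
#' @param series A `dynamic_series`.
#' @param traj A `motion_trajectory` of the same length, on the same grid.
#' @param interpolation Passed to [resample()]; trilinear by default.
#' @return A corrected `dynamic_series`.
#' @export
correct_series <- function(series, traj,
                           interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (length(series$frames) != length(traj$transforms))
    stop("series and trajectory lengths differ")
  frames <- vector("list", length(series$frames))
  for (f in seq_along(frames)) {
    tr <- traj$transforms[[f]]
    frames[[f]] <- if (is_identity_transform(tr)) series$frames[[f]] else
      resample(series$frames[[f]], tr, interpolation)
  }
  dynamic_series(frames, series$timing)
}

#' Integrate a frame series into a static image
#'
#' Duration-weighted voxelwise mean of the frames — the image-space
#' surrogate for a single static reconstruction of the whole acquisition.
#'
#' @param series A `dynamic_series`.
#' @param timing A [frame_timing()]; defaults to the series' own timing.
#' @return A `volume_grid`.
#' @export
integrate_series <- function(series, timing = series$timing) {
  if (length(series$frames) != nrow(timing))
    stop("series and timing lengths differ")
  w <- timing$duration
  if (sum(w) <= 0) stop("zero total duration")
  w <- w / sum(w)
  acc <- series$frames[[1]]$values * w[1]
  for (f in seq_along(series$frames)[-1])
    acc <- acc + series$frames[[f]]$values * w[f]
  volume_grid(acc, series$frames[[1]]$spacing, series$frames[[1]]$origin)
}
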