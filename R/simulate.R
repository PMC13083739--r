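#' Dynamic frame series
#'
#' An ordered set of reconstructed frames on a common grid with frame
#' timing.
#'
#' @param frames List of `volume_grid` objects, all aligned.
#' @param timing A [frame_timing()] with one row per frame.
#' @return A `dynamic_series`.
#' @export
dynamic_series <- function(frames, timing) {
  if (length(frames) != nrow(timing))
    stop("number of frames and timing rows differ")
  if (length(frames) > 1L &&
      !all(vapply(frames[-1], grids_aligned, TRUE, b = frames[[1]])))
    stop("all frames must share one grid")
  structure(list(frames = frames, timing = timing), class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %d frames over [%g, %g] s\n",
              length(x$frames), x$timing$start[1],
              x$timing$start[nrow(x$timing)] +
                x$timing$duration[nrow(x$timing)]))
  print(x$frames[[1]])
  invisible(x)
}

#' @export
length.dynamic_series <- function(x) length(x$frames)

#' Simulate a dynamic PET frame series from a phantom and a trajectory
#'
#' Each frame is the phantom activity moved by that frame's subject pose
#' (the frame image is the push-forward of the activity through the
#' trajectory transform), optionally blurred by an isotropic Gaussian PSF,
#' scaled so the expected total equals `counts_per_frame`, and — unless
#' `noise = "none"` — replaced by an independent per-voxel Poisson draw.
#'
#' @param phantom A [make_phantom()] result.
#' @param traj A `motion_trajectory` (transforms map reference space to
#'   frame space).
#' @param timing A [frame_timing()]; defaults to the trajectory's timing.
#' @param counts_per_frame Expected events per frame (default 5e5,
#'   the constant-count framing used for data-driven motion estimation).
#' @param psf_fwhm_mm Isotropic PSF applied to the expectation (mm; 0 = none).
#' @param noise `"poisson"` or `"none"` (return the expectation directly).
#' @param seed Integer seed for the Poisson draws.
#' @return A `dynamic_series`.
#' @export
simulate_frames <- function(phantom, traj, timing = traj$timing,
                            counts_per_frame = 5e5, psf_fwhm_mm = 5,
                            noise = c("poisson", "none"), seed = 1) {
  noise <- match.arg(noise)
  if (counts_per_frame <= 0) stop("counts_per_frame must be > 0")
  n <- nrow(timing)
  if (length(traj$transforms) != n)
    stop("trajectory and timing lengths differ")
  act <- phantom$activity
  frames <- vector("list", n)
  for (f in seq_len(n)) {
    tr <- traj$transforms[[f]]
    exp_f <- if (is_identity_transform(tr)) act else
      resample(act, invert_transform(tr))
    if (psf_fwhm_mm > 0) exp_f <- gaussian_smooth(exp_f, psf_fwhm_mm)
    tot <- sum(exp_f$values)
    if (tot <= 0) stop("phantom expectation sums to zero")
    lambda <- exp_f$values * (counts_per_frame / tot)
    vals <- if (noise == "poisson")
      with_seed(seed + f, array(stats::rpois(length(lambda), lambda),
                                dim(lambda)))
    else lambda
    frames[[f]] <- volume_grid(vals, act$spacing, act$origin)
  }
  dynamic_series(frames, timing)
}

#' Simulate an uncorrected / ground-truth-corrected static image pair
#'
#' Convenience wrapper producing the image-space analogue of a static
#' reconstruction without motion correction (`nomc`) and one corrected with
#' the *true* simulated transforms (`ddmc_oracle`) — a ground-truth
#' correction independent of any motion estimator. Both are
#' duration-weighted integrals of the frame series.
#'
#' @inheritParams simulate_frames
#' @return List with elements `nomc`, `ddmc_oracle` (both `volume_grid`)
#'   and `series` (the uncorrected `dynamic_series`).
#' @export
simulate_static_pair <- function(phantom, traj, timing = traj$timing,
                                 counts_per_frame = 5e5, psf_fwhm_mm = 5,
                                 noise = c("poisson", "none"), seed = 1) {
  series <- simulate_frames(phantom, traj, timing, counts_per_frame,
                            psf_fwhm_mm, noise, seed)
  corrected <- correct_series(series, traj)
  list(nomc = integrate_series(series, timing),
       ddmc_oracle = integrate_series(corrected, timing),
       series = series)
}
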