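#' Frame timing table
#'
#' @param start Frame start times (s), strictly increasing.
#' @param duration Frame durations (s), strictly positive; frames must not
#'   overlap.
#' @return A `data.frame` of class `frame_timing` with columns `start` and
#'   `duration`.
#' @export
frame_timing <- function(start, duration) {
  start <- as.numeric(start); duration <- as.numeric(duration)
  if (length(start) != length(duration) || length(start) < 1L)
    stop("'start' and 'duration' must be nonempty and of equal length")
  if (any(duration <= 0)) stop("durations must be > 0")
  if (is.unsorted(start, strictly = TRUE)) stop("starts must be strictly increasing")
  if (length(start) > 1L && any(start[-1] < (start + duration)[-length(start)] - 1e-9))
    stop("frames must not overlap")
  structure(data.frame(start = start, duration = duration),
            class = c("frame_timing", "data.frame"))
}

#' Equal-length frame timing helper
#' @param n_frames Number of frames.
#' @param frame_dur_s Duration of each frame (s).
#' @param t0 Scan start time (s).
#' @return A `frame_timing`.
#' @export
uniform_timing <- function(n_frames, frame_dur_s = 30, t0 = 0) {
  frame_timing(t0 + (seq_len(n_frames) - 1) * frame_dur_s,
               rep(frame_dur_s, n_frames))
}

frame_mid_times <- function(timing) timing$start + timing$duration / 2

# base tissue labels; WB/GM/WM are unions resolved in roi_labels()
.tissue_ids <- c(FC = 1L, PC = 2L, TC = 3L, OC = 4L, CTX = 5L,
                 CER = 6L, STR = 7L, THA = 8L, HIP = 9L, WM = 10L)

# mean relative tracer concentration per tissue and contrast regime.
# fdg_like mimics FDG gray/white contrast (~2.7 GM:WM); met_like compresses
# the contrast and lowers overall uptake, as for a low-accumulating
# amino-acid tracer.
.tissue_activity <- list(
  fdg_like = c(FC = 4.0, PC = 4.0, TC = 4.0, OC = 4.0, CTX = 4.0,
               CER = 4.0, STR = 3.8, THA = 3.6, HIP = 3.2, WM = 1.5,
               VENT = 0.2),
  met_like = c(FC = 1.3, PC = 1.3, TC = 1.3, OC = 1.3, CTX = 1.3,
               CER = 1.3, STR = 1.25, THA = 1.2, HIP = 1.15, WM = 0.9,
               VENT = 0.1))

#' Procedural brain-like phantom with ROI labels
#'
#' Builds a deterministic (seeded) digital brain phantom: an ellipsoidal
#' cerebrum with a folded cortical shell split into frontal, parietal,
#' temporal and occipital sectors, a cerebellum, striatum, thalamus and
#' hippocampus, ventricle-like voids, and white matter filling the rest.
#' Two contrast regimes are provided: `fdg_like` (high uptake, GM:WM mean
#' ratio about 2.7) and `met_like` (low uptake, compressed contrast) with
#' identical label geometry.
#'
#' @param shape Grid size in voxels (length 3, each >= 32).
#' @param spacing Voxel size in mm (length 3).
#' @param contrast `"fdg_like"` or `"met_like"`.
#' @param seed Integer seed controlling cortical folding and tissue texture.
#' @return A `labeled_phantom`: list with `activity` (`volume_grid`),
#'   `labels` (`roi_labels`), and `brain_center` (world mm).
#' @export
make_phantom <- function(shape = c(48, 48, 48), spacing = c(4, 4, 4),
                         contrast = c("fdg_like", "met_like"), seed = 1) {
  contrast <- match.arg(contrast)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 32L))
    stop("phantom shape must be at least 32 voxels on every axis")
  spacing <- as.numeric(spacing)
  d <- shape
  origin <- c(0, 0, 0)
  center <- origin + (d - 1) / 2 * spacing
  # world coordinates relative to the brain centre
  xs <- origin[1] + (seq_len(d[1]) - 1) * spacing[1] - center[1]
  ys <- origin[2] + (seq_len(d[2]) - 1) * spacing[2] - center[2]
  zs <- origin[3] + (seq_len(d[3]) - 1) * spacing[3] - center[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  fov <- (d - 1) * spacing
  semi <- pmin(c(55, 70, 50), fov / 2 - 2 * spacing)  # cerebrum semi-axes, mm
  ux <- X / semi[1]; uy <- Y / semi[2]; uz <- Z / semi[3]
  r <- sqrt(ux^2 + uy^2 + uz^2)
  inside <- r <= 1

  # folded cortical shell: thickness modulated by seeded angular harmonics
  ph <- with_seed(seed, stats::runif(4, 0, 2 * pi))
  theta <- atan2(uy, ux)
  psi <- atan2(uz, sqrt(ux^2 + uy^2))
  thick <- 0.14 + 0.05 * sin(6 * theta + ph[1]) * cos(4 * psi + ph[2]) +
    0.03 * sin(3 * psi + ph[3])
  shell <- inside & (r >= 1 - thick)

  lab <- array(0L, d)
  lab[inside] <- .tissue_ids[["WM"]]
  ctx <- array(.tissue_ids[["CTX"]], d)
  ctx[Y > 15 & Z > -10] <- .tissue_ids[["FC"]]
  ctx[Y < -35] <- .tissue_ids[["OC"]]
  ctx[Y >= -35 & Y <= 15 & Z > 25] <- .tissue_ids[["PC"]]
  ctx[Y >= -35 & Y <= 15 & Z < -5 & abs(X) > 18] <- .tissue_ids[["TC"]]
  lab[shell] <- ctx[shell]

  ell <- function(cx, cy, cz, ax, ay, az)
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2 <= 1
  cer <- inside & ell(0, -42, -30, 30, 22, 18)
  lab[cer] <- .tissue_ids[["CER"]]
  for (s in c(-1, 1)) {
    lab[ell(s * 20, 8, 2, 9, 14, 10)] <- .tissue_ids[["STR"]]
    lab[ell(s * 10, -12, 2, 9, 11, 9)] <- .tissue_ids[["THA"]]
    lab[ell(s * 26, -16, -14, 8, 16, 8)] <- .tissue_ids[["HIP"]]
  }
  vent <- ell(-8, 2, 10, 5, 18, 7) | ell(8, 2, 10, 5, 18, 7)
  lab[vent] <- 0L

  act_tab <- .tissue_activity[[contrast]]
  act <- array(0, d)
  for (nm in names(.tissue_ids)) act[lab == .tissue_ids[[nm]]] <- act_tab[[nm]]
  act[vent & inside] <- act_tab[["VENT"]]
  # seeded smooth texture: breaks the left-right symmetry of the geometry
  # (real anatomy is asymmetric) and keeps all rotations identifiable to
  # the registration; ~12% modulation at ~10 mm scale
  tex <- with_seed(seed + 101L, array(stats::rnorm(prod(d)), d))
  tex <- gaussian_smooth(tex, fwhm_mm = 10, spacing = spacing)
  tex <- tex / stats::sd(tex)
  act <- act * (1 + 0.12 * tex)
  act[act < 0] <- 0

  labels <- roi_labels(volume_grid(lab, spacing, origin), .default_label_map())
  structure(list(activity = volume_grid(act, spacing, origin),
                 labels = labels,
                 brain_center = center,
                 contrast = contrast, seed = seed),
            class = "labeled_phantom")
}

.default_label_map <- function() {
  ids <- .tissue_ids
  base <- c("FC", "PC", "TC", "OC", "CTX", "CER", "STR", "THA", "HIP")
  gm <- unname(ids[base])
  c(lapply(ids[base], function(i) unname(i)),
    list(GM = gm, WM = unname(ids[["WM"]]), WB = unname(ids)))
}

#' @export
print.labeled_phantom <- function(x, ...) {
  cat(sprintf("<labeled_phantom> %s contrast, seed %d\n", x$contrast, x$seed))
  print(x$activity)
  cat("  ROIs:", paste(names(x$labels$map), collapse = ", "), "\n")
  invisible(x)
}

#' Motion trajectory specification
#'
#' Describes a rigid head-motion pattern over a scan: `static` (no motion),
#' `drift` (parameters linear in frame mid-time, reaching the stated
#' amplitude at scan end), `step` (identity before `event_time_s`, a
#' constant transform after), `jitter` (zero-mean seeded frame-to-frame
#' perturbations), or `composite` (sum of the above contributions).
#'
#' @param pattern One of `"static"`, `"drift"`, `"step"`, `"jitter"`,
#'   `"composite"`.
#' @param translation Target translation (mm, length 3) for drift/step.
#' @param rotation Target rotation (deg, length 3) for drift/step.
#' @param event_time_s Step time (s) for the step pattern.
#' @param jitter_sd_mm,jitter_sd_deg Per-axis jitter standard deviations.
#' @param seed Seed for the jitter component.
#' @return A `trajectory_spec`.
#' @export
trajectory_spec <- function(pattern = c("static", "drift", "step", "jitter",
                                        "composite"),
                            translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            event_time_s = NULL, jitter_sd_mm = 0,
                            jitter_sd_deg = 0, seed = 1) {
  pattern <- match.arg(pattern)
  if (any(c(jitter_sd_mm, jitter_sd_deg) < 0)) stop("jitter sds must be >= 0")
  structure(list(pattern = pattern, translation = as.numeric(translation),
                 rotation = as.numeric(rotation), event_time_s = event_time_s,
                 jitter_sd_mm = jitter_sd_mm, jitter_sd_deg = jitter_sd_deg,
                 seed = seed),
            class = "trajectory_spec")
}

#' Build a motion trajectory from a specification
#'
#' Per-frame poses are generated from the pattern, then re-expressed
#' relative to the reference frame so that the reference transform is
#' exactly identity.
#'
#' @param spec A [trajectory_spec()].
#' @param timing A [frame_timing()].
#' @param reference_index Reference frame (1-based).
#' @param center Rotation centre (world mm), typically the brain centre.
#' @return A `motion_trajectory`.
#' @export
make_trajectory <- function(spec, timing, reference_index = 1L,
                            center = c(0, 0, 0)) {
  n <- nrow(timing)
  if (reference_index < 1L || reference_index > n)
    stop("reference_index out of range")
  mid <- frame_mid_times(timing)
  scan_end <- timing$start[n] + timing$duration[n]
  if (!is.null(spec$event_time_s) &&
      (spec$event_time_s < timing$start[1] || spec$event_time_s > scan_end))
    stop("event_time_s outside the scan interval")
  par <- matrix(0, n, 6)  # columns rx,ry,rz (deg), tx,ty,tz (mm)
  add_drift <- function(par) {
    frac <- if (n == 1) rep(0, 1) else (mid - mid[1]) / (mid[n] - mid[1])
    par + outer(frac, c(spec$rotation, spec$translation))
  }
  add_step <- function(par) {
    ev <- if (is.null(spec$event_time_s)) (timing$start[1] + scan_end) / 2 else
      spec$event_time_s
    after <- mid >= ev
    par + outer(as.numeric(after), c(spec$rotation, spec$translation))
  }
  add_jitter <- function(par) {
    jit <- with_seed(spec$seed, cbind(
      matrix(stats::rnorm(3 * n, 0, spec$jitter_sd_deg), n, 3),
      matrix(stats::rnorm(3 * n, 0, spec$jitter_sd_mm), n, 3)))
    par + jit
  }
  par <- switch(spec$pattern,
                static = par,
                drift = add_drift(par),
                step = add_step(par),
                jitter = add_jitter(par),
                composite = add_jitter(add_step(add_drift(par))))
  poses <- lapply(seq_len(n), function(f)
    rigid_transform(par[f, 1:3], par[f, 4:6], center))
  ref_inv <- invert_transform(poses[[reference_index]])
  transforms <- lapply(poses, function(p) compose_transform(p, ref_inv))
  transforms[[reference_index]] <- rigid_transform(center = center)
  motion_trajectory(transforms, timing, reference_index = reference_index)
}
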