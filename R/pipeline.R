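#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end evaluation with the study
#' defaults: 70 mm probe offsets, 1/2 mm category boundaries, 16 mm / 30%
#' brain-mask parameters, 3 mm XC smoothing, 5e5 counts per frame, alpha
#' 0.05. The configuration round-trips losslessly through JSON.
#'
#' @param seed Root seed; stage seeds are derived from it.
#' @param shape,spacing Phantom grid (voxels, mm).
#' @param contrast Tracer regime, `"fdg_like"` or `"met_like"`.
#' @param pattern Trajectory pattern (see [trajectory_spec()]).
#' @param translation,rotation,event_time_s,jitter_sd_mm,jitter_sd_deg
#'   Trajectory parameters.
#' @param n_frames,frame_dur_s Frame count and duration (s).
#' @param counts_per_frame Expected events per frame.
#' @param psf_fwhm_mm Simulated PSF FWHM (mm).
#' @param noise `"poisson"` or `"none"`.
#' @param reference_time_s Reference time (s); the frame containing it is
#'   the reference frame.
#' @param probe_offset_mm Probe-point offset (mm).
#' @param boundaries_mm Category boundaries (mm).
#' @param mask_fwhm_mm,mask_frac Brain-mask smoothing and threshold.
#' @param xc_fwhm_mm XC smoothing (mm).
#' @param presmooth_fwhm_mm,multires_levels Motion-estimation settings.
#' @param alpha,m_tests Significance level and Bonferroni family size.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, shape = c(48, 48, 48), spacing = c(4, 4, 4),
                       contrast = "fdg_like", pattern = "static",
                       translation = c(0, 0, 0), rotation = c(0, 0, 0),
                       event_time_s = NULL, jitter_sd_mm = 0,
                       jitter_sd_deg = 0, n_frames = 10, frame_dur_s = 30,
                       counts_per_frame = 5e5, psf_fwhm_mm = 5,
                       noise = "poisson", reference_time_s = 0,
                       probe_offset_mm = 70, boundaries_mm = c(1, 2),
                       mask_fwhm_mm = 16, mask_frac = 0.30, xc_fwhm_mm = 3,
                       presmooth_fwhm_mm = 10, multires_levels = 2,
                       alpha = 0.05, m_tests = 11) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Run the full motion-evaluation pipeline
#'
#' Executes simulate -> estimate -> correct -> categorize -> cDTH -> XC ->
#' ROI differences on a synthetic scan described by the configuration, and
#' (optionally) writes a report directory with the category JSON, cDTH and
#' XC tables and plots, the motion plot, the relative-difference table and
#' a machine-readable summary JSON. Fully reproducible from the
#' configuration and its seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for the report bundle; `NULL` (default)
#'   skips file output.
#' @return A `pipeline_result` list: `trajectory_true`,
#'   `trajectory_estimated`, `displacements`, `category`, `cdth`,
#'   `xc_nomc`, `xc_ddmc`, `roi_rel_diff`, `summary`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stage <- "simulate"
  result <- tryCatch({
    phantom <- make_phantom(config$shape, config$spacing, config$contrast,
                            seed = config$seed)
    timing <- uniform_timing(config$n_frames, config$frame_dur_s)
    ref_idx <- select_reference_frame(list(timing = timing),
                                      config$reference_time_s)
    spec <- trajectory_spec(config$pattern, config$translation,
                            config$rotation, config$event_time_s,
                            config$jitter_sd_mm, config$jitter_sd_deg,
                            seed = config$seed + 1)
    traj_true <- make_trajectory(spec, timing, ref_idx,
                                 center = phantom$brain_center)
    series <- simulate_frames(phantom, traj_true, timing,
                              config$counts_per_frame, config$psf_fwhm_mm,
                              config$noise, seed = config$seed + 2)

    stage <- "estimate"
    traj_est <- estimate_motion(series, ref_idx,
                                presmooth_fwhm_mm = config$presmooth_fwhm_mm,
                                multires_levels = config$multires_levels,
                                center = phantom$brain_center)

    stage <- "categorize"
    disp <- probe_displacements(traj_est, phantom$brain_center,
                                config$probe_offset_mm)
    category <- categorize_motion(disp, config$boundaries_mm)
    hist <- cdth(disp)

    stage <- "correct"
    corrected <- correct_series(series, traj_est)

    stage <- "xc"
    mask <- make_brain_mask(series$frames[[ref_idx]], config$mask_fwhm_mm,
                            config$mask_frac)
    xc_nomc <- xc_series(series, ref_idx, mask, config$xc_fwhm_mm)
    xc_ddmc <- xc_series(corrected, ref_idx, mask, config$xc_fwhm_mm)

    stage <- "roidiff"
    nomc_img <- integrate_series(series, timing)
    ddmc_img <- integrate_series(corrected, timing)
    rel <- relative_diff(roi_means(ddmc_img, phantom$labels),
                         roi_means(nomc_img, phantom$labels))

    summary_list <- list(
      config = unclass(config),
      category = category$category,
      deciding_median_mm = category$deciding_median,
      deciding_point = category$deciding_point,
      median_xc_nomc = median_xc(xc_nomc),
      median_xc_ddmc = median_xc(xc_ddmc),
      roi_rel_diff_pct = as.list(rel))
    list(trajectory_true = traj_true, trajectory_estimated = traj_est,
         displacements = disp, category = category, cdth = hist,
         xc_nomc = xc_nomc, xc_ddmc = xc_ddmc, roi_rel_diff = rel,
         nomc = nomc_img, ddmc = ddmc_img, mask = mask,
         summary = summary_list)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(category = result$category$category,
                              deciding_median_mm = result$category$deciding_median,
                              deciding_point = result$category$deciding_point),
                         file.path(out_dir, "category.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(threshold_mm = result$cdth$thresholds_mm,
                 anterior = result$cdth$anterior,
                 posterior = result$cdth$posterior),
      file.path(out_dir, "cdth.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    utils::write.table(
      data.frame(frame = seq_along(result$xc_nomc$values),
                 t_mid_s = result$xc_nomc$timing$start +
                   result$xc_nomc$timing$duration / 2,
                 xc_nomc = result$xc_nomc$values,
                 xc_ddmc = result$xc_ddmc$values),
      file.path(out_dir, "xc.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    utils::write.table(
      data.frame(roi = names(result$roi_rel_diff),
                 rel_diff_pct = as.numeric(result$roi_rel_diff)),
      file.path(out_dir, "rel_diff.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    write_trajectory(result$trajectory_estimated,
                     file.path(out_dir, "trajectory_estimated.tsv"))
    for (nm in c("motion", "cdth", "xc")) {
      grDevices::png(file.path(out_dir, paste0(nm, ".png")),
                     width = 700, height = 500)
      switch(nm,
             motion = plot(result$displacements),
             cdth = plot(result$cdth),
             xc = {
               plot(result$xc_nomc, col = "grey40",
                    main = "XC over time (points: noMC, red: ddMC)")
               graphics::lines(result$xc_ddmc$timing$start +
                                 result$xc_ddmc$timing$duration / 2,
                               result$xc_ddmc$values, col = "firebrick")
             })
      grDevices::dev.off()
    }
    jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Motion-evaluation pipeline result\n")
  print(x$category)
  cat(sprintf("  median XC: noMC %.4f, ddMC %.4f\n",
              median_xc(x$xc_nomc), median_xc(x$xc_ddmc)))
  cat(sprintf("  whole-brain relative difference %.3g%%\n",
              x$roi_rel_diff[["WB"]]))
  invisible(x)
}
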