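test_that("phantom generation is deterministic and respects size limits", {
  a <- small_phantom(seed = 9)
  b <- small_phantom(seed = 9)
  expect_identical(a$activity$values, b$activity$values)
  expect_identical(a$labels$labels$values, b$labels$labels$values)
  expect_error(make_phantom(shape = c(20, 48, 48)), "at least 32")
})

test_that("phantom anatomy satisfies the labelled-region contract", {
  ph <- study_phantom(seed = 1)
  lab <- ph$labels$labels$values
  counts <- vapply(ph$labels$map, function(ids) sum(lab %in% ids), 0L)
  expect_true(all(counts >= 50))
  expect_setequal(
    c("FC", "PC", "TC", "OC", "CTX", "CER", "STR", "THA", "HIP",
      "GM", "WM", "WB"),
    names(ph$labels$map))
  # WB is the union of all labelled voxels
  expect_equal(sum(lab %in% ph$labels$map$WB), sum(lab != 0))

  m <- roi_means(ph$activity, ph$labels)
  expect_gt(m["GM"] / m["WM"], 2)
  expect_lt(m["GM"] / m["WM"], 4)
})

test_that("met-like regime scales activity on identical geometry", {
  fdg <- small_phantom(seed = 6, contrast = "fdg_like")
  met <- small_phantom(seed = 6, contrast = "met_like")
  expect_identical(fdg$labels$labels$values, met$labels$labels$values)
  expect_true(all(met$activity$values <= fdg$activity$values + 1e-12))
  expect_lte(mean(met$activity$values), 0.5 * mean(fdg$activity$values))
})

test_that("trajectory archetypes produce their defining displacement shapes", {
  center <- c(0, 0, 0)
  timing <- uniform_timing(8, 30)

  static <- make_trajectory(trajectory_spec("static"), timing, 1, center)
  d <- probe_displacements(static, center)
  expect_equal(d$anterior, rep(0, 8))
  expect_equal(d$posterior, rep(0, 8))

  # step at 50% of the scan: 0 before, the full magnitude after
  step <- make_trajectory(
    trajectory_spec("step", translation = c(0, 2.5, 0), event_time_s = 120),
    timing, 1, center)
  d <- probe_displacements(step, center)
  expect_equal(d$anterior, c(0, 0, 0, 0, 2.5, 2.5, 2.5, 2.5))

  # drift: displacement linear in frame mid-time
  drift <- make_trajectory(
    trajectory_spec("drift", translation = c(0, 0, 5)), timing, 1, center)
  d <- probe_displacements(drift, center)
  expect_equal(d$anterior, seq(0, 5, length.out = 8), tolerance = 1e-9)
  expect_equal(d$anterior, d$posterior, tolerance = 1e-9)

  # reference transform is identity for every pattern
  jit <- make_trajectory(
    trajectory_spec("jitter", jitter_sd_mm = 0.5, jitter_sd_deg = 0.2,
                    seed = 3),
    timing, reference_index = 4, center = center)
  expect_true(is_identity_transform(jit$transforms[[4]]))
  expect_error(
    make_trajectory(trajectory_spec("step", translation = c(1, 0, 0),
                                    event_time_s = 1e4), timing, 1, center),
    "outside")
})

test_that("simulated frame totals follow the constant-counts design", {
  ph <- small_phantom(seed = 5)
  timing <- uniform_timing(4, 30)
  traj <- make_trajectory(trajectory_spec("static"), timing, 1,
                          ph$brain_center)
  series <- simulate_frames(ph, traj, timing, counts_per_frame = 5e5,
                            seed = 21)
  totals <- vapply(series$frames, function(f) sum(f$values), 0)
  # Poisson with expectation 5e5: totals within 5 sigma
  expect_true(all(abs(totals - 5e5) < 5 * sqrt(5e5)))
  expect_error(simulate_frames(ph, traj, timing, counts_per_frame = 0),
               "> 0")
})

test_that("zero-noise static simulation yields identical frames that commute with integration", {
  ph <- small_phantom(seed = 5)
  timing <- uniform_timing(5, 30)
  traj <- make_trajectory(trajectory_spec("static"), timing, 1,
                          ph$brain_center)
  series <- simulate_frames(ph, traj, timing, noise = "none")
  for (f in 2:5)
    expect_equal(series$frames[[f]]$values, series$frames[[1]]$values)
  expect_equal(integrate_series(series)$values, series$frames[[1]]$values,
               tolerance = 1e-12)
  # expected counts conservation across the series
  tot <- sum(vapply(series$frames, function(f) sum(f$values), 0))
  expect_equal(tot, 5e5 * 5, tolerance = 1e-6)
})

test_that("two seeds differ in noise but share the expectation", {
  ph <- small_phantom(seed = 5)
  timing <- uniform_timing(50, 10)
  traj <- make_trajectory(trajectory_spec("static"), timing, 1,
                          ph$brain_center)
  s1 <- simulate_frames(ph, traj, timing, counts_per_frame = 2e5, seed = 1)
  s2 <- simulate_frames(ph, traj, timing, counts_per_frame = 2e5, seed = 2)
  expect_false(identical(s1$frames[[1]]$values, s2$frames[[1]]$values))
  m1 <- Reduce(`+`, lapply(s1$frames, `[[`, "values")) / 50
  m2 <- Reduce(`+`, lapply(s2$frames, `[[`, "values")) / 50
  traj1 <- make_trajectory(trajectory_spec("static"), uniform_timing(1, 10),
                           1, ph$brain_center)
  lambda <- simulate_frames(ph, traj1, counts_per_frame = 2e5,
                            noise = "none")$frames[[1]]$values
  # mean over 50 frames stays within 3 sigma of the common expectation
  brain <- lambda > 1
  se <- sqrt(lambda[brain] / 50)
  expect_gt(mean(abs(m1[brain] - lambda[brain]) < 3 * se), 0.99)
  expect_gt(mean(abs(m2[brain] - lambda[brain]) < 3 * se), 0.99)
})

test_that("met-like frames have lower gray-matter SNR than fdg-like at equal counts", {
  nrep <- 20
  timing <- uniform_timing(nrep, 10)
  snr_gm <- function(contrast) {
    ph <- small_phantom(seed = 13, contrast = contrast)
    traj <- make_trajectory(trajectory_spec("static"), timing, 1,
                            ph$brain_center)
    series <- simulate_frames(ph, traj, timing, counts_per_frame = 2e5,
                              psf_fwhm_mm = 0, seed = 31)
    gm <- ph$labels$labels$values %in% ph$labels$map$GM
    vals <- vapply(series$frames, function(f) f$values[gm], numeric(sum(gm)))
    mu <- rowMeans(vals)
    s <- apply(vals, 1, stats::sd)
    mean(mu[s > 0] / s[s > 0])
  }
  expect_lt(snr_gm("met_like"), snr_gm("fdg_like"))
})
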