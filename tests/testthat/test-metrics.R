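test_that("probe displacements follow translation and chord-length geometry", {
  center <- c(100, 100, 100)
  id <- rigid_transform(center = center)

  traj <- two_frame_trajectory(id, center)
  d <- probe_displacements(traj, center)
  expect_equal(d$anterior, c(0, 0))
  expect_equal(d$posterior, c(0, 0))

  # pure translation along the anterior axis moves both probes equally
  tr <- rigid_transform(translations = c(0, 2.5, 0), center = center)
  d <- probe_displacements(two_frame_trajectory(tr, center), center)
  expect_equal(d$anterior[2], 2.5, tolerance = 1e-12)
  expect_equal(d$posterior[2], 2.5, tolerance = 1e-12)

  # 2 degree rotation about the left-right axis through the brain centre:
  # both probes sit 70 mm from the axis
  rot <- rigid_transform(rotations = c(2, 0, 0), center = center)
  d <- probe_displacements(two_frame_trajectory(rot, center), center)
  chord <- 2 * 70 * sin(1 * pi / 180)
  expect_equal(d$anterior[2], chord, tolerance = 1e-9)
  expect_equal(d$posterior[2], chord, tolerance = 1e-9)
})

test_that("categorization applies the boundary rules and picks the larger median", {
  timing <- uniform_timing(5, 30)
  mk <- function(ant, post) displacement_series(ant, post, timing)

  zero <- mk(rep(0, 5), rep(0, 5))
  cat0 <- categorize_motion(zero)
  expect_equal(cat0$category, "low")
  expect_equal(cat0$deciding_median, 0)

  high <- categorize_motion(mk(c(0, 2.8, 2.8, 2.8, 2.8), rep(0.2, 5) * c(0, 1, 1, 1, 1)))
  expect_equal(high$category, "high")
  expect_equal(high$deciding_median, 2.8)
  expect_equal(high$deciding_point, "anterior")

  # boundary medians land in the closed middle interval
  expect_equal(categorize_motion(mk(rep(c(0, 1), c(1, 4)), rep(0, 5)))$category,
               "medium")
  expect_equal(categorize_motion(mk(rep(c(0, 2), c(1, 4)), rep(0, 5)))$category,
               "medium")
  expect_equal(categorize_motion(mk(rep(c(0, 0.999), c(1, 4)), rep(0, 5)))$category,
               "low")
  expect_equal(categorize_motion(mk(rep(c(0, 2.001), c(1, 4)), rep(0, 5)))$category,
               "high")
})

test_that("categorization agrees with a brute-force oracle on 1000 seeded series", {
  # oracle: sort-based median and explicit max, written independently
  oracle <- function(ant, post) {
    med <- function(x) {
      s <- sort(x); n <- length(s)
      if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    }
    m <- if (med(ant) >= med(post)) med(ant) else med(post)
    if (m < 1) "low" else if (m > 2) "high" else "medium"
  }
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    ant <- c(0, runif(n - 1, 0, 4))
    post <- c(0, runif(n - 1, 0, 4))
    d <- displacement_series(ant, post, uniform_timing(n, 30))
    expect_identical(categorize_motion(d)$category, oracle(ant, post))
  }
})

test_that("scaling displacements up never lowers the category", {
  set.seed(77)
  rank_of <- c(low = 1, medium = 2, high = 3)
  for (i in 1:50) {
    n <- sample(3:9, 1)
    ant <- c(0, runif(n - 1, 0, 3))
    post <- c(0, runif(n - 1, 0, 3))
    timing <- uniform_timing(n, 30)
    base <- categorize_motion(displacement_series(ant, post, timing))
    up <- categorize_motion(displacement_series(1.7 * ant, 1.7 * post, timing))
    expect_gte(rank_of[[up$category]], rank_of[[base$category]])
  }
})

test_that("cDTH is a normalized, monotone, duration-weighted cumulative curve", {
  timing <- uniform_timing(4, 30)
  d <- displacement_series(c(0, 0.5, 2.5, 2.5), c(0, 0.5, 0.5, 2.5), timing)
  h <- cdth(d)
  expect_equal(h$thresholds_mm[1], 0)
  expect_true(all(diff(h$anterior) >= 0))
  expect_true(all(diff(h$posterior) >= 0))
  expect_equal(h$anterior[length(h$anterior)], 1, tolerance = 1e-12)
  # half the frames at 0.5 mm or 0 mm: fraction at 1.0 mm is 0.5
  at <- function(th) h$anterior[which.min(abs(h$thresholds_mm - th))]
  expect_equal(at(1.0), 0.5)
  expect_equal(at(3.0), 1.0)

  # static: fraction 1 already at threshold 0
  h0 <- cdth(displacement_series(rep(0, 4), rep(0, 4), timing))
  expect_equal(h0$anterior[1], 1)

  # duration weighting: a long frame dominates the curve
  tw <- frame_timing(c(0, 30), c(30, 90))
  hw <- cdth(displacement_series(c(0, 3), c(0, 0), tw))
  expect_equal(hw$anterior[which.min(abs(hw$thresholds_mm - 1))], 0.25)
})

test_that("cDTH is invariant to frame order and obeys median-quantile duality", {
  set.seed(9)
  n <- 7  # odd: the median is an attained displacement
  ant <- c(0, runif(n - 1, 0, 4))
  post <- c(0, runif(n - 1, 0, 4))
  timing <- uniform_timing(n, 30)
  h <- cdth(displacement_series(ant, post, timing))
  # reorder the non-reference frames (the reference stays first so the
  # constructor's zero-at-reference invariant holds)
  perm <- c(1, sample(2:n))
  h2 <- cdth(displacement_series(ant[perm], post[perm], timing))
  expect_equal(h$anterior, h2$anterior)
  expect_equal(h$posterior, h2$posterior)

  d <- displacement_series(ant, post, timing)
  ct <- categorize_motion(d)
  dec <- if (ct$deciding_point == "anterior") h$anterior else h$posterior
  at_median <- dec[min(which(h$thresholds_mm >= ct$deciding_median - 1e-9))]
  expect_gte(at_median, 0.5)
})

test_that("motion plots render displacement curves to file", {
  timing <- uniform_timing(6, 30)
  d <- displacement_series(c(0, 1, 2, 3, 4, 5), rep(0, 6), timing)
  path <- tempfile(fileext = ".png")
  grDevices::png(path, width = 400, height = 300)
  plot(d)
  grDevices::dev.off()
  expect_true(file.exists(path) && file.size(path) > 0)
  # drift fixture: the underlying curve is monotone
  expect_true(all(diff(d$anterior) > 0))

  path2 <- tempfile(fileext = ".png")
  grDevices::png(path2, width = 400, height = 300)
  plot(cdth(d))
  grDevices::dev.off()
  expect_true(file.exists(path2) && file.size(path2) > 0)
})
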