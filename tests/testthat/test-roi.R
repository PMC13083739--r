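toy_labels <- function() {
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, , ] <- 1L
  lab[3:4, , ] <- 2L
  roi_labels(volume_grid(lab, c(1, 1, 1)),
             list(A = 1L, B = 2L, BOTH = c(1L, 2L)))
}

test_that("roi_means averages per region and unions of labels", {
  labs <- toy_labels()
  uni <- volume_grid(array(5, c(4, 4, 4)), c(1, 1, 1))
  m <- roi_means(uni, labs)
  expect_equal(unname(m[c("A", "B", "BOTH")]), c(5, 5, 5))

  split <- volume_grid(array(rep(c(1, 1, 3, 3), times = 16), c(4, 4, 4)),
                       c(1, 1, 1))
  m2 <- roi_means(split, labs)
  expect_equal(unname(m2["A"]), 1)
  expect_equal(unname(m2["B"]), 3)
  expect_equal(unname(m2["BOTH"]), 2)

  # checkerboard fixture against a voxel-loop oracle
  set.seed(10)
  v <- volume_grid(array(rnorm(64), c(4, 4, 4)), c(1, 1, 1))
  oracle <- function(ids) {
    tot <- 0; n <- 0
    for (i in seq_along(v$values))
      if (labs$labels$values[i] %in% ids) { tot <- tot + v$values[i]; n <- n + 1 }
    tot / n
  }
  m3 <- roi_means(v, labs)
  expect_equal(unname(m3["A"]), oracle(1L))
  expect_equal(unname(m3["BOTH"]), oracle(c(1L, 2L)))

  empty <- roi_labels(labs$labels, list(A = 1L, GONE = 99L))
  expect_error(roi_means(uni, empty), "GONE")
})

test_that("relative_diff implements (ddMC - noMC)/ddMC x 100 with sign convention", {
  dd <- structure(c(WB = 10.0, FC = 2.0, WM = 0), class = "roi_table")
  no <- structure(c(WB = 9.9, FC = 2.5, WM = 1), class = "roi_table")
  rel <- relative_diff(dd, no)
  expect_equal(unname(rel["WB"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(rel["FC"]), -25, tolerance = 1e-12)
  expect_true(is.na(rel["WM"]))  # undefined where the corrected mean is 0

  same <- relative_diff(dd, dd)
  expect_equal(unname(same[c("WB", "FC")]), c(0, 0))

  # swap antisymmetry, checked against direct evaluation of the formula
  swapped <- relative_diff(no, dd)
  expect_equal(unname(swapped["FC"]),
               (2.5 - 2.0) / 2.5 * 100, tolerance = 1e-12)
})

test_that("group summaries use interpolated quartiles and ignore scan order", {
  g <- group_summary(c(1, 2, 3, 4, 5), rep("high", 5))
  expect_equal(g$median, 3)
  expect_equal(g$q1, 2)
  expect_equal(g$q3, 4)

  single <- group_summary(2.5, "low")
  expect_equal(single$median, 2.5)
  expect_equal(single$q1, single$q3)

  set.seed(14)
  vals <- rnorm(100)
  grp <- sample(c("low", "medium", "high"), 100, replace = TRUE)
  a <- group_summary(vals, grp)
  perm <- sample(100)
  b <- group_summary(vals[perm], grp[perm])
  b <- b[match(a$group, b$group), ]
  expect_equal(a$median, b$median)
  expect_equal(a$q1, b$q1)
  # sort-based oracle for one group
  x <- sort(vals[grp == "high"])
  expect_equal(a$median[a$group == "high"],
               stats::quantile(x, 0.5, type = 7, names = FALSE))
})

test_that("exact Mann-Whitney p-values match the stated enumerations", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$p_value, 2 / 20, tolerance = 1e-12)

  same <- mann_whitney_u(c(2, 2, 2), c(2, 2))
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  ident <- mann_whitney_u(c(1, 5, 9), c(1, 5, 9))
  expect_equal(ident$p_value, 1, tolerance = 1e-12)
})

test_that("exact p agrees with full bitmask enumeration for all combined n <= 10", {
  # independent oracle: iterate every subset assignment via bitmasks and
  # count U by direct pairwise comparison with half-credit for ties
  oracle_p <- function(a, b) {
    pooled <- c(a, b); n <- length(pooled); na <- length(a)
    u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    u_obs <- u_of(a, b)
    us <- c()
    for (m in 0:(2^n - 1)) {
      idx <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
      if (length(idx) != na) next
      us <- c(us, u_of(pooled[idx], pooled[-idx]))
    }
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  set.seed(20)
  for (na in 1:5) for (nb in na:(10 - na)) {
    a <- round(runif(na, 0, 4), 1)  # rounding induces occasional ties
    b <- round(runif(nb, 0, 4), 1)
    expect_equal(mann_whitney_u(a, b)$p_value, oracle_p(a, b),
                 tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("tie-free exact p matches wilcox.test's exact two-sided p", {
  set.seed(33)
  for (i in 1:10) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1))
    ours <- mann_whitney_u(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(8)
  a <- rnorm(15); b <- rnorm(15, 1)
  r <- mann_whitney_u(a, b)
  expect_equal(r$method, "normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-6)
})

test_that("Bonferroni flags significance at alpha over the family size", {
  p <- c(CER = 0.004, FC = 0.02, WB = 0.01)
  out <- bonferroni(p, alpha = 0.05, m = 11)
  expect_true(out$significant[out$roi == "CER"])    # 0.004 < 0.004545
  expect_false(out$significant[out$roi == "FC"])    # 0.02 > 0.004545
  expect_true(bonferroni(c(x = 0.01), m = 1)$significant)
})

test_that("registration QC passes at exactly 1 mm and fails just above", {
  expect_true(registration_qc(c(1, 2, 3), c(1, 2, 3))$pass)
  expect_equal(registration_qc(c(1, 2, 3), c(1, 2, 3))$difference_mm, 0)

  r <- registration_qc(c(0.6, 0.8, 0), c(0, 0, 0))
  expect_equal(r$difference_mm, 1.0, tolerance = 1e-12)
  expect_true(r$pass)  # boundary inclusive

  expect_false(registration_qc(c(0, 0, 1.01), c(0, 0, 0))$pass)
  expect_error(registration_qc(c(1, 2), c(1, 2, 3)), "length 3")
})
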