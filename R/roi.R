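#' ROI label map
#'
#' An integer label volume plus a mapping from ROI names to the label ids
#' they comprise. Composite ROIs (whole brain, grey matter, white matter)
#' are expressed as unions of base labels.
#'
#' @param labels A `volume_grid` of integer labels (0 = unlabeled).
#' @param map Named list: ROI name -> integer vector of label ids.
#' @return A `roi_labels` object.
#' @export
roi_labels <- function(labels, map) {
  if (!inherits(labels, "volume_grid")) stop("'labels' must be a volume_grid")
  if (is.null(names(map)) || any(names(map) == ""))
    stop("'map' must be a fully named list")
  structure(list(labels = labels, map = lapply(map, as.integer)),
            class = "roi_labels")
}

#' Mean signal per region of interest
#'
#' Arithmetic mean of the voxel values inside each ROI of the label map;
#' composite ROIs are computed over the union of their label ids.
#'
#' @param v A `volume_grid` aligned with the label map.
#' @param labels A [roi_labels()] object.
#' @return An `roi_table`: named numeric vector of means with an
#'   `n_voxels` attribute.
#' @export
roi_means <- function(v, labels) {
  if (!grids_aligned(v, labels$labels))
    stop("volume and label map grids are not aligned")
  lab <- labels$labels$values
  out <- numeric(length(labels$map))
  nv <- integer(length(labels$map))
  names(out) <- names(nv) <- names(labels$map)
  for (nm in names(labels$map)) {
    sel <- lab %in% labels$map[[nm]]
    if (!any(sel)) stop("ROI '", nm, "' has no voxels")
    out[nm] <- mean(v$values[sel])
    nv[nm] <- sum(sel)
  }
  structure(out, n_voxels = nv, class = "roi_table")
}

#' @export
print.roi_table <- function(x, ...) {
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Relative signal difference between corrected and uncorrected images
#'
#' Per ROI: (ddMC - noMC) / ddMC x 100. Positive values mean the corrected
#' image has the higher signal. ROIs whose corrected mean is exactly zero
#' are reported as `NA`.
#'
#' @param ddmc,nomc `roi_table` objects over the same ROI set (corrected
#'   and uncorrected means respectively).
#' @return Named numeric vector of relative differences in percent.
#' @export
relative_diff <- function(ddmc, nomc) {
  if (!setequal(names(ddmc), names(nomc)))
    stop("ROI sets differ between the two tables")
  nomc <- nomc[names(ddmc)]
  out <- ifelse(as.numeric(ddmc) == 0, NA_real_,
                (as.numeric(ddmc) - as.numeric(nomc)) / as.numeric(ddmc) * 100)
  stats::setNames(out, names(ddmc))
}

#' Median and interquartile range per group
#'
#' Summarises per-scan relative differences by group (e.g. motion category
#' x tracer regime). Quartiles use linear interpolation between order
#' statistics (quantile type 7).
#'
#' @param values Numeric vector of per-scan values (one ROI).
#' @param group Factor/character vector of group labels, same length.
#' @return Data frame with columns `group`, `n`, `median`, `q1`, `q3`.
#' @export
group_summary <- function(values, group) {
  if (length(values) != length(group)) stop("lengths differ")
  keep <- !is.na(values)
  values <- values[keep]; group <- as.character(group)[keep]
  if (!length(values)) stop("no usable values")
  groups <- unique(group)
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- values[group == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(x), median = q[2], q1 = q[1], q3 = q[3])
  }))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. For combined sample sizes up to
#' `exact_max` the two-sided p-value is exact: the U statistic's null
#' distribution is enumerated over all combinations of group labels, and
#' p = min(1, 2 min(P(U <= u), P(U >= u))). Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest combined n for which full enumeration is used
#'   (default 20).
#' @return An `mwu_result`: list with `U` (statistic of sample `a`),
#'   `p_value`, `method` (`"exact"` or `"normal"`), and `degenerate`
#'   (`TRUE` when all pooled values are identical, in which case p = 1).
#' @export
mann_whitney_u <- function(a, b, exact_max = 20L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be nonempty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(structure(list(U = U, p_value = 1, method = "degenerate",
                          degenerate = TRUE), class = "mwu_result"))
  if (n <= exact_max) {
    combos <- utils::combn(n, na)
    u_all <- apply(combos, 2, function(idx)
      sum(r[idx]) - na * (na + 1) / 2)
    eps <- 1e-9
    p_lo <- mean(u_all <= U + eps)
    p_hi <- mean(u_all >= U - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    z <- (U - mu - sign(U - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(U = U, p_value = p, method = method, degenerate = FALSE),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-sided p = %.4g (%s)\n",
              x$U, x$p_value, x$method))
  invisible(x)
}

#' Bonferroni adjustment over a family of tests
#'
#' @param p_values Named numeric vector of two-sided p-values (one per ROI).
#' @param alpha Family-wise significance level (default 0.05).
#' @param m Family size; defaults to the number of tests supplied (the
#'   study design uses 11 ROIs per comparison family).
#' @return Data frame with columns `p_value`, `alpha_adjusted`,
#'   `significant` (p < alpha / m).
#' @export
bonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
  if (m < 1) stop("m must be >= 1")
  data.frame(roi = names(p_values), p_value = as.numeric(p_values),
             alpha_adjusted = alpha / m,
             significant = as.numeric(p_values) < alpha / m,
             row.names = NULL)
}

#' Registration quality-control criterion
#'
#' Compares two displacement vectors of a point source; registration passes
#' when the Euclidean norm of their difference is at most `tol_mm`
#' (boundary inclusive).
#'
#' @param disp_a,disp_b Length-3 displacement vectors (mm).
#' @param tol_mm Tolerance in mm (default 1).
#' @return List with `pass` (logical) and `difference_mm` (magnitude).
#' @export
registration_qc <- function(disp_a, disp_b, tol_mm = 1.0) {
  disp_a <- as.numeric(disp_a); disp_b <- as.numeric(disp_b)
  if (length(disp_a) != 3L || length(disp_b) != 3L ||
      any(!is.finite(c(disp_a, disp_b))))
    stop("displacement vectors must be finite and of length 3")
  mag <- sqrt(sum((disp_a - disp_b)^2))
  list(pass = mag <= tol_mm, difference_mm = mag)
}
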