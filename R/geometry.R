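#' Volumetric image on a regular grid
#'
#' The universal image carrier of the package: a 3-D scalar field on an
#' axis-aligned regular grid in RAS world coordinates (mm). `origin` is the
#' world coordinate of the centre of voxel (1,1,1).
#'
#' @param values Numeric 3-D array.
#' @param spacing Per-axis voxel size in mm (length 3, strictly positive).
#' @param origin World coordinate (mm) of the first voxel centre (length 3).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array")
  if (any(dim(values) == 0L))
    stop("degenerate grid: every axis must have length >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  if (any(!is.finite(values)))
    stop("'values' must be finite everywhere")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  value range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Test whether two grids share the same lattice
#'
#' Two grids are aligned iff shape, spacing and origin match exactly.
#' @param a,b `volume_grid` objects.
#' @return Logical scalar.
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all(a$spacing == b$spacing)) &&
    isTRUE(all(a$origin == b$origin))
}

# world coordinates of all voxel centres, as an n x 3 matrix (column-major
# voxel order, matching as.vector on the values array)
voxel_world_coords <- function(v) {
  d <- dim(v$values)
  xs <- v$origin[1] + (seq_len(d[1]) - 1) * v$spacing[1]
  ys <- v$origin[2] + (seq_len(d[2]) - 1) * v$spacing[2]
  zs <- v$origin[3] + (seq_len(d[3]) - 1) * v$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Rigid-body transform (6 degrees of freedom)
#'
#' Rotation angles are extrinsic, in degrees, applied in the order
#' Rz %*% Ry %*% Rx about the world axes; the rotation is taken about an
#' explicit `center` (mm). The transform maps reference-space world
#' coordinates into frame space:
#' `p -> R (p - center) + center + translation`.
#'
#' @param rotations Angles in degrees about the x, y, z axes (length 3).
#' @param translations Offsets in mm (length 3).
#' @param center Rotation centre in world mm (length 3).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotations <- as.numeric(rotations)
  translations <- as.numeric(translations)
  center <- as.numeric(center)
  stopifnot(length(rotations) == 3L, length(translations) == 3L,
            length(center) == 3L)
  if (any(!is.finite(c(rotations, translations, center))))
    stop("transform parameters must be finite")
  structure(list(rotations = rotations, translations = translations,
                 center = center),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (%.4g, %.4g, %.4g) deg, trans (%.4g, %.4g, %.4g) mm, center (%g, %g, %g) mm\n",
              x$rotations[1], x$rotations[2], x$rotations[3],
              x$translations[1], x$translations[2], x$translations[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#'
#' Builds the 3x3 matrix Rz(rz) Ry(ry) Rx(rx) from angles in degrees.
#' @param rotations Angles in degrees about x, y, z.
#' @return 3x3 orthonormal matrix.
#' @export
rotation_matrix <- function(rotations) {
  a <- rotations * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Euler angles (degrees, Rz Ry Rx convention) from a rotation matrix.
# Small rigid head motions stay far from gimbal lock.
euler_from_matrix <- function(R) {
  beta <- asin(max(-1, min(1, -R[3, 1])))
  alpha <- atan2(R[3, 2], R[3, 3])
  gamma <- atan2(R[2, 1], R[1, 1])
  c(alpha, beta, gamma) * 180 / pi
}

#' Apply a rigid transform to world points
#'
#' @param t A `rigid_transform`.
#' @param p A length-3 world point (mm) or an n x 3 matrix of points.
#' @return Transformed point(s), same shape as the input.
#' @export
apply_transform <- function(t, p) {
  R <- rotation_matrix(t$rotations)
  if (is.matrix(p)) {
    out <- sweep(p, 2, t$center) %*% t(R)
    sweep(out, 2, t$center + t$translations, `+`)
  } else {
    as.numeric(R %*% (p - t$center) + t$center + t$translations)
  }
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`:
#' the result satisfies
#' `apply_transform(compose_transform(a, b), p) == apply_transform(a, apply_transform(b, p))`.
#' Both transforms must share the same rotation centre.
#'
#' @param a,b `rigid_transform` objects with identical centres.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  if (!isTRUE(all(a$center == b$center)))
    stop("transforms must share the same rotation center")
  Ra <- rotation_matrix(a$rotations)
  Rb <- rotation_matrix(b$rotations)
  R <- Ra %*% Rb
  rigid_transform(rotations = euler_from_matrix(R),
                  translations = as.numeric(Ra %*% b$translations) + a$translations,
                  center = a$center)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse `rigid_transform` (same centre).
#' @export
invert_transform <- function(t) {
  R <- rotation_matrix(t$rotations)
  rigid_transform(rotations = euler_from_matrix(t(R)),
                  translations = as.numeric(-t(R) %*% t$translations),
                  center = t$center)
}

#' Identity test for a rigid transform
#' @param t A `rigid_transform`.
#' @param tol Absolute tolerance on parameters.
#' @return Logical scalar.
#' @export
is_identity_transform <- function(t, tol = 1e-9) {
  all(abs(t$rotations) < tol) && all(abs(t$translations) < tol)
}

#' Resample a volume through a rigid transform
#'
#' Pull-back resampling onto the input's own lattice: each output voxel at
#' world position x takes the value of `v` interpolated at the
#' transform-mapped location `t(x)`. Samples falling outside the field of
#' view are set to 0. Nearest-neighbour mode preserves the input value set.
#'
#' @param v A `volume_grid`.
#' @param t A `rigid_transform`.
#' @param interpolation `"trilinear"` (default), `"nearest"`, or `"cubic"`
#'   (Keys cubic convolution; used internally by the registration, where
#'   linear interpolation's offset-dependent high-frequency attenuation
#'   would bias the similarity optimum).
#' @return A `volume_grid` aligned with `v`.
#' @export
resample <- function(v, t, interpolation = c("trilinear", "nearest", "cubic")) {
  interpolation <- match.arg(interpolation)
  d <- dim(v$values)
  if (any(d == 0L)) stop("degenerate grid: zero-length axis")
  out <- if (interpolation == "cubic")
    cpp_resample_cubic(as.numeric(v$values), as.integer(d), v$spacing,
                       v$origin, rotation_matrix(t$rotations), t$center,
                       t$translations)
  else
    cpp_resample(as.numeric(v$values), as.integer(d), v$spacing,
                 v$origin, rotation_matrix(t$rotations), t$center,
                 t$translations, interpolation == "nearest")
  volume_grid(array(out, d), v$spacing, v$origin)
}

# block-mean downsampling by an integer factor (multi-resolution registration)
downsample_volume <- function(v, factor = 2L) {
  d <- dim(v$values)
  nd <- pmax(1L, d %/% factor)
  acc <- array(0, nd)
  cnt <- array(0, nd)
  idx1 <- pmin((seq_len(d[1]) - 1L) %/% factor + 1L, nd[1])
  idx2 <- pmin((seq_len(d[2]) - 1L) %/% factor + 1L, nd[2])
  idx3 <- pmin((seq_len(d[3]) - 1L) %/% factor + 1L, nd[3])
  # accumulate along each axis in turn via rowsum on matricised views
  m <- v$values; dim(m) <- c(d[1], d[2] * d[3])
  m <- rowsum(m, idx1)
  dim(m) <- c(nd[1], d[2], d[3])
  m <- aperm(m, c(2, 1, 3)); dim(m) <- c(d[2], nd[1] * d[3])
  m <- rowsum(m, idx2)
  dim(m) <- c(nd[2], nd[1], d[3]); m <- aperm(m, c(2, 1, 3))
  dim(m) <- c(nd[1] * nd[2], d[3])
  m <- t(rowsum(t(m), idx3))
  dim(m) <- nd
  nper <- tabulate(idx1, nd[1]) %o% tabulate(idx2, nd[2]) %o% tabulate(idx3, nd[3])
  # voxel centres of the coarse grid sit at the mean of the fine centres
  off <- (factor - 1) / 2 * v$spacing
  volume_grid(m / nper, v$spacing * factor, v$origin + off)
}
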