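#' Read a volume from a NIfTI-1 file
#'
#' Loads a 3-D NIfTI image as a `volume_grid`. The on-disk orientation is
#' forced to RAS on load; oblique (non-axis-aligned) orientations raise an
#' error.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `volume_grid`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(dim(img)), " dimensions")
  RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  sp <- sqrt(colSums(rot^2))
  if (max(abs(rot - diag(sp))) > 1e-4 * max(sp))
    stop("non-orthogonal (oblique) NIfTI orientation is not supported")
  volume_grid(array(as.numeric(img), dim(img)), spacing = sp,
              origin = aff[1:3, 4])
}

#' Write a volume to a NIfTI-1 file
#'
#' @param v A `volume_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  arr <- v$values
  attr(arr, "pixdim") <- v$spacing
  img <- RNifti::asNifti(arr)
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 4-D frame series to NIfTI plus a timing TSV
#'
#' @param series A `dynamic_series`.
#' @param path Output NIfTI path; the timing table goes to
#'   `paste0(path, ".timing.tsv")` unless `timing_path` is given.
#' @param timing_path Optional explicit timing TSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, timing_path = paste0(path, ".timing.tsv")) {
  fr <- series$frames
  d <- dim(fr[[1]]$values)
  arr <- array(0, c(d, length(fr)))
  for (f in seq_along(fr)) arr[, , , f] <- fr[[f]]$values
  attr(arr, "pixdim") <- fr[[1]]$spacing
  img <- RNifti::asNifti(arr)
  aff <- diag(c(fr[[1]]$spacing, 1))
  aff[1:3, 4] <- fr[[1]]$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  utils::write.table(series$timing, timing_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 4-D NIfTI frame series with its timing TSV
#'
#' @param path NIfTI path.
#' @param timing_path Timing TSV path (columns `start`, `duration`, seconds).
#' @return A `dynamic_series`.
#' @export
read_series <- function(path, timing_path = paste0(path, ".timing.tsv")) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4-D NIfTI series")
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  timing <- utils::read.delim(timing_path)
  timing <- frame_timing(timing$start, timing$duration)
  arr <- array(as.numeric(img), dim(img))
  frames <- lapply(seq_len(dim(arr)[4]), function(f)
    volume_grid(arr[, , , f], spacing = sp, origin = aff[1:3, 4]))
  dynamic_series(frames, timing)
}

.trajectory_columns <- c("frame_index", "t_start_s", "t_dur_s",
                         "rx_deg", "ry_deg", "rz_deg",
                         "tx_mm", "ty_mm", "tz_mm",
                         "cx_mm", "cy_mm", "cz_mm")

#' Write a motion trajectory as TSV
#'
#' One row per frame with columns frame_index, t_start_s, t_dur_s, rx_deg,
#' ry_deg, rz_deg, tx_mm, ty_mm, tz_mm, cx_mm, cy_mm, cz_mm. Rotations are
#' extrinsic Rz Ry Rx in degrees about the stated centre (a header comment
#' records the convention and the reference frame).
#'
#' @param traj A `motion_trajectory`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  n <- length(traj$transforms)
  tab <- data.frame(
    frame_index = seq_len(n),
    t_start_s = traj$timing$start,
    t_dur_s = traj$timing$duration,
    rx_deg = vapply(traj$transforms, function(t) t$rotations[1], 0),
    ry_deg = vapply(traj$transforms, function(t) t$rotations[2], 0),
    rz_deg = vapply(traj$transforms, function(t) t$rotations[3], 0),
    tx_mm = vapply(traj$transforms, function(t) t$translations[1], 0),
    ty_mm = vapply(traj$transforms, function(t) t$translations[2], 0),
    tz_mm = vapply(traj$transforms, function(t) t$translations[3], 0),
    cx_mm = vapply(traj$transforms, function(t) t$center[1], 0),
    cy_mm = vapply(traj$transforms, function(t) t$center[2], 0),
    cz_mm = vapply(traj$transforms, function(t) t$center[3], 0))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# rigid transforms, extrinsic Rz*Ry*Rx, degrees/mm, reference_index=%d",
    traj$reference_index), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a motion trajectory TSV
#'
#' @param path TSV written by [write_trajectory()] (or any file with the
#'   same columns).
#' @param reference_index Reference frame; defaults to the value recorded in
#'   the header comment, else the frame closest to identity.
#' @return A `motion_trajectory`.
#' @export
read_trajectory <- function(path, reference_index = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(reference_index) && grepl("reference_index=", first))
    reference_index <- as.integer(sub(".*reference_index=(\\d+).*", "\\1", first))
  tab <- utils::read.delim(path, comment.char = "#")
  missing_cols <- setdiff(.trajectory_columns, names(tab))
  if (length(missing_cols))
    stop("trajectory TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  transforms <- lapply(seq_len(nrow(tab)), function(i)
    rigid_transform(rotations = c(tab$rx_deg[i], tab$ry_deg[i], tab$rz_deg[i]),
                    translations = c(tab$tx_mm[i], tab$ty_mm[i], tab$tz_mm[i]),
                    center = c(tab$cx_mm[i], tab$cy_mm[i], tab$cz_mm[i])))
  if (is.null(reference_index)) {
    mag <- vapply(transforms, function(t)
      sum(abs(t$rotations)) + sum(abs(t$translations)), 0)
    reference_index <- which.min(mag)
  }
  motion_trajectory(transforms,
                    frame_timing(tab$t_start_s, tab$t_dur_s),
                    reference_index = reference_index)
}

#' Read an ROI label map from NIfTI plus a name table
#'
#' @param path Label NIfTI (integer voxel values).
#' @param names_path TSV with columns `roi` and `labels` (labels a
#'   comma-separated list of integer ids belonging to that ROI).
#' @return A `roi_labels` object (see [roi_labels()]).
#' @export
read_labels <- function(path, names_path) {
  vol <- read_volume(path)
  tab <- utils::read.delim(names_path)
  if (!all(c("roi", "labels") %in% names(tab)))
    stop("label names TSV needs columns 'roi' and 'labels'")
  map <- lapply(strsplit(as.character(tab$labels), ","), as.integer)
  names(map) <- tab$roi
  present <- sort(unique(as.integer(vol$values)))
  known <- sort(unique(unlist(map)))
  unknown <- setdiff(setdiff(present, 0L), known)
  if (length(unknown))
    stop("label map contains unknown ROI id(s) ",
         paste(unknown, collapse = ", "), "; known ids: ",
         paste(known, collapse = ", "))
  roi_labels(vol, map)
}

# restore-on-exit seeded evaluation; NULL seed leaves the RNG stream alone
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  code
}
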