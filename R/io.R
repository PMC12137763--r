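#' Construct a multi-echo volume
#'
#' Container for a 4D magnitude multi-echo gradient-echo acquisition: the
#' signal grid (x, y, z, echo), the echo-time schedule in milliseconds, the
#' voxel geometry, and optional subject metadata. Echo times live alongside
#' the data (not in the NIfTI header) because NIfTI-1 has no standard
#' multi-echo timing field.
#'
#' @param signal 4D numeric array of non-negative magnitudes, echoes on the
#'   4th axis, in arbitrary scanner units.
#' @param echo_times Strictly increasing positive echo times in ms; length
#'   must equal `dim(signal)[4]`.
#' @param voxel_dims Three positive voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform; passed through unchanged.
#' @param ga_weeks Optional gestational age at scan, decimal weeks.
#' @return An object of class `multi_echo_volume`.
#' @export
multi_echo_volume <- function(signal, echo_times,
                              voxel_dims = c(3.125, 3.125, 3),
                              affine = NULL, ga_weeks = NULL) {
  signal <- unclass(signal)
  attributes(signal) <- list(dim = dim(signal))
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array (x, y, z, echo); got ",
         length(dim(signal)), " dimensions", call. = FALSE)
  echo_times <- as.numeric(echo_times)
  if (dim(signal)[4] != length(echo_times))
    stop("echo count mismatch: signal has ", dim(signal)[4],
         " echoes but echo_times has length ", length(echo_times),
         call. = FALSE)
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("echo_times must be positive and strictly increasing", call. = FALSE)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(voxel_dims) != 3L || any(voxel_dims <= 0))
    stop("voxel_dims must be three positive lengths in mm", call. = FALSE)
  if (any(!is.finite(signal)))
    stop("signal contains non-finite values", call. = FALSE)
  if (any(signal < 0))
    stop("signal contains negative values; magnitude data expected ",
         "(read_multi_echo clamps interpolation artifacts)", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_dims, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  structure(list(signal = signal, echo_times = echo_times,
                 voxel_dims = voxel_dims, affine = affine,
                 ga_weeks = if (is.null(ga_weeks)) NULL else as.numeric(ga_weeks),
                 n_clamped = 0L),
            class = "multi_echo_volume")
}

#' @export
print.multi_echo_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("<multi_echo_volume> ", paste(d[1:3], collapse = "x"),
      " voxels, ", d[4], " echoes (TE = ",
      paste(x$echo_times, collapse = ", "), " ms)\n", sep = "")
  cat("  voxel size ", paste(x$voxel_dims, collapse = " x "), " mm",
      if (!is.null(x$ga_weeks)) paste0("; GA ", x$ga_weeks, " weeks"),
      "\n", sep = "")
  invisible(x)
}

spatial_dim <- function(volume) dim(volume$signal)[1:3]

#' Read a 4D multi-echo NIfTI volume
#'
#' Reads a 4D magnitude NIfTI file and attaches the echo-time schedule
#' supplied by the caller (from a sidecar or CLI flag). Voxel dimensions and
#' the affine come from the file header. Negative values, which can arise
#' from reconstruction interpolation, are clamped to zero and counted; such
#' samples fall below any positive signal floor and are excluded from fits.
#'
#' @param path Path to a readable 4D NIfTI (.nii/.nii.gz) file.
#' @param echo_times Echo times in ms; length must match the 4th dimension.
#' @param ga_weeks Optional gestational age in decimal weeks.
#' @return A [multi_echo_volume()] with `n_clamped` recording how many
#'   samples were clamped to zero.
#' @export
read_multi_echo <- function(path, echo_times, ga_weeks = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D multi-echo file, got ", length(dim(arr)),
         "D: ", path, call. = FALSE)
  if (dim(arr)[4] != length(echo_times))
    stop("echo count mismatch: file has ", dim(arr)[4],
         " volumes but echo_times has length ", length(echo_times),
         call. = FALSE)
  n_clamped <- sum(arr < 0)
  if (n_clamped > 0) {
    arr[arr < 0] <- 0
    message("read_multi_echo: clamped ", n_clamped,
            " negative samples to 0")
  }
  vol <- multi_echo_volume(
    signal = arr * 1.0, echo_times = echo_times,
    voxel_dims = RNifti::pixdim(img)[1:3],
    affine = RNifti::xform(img), ga_weeks = ga_weeks)
  vol$n_clamped <- n_clamped
  vol
}

nifti_from_array <- function(arr, voxel_dims, affine) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxel_dims, rep(1, nd - 3L))
  aff <- structure(matrix(as.numeric(affine), 4, 4), code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  img
}

#' Write a multi-echo volume to NIfTI
#'
#' @param volume A [multi_echo_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_multi_echo <- function(volume, path) {
  stopifnot(inherits(volume, "multi_echo_volume"))
  RNifti::writeNifti(nifti_from_array(volume$signal, volume$voxel_dims,
                                      volume$affine), path)
  invisible(path)
}

#' Construct an organ mask
#'
#' Binary 3D mask aligned voxel-for-voxel with a companion multi-echo volume
#' (no resampling: maps and masks share one acquisition grid).
#'
#' @param grid 3D array; values must be exactly 0 or 1 after binarization.
#' @param organ `"fetal_brain"` or `"placenta"`.
#' @param source Provenance: `"manual"`, `"automatic"` or `"phantom_truth"`.
#' @return An object of class `organ_mask`.
#' @export
organ_mask <- function(grid, organ, source) {
  organ <- match.arg(organ, ORGANS)
  source <- match.arg(source, MASK_SOURCES)
  if (length(dim(grid)) != 3L)
    stop("mask grid must be 3D", call. = FALSE)
  g <- array(as.integer(grid >= 0.5), dim = dim(grid))
  if (sum(g) == 0L)
    warning("organ mask for ", organ, " has no foreground voxels",
            call. = FALSE)
  structure(list(grid = g, organ = organ, source = source),
            class = "organ_mask")
}

#' @export
print.organ_mask <- function(x, ...) {
  cat("<organ_mask> ", x$organ, " (", x$source, "): ", sum(x$grid),
      " voxels in ", paste(dim(x$grid), collapse = "x"), " grid\n", sep = "")
  invisible(x)
}

#' Read a binary organ mask aligned to a reference volume
#'
#' Values are binarized at 0.5. An empty mask is a warning, not an error:
#' downstream operations decide how to treat it.
#'
#' @param path 3D NIfTI mask file.
#' @param reference The [multi_echo_volume()] the mask must align with.
#' @param organ Organ label.
#' @param source Provenance label recorded from the caller.
#' @return An [organ_mask()].
#' @export
read_mask <- function(path, reference, organ, source = "automatic") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L)
    stop("mask must be a 3D file: ", path, call. = FALSE)
  ref_dim <- spatial_dim(reference)
  if (!identical(dim(arr), as.integer(ref_dim)))
    stop("mask misaligned with reference volume: mask ",
         paste(dim(arr), collapse = "x"), " vs volume ",
         paste(ref_dim, collapse = "x"), call. = FALSE)
  organ_mask(arr, organ = organ, source = source)
}

#' Write an organ mask to NIfTI
#'
#' @param mask An [organ_mask()].
#' @param path Output path.
#' @param reference Optional [multi_echo_volume()] supplying geometry; an
#'   identity-scaled affine is used otherwise.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, reference = NULL) {
  stopifnot(inherits(mask, "organ_mask"))
  voxel_dims <- if (is.null(reference)) c(1, 1, 1) else reference$voxel_dims
  affine <- if (is.null(reference)) diag(4) else reference$affine
  RNifti::writeNifti(nifti_from_array(mask$grid, voxel_dims, affine), path)
  invisible(path)
}

#' Read and validate a normative control table
#'
#' The control table holds one row per (case, organ, measure):
#' columns `ga_weeks`, `organ`, `measure`, `value`. Rows are validated
#' (gestational age within 12-45 weeks, value finite and positive); invalid
#' rows are dropped with a warning naming their row numbers.
#'
#' @param path CSV file path.
#' @return A data frame with columns `ga_weeks`, `organ`, `measure`, `value`.
#' @export
read_normative_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("ga_weeks", "organ", "measure", "value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("normative table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(tab) == 0)
    stop("normative table has no rows: ", path, call. = FALSE)
  ga <- suppressWarnings(as.numeric(tab$ga_weeks))
  val <- suppressWarnings(as.numeric(tab$value))
  ok <- is.finite(ga) & ga >= 12 & ga <= 45 & is.finite(val) & val > 0
  if (any(!ok))
    warning("rejected ", sum(!ok), " invalid row(s): ",
            paste(utils::head(which(!ok), 20), collapse = ", "),
            call. = FALSE)
  if (!any(ok))
    stop("normative table has no valid rows after validation", call. = FALSE)
  data.frame(ga_weeks = ga[ok], organ = as.character(tab$organ)[ok],
             measure = as.character(tab$measure)[ok], value = val[ok],
             stringsAsFactors = FALSE)
}
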