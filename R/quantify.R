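#' Threshold-filtered organ summary at a gestational age
#'
#' Mean T2* over the voxels of an organ mask after two filters: voxels with
#' invalid fits are dropped, and voxels whose T2* exceeds the organ-specific
#' upper threshold (500 ms placenta, 900 ms fetal brain by default) are
#' excluded to avoid partial-volume contamination from fluid-dominated
#' regions. The threshold comparison is inclusive (T2* equal to the threshold
#' is kept). Organ volume is pure mask geometry: full mask voxel count times
#' voxel volume, independent of any filtering.
#'
#' @param map A `t2star_map` from [fit_volume()].
#' @param mask An [organ_mask()] aligned with the map.
#' @param ga_weeks Gestational age at scan, decimal weeks.
#' @param threshold_ms Upper T2* limit in ms; defaults to
#'   [organ_threshold()] for the mask's organ.
#' @param voxel_dims Voxel edge lengths in mm; defaults to the map's.
#' @return An object of class `organ_summary` with the mean, volume, and a
#'   full voxel accounting (`n_voxels_used + n_voxels_over_threshold +
#'   n_voxels_invalid_fit = n_voxels_mask`). With zero usable voxels the mean
#'   is NaN and a warning is raised, not an error.
#' @export
#' @examples
#' # see summarize_exam() for an end-to-end phantom example
summarize_organ <- function(map, mask, ga_weeks, threshold_ms = NULL,
                            voxel_dims = NULL) {
  stopifnot(inherits(map, "t2star_map"), inherits(mask, "organ_mask"))
  if (!identical(dim(map$t2star), dim(mask$grid)))
    stop("map and mask are misaligned: ",
         paste(dim(map$t2star), collapse = "x"), " vs ",
         paste(dim(mask$grid), collapse = "x"), call. = FALSE)
  if (is.null(threshold_ms)) threshold_ms <- organ_threshold(mask$organ)
  if (threshold_ms <= 0) stop("threshold_ms must be positive", call. = FALSE)
  if (is.null(voxel_dims)) voxel_dims <- map$voxel_dims
  in_mask <- mask$grid == 1L
  n_mask <- sum(in_mask)
  valid <- map$valid & in_mask
  t2 <- map$t2star[valid]
  used <- t2 <= threshold_ms
  n_used <- sum(used)
  n_over <- sum(!used)
  n_invalid <- n_mask - n_used - n_over
  mean_t2 <- if (n_used > 0) mean(t2[used]) else NaN
  if (n_used == 0)
    warning("no usable voxels for ", mask$organ,
            " (mask ", n_mask, ", invalid ", n_invalid,
            ", over threshold ", n_over, ")", call. = FALSE)
  structure(list(organ = mask$organ, ga_weeks = as.numeric(ga_weeks),
                 mean_t2star = mean_t2,
                 volume_mm3 = n_mask * prod(voxel_dims),
                 n_voxels_mask = n_mask, n_voxels_used = n_used,
                 n_voxels_over_threshold = n_over,
                 n_voxels_invalid_fit = n_invalid,
                 threshold_ms = threshold_ms,
                 mask_source = mask$source),
            class = "organ_summary")
}

#' @export
print.organ_summary <- function(x, ...) {
  cat(sprintf("<organ_summary> %s @ GA %.2f wk: mean T2* = %.2f ms (<= %g ms), volume = %.1f mm3\n",
              x$organ, x$ga_weeks, x$mean_t2star, x$threshold_ms,
              x$volume_mm3))
  cat(sprintf("  voxels: %d mask = %d used + %d over threshold + %d invalid\n",
              x$n_voxels_mask, x$n_voxels_used, x$n_voxels_over_threshold,
              x$n_voxels_invalid_fit))
  invisible(x)
}

#' @export
as.data.frame.organ_summary <- function(x, ...) {
  data.frame(organ = x$organ, ga_weeks = x$ga_weeks,
             mean_t2star_ms = x$mean_t2star, volume_mm3 = x$volume_mm3,
             n_voxels_mask = x$n_voxels_mask,
             n_voxels_used = x$n_voxels_used,
             n_voxels_over_threshold = x$n_voxels_over_threshold,
             n_voxels_invalid_fit = x$n_voxels_invalid_fit,
             threshold_ms = x$threshold_ms, stringsAsFactors = FALSE)
}

#' Summarize a whole exam (all available organs)
#'
#' One [summarize_organ()] call per organ present in `masks`; organs without
#' a mask are skipped with a message. Optionally appends one CSV row per
#' organ to a summary file.
#'
#' @param map A `t2star_map`.
#' @param masks Named list of [organ_mask()] objects (names are organ
#'   labels); at least one required.
#' @param ga_weeks Gestational age, decimal weeks.
#' @param thresholds Optional named vector of per-organ thresholds in ms;
#'   defaults per organ via [organ_threshold()].
#' @param csv_path Optional path; rows are appended (with header if new).
#' @return Named list of `organ_summary` objects.
#' @export
summarize_exam <- function(map, masks, ga_weeks, thresholds = NULL,
                           csv_path = NULL) {
  if (length(masks) == 0) stop("at least one organ mask required",
                               call. = FALSE)
  out <- list()
  for (org in ORGANS) {
    if (is.null(masks[[org]])) {
      message("summarize_exam: no mask for ", org, "; skipped")
      next
    }
    thr <- if (!is.null(thresholds) && !is.na(thresholds[org]))
      unname(thresholds[org]) else NULL
    out[[org]] <- summarize_organ(map, masks[[org]], ga_weeks,
                                  threshold_ms = thr)
  }
  if (length(out) == 0) stop("no recognized organ masks supplied",
                             call. = FALSE)
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(out, as.data.frame))
    write.table(rows, csv_path, sep = ",", row.names = FALSE,
                col.names = !file.exists(csv_path), append = file.exists(csv_path))
  }
  out
}
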