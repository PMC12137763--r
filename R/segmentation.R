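#' Extract the echo image used as segmentation input
#'
#' Organ segmentation operates on a single echo of the multi-echo
#' acquisition; the second echo is the default input (good organ contrast
#' with limited decay).
#'
#' @param volume A [multi_echo_volume()].
#' @param echo Echo index (1-based); default 2, the second echo.
#' @return The 3D signal array for that echo.
#' @export
select_segmentation_echo <- function(volume, echo = 2L) {
  stopifnot(inherits(volume, "multi_echo_volume"))
  ne <- dim(volume$signal)[4]
  echo <- as.integer(echo)
  if (length(echo) != 1L || is.na(echo) || echo < 1L || echo > ne)
    stop("echo index out of range: ", echo, " (volume has ", ne, " echoes)",
         call. = FALSE)
  volume$signal[, , , echo, drop = TRUE]
}

#' Deterministic reference segmenter for synthetic phantoms
#'
#' Stands in for a trained segmentation network when exercising the pipeline
#' on phantoms: combines the known organ geometry of the generating
#' [phantom_spec()] with an intensity gate on the second-echo image. A voxel
#' belongs to an organ's mask when it lies inside that organ's generating
#' ellipsoid and its second-echo intensity is within `noise_tolerance`
#' (fractional) of the organ's expected noiseless intensity. On a noiseless
#' phantom the result equals the truth mask exactly; real anatomy is out of
#' scope (external masks come in through [load_external_mask()]).
#'
#' @param volume A phantom [multi_echo_volume()].
#' @param spec The [phantom_spec()] that generated it.
#' @param noise_tolerance Fractional intensity tolerance; default 0.5.
#' @param echo Echo used for the intensity gate (default 2).
#' @return Named list of [organ_mask()] objects (source `"automatic"`).
#' @export
segment_phantom <- function(volume, spec, noise_tolerance = 0.5, echo = 2L) {
  stopifnot(inherits(spec, "phantom_spec"))
  img <- select_segmentation_echo(volume, echo)
  te_e <- volume$echo_times[echo]
  truth_t2 <- phantom_truth_values(spec)
  masks <- list()
  for (org in names(spec$organ_geometries)) {
    region <- ellipsoid_mask(spec$grid_shape, spec$organ_geometries[[org]])
    expected <- spec$true_s0[[org]] * exp(-te_e / truth_t2[[org]])
    keep <- region == 1L &
      abs(img - expected) <= noise_tolerance * expected + 1e-9
    g <- array(as.integer(keep), dim = spec$grid_shape)
    if (sum(g) == 0L)
      warning("segment_phantom: empty mask for ", org, call. = FALSE)
    masks[[org]] <- suppressWarnings(
      organ_mask(g, organ = org, source = "automatic"))
  }
  masks
}

#' Load an externally produced organ mask
#'
#' Entry point for masks from any external segmenter (manual or automatic,
#' e.g. a trained network run outside this package); delegates to
#' [read_mask()] with the stated provenance.
#'
#' @param path NIfTI mask file.
#' @param reference The [multi_echo_volume()] the mask aligns with.
#' @param organ Organ label.
#' @param source `"manual"` or `"automatic"`.
#' @return An [organ_mask()].
#' @export
load_external_mask <- function(path, reference, organ,
                               source = c("manual", "automatic")) {
  source <- match.arg(source)
  read_mask(path, reference, organ, source = source)
}
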