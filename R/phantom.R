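#' Default gestational-age trends for the synthetic generator
#'
#' Generating polynomial coefficients (ascending powers of GA in weeks) for
#' each organ and measure: linearly decreasing placental mean T2*, a
#' quadratically decreasing fetal-brain mean T2*, and linearly increasing
#' volumes. Magnitudes are plausible for low-field (0.55T) late-gestation
#' imaging and sit below the organ thresholds; they are generator constants
#' for testing, not physiological claims.
#'
#' @return Nested list `trends[[organ]][[measure]]` of coefficient vectors.
#' @export
default_ga_trends <- function() {
  list(
    placenta = list(mean_t2star = c(375, -4.5),
                    volume = c(-100000, 15000)),
    fetal_brain = list(mean_t2star = c(600, -2, -0.15),
                       volume = c(-180000, 12000)))
}

#' Default noise standard deviations for the synthetic control cohort
#'
#' @return Nested list `sds[[organ]][[measure]]` (ms for mean T2*, mm^3 for
#'   volume). Placental T2* gets the larger scatter, mirroring the greater
#'   variability of placental measurements at late gestation.
#' @export
default_cohort_noise_sd <- function() {
  list(placenta = list(mean_t2star = 30, volume = 60000),
       fetal_brain = list(mean_t2star = 20, volume = 15000))
}

default_organ_geometries <- function(grid_shape) {
  g <- grid_shape
  list(
    fetal_brain = list(center = round(g * c(0.50, 0.68, 0.50)),
                       semi_axes = pmax(round(g * c(0.14, 0.14, 0.16)), 2)),
    placenta = list(center = round(g * c(0.50, 0.30, 0.50)),
                    semi_axes = pmax(round(g * c(0.30, 0.17, 0.19)), 2)))
}

ellipsoid_mask <- function(grid_shape, geom) {
  cx <- geom$center; ax <- geom$semi_axes
  x <- (seq_len(grid_shape[1]) - cx[1]) / ax[1]
  y <- (seq_len(grid_shape[2]) - cx[2]) / ax[2]
  z <- (seq_len(grid_shape[3]) - cx[3]) / ax[3]
  d2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(as.integer(d2 <= 1), dim = grid_shape)
}

#' Specify a synthetic uterine phantom
#'
#' Defines a GA-dependent multi-echo phantom: an ellipsoidal fetal brain and
#' an oblate-ellipsoid placenta embedded in low-signal short-T2* background
#' tissue, imaged with the package's default acquisition constants
#' (TE = 57/152/248/344 ms, 3.125 x 3.125 x 3 mm voxels). Organ T2* defaults
#' follow [default_ga_trends()] at `ga_weeks`. Optional confounds: additive
#' noise (Gaussian by default, Rician on request), a placental contraction
#' (fractional T2* depression of the half of the placenta on one side of its
#' center plane), and per-echo rigid motion of the brain.
#'
#' @param grid_shape Three integers; default `c(64, 64, 48)` (a
#'   down-sampled whole-uterus field of view that keeps tests fast).
#' @param voxel_dims Voxel edge lengths in mm.
#' @param echo_times Echo times in ms.
#' @param ga_weeks Gestational age in decimal weeks.
#' @param organ_geometries Per-organ `list(center, semi_axes)` in voxels;
#'   defaults scale with the grid. Organs must be disjoint and inside the
#'   grid.
#' @param true_t2star Named list with entries `fetal_brain`, `placenta`,
#'   `background` (ms). Missing organ entries default to the GA trend;
#'   background defaults to 60 ms.
#' @param true_s0 Named list of TE=0 signals; background defaults low (300)
#'   so organs are trivially separable by intensity.
#' @param noise_sigma Additive noise SD in scanner units (>= 0).
#' @param noise_model `"gaussian"` (default, magnitude-bias-free) or
#'   `"rician"`.
#' @param contraction `NULL`, or `list(fraction = f, region = r)` with
#'   `0 < f < 1`: T2* of the affected placental voxels is multiplied by
#'   `1 - f`. `region` is `"full"` (default: the whole parenchyma, the
#'   organ-level depression a strong contractile state produces) or
#'   `"half"` (the half of the placenta on one side of its center plane,
#'   for localized contractile activity). The default fraction 0.4 on the
#'   full placenta drops the organ mean well below its 5th centile while
#'   keeping all echoes above the noise floor.
#' @param motion `NULL`, or `list(echoes = indices, shift = c(dx, dy, dz))`
#'   voxel shift applied to the brain on the listed echoes.
#' @param seed Integer seed; the same spec and seed give bit-identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         voxel_dims = c(3.125, 3.125, 3),
                         echo_times = c(57, 152, 248, 344),
                         ga_weeks = 37,
                         organ_geometries = NULL,
                         true_t2star = NULL,
                         true_s0 = NULL,
                         noise_sigma = 0,
                         noise_model = c("gaussian", "rician"),
                         contraction = NULL,
                         motion = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L))
  noise_model <- match.arg(noise_model)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (is.null(organ_geometries))
    organ_geometries <- default_organ_geometries(grid_shape)
  stopifnot(all(ORGANS %in% names(organ_geometries)))
  s0_def <- list(fetal_brain = 1000, placenta = 1000, background = 300)
  true_s0 <- utils::modifyList(s0_def, as.list(true_s0 %||% list()))
  t2_def <- list(fetal_brain = NULL, placenta = NULL, background = 60)
  true_t2star <- utils::modifyList(t2_def, as.list(true_t2star %||% list()))
  if (!is.null(contraction)) {
    f <- contraction$fraction %||% 0.4
    if (f <= 0 || f >= 1) stop("contraction fraction must be in (0, 1)",
                               call. = FALSE)
    contraction <- list(fraction = f,
                        region = match.arg(contraction$region %||% "full",
                                           c("full", "half")))
  }
  if (!is.null(motion)) {
    stopifnot(length(motion$shift) == 3L, length(motion$echoes) >= 1L)
    motion$shift <- as.integer(round(motion$shift))
    motion$echoes <- as.integer(motion$echoes)
  }
  spec <- structure(list(grid_shape = grid_shape,
                         voxel_dims = as.numeric(voxel_dims),
                         echo_times = as.numeric(echo_times),
                         ga_weeks = as.numeric(ga_weeks),
                         organ_geometries = organ_geometries[ORGANS],
                         true_t2star = true_t2star, true_s0 = true_s0,
                         noise_sigma = as.numeric(noise_sigma),
                         noise_model = noise_model,
                         contraction = contraction, motion = motion,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  masks <- lapply(spec$organ_geometries, function(g)
    ellipsoid_mask(grid_shape, g))
  overlap <- Reduce(`+`, masks)
  if (any(overlap > 1L))
    stop("phantom spec error: organ regions overlap", call. = FALSE)
  for (org in ORGANS) {
    g <- spec$organ_geometries[[org]]
    if (any(g$center - g$semi_axes < 1) ||
        any(g$center + g$semi_axes > grid_shape))
      stop("phantom spec error: ", org, " extends outside the grid",
           call. = FALSE)
    if (sum(masks[[org]]) == 0L)
      stop("phantom spec error: ", org, " region is empty", call. = FALSE)
  }
  tv <- phantom_truth_values(spec)
  if (any(unlist(tv) <= 0))
    stop("phantom spec error: true T2* values must be positive",
         call. = FALSE)
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-organ (and background) true T2* at the spec's GA
phantom_truth_values <- function(spec) {
  trends <- default_ga_trends()
  out <- list()
  for (org in ORGANS) {
    out[[org]] <- spec$true_t2star[[org]] %||%
      poly_eval(trends[[org]]$mean_t2star, spec$ga_weeks)
  }
  out$background <- spec$true_t2star$background
  out
}

# noise sigma giving the requested first-echo SNR in the worst organ
#' Noise level for a target first-echo SNR
#'
#' Returns the additive noise standard deviation such that the organ with
#' the weakest first-echo signal still has `snr` at the first echo.
#'
#' @param spec A [phantom_spec()].
#' @param snr Target first-echo signal-to-noise ratio.
#' @return Noise SD in scanner units.
#' @export
snr_sigma <- function(spec, snr) {
  tv <- phantom_truth_values(spec)
  s1 <- vapply(ORGANS, function(org)
    spec$true_s0[[org]] * exp(-spec$echo_times[1] / tv[[org]]), 0)
  min(s1) / snr
}

# truth T2*/S0 grids, optionally with the brain displaced by `brain_shift`
phantom_maps <- function(spec, brain_shift = c(0L, 0L, 0L)) {
  tv <- phantom_truth_values(spec)
  t2 <- array(tv$background, dim = spec$grid_shape)
  s0 <- array(spec$true_s0$background, dim = spec$grid_shape)
  pl_geom <- spec$organ_geometries$placenta
  pl <- ellipsoid_mask(spec$grid_shape, pl_geom) == 1L
  t2[pl] <- tv$placenta
  s0[pl] <- spec$true_s0$placenta
  if (!is.null(spec$contraction)) {
    sub <- if (spec$contraction$region == "half") {
      pl & slice.index(pl, 1) < pl_geom$center[1]
    } else pl
    t2[sub] <- t2[sub] * (1 - spec$contraction$fraction)
  }
  br_geom <- spec$organ_geometries$fetal_brain
  br_geom$center <- br_geom$center + brain_shift
  if (any(br_geom$center - br_geom$semi_axes < 1) ||
      any(br_geom$center + br_geom$semi_axes > spec$grid_shape))
    stop("motion shift pushes the brain outside the grid", call. = FALSE)
  br <- ellipsoid_mask(spec$grid_shape, br_geom) == 1L
  t2[br] <- tv$fetal_brain
  s0[br] <- spec$true_s0$fetal_brain
  list(t2 = t2, s0 = s0)
}

#' Generate a synthetic multi-echo uterine phantom
#'
#' Builds, per voxel v and echo e, the signal
#' \eqn{S_0(v) \exp(-TE_e / T_2^*(v))} plus noise; returns the volume, exact
#' truth masks for both organs, and the true (noiseless, confound-included)
#' T2* map. Deterministic under the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: list with `volume`
#'   ([multi_echo_volume()]), `masks` (named [organ_mask()] list, source
#'   `"phantom_truth"`), `true_t2star` (3D array, ms), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ne <- length(spec$echo_times)
  base <- phantom_maps(spec)
  signal <- array(0, dim = c(spec$grid_shape, ne))
  for (e in seq_len(ne)) {
    shift <- c(0L, 0L, 0L)
    if (!is.null(spec$motion) && e %in% spec$motion$echoes)
      shift <- spec$motion$shift
    maps <- if (all(shift == 0L)) base else phantom_maps(spec, shift)
    signal[, , , e] <- maps$s0 * exp(-spec$echo_times[e] / maps$t2)
  }
  if (spec$noise_sigma > 0) {
    signal <- with_seed(spec$seed, {
      if (spec$noise_model == "gaussian") {
        pmax(signal + rnorm(length(signal), 0, spec$noise_sigma), 0)
      } else {
        re <- signal + rnorm(length(signal), 0, spec$noise_sigma)
        im <- rnorm(length(signal), 0, spec$noise_sigma)
        sqrt(re^2 + im^2)
      }
    })
    signal <- array(signal, dim = c(spec$grid_shape, ne))
  }
  affine <- diag(c(spec$voxel_dims, 1))
  affine[1:3, 4] <- -spec$voxel_dims * spec$grid_shape / 2
  vol <- multi_echo_volume(signal, spec$echo_times, spec$voxel_dims,
                           affine = affine, ga_weeks = spec$ga_weeks)
  masks <- lapply(ORGANS, function(org)
    organ_mask(ellipsoid_mask(spec$grid_shape, spec$organ_geometries[[org]]),
               organ = org, source = "phantom_truth"))
  names(masks) <- ORGANS
  structure(list(volume = vol, masks = masks, true_t2star = base$t2,
                 spec = spec),
            class = "phantom")
}

#' Generate a synthetic normative control cohort table
#'
#' Emulates a retrospective control cohort: `n` cases with gestational ages
#' drawn uniformly over `ga_range`, and for each case one row per organ and
#' measure with value = trend(GA) + Gaussian noise. Generating mean-T2*
#' trends must be decreasing in GA for both organs (normative T2* falls over
#' gestation); increasing trends are a spec error.
#'
#' @param n Number of cases (>= 10); default 88.
#' @param ga_range GA span in weeks, default `c(20, 40)`.
#' @param trends Generating coefficients, see [default_ga_trends()].
#' @param noise_sd Noise SDs, see [default_cohort_noise_sd()].
#' @param seed Integer seed.
#' @return Data frame with columns `case`, `ga_weeks`, `organ`, `measure`,
#'   `value` (n rows per organ/measure).
#' @export
generate_control_cohort <- function(n = 88, ga_range = c(20, 40),
                                    trends = default_ga_trends(),
                                    noise_sd = default_cohort_noise_sd(),
                                    seed = 1L) {
  if (n < 10) stop("cohort must have at least 10 cases", call. = FALSE)
  stopifnot(length(ga_range) == 2L, ga_range[1] < ga_range[2])
  for (org in ORGANS) {
    co <- trends[[org]]$mean_t2star
    dco <- co[-1] * seq_len(length(co) - 1)   # derivative coefficients
    if (any(poly_eval(dco, ga_range) >= 0))
      stop("spec error: mean T2* trend for ", org,
           " must be decreasing over the GA range", call. = FALSE)
  }
  with_seed(seed, {
    ga <- runif(n, ga_range[1], ga_range[2])
    rows <- list()
    for (org in ORGANS) {
      for (meas in MEASURES) {
        mu <- poly_eval(trends[[org]][[meas]], ga)
        val <- mu + rnorm(n, 0, noise_sd[[org]][[meas]])
        rows[[paste(org, meas)]] <- data.frame(
          case = seq_len(n), ga_weeks = ga, organ = org, measure = meas,
          value = val, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Generate a series of repeat acquisitions of one phantom
#'
#' k phantoms sharing geometry and truth values, differing only in their
#' noise realization (seeds derived deterministically from the base seed)
#' and any per-repeat perturbation, emulating repeated acquisitions at the
#' beginning, middle and end of a scan.
#'
#' @param spec Base [phantom_spec()].
#' @param k Number of repeats (>= 2), default 3.
#' @param perturbations Optional list of length `k`; each element `NULL` or
#'   a list with `contraction` and/or `motion` entries (formats as in
#'   [phantom_spec()]) applied to that repeat only.
#' @return List of `phantom` objects, class `phantom_series`.
#' @export
generate_repeat_series <- function(spec, k = 3, perturbations = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (k < 2) stop("need at least 2 repeats", call. = FALSE)
  if (!is.null(perturbations) && length(perturbations) != k)
    stop("perturbations must have one entry per repeat", call. = FALSE)
  out <- vector("list", k)
  for (r in seq_len(k)) {
    sp <- spec
    sp$seed <- as.integer((spec$seed + 9973 * r) %% .Machine$integer.max)
    pert <- if (is.null(perturbations)) NULL else perturbations[[r]]
    if (!is.null(pert$contraction)) sp$contraction <- pert$contraction
    if (!is.null(pert$motion)) sp$motion <- pert$motion
    # re-validate through the constructor
    sp2 <- phantom_spec(grid_shape = sp$grid_shape,
                        voxel_dims = sp$voxel_dims,
                        echo_times = sp$echo_times, ga_weeks = sp$ga_weeks,
                        organ_geometries = sp$organ_geometries,
                        true_t2star = sp$true_t2star, true_s0 = sp$true_s0,
                        noise_sigma = sp$noise_sigma,
                        noise_model = sp$noise_model,
                        contraction = sp$contraction, motion = sp$motion,
                        seed = sp$seed)
    out[[r]] <- generate_phantom(sp2)
  }
  structure(out, class = "phantom_series")
}

#' Write a phantom's files to a directory
#'
#' Writes `volume.nii.gz`, `mask_<organ>.nii.gz`, `true_t2star.nii.gz` and a
#' `spec.yaml` sidecar (echo times, geometry, seed).
#'
#' @param phantom A `phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_multi_echo(phantom$volume, file.path(dir, "volume.nii.gz"))
  for (org in names(phantom$masks))
    write_mask(phantom$masks[[org]],
               file.path(dir, paste0("mask_", org, ".nii.gz")),
               reference = phantom$volume)
  RNifti::writeNifti(nifti_from_array(phantom$true_t2star,
                                      phantom$spec$voxel_dims,
                                      phantom$volume$affine),
                     file.path(dir, "true_t2star.nii.gz"))
  write_phantom_spec(phantom$spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Serialize a phantom spec to YAML
#'
#' @param spec A [phantom_spec()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(lapply(unclass(spec), function(x)
    if (is.null(x)) NULL else x), path)
  invisible(path)
}

#' Read a phantom spec from YAML
#'
#' @param path YAML path written by [write_phantom_spec()] (or hand-written
#'   with the same fields; missing fields take defaults).
#' @return A validated [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.list(y)) stop("malformed phantom spec YAML: ", path, call. = FALSE)
  geoms <- y$organ_geometries
  if (!is.null(geoms))
    geoms <- lapply(geoms, function(g)
      list(center = as.numeric(g$center), semi_axes = as.numeric(g$semi_axes)))
  phantom_spec(
    grid_shape = y$grid_shape %||% c(64, 64, 48),
    voxel_dims = y$voxel_dims %||% c(3.125, 3.125, 3),
    echo_times = y$echo_times %||% c(57, 152, 248, 344),
    ga_weeks = y$ga_weeks %||% 37,
    organ_geometries = geoms,
    true_t2star = y$true_t2star,
    true_s0 = y$true_s0,
    noise_sigma = y$noise_sigma %||% 0,
    noise_model = y$noise_model %||% "gaussian",
    contraction = y$contraction,
    motion = y$motion,
    seed = y$seed %||% 1L)
}
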