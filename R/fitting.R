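#' Options controlling voxelwise T2* fitting
#'
#' @param method `"nlls"` (default): bounded nonlinear least squares on the
#'   untransformed signal, initialized from the log-linear fit; or
#'   `"loglinear"`: closed-form ordinary least squares on log-signal, the
#'   standard fast approximation.
#' @param t2_bounds Admissible T2* interval in ms. The default `c(1, 2000)`
#'   comfortably exceeds the organ thresholds (500/900 ms) and the long fluid
#'   T2* they guard against.
#' @param min_valid_echoes Minimum usable echo samples per voxel (>= 2).
#' @param signal_floor Samples at or below this value (scanner units) are
#'   excluded from the fit. Default 0: every strictly positive sample is used.
#' @param rician_correction Apply the magnitude noise-floor correction
#'   \eqn{S' = \sqrt{\max(S^2 - 2\sigma_n^2, 0)}} before fitting. Off by
#'   default: the standard fit ignores the noise floor, which can bias T2*
#'   upward at low SNR; the correction is provided as an opt-in.
#' @param sigma_n Noise standard deviation (scanner units) for the Rician
#'   correction; required when `rician_correction = TRUE`.
#' @param tol NLLS convergence tolerance on the relative parameter change.
#' @param max_iter NLLS iteration cap.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(method = c("nlls", "loglinear"),
                        t2_bounds = c(1, 2000), min_valid_echoes = 2L,
                        signal_floor = 0, rician_correction = FALSE,
                        sigma_n = NULL, tol = 1e-8, max_iter = 200L) {
  method <- match.arg(method)
  t2_bounds <- as.numeric(t2_bounds)
  if (length(t2_bounds) != 2L || t2_bounds[1] <= 0 ||
      t2_bounds[1] >= t2_bounds[2])
    stop("t2_bounds must satisfy 0 < t2_min < t2_max", call. = FALSE)
  min_valid_echoes <- as.integer(min_valid_echoes)
  if (min_valid_echoes < 2L)
    stop("min_valid_echoes must be at least 2", call. = FALSE)
  if (rician_correction && (is.null(sigma_n) || sigma_n <= 0))
    stop("rician_correction requires a positive sigma_n", call. = FALSE)
  structure(list(method = method, t2_bounds = t2_bounds,
                 min_valid_echoes = min_valid_echoes,
                 signal_floor = as.numeric(signal_floor),
                 rician_correction = isTRUE(rician_correction),
                 sigma_n = sigma_n, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "fit_options")
}

apply_rician_correction <- function(S, options) {
  if (!options$rician_correction) return(S)
  sqrt(pmax(S^2 - 2 * options$sigma_n^2, 0))
}

# Closed-form log-linear solver, vectorized over rows of S (nvox x necho).
# Returns per-voxel t2star/s0/r2 (log-domain R^2), validity, and flags for
# why a voxel was rejected. Samples at or below `floor` are excluded.
loglinear_engine <- function(S, te, floor, min_echoes, bounds) {
  w <- (S > floor) & is.finite(S)
  n <- rowSums(w)
  L <- ifelse(w, log(pmax(S, .Machine$double.xmin)), 0)
  sx <- as.vector(w %*% te)
  sxx <- as.vector(w %*% (te^2))
  sy <- rowSums(L)
  sxy <- as.vector(L %*% te)
  den <- n * sxx - sx^2
  slope <- ifelse(den > 0, (n * sxy - sx * sy) / den, NA_real_)
  intercept <- ifelse(n > 0, (sy - ifelse(is.na(slope), 0, slope) * sx) / n,
                      NA_real_)
  enough <- n >= min_echoes
  decaying <- enough & is.finite(slope) & slope < 0
  t2 <- ifelse(decaying, -1 / slope, NA_real_)
  clipped <- decaying & (t2 < bounds[1] | t2 > bounds[2])
  t2_out <- pmin(pmax(t2, bounds[1]), bounds[2])
  valid <- decaying & !clipped
  s0 <- ifelse(decaying, exp(intercept), NA_real_)
  # R^2 in the log domain, defined only for valid voxels
  fitted <- sweep(outer(ifelse(is.na(slope), 0, slope), te), 1,
                  ifelse(is.na(intercept), 0, intercept), "+")
  sse <- rowSums(w * (L - fitted)^2)
  ybar <- ifelse(n > 0, sy / n, 0)
  sst <- rowSums(w * (L - ybar)^2)
  r2 <- ifelse(valid & sst > 0, pmax(0, pmin(1, 1 - sse / sst)),
               ifelse(valid, 1, NA_real_))
  list(t2star = ifelse(valid | clipped, t2_out, NA_real_),
       s0 = ifelse(valid, s0, NA_real_),
       r2 = ifelse(valid, r2, NA_real_),
       valid = valid, clipped = clipped, n_used = n)
}

# Bounded Levenberg-Marquardt on the untransformed objective
#   f(s0, t2) = sum_e w_e (S_e - s0 exp(-TE_e / t2))^2
# vectorized over voxels, with projection onto s0 >= 0 and t2 in bounds.
nlls_engine <- function(S, te, floor, min_echoes, bounds, init_t2, init_s0,
                        tol = 1e-8, max_iter = 200L) {
  w <- (S > floor) & is.finite(S)
  n <- rowSums(w)
  nv <- nrow(S)
  active <- n >= min_echoes & is.finite(init_t2) & is.finite(init_s0)
  t2 <- pmin(pmax(init_t2, bounds[1]), bounds[2])
  s0 <- pmax(init_s0, 0)
  sse_of <- function(s0v, t2v, Sw, wv) {
    E <- exp(-outer(1 / t2v, te))
    rowSums(wv * (Sw - s0v * E)^2)
  }
  idx <- which(active)
  converged <- nonconverged <- rep(FALSE, nv)
  if (length(idx) > 0) {
    Sa <- S[idx, , drop = FALSE]
    wa <- w[idx, , drop = FALSE]
    p1 <- s0[idx]; p2 <- t2[idx]
    lam <- rep(1e-3, length(idx))
    done <- rep(FALSE, length(idx))
    sse <- sse_of(p1, p2, Sa, wa)
    for (iter in seq_len(max_iter)) {
      live <- which(!done)
      if (length(live) == 0) break
      s0l <- p1[live]; t2l <- p2[live]
      Sl <- Sa[live, , drop = FALSE]; wl <- wa[live, , drop = FALSE]
      E <- exp(-outer(1 / t2l, te))
      r <- wl * (Sl - s0l * E)
      J1 <- -E * wl
      J2 <- -(s0l * outer(1 / t2l^2, te)) * E * wl
      A11 <- rowSums(J1 * J1); A12 <- rowSums(J1 * J2)
      A22 <- rowSums(J2 * J2)
      g1 <- rowSums(J1 * r); g2 <- rowSums(J2 * r)
      B11 <- A11 * (1 + lam[live]); B22 <- A22 * (1 + lam[live])
      det <- B11 * B22 - A12^2
      ok <- is.finite(det) & det > .Machine$double.xmin
      d1 <- ifelse(ok, (-g1 * B22 + g2 * A12) / det, 0)
      d2 <- ifelse(ok, (-g2 * B11 + g1 * A12) / det, 0)
      n1 <- pmax(s0l + d1, 0)
      n2 <- pmin(pmax(t2l + d2, bounds[1]), bounds[2])
      new_sse <- sse_of(n1, n2, Sl, wl)
      better <- is.finite(new_sse) & new_sse <= sse[live]
      rel <- pmax(abs(n1 - s0l) / pmax(abs(s0l), 1e-12),
                  abs(n2 - t2l) / pmax(abs(t2l), 1e-12))
      p1[live[better]] <- n1[better]
      p2[live[better]] <- n2[better]
      sse[live[better]] <- new_sse[better]
      lam[live[better]] <- lam[live[better]] / 4
      lam[live[!better]] <- lam[live[!better]] * 8
      done[live[better & rel < tol]] <- TRUE
      done[live[!ok]] <- TRUE
    }
    s0[idx] <- p1; t2[idx] <- p2
    conv <- done
    at_bound <- p2 <= bounds[1] * (1 + 1e-12) | p2 >= bounds[2] * (1 - 1e-12)
    converged[idx] <- conv & !at_bound
    nonconverged[idx] <- !conv
    # signal-domain R^2
    sst <- {
      m <- rowSums(wa * Sa) / pmax(rowSums(wa), 1)
      rowSums(wa * (Sa - m)^2)
    }
    r2v <- ifelse(sst > 0, pmax(0, pmin(1, 1 - sse / sst)), 1)
    r2 <- rep(NA_real_, nv); r2[idx] <- r2v
    sse_full <- rep(NA_real_, nv); sse_full[idx] <- sse
  } else {
    r2 <- rep(NA_real_, nv)
    sse_full <- rep(NA_real_, nv)
  }
  valid <- converged
  list(t2star = ifelse(active, t2, NA_real_),
       s0 = ifelse(active, s0, NA_real_),
       r2 = ifelse(valid, r2, NA_real_),
       valid = valid, nonconverged = nonconverged,
       at_bounds = active & !valid & !nonconverged,
       sse = sse_full, n_used = n)
}

voxel_result <- function(eng, i = 1L) {
  list(t2star = unname(eng$t2star[i]), s0 = unname(eng$s0[i]),
       r2 = unname(eng$r2[i]), valid = unname(eng$valid[i]))
}

#' Log-linear T2* fit for a single voxel
#'
#' Ordinary least squares of \eqn{\ln S} against TE; \eqn{T_2^* = -1/slope},
#' \eqn{S_0 = e^{intercept}}. A non-decaying signal (slope >= 0) or a result
#' outside `t2_bounds` is flagged invalid (clipped values are reported but
#' not trusted). Fewer than `min_valid_echoes` usable samples gives sentinel
#' (NaN) outputs rather than an error.
#'
#' @param signal Per-echo magnitude samples.
#' @param echo_times Echo times in ms, same length as `signal`.
#' @param options A [fit_options()].
#' @return List with `t2star` (ms), `s0`, `r2` (log-domain), `valid`.
#' @export
#' @examples
#' te <- c(57, 152, 248, 344)
#' fit_voxel_loglinear(1000 * exp(-te / 200), te, fit_options())
fit_voxel_loglinear <- function(signal, echo_times, options = fit_options()) {
  stopifnot(length(signal) == length(echo_times))
  S <- matrix(apply_rician_correction(as.numeric(signal), options), nrow = 1)
  eng <- loglinear_engine(S, as.numeric(echo_times), options$signal_floor,
                          options$min_valid_echoes, options$t2_bounds)
  voxel_result(eng)
}

#' Bounded nonlinear least-squares T2* fit for a single voxel
#'
#' Minimizes \eqn{\sum_e (S_e - S_0 e^{-TE_e/T_2^*})^2} by projected
#' Levenberg-Marquardt with \eqn{S_0 \ge 0} and T2* within `t2_bounds`,
#' initialized from the log-linear fit (fallback: T2* = median TE, S0 = first
#' usable echo). Voxels that terminate at a bound or fail to converge are
#' flagged invalid.
#'
#' @inheritParams fit_voxel_loglinear
#' @param init Optional list with `t2star` and `s0` starting values.
#' @return List with `t2star` (ms), `s0`, `r2` (signal-domain), `valid`.
#' @export
fit_voxel_nlls <- function(signal, echo_times, options = fit_options(),
                           init = NULL) {
  stopifnot(length(signal) == length(echo_times))
  te <- as.numeric(echo_times)
  S <- matrix(apply_rician_correction(as.numeric(signal), options), nrow = 1)
  if (is.null(init)) {
    ll <- loglinear_engine(S, te, options$signal_floor,
                           options$min_valid_echoes, options$t2_bounds)
    init <- list(t2star = ll$t2star[1], s0 = ll$s0[1])
  }
  if (!isTRUE(is.finite(init$t2star)) || !isTRUE(is.finite(init$s0))) {
    usable <- which(S[1, ] > options$signal_floor & is.finite(S[1, ]))
    init <- list(t2star = median(te),
                 s0 = if (length(usable)) S[1, usable[1]] else NA_real_)
  }
  eng <- nlls_engine(S, te, options$signal_floor, options$min_valid_echoes,
                     options$t2_bounds, init$t2star, init$s0,
                     tol = options$tol, max_iter = options$max_iter)
  voxel_result(eng)
}

#' Fit a T2* map over a whole multi-echo volume
#'
#' Applies the selected voxel solver to every voxel (vectorized; a 64x64x48
#' grid fits in seconds). Deterministic given the volume and options. The
#' returned map carries the input affine unchanged and a structured log with
#' voxel accounting.
#'
#' @param volume A [multi_echo_volume()].
#' @param options A [fit_options()].
#' @return An object of class `t2star_map` with 3D grids `t2star` (ms), `s0`,
#'   `fit_quality` (R-squared), `valid` (logical), plus `voxel_dims`,
#'   `affine`, `method`, and `log` (counts of total/valid/invalid/clipped/
#'   non-converged voxels).
#' @export
fit_volume <- function(volume, options = fit_options()) {
  stopifnot(inherits(volume, "multi_echo_volume"))
  d <- dim(volume$signal)
  te <- volume$echo_times
  nv <- prod(d[1:3])
  S <- matrix(volume$signal, nrow = nv, ncol = d[4])
  S <- apply_rician_correction(S, options)
  ll <- loglinear_engine(S, te, options$signal_floor,
                         options$min_valid_echoes, options$t2_bounds)
  n_clipped <- sum(ll$clipped)
  n_nonconv <- 0L
  if (options$method == "loglinear") {
    eng <- ll
  } else {
    init_t2 <- ll$t2star
    init_s0 <- ll$s0
    fallback <- !is.finite(init_t2) | !is.finite(init_s0)
    if (any(fallback)) {
      init_t2[fallback] <- median(te)
      first_usable <- apply(S[fallback, , drop = FALSE], 1, function(s) {
        u <- which(s > options$signal_floor & is.finite(s))
        if (length(u)) s[u[1]] else NA_real_
      })
      init_s0[fallback] <- first_usable
    }
    eng <- nlls_engine(S, te, options$signal_floor, options$min_valid_echoes,
                       options$t2_bounds, init_t2, init_s0,
                       tol = options$tol, max_iter = options$max_iter)
    n_clipped <- sum(eng$at_bounds)
    n_nonconv <- sum(eng$nonconverged)
  }
  shape3 <- d[1:3]
  as3 <- function(x) array(x, dim = shape3)
  res <- structure(list(
    t2star = as3(ifelse(eng$valid, eng$t2star, NA_real_)),
    s0 = as3(ifelse(eng$valid, eng$s0, NA_real_)),
    fit_quality = as3(eng$r2),
    valid = as3(eng$valid),
    voxel_dims = volume$voxel_dims,
    affine = volume$affine,
    method = options$method,
    options = options,
    log = list(n_voxels = nv, n_valid = sum(eng$valid),
               n_invalid = nv - sum(eng$valid), n_clipped = n_clipped,
               n_nonconverged = n_nonconv)),
    class = "t2star_map")
  res
}

#' @export
print.t2star_map <- function(x, ...) {
  cat("<t2star_map> ", paste(dim(x$t2star), collapse = "x"),
      " (", x$method, "): ", x$log$n_valid, "/", x$log$n_voxels,
      " valid voxels", sep = "")
  if (x$log$n_clipped > 0) cat(", ", x$log$n_clipped, " at bounds", sep = "")
  cat("\n")
  invisible(x)
}

#' Write a fitted T2* map to NIfTI files plus a JSON fit report
#'
#' Writes `<prefix>_t2star.nii.gz`, `<prefix>_s0.nii.gz`,
#' `<prefix>_valid.nii.gz` (all with the input affine) and
#' `<prefix>_report.json` with the voxel accounting.
#'
#' @param map A `t2star_map`.
#' @param prefix Output path prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_t2star_map <- function(map, prefix) {
  stopifnot(inherits(map, "t2star_map"))
  paths <- c(t2star = paste0(prefix, "_t2star.nii.gz"),
             s0 = paste0(prefix, "_s0.nii.gz"),
             valid = paste0(prefix, "_valid.nii.gz"),
             report = paste0(prefix, "_report.json"))
  RNifti::writeNifti(nifti_from_array(ifelse(is.na(map$t2star), 0,
                                             map$t2star),
                                      map$voxel_dims, map$affine),
                     paths[["t2star"]])
  RNifti::writeNifti(nifti_from_array(ifelse(is.na(map$s0), 0, map$s0),
                                      map$voxel_dims, map$affine),
                     paths[["s0"]])
  RNifti::writeNifti(nifti_from_array(array(as.integer(map$valid),
                                            dim = dim(map$valid)),
                                      map$voxel_dims, map$affine),
                     paths[["valid"]])
  jsonlite::write_json(c(list(method = map$method), map$log),
                       paths[["report"]], auto_unbox = TRUE)
  invisible(paths)
}
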