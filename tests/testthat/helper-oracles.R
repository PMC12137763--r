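# Independent oracles used across the suite. These deliberately avoid the
# package's solvers: brute force, closed forms, and naive set arithmetic.

# exhaustive 2D grid search minimizing sum of squared residuals of
# s0 * exp(-te / t2) over (s0, t2)
oracle_grid_fit <- function(signal, te, t2_grid, s0_grid) {
  E <- exp(-outer(t2_grid, te, function(t, e) e / t))  # nt x ne
  a <- rowSums(E^2)                    # sum E^2 per t2
  b <- as.vector(E %*% signal)         # sum S*E per t2
  cst <- sum(signal^2)
  # SSE(t2, s0) = cst - 2 s0 b + s0^2 a
  sse <- outer(b, s0_grid, function(bb, s) -2 * s * bb) +
    outer(a, s0_grid, function(aa, s) s^2 * aa) + cst
  idx <- arrayInd(which.min(sse), dim(sse))
  list(t2star = t2_grid[idx[1]], s0 = s0_grid[idx[2]],
       sse = sse[idx[1], idx[2]])
}

# pinball (check) loss of residuals at quantile level tau
pinball_loss <- function(y, X, beta, tau) {
  r <- y - as.vector(X %*% beta)
  sum(ifelse(r > 0, tau * r, (tau - 1) * r))
}

# naive Dice via explicit index sets
brute_dice <- function(a, b) {
  ia <- which(a == 1)
  ib <- which(b == 1)
  if (length(ia) + length(ib) == 0) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# naive Bland-Altman by summation formulas
brute_bland_altman <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(mean_diff = m, sd_diff = s, loa_low = m - 1.96 * s,
       loa_high = m + 1.96 * s)
}

# monoexponential SSE of a parameter pair on one voxel
sse_of <- function(signal, te, s0, t2) sum((signal - s0 * exp(-te / t2))^2)

TE_DEFAULT <- c(57, 152, 248, 344)

# small phantom spec for fast tests
small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 24), ...)
}

# hand-built t2star_map for quantification tests
make_map <- function(t2_values, dim3, valid = NULL,
                     voxel_dims = c(3.125, 3.125, 3)) {
  t2 <- array(t2_values, dim = dim3)
  if (is.null(valid)) valid <- array(is.finite(t2), dim = dim3)
  structure(list(t2star = ifelse(valid, t2, NA_real_),
                 s0 = array(1000, dim = dim3),
                 fit_quality = array(1, dim = dim3), valid = valid,
                 voxel_dims = voxel_dims, affine = diag(c(voxel_dims, 1)),
                 method = "loglinear",
                 log = list(n_voxels = prod(dim3), n_valid = sum(valid),
                            n_invalid = sum(!valid), n_clipped = 0,
                            n_nonconverged = 0)),
            class = "t2star_map")
}
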