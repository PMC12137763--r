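test_that("phantom generation is deterministic under its seed", {
  spec <- small_spec(noise_sigma = 15, seed = 123)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$volume$signal, p2$volume$signal)
  expect_identical(p1$masks$placenta$grid, p2$masks$placenta$grid)
  p3 <- generate_phantom(small_spec(noise_sigma = 15, seed = 124))
  expect_false(identical(p1$volume$signal, p3$volume$signal))
})

test_that("phantom construction rejects bad geometry", {
  overlapping <- list(
    fetal_brain = list(center = c(16, 16, 12), semi_axes = c(6, 6, 5)),
    placenta = list(center = c(18, 16, 12), semi_axes = c(6, 6, 5)))
  expect_error(small_spec(organ_geometries = overlapping), "overlap")
  outside <- list(
    fetal_brain = list(center = c(2, 16, 12), semi_axes = c(6, 6, 5)),
    placenta = list(center = c(24, 16, 12), semi_axes = c(5, 5, 4)))
  expect_error(small_spec(organ_geometries = outside), "outside the grid")
  expect_error(small_spec(noise_sigma = -1), "noise_sigma")
  expect_error(small_spec(contraction = list(fraction = 1.5)), "fraction")
})

test_that("noiseless generate-fit-summarize round trip recovers truth", {
  spec <- small_spec(ga_weeks = 32)
  ph <- generate_phantom(spec)
  truth <- fetalT2star:::phantom_truth_values(spec)
  map <- fit_volume(ph$volume, fit_options(method = "loglinear"))
  for (org in c("fetal_brain", "placenta")) {
    s <- summarize_organ(map, ph$masks[[org]], spec$ga_weeks)
    expect_equal(s$mean_t2star, truth[[org]], tolerance = 1e-9)
    expect_identical(s$volume_mm3,
                     sum(ph$masks[[org]]$grid) * prod(spec$voxel_dims))
  }
})

test_that("organ truth values follow the GA trends and stay in range", {
  trends <- default_ga_trends()
  for (ga in c(22, 30, 38)) {
    tv <- fetalT2star:::phantom_truth_values(small_spec(ga_weeks = ga))
    expect_equal(tv$placenta, 375 - 4.5 * ga)
    expect_equal(tv$fetal_brain, 600 - 2 * ga - 0.15 * ga^2)
    expect_lt(tv$placenta, 500)     # below the placental threshold
    expect_lt(tv$fetal_brain, 900)  # below the brain threshold
    expect_gt(tv$placenta, 0)
  }
})

test_that("half-placenta contraction depresses the organ mean by the region-weighted factor", {
  f <- 0.3
  spec <- small_spec(contraction = list(fraction = f, region = "half"))
  ph <- generate_phantom(spec)
  pl <- ph$masks$placenta$grid == 1
  base <- fetalT2star:::phantom_truth_values(spec)$placenta
  # expected factor from region sizes: affected half at (1 - f), rest at 1
  xidx <- slice.index(pl, 1)
  n_aff <- sum(pl & xidx < spec$organ_geometries$placenta$center[1])
  n_tot <- sum(pl)
  expected <- base * (n_aff * (1 - f) + (n_tot - n_aff)) / n_tot
  expect_equal(mean(ph$true_t2star[pl]), expected, tolerance = 1e-12)
  # full-organ contraction: uniform depression
  spec_full <- small_spec(contraction = list(fraction = 0.4))
  ph_full <- generate_phantom(spec_full)
  expect_equal(mean(ph_full$true_t2star[pl]), base * 0.6, tolerance = 1e-12)
})

test_that("per-echo brain motion corrupts only the shifted echoes", {
  spec <- small_spec(motion = list(echoes = 3:4, shift = c(3, 0, 0)))
  still <- generate_phantom(small_spec())
  moved <- generate_phantom(spec)
  expect_identical(moved$volume$signal[, , , 1:2],
                   still$volume$signal[, , , 1:2])
  expect_false(identical(moved$volume$signal[, , , 3],
                         still$volume$signal[, , , 3]))
  # truth masks stay at the nominal position
  expect_identical(moved$masks$fetal_brain$grid,
                   still$masks$fetal_brain$grid)
})

test_that("control cohort generation respects its contract", {
  tab <- generate_control_cohort(n = 88, seed = 7)
  expect_equal(nrow(tab), 88 * 4)
  expect_equal(length(unique(tab$case)), 88)
  ga <- tab$ga_weeks[tab$organ == "placenta" & tab$measure == "mean_t2star"]
  expect_length(ga, 88)
  expect_true(all(ga >= 20 & ga <= 40))
  # one GA per case shared by all four measures
  expect_equal(length(unique(paste(tab$case, tab$ga_weeks))), 88)
  expect_identical(tab, generate_control_cohort(n = 88, seed = 7))
  expect_error(generate_control_cohort(n = 5), "at least 10")
  increasing <- default_ga_trends()
  increasing$placenta$mean_t2star <- c(100, 4.5)
  expect_error(generate_control_cohort(trends = increasing),
               "decreasing")
})

test_that("repeat series share truth and differ only as specified", {
  spec <- small_spec(noise_sigma = 10, seed = 21)
  ser <- generate_repeat_series(spec, k = 3)
  expect_length(ser, 3)
  for (r in 2:3) {
    expect_identical(ser[[r]]$true_t2star, ser[[1]]$true_t2star)
    expect_identical(ser[[r]]$masks$placenta$grid,
                     ser[[1]]$masks$placenta$grid)
    expect_false(identical(ser[[r]]$volume$signal, ser[[1]]$volume$signal))
  }
  expect_identical(generate_repeat_series(spec, k = 3)[[2]]$volume$signal,
                   ser[[2]]$volume$signal)  # derived seeds deterministic
  expect_error(generate_repeat_series(spec, k = 1), "at least 2")
  expect_error(generate_repeat_series(spec, k = 3, perturbations = list(NULL)),
               "one entry per repeat")
})

test_that("brain motion in one repeat inflates its pairwise difference", {
  spec <- small_spec(noise_sigma = 10, seed = 31)
  quiet <- generate_repeat_series(spec, k = 2)
  moved <- generate_repeat_series(spec, k = 2, perturbations = list(
    NULL, list(motion = list(echoes = 2:4, shift = c(4, 0, 0)))))
  mean_brain <- function(p) {
    map <- fit_volume(p$volume, fit_options(method = "loglinear"))
    suppressWarnings(summarize_organ(map, p$masks$fetal_brain, 37))$mean_t2star
  }
  diff_quiet <- abs(mean_brain(quiet[[1]]) - mean_brain(quiet[[2]]))
  diff_moved <- abs(mean_brain(moved[[1]]) - mean_brain(moved[[2]]))
  expect_gt(diff_moved, diff_quiet)
})

test_that("repeat-to-repeat variability grows with the noise level", {
  sds <- vapply(c(2, 5, 10), function(sig) {
    diffs <- vapply(1:12, function(s) {
      ser <- generate_repeat_series(
        phantom_spec(grid_shape = c(24, 24, 18), noise_sigma = sig,
                     seed = 1000 + s), k = 2)
      means <- vapply(ser, function(p) {
        map <- fit_volume(p$volume, fit_options(method = "loglinear"))
        suppressWarnings(
          summarize_organ(map, p$masks$placenta, 37))$mean_t2star
      }, 0)
      means[1] - means[2]
    }, 0)
    sd(diffs)
  }, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("phantom files and spec YAML round trip", {
  spec <- small_spec(noise_sigma = 8, seed = 91)
  ph <- generate_phantom(spec)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "volume.nii.gz")))
  back_spec <- read_phantom_spec(file.path(dir, "spec.yaml"))
  ph2 <- generate_phantom(back_spec)
  expect_identical(ph2$volume$signal, ph$volume$signal)
  vol <- read_multi_echo(file.path(dir, "volume.nii.gz"), spec$echo_times)
  expect_equal(vol$signal, ph$volume$signal, tolerance = 1e-6)
})
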