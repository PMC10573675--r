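test_that("phantom simulation: empty, analytic truth, determinism, bounds", {
  empty <- phantom_spec(c(10, 10, 10), spacing = c(1, 1, 1))
  ph <- simulate_phantom(empty, seed = 1)
  expect_equal(nrow(ph$truth), 0)
  expect_true(all(abs(ph$volume$voxels - 40) < 200))  # background only

  sp <- phantom_spec(c(24, 24, 24), spacing = c(1, 1, 1),
                     stones = list(stone_sphere(c(12, 12, 12), 6)))
  ph <- simulate_phantom(sp, seed = 2)
  expect_equal(ph$truth$true_volume_mm3, 4 / 3 * pi * 216)  # 904.78 analytic

  # same spec, same seed: bit-identical; truth independent of the noise seed
  ph2 <- simulate_phantom(sp, seed = 2)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)
  ph3 <- simulate_phantom(sp, seed = 99)
  expect_false(identical(ph$volume$voxels, ph3$volume$voxels))
  expect_identical(ph$truth, ph3$truth)

  expect_error(phantom_spec(c(10, 10, 10), spacing = c(1, 1, 1),
                            stones = list(stone_sphere(c(5, 5, 5), 8))),
               "outside")
  expect_error(phantom_spec(c(30, 30, 30), spacing = c(1, 1, 1),
                            stones = list(stone_sphere(c(15, 15, 15), 5,
                                                       hu_core = 200))),
               "300 HU")
})

test_that("noise-free phantoms recover analytic volume within the surface bound", {
  r <- 6
  truth <- 4 / 3 * pi * r^3
  for (h in c(1.0, 0.5)) {
    n <- ceiling((2 * r + 8) / h)
    sp <- phantom_spec(rep(n, 3), spacing = rep(h, 3),
                       stones = list(stone_sphere(rep(n * h / 2, 3), r)),
                       background_hu_sd = 0, blur_sigma_mm = 0, noise_sd_hu = 0)
    ph <- simulate_phantom(sp, seed = 3)
    seg <- segment_stones(ph$volume, c(600, 2000), measure_diameters = FALSE)
    expect_lt(abs(seg$total_volume_mm3 - truth), 4 * pi * r^2 * h)
  }
})

test_that("staghorn truth: branched union exceeds its pelvis, overlap counted once", {
  st <- stone_staghorn(c(0, 0, 0), size_mm = 6)
  v_union <- true_stone_volume(st, spacing_mm = 1, oversample = 4)
  pelvis <- 4 / 3 * pi * prod(6 * c(1.0, 0.65, 0.6))
  sum_parts <- sum(sapply(st$components, function(cp)
    4 / 3 * pi * prod(cp$semi_axes)))
  expect_gt(v_union, pelvis)       # branches add material
  expect_lt(v_union, sum_parts)    # overlaps not double counted

  # numeric path agrees with the closed form on a plain ellipsoid
  el <- stone_ellipsoid(c(0, 0, 0), c(5, 3, 2), rotation_deg = c(30, 20, 10))
  el_num <- el; el_num$shape <- "staghorn"  # force the voxelization path
  expect_equal(true_stone_volume(el_num, spacing_mm = 1, oversample = 8),
               4 / 3 * pi * 30, tolerance = 0.01)
})

test_that("heterogeneous (core/shell) stones are flagged by the segmenter", {
  sp <- phantom_spec(c(30, 30, 30), spacing = c(0.5, 0.5, 0.5),
                     stones = list(stone_sphere(c(7.5, 7.5, 7.5), 5,
                                                hu_core = 1500, hu_shell = 700)),
                     background_hu_sd = 0, blur_sigma_mm = 0, noise_sd_hu = 0)
  ph <- simulate_phantom(sp, seed = 4)
  seg <- segment_stones(ph$volume, c(600, 2000))
  expect_equal(seg$n_segments, 1)
  expect_true(seg$segments$is_heterogeneous)  # HU range 800 > 600
})

test_that("observer simulation: row count, zero jitter, degenerate windows", {
  set.seed(41)
  phs <- lapply(1:3, function(i) {
    n <- 20
    simulate_phantom(phantom_spec(rep(n, 3), spacing = c(1, 1, 1),
                                  stones = list(stone_sphere(rep(10, 3), 4 + i)),
                                  blur_sigma_mm = 0.8, noise_sd_hu = 15),
                     seed = i)
  })
  panel <- rbind(observer_model("A", 600, 0), observer_model("B", 650, 0))
  tab <- simulate_observer_measurements(phs, panel, n_replicates = 4, seed = 5)
  expect_equal(nrow(tab), 3 * 2 * 4)  # cases x observers x replicates
  expect_true(all(c("is_complex", "is_homogeneous", "is_multiple", "location")
                  %in% names(tab)))

  # zero jitter: replicates identical, CV exactly 0
  cv <- coefficient_of_variation(tab)
  expect_true(all(cv$per_case$cv_percent == 0))

  # mean above hu_high forces the bounded-retry warning path
  bad <- observer_model("Z", 5000, 1)
  expect_warning(simulate_observer_measurements(phs[1], bad, n_replicates = 1,
                                                hu_high = 3000, seed = 6),
                 "degenerate")
})

test_that("larger threshold jitter raises replicate variability", {
  phs <- lapply(1:4, function(i)
    simulate_phantom(phantom_spec(c(24, 24, 24), spacing = c(1, 1, 1),
                                  stones = list(stone_sphere(rep(12, 3),
                                                             4 + 0.8 * i)),
                                  blur_sigma_mm = 1, noise_sd_hu = 10),
                     seed = 100 + i))
  mean_cv <- function(sd_hu, seed) {
    panel <- observer_model("A", 600, sd_hu)
    tab <- simulate_observer_measurements(phs, panel, n_replicates = 5,
                                          seed = seed)
    mean(coefficient_of_variation(tab)$per_case$cv_percent, na.rm = TRUE)
  }
  seeds <- 1:8
  low <- mean(sapply(seeds, function(s) mean_cv(15, s)))
  high <- mean(sapply(seeds, function(s) mean_cv(80, s + 500)))
  expect_gt(high, low)
})

test_that("end-to-end parameter recovery: agreement tightens as jitter vanishes", {
  phs <- lapply(1:6, function(i)
    simulate_phantom(phantom_spec(c(22, 22, 22), spacing = c(1, 1, 1),
                                  stones = list(stone_sphere(rep(11, 3),
                                                             3.5 + 0.9 * i)),
                                  blur_sigma_mm = 0.8, noise_sd_hu = 10),
                     seed = 200 + i))
  run <- function(sd_hu) {
    panel <- rbind(observer_model("A", 590, sd_hu),
                   observer_model("B", 610, sd_hu),
                   observer_model("C", 630, sd_hu))
    tab <- simulate_observer_measurements(phs, panel, n_replicates = 3,
                                          seed = 7)
    fit <- suppressWarnings(agreement_study(tab, aggregation = "median"))
    list(ccc = min(fit$pairwise$lin_ccc),
         cv = mean(fit$per_observer$mean_cv_percent))
  }
  at0 <- run(0)
  expect_equal(at0$cv, 0)                 # CV -> 0 as jitter -> 0
  expect_gt(at0$ccc, 0.999)               # CCC -> 1
  at_big <- run(120)
  expect_gt(at_big$cv, at0$cv)

  # injected inter-observer window bias appears as Bland-Altman bias:
  # the higher-threshold observer segments systematically less volume
  panel <- rbind(observer_model("lowT", 520, 0), observer_model("highT", 800, 0))
  tab <- simulate_observer_measurements(phs, panel, n_replicates = 1, seed = 8)
  fit <- suppressWarnings(agreement_study(tab, aggregation = "median"))
  signed_bias <- if (fit$pairwise$observer_1[1] == "lowT")
    fit$pairwise$bias[1] else -fit$pairwise$bias[1]
  expect_gt(signed_bias, 0)  # lowT segments systematically more volume
})

test_that("branched stones are harder to re-measure than spheres", {
  # same jitter, matched scale: staghorn per-case CV >= sphere CV on average
  cv_for <- function(shape_fun, seed) {
    ph <- simulate_phantom(
      phantom_spec(c(44, 44, 44), spacing = c(1, 1, 1),
                   stones = list(shape_fun), blur_sigma_mm = 1,
                   noise_sd_hu = 10),
      seed = seed)
    tab <- simulate_observer_measurements(
      list(ph), observer_model("A", 600, 60), n_replicates = 5,
      seed = seed + 1)
    coefficient_of_variation(tab)$per_case$cv_percent
  }
  sph <- stone_sphere(c(22, 22, 22), 7)
  stag <- stone_staghorn(c(16, 20, 22), 5)
  seeds <- seq(300, 300 + 19 * 7, by = 7)  # 20 seeds
  cv_sph <- sapply(seeds, function(s) cv_for(sph, s))
  cv_stag <- sapply(seeds, function(s) cv_for(stag, s))
  expect_gte(mean(cv_stag), mean(cv_sph))
})

test_that("default cohort + panel reproduce the full study design", {
  phs <- default_phantom_cohort(n_cases = 4, seed = 9)
  expect_length(phs, 4)
  expect_true(all(sapply(phs, inherits, "stone_phantom")))
  panel <- default_observer_panel()
  expect_equal(nrow(panel), 3)
  tab <- simulate_observer_measurements(phs, panel, n_replicates = 5, seed = 10)
  expect_equal(nrow(tab), 4 * 3 * 5)
  expect_equal(anyDuplicated(paste(tab$case_id, tab$observer_id,
                                   tab$replicate)), 0)
})
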