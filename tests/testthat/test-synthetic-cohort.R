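test_that("volume generation is a pure function of (config, seed)", {
  cfg <- small_config()
  a <- generate_brain_volume(cfg, 123L)
  b <- generate_brain_volume(cfg, 123L)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$landmark_points, b$truth$landmark_points)
  c <- generate_brain_volume(cfg, 124L)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("disabling all stochastic terms makes subjects voxel-identical", {
  cfg <- frozen_config()
  a <- generate_brain_volume(cfg, 1L)
  b <- generate_brain_volume(cfg, 999L)
  expect_identical(a$volume$voxels, b$volume$voxels)
})

test_that("the painted layer is brighter than surrounding tissue", {
  cfg <- small_config()
  sub <- generate_brain_volume(cfg, 3L)
  v <- sub$volume$voxels
  layer_mean <- mean(v[sub$truth$layer$lin])
  tissue <- setdiff(which(v > cfg$tissue_intensity / 2), sub$truth$layer$lin)
  expect_gt(layer_mean, mean(v[tissue]))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(generate_brain_volume(small_config(), 5L))
  expect_identical(runif(1), before)
})

test_that("an empty lesion window returns the volume unchanged with a warning", {
  cfg <- small_config(lesion_ap_extent = c(0.4, 0.4))
  sub <- generate_brain_volume(cfg, 2L)
  expect_warning(out <- apply_lesion(sub$volume, sub$truth, cfg, 9L), "empty")
  expect_identical(out$volume$voxels, sub$volume$voxels)
  expect_true(out$truth$lesion_warning)
  expect_equal(out$truth$label, "control")
})

test_that("a full-extent lesion at zero cavity darkens the layer", {
  cfg <- small_config(lesion_ap_extent = c(0, 1), cavity_intensity = 0,
                      noise_sd = 0)
  sub <- generate_brain_volume(cfg, 4L)
  les <- apply_lesion(sub$volume, sub$truth, cfg, 10L)
  lin <- sub$truth$layer$lin
  expect_lt(mean(les$volume$voxels[lin]), mean(sub$volume$voxels[lin]))
  expect_equal(les$truth$label, "lesion")
})

test_that("lesion changes are confined exactly to the recorded cavity mask", {
  cfg <- small_config()
  sub <- generate_brain_volume(cfg, 6L)
  les <- apply_lesion(sub$volume, sub$truth, cfg, 11L)
  diff_lin <- which(les$volume$voxels != sub$volume$voxels)
  expect_setequal(diff_lin, les$truth$lesioned_voxel_mask)
  # and the cavity sits inside a dilation of the in-window layer core
  ext <- cfg$lesion_ap_extent
  core <- sub$truth$layer$lin[sub$truth$layer$t >= ext[1] &
                              sub$truth$layer$t <= ext[2]]
  d <- cfg$grid_shape
  m <- array(FALSE, d)
  m[core] <- TRUE
  allowed <- which(dilate_mask(m, cfg$lesion_margin, 26L))
  expect_true(all(diff_lin %in% allowed))
})

test_that("electrode insertion honors layout, tips, and empty layouts", {
  cfg <- small_config()
  sub <- generate_brain_volume(cfg, 8L)
  empty <- cannula_layout(0, 0)
  out <- insert_electrodes(sub$volume, sub$truth, cfg, empty)
  expect_identical(out$volume$voxels, sub$volume$voxels)
  one <- cannula_layout(1, 1, anchor = c(25, 30))
  out1 <- insert_electrodes(sub$volume, sub$truth, cfg, one, tip_depths = 24)
  expect_equal(out1$truth$electrode_tips$ap, 25)
  expect_equal(out1$truth$electrode_tips$dv, 24)
  expect_equal(out1$truth$electrode_tips$ml, 30)
  # one above-threshold connected component in a horizontal slice through
  # the rod
  sl <- out1$volume$voxels[, 15, ] > cfg$layer_intensity * 1.5
  lab <- label_components(sl, connectivity = 8L)
  expect_equal(max(lab), 1L)
  # a tip below the grid is clipped with a warning
  expect_warning(insert_electrodes(sub$volume, sub$truth, cfg, one,
                                   tip_depths = 500), "clipped")
  expect_error(insert_electrodes(sub$volume, sub$truth, cfg,
                                 cannula_layout(1, 1, anchor = c(500, 30))),
               "outside")
})

test_that("cohort generation yields labeled, reproducible subjects", {
  cfg <- small_config(n_control = 2L, n_lesion = 3L, master_seed = 42L)
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, 5L)
  expect_equal(sum(coh$labels == "control"), 2L)
  expect_equal(sum(coh$labels == "lesion"), 3L)
  has_mask <- vapply(coh$subjects,
                     function(s) length(s$truth$lesioned_voxel_mask) > 0,
                     logical(1))
  expect_equal(has_mask, coh$labels == "lesion")
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$subjects[[5]]$volume$voxels,
                   coh2$subjects[[5]]$volume$voxels)
  none <- generate_cohort(small_config(n_control = 2L, n_lesion = 0L))
  expect_true(all(none$labels == "control"))
})

test_that("LFP sessions realize the requested offsets, SNR, and schedule", {
  po <- phase_offset_spec(c(0, 0), snr = Inf, duration = 4)
  ses <- generate_lfp_session(po, fs = 600, seed = 1L)
  expect_identical(ses$lfp$data[1, ], ses$lfp$data[2, ])
  anti <- generate_lfp_session(phase_offset_spec(c(0, pi), snr = Inf,
                                                 duration = 4),
                               fs = 600, seed = 1L)
  expect_equal(stats::cor(anti$lfp$data[1, ], anti$lfp$data[2, ]), -1,
               tolerance = 1e-9)
  expect_warning(phase_offset_spec(c(0, 3 * pi / 2)), "wrapped")
  # speed alternates above/below the 10 cm/s criterion per the schedule
  sch <- run_schedule(run_s = 2, still_s = 1)
  s <- generate_lfp_session(po, fs = 600, schedule = sch, speed_fs = 10,
                            seed = 1L)$speed
  expect_equal(s$values[1:20], rep(25, 20))
  expect_equal(s$values[21:30], rep(3, 10))
  expect_error(generate_lfp_session(po, fs = 10), "fs")
})

test_that("derived seeds are deterministic, distinct, and bounded", {
  s1 <- derive_seed(1L, 1L)
  expect_identical(s1, derive_seed(1L, 1L))
  seeds <- vapply(1:200, function(i) derive_seed(7L, i), integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
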