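test_that("rigid estimation recovers constructed transforms", {
  P <- landmark_set(rbind(a = c(0, 0, 0), b = c(10, 0, 0), c = c(0, 8, 0),
                          d = c(3, 2, 7)))
  # identity
  t0 <- estimate_rigid(P, P)
  expect_lt(max(abs(t0$rotation - diag(3))), 1e-10)
  expect_lt(max(abs(t0$translation)), 1e-10)
  # 10 degrees about the DV axis plus a translation
  th <- 10 * pi / 180
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  tr <- c(3, -2, 5)
  Q <- landmark_set(sweep(P$points %*% t(R), 2, tr, `+`),
                    names = rownames(P$points))
  est <- estimate_rigid(P, Q)
  expect_lt(max(abs(est$rotation - R)), 1e-8)
  expect_lt(max(abs(est$translation - tr)), 1e-8)
})

test_that("noisy alignment never increases landmark RMSD", {
  set.seed(5)
  for (rep in 1:10) {
    P <- matrix(runif(18, 0, 20), 6, 3)
    R <- random_rotation()
    tr <- runif(3, -5, 5)
    Q <- sweep(P %*% t(R), 2, tr, `+`) + matrix(rnorm(18, 0, 0.5), 6, 3)
    nm <- letters[1:6]
    est <- estimate_rigid(landmark_set(P, nm), landmark_set(Q, nm))
    pre <- sqrt(mean((P - Q)^2))
    post <- sqrt(mean((apply_rigid(est, P) - Q)^2))
    expect_lte(post, pre + 1e-12)
  }
})

test_that("degenerate landmark configurations are rejected", {
  P <- landmark_set(rbind(a = c(0, 0, 0), b = c(1, 1, 1), c = c(2, 2, 2)))
  expect_error(estimate_rigid(P, P), "collinear")
  expect_error(estimate_rigid(
    landmark_set(rbind(a = c(0, 0, 0), b = c(1, 0, 0))),
    landmark_set(rbind(a = c(0, 0, 0), b = c(1, 0, 0)))), "3 correspondences")
})

test_that("transform algebra closes: inverse and composition", {
  set.seed(8)
  R <- random_rotation()
  t1 <- lesionscope:::new_rigid_transform(R, c(1, -2, 3))
  inv <- invert_rigid(t1)
  id <- compose_rigid(inv, t1)
  expect_lt(max(abs(id$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(id$translation)), 1e-12)
  P <- matrix(runif(15), 5, 3)
  expect_equal(apply_rigid(inv, apply_rigid(t1, P)), P, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("resampling honors identity, pure shifts, and fill values", {
  cfg <- frozen_config()
  vol <- generate_brain_volume(cfg, 1L)$volume
  idt <- lesionscope:::new_rigid_transform(diag(3), c(0, 0, 0))
  same <- resample_to_reference(vol, idt)
  expect_equal(same$voxels, vol$voxels, tolerance = 1e-12)
  # translating the source by exactly +1 voxel along AP index-shifts it
  sh <- lesionscope:::new_rigid_transform(diag(3), c(1, 0, 0))
  out <- resample_to_reference(vol, sh, fill_value = -1)
  d <- dim(vol$voxels)
  expect_equal(out$voxels[2:d[1], , ], vol$voxels[1:(d[1] - 1), , ],
               tolerance = 1e-12)
  # a transform mapping everything out of domain yields pure fill
  far <- lesionscope:::new_rigid_transform(diag(3), c(1e4, 0, 0))
  off <- resample_to_reference(vol, far, fill_value = 0.123)
  expect_true(all(off$voxels == 0.123))
})

test_that("resampling there-and-back reproduces interior voxels", {
  cfg <- frozen_config()
  vol <- generate_brain_volume(cfg, 2L)$volume
  th <- 3 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tf <- lesionscope:::new_rigid_transform(R, c(0.4, -0.7, 0.2))
  fwd <- resample_to_reference(vol, tf)
  back <- resample_to_reference(fwd, invert_rigid(tf))
  d <- dim(vol$voxels)
  core <- list(10:(d[1] - 10), 10:(d[2] - 10), 10:(d[3] - 10))
  a <- vol$voxels[core[[1]], core[[2]], core[[3]]]
  b <- back$voxels[core[[1]], core[[2]], core[[3]]]
  # interpolation smooths; tolerance scales with the local intensity step
  expect_lt(stats::quantile(abs(a - b), 0.99), cfg$layer_intensity / 2)
  expect_lt(mean(abs(a - b)), 0.02)
})

test_that("landmarks are found near ground truth and scale-invariantly", {
  cfg <- frozen_config()
  sub <- generate_brain_volume(cfg, 1L)
  lm <- detect_anatomical_landmarks(sub$volume)
  truth <- do.call(rbind, sub$truth$landmark_points)
  err <- sqrt(rowSums((lm$points - truth[rownames(lm$points), ])^2))
  expect_true(all(err < 2))
  # global affine intensity rescaling leaves the landmarks untouched
  scaled <- sub$volume
  scaled$voxels <- scaled$voxels * 2
  lm2 <- detect_anatomical_landmarks(scaled)
  expect_equal(lm2$points, lm$points)
  shifted <- sub$volume
  shifted$voxels <- shifted$voxels * 1.7 + 0.1
  lm3 <- detect_anatomical_landmarks(shifted)
  expect_equal(lm3$points, lm$points)
})

test_that("an invisible layer raises a landmarks-not-found error", {
  cfg <- frozen_config()
  sub <- generate_brain_volume(cfg, 1L)
  flat <- sub$volume
  flat$voxels[flat$voxels > cfg$tissue_intensity] <- cfg$tissue_intensity
  expect_error(detect_anatomical_landmarks(flat), "landmarks not found")
})
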