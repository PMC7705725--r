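test_that("the normalized frame maps its defining points to (0,0) and (1,1)", {
  fr <- make_frame(c(10, 20), c(110, 70))
  expect_equal(normalize_points(cbind(10, 20), fr)[1, ], c(ap = 0, ml = 0))
  expect_equal(normalize_points(cbind(110, 70), fr)[1, ], c(ap = 1, ml = 1))
  expect_equal(normalize_points(cbind(60, 45), fr)[1, ], c(ap = 0.5, ml = 0.5))
  expect_error(make_frame(c(10, 20), c(10, 70)), "AP axis")
  expect_error(make_frame(c(10, 20), c(110, 20)), "ML axis")
})

test_that("normalization is invariant to axis-aligned translation and scaling", {
  set.seed(2)
  pts <- cbind(runif(10, 0, 100), runif(10, 0, 50))
  fr <- make_frame(c(5, 4), c(80, 44))
  base <- normalize_points(pts, fr)
  # common translation of points and both landmarks
  dd <- c(13, -7)
  fr_t <- make_frame(c(5, 4) + dd, c(80, 44) + dd)
  expect_equal(normalize_points(sweep(pts, 2, dd, `+`), fr_t), base,
               tolerance = 1e-12)
  # per-axis positive scaling
  s <- c(1, 3.7)
  fr_s <- make_frame(c(5, 4) * s, c(80, 44) * s)
  expect_equal(normalize_points(sweep(pts, 2, s, `*`), fr_s), base,
               tolerance = 1e-12)
  # exact round trip
  expect_equal(denormalize_points(base, fr), pts, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("layer curves of a noiseless subject track the template geometry", {
  cfg <- frozen_config()
  sub <- generate_brain_volume(cfg, 1L)
  lm <- detect_anatomical_landmarks(sub$volume)
  frames <- frames_from_landmarks(lm)
  curves <- extract_layer_curves(sub$volume, frames)
  expect_true(all(c("lateral", "medial") %in% curves$curve))
  # ground truth: lateral extreme of the generator's painted layer voxels
  d <- cfg$grid_shape
  lay <- cbind(arrayInd(sub$truth$layer$lin, d) - 1L)
  mid <- (d[3] - 1) / 2
  for (side in c("left", "right")) {
    s <- if (side == "left") -1 else 1
    cv <- curves[curves$side == side & curves$curve == "lateral", ]
    ls <- lay[(if (s < 0) lay[, 3] < mid else lay[, 3] > mid), , drop = FALSE]
    true_ml <- vapply(cv$ap, function(ap) {
      sl <- ls[ls[, 1] == ap, , drop = FALSE]
      sl[which.max(s * (sl[, 3] - mid)), 3]
    }, numeric(1))
    true_norm <- normalize_points(cbind(cv$ap, true_ml), frames[[side]])
    # within 2 normalized percent of the ground-truth geometry on ML
    expect_lt(stats::median(abs(cv$ml_norm - true_norm[, 2])), 0.02)
    expect_lt(max(abs(cv$ml_norm - true_norm[, 2])), 0.1)
  }
})

test_that("a volume without a dentate sheet yields no medial curve", {
  cfg <- frozen_config(dentate = FALSE)
  sub <- generate_brain_volume(cfg, 1L)
  frames <- frames_from_landmarks(detect_anatomical_landmarks(sub$volume))
  curves <- extract_layer_curves(sub$volume, frames)
  expect_true(nrow(curves[curves$curve == "lateral", ]) > 0)
  expect_equal(nrow(curves[curves$curve == "medial", ]), 0L)
})

test_that("electrode tips are detected at ground truth and merged rods flagged", {
  cfg <- frozen_config()
  sub <- generate_brain_volume(cfg, 2L)
  layout <- cannula_layout(2, 2, spacing = 8, anchor = c(22, 27))
  out <- insert_electrodes(sub$volume, sub$truth, cfg, layout, tip_depths = 22)
  det <- detect_electrode_tips(out$volume)
  expect_equal(nrow(det$tips), 4L)
  tr <- out$truth$electrode_tips
  for (k in seq_len(nrow(tr))) {
    dmin <- min(sqrt((det$tips$ap - tr$ap[k])^2 + (det$tips$dv - tr$dv[k])^2 +
                     (det$tips$ml - tr$ml[k])^2))
    expect_lt(dmin, 1)
  }
  expect_false(any(det$tips$ambiguous))
  # nothing above the quantile: empty set
  flat <- sub$volume
  none <- detect_electrode_tips(flat)
  expect_equal(nrow(none$tips), 0L)
  # two rods closer than 2 voxels merge into one flagged component
  tight <- data.frame(slot = c("a", "b"), ap = c(30, 31), ml = c(24, 24),
                      occupied = TRUE)
  out2 <- insert_electrodes(sub$volume, sub$truth, cfg, tight, tip_depths = 22)
  det2 <- detect_electrode_tips(out2$volume)
  expect_equal(nrow(det2$tips), 1L)
})

test_that("electrode detection has full recall and no false positives across seeds", {
  layout <- cannula_layout(2, 3, spacing = 6, anchor = c(22, 24))
  for (seed in 1:5) {
    cfg <- small_config(master_seed = seed)
    sub <- generate_brain_volume(cfg, derive_seed(seed, 1L))
    out <- insert_electrodes(sub$volume, sub$truth, cfg, layout,
                             tip_depths = 22)
    det <- detect_electrode_tips(out$volume)
    expect_equal(nrow(det$tips), nrow(out$truth$electrode_tips),
                 label = sprintf("rod count at seed %d", seed))
    for (k in seq_len(nrow(out$truth$electrode_tips))) {
      tr <- out$truth$electrode_tips[k, ]
      dmin <- min(sqrt((det$tips$ap - tr$ap)^2 + (det$tips$dv - tr$dv)^2 +
                       (det$tips$ml - tr$ml)^2))
      expect_lt(dmin, 1.5)
    }
  }
})

test_that("cannula matching recovers assignments under similarity transforms", {
  layout <- cannula_layout(3, 3, spacing = 5, anchor = c(0, 0))
  P <- as.matrix(layout[, c("ap", "ml")])
  # exact detections: identity assignment with zero residual
  m0 <- match_cannula(P, layout)
  expect_equal(m0$assignment$det_ap, m0$assignment$ap)
  expect_lt(m0$rms, 1e-9)
  # rotated, scaled, translated detections
  th <- 15 * pi / 180
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Q <- sweep(1.2 * P %*% t(Rm), 2, c(40, -10), `+`)
  m1 <- match_cannula(Q, layout)
  expect_equal(m1$assignment$slot[!is.na(m1$assignment$det_ap)], layout$slot)
  ord <- match(layout$slot, m1$assignment$slot)
  expect_lt(max(abs(cbind(m1$assignment$det_ap, m1$assignment$det_ml)[ord, ] - Q)),
            1e-6)
  # drop one slot's detection: that slot unassigned, the rest correct
  drop <- 5L
  m2 <- match_cannula(Q[-drop, ], layout)
  expect_true(is.na(m2$assignment$det_ap[drop]))
  ok <- setdiff(seq_len(nrow(P)), drop)
  expect_lt(max(abs(m2$assignment$det_ap[ok] - Q[ok, 1])), 1e-6)
  expect_error(match_cannula(Q[1, , drop = FALSE], layout), ">= 2")
})
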