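# Small aligned "cohorts" for similarity tests are built directly on the
# reference grid (no jitter), so no alignment step is needed.
make_test_cohort <- function(cfg, seeds, ids = NULL) {
  vols <- lapply(seq_along(seeds), function(i) {
    v <- generate_brain_volume(cfg, seeds[i],
                               if (is.null(ids)) sprintf("S%02d", i) else ids[i])
    v$volume
  })
  vols
}

test_that("slice-wise similarity is symmetric with unit diagonal and detects duplicates", {
  cfg <- small_config(pose_jitter = list(rot_deg = 0, trans_vox = 0))
  mask <- make_region_mask(cfg, margin = 3L)
  vols <- make_test_cohort(cfg, c(1L, 2L, 1L))   # subjects 1 and 3 identical
  sim <- masked_slicewise_similarity(vols, mask, ids = c("a", "b", "a2"))
  expect_equal(diag(sim$S_bar), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(sim$S_bar, t(sim$S_bar))
  expect_true(all(sim$S_bar <= 1 + 1e-12))
  expect_equal(sim$S_bar["a", "a2"], 1, tolerance = 1e-12)
  # per-slice matrices share the invariants
  expect_true(all(apply(sim$S_slices, 3, function(M) max(abs(M - t(M)))) < 1e-12))
})

test_that("the averaged matrix is the arithmetic mean of per-slice values", {
  cfg <- small_config(pose_jitter = list(rot_deg = 0, trans_vox = 0))
  mask <- make_region_mask(cfg, margin = 3L)
  vols <- make_test_cohort(cfg, c(3L, 4L, 5L))
  slices <- mask$slices[1:3]
  sim <- masked_slicewise_similarity(vols, mask, ap_slices = slices)
  manual <- matrix(0, 3, 3)
  for (e in seq_len(dim(sim$S_slices)[3])) manual <- manual + sim$S_slices[, , e]
  manual <- manual / dim(sim$S_slices)[3]
  expect_equal(unname(sim$S_bar), manual, tolerance = 1e-12)
})

test_that("nearest-control profiles take maxima and exclude self", {
  # toy hand-built result: 3 subjects (2 controls, 1 lesion), 3 slices
  S <- array(1, dim = c(3, 3, 3))
  vals <- list(c(0.9, 0.4, 0.7), c(0.8, 0.3, 0.6), c(0.5, 0.2, 0.1))
  # slice e: S[1,2]=vals[[e]][1], S[1,3]=vals[[e]][2], S[2,3]=vals[[e]][3]
  for (e in 1:3) {
    S[1, 2, e] <- S[2, 1, e] <- vals[[e]][1]
    S[1, 3, e] <- S[3, 1, e] <- vals[[e]][2]
    S[2, 3, e] <- S[3, 2, e] <- vals[[e]][3]
  }
  res <- structure(list(S_bar = apply(S, c(1, 2), mean), S_slices = S,
                        slice_info = data.frame(ap = 1:3, side = "right"),
                        ids = c("c1", "c2", "l1")),
                   class = "similarity_result")
  prof <- nearest_control_profile(res, c("c1", "c2"), "l1")
  # controls: similarity to the only other control (S12 per slice);
  # lesion: max over the controls (S13 vs S23 per slice)
  expect_equal(unname(prof$values["c1", ]), c(0.9, 0.8, 0.5))
  expect_equal(unname(prof$values["c2", ]), c(0.9, 0.8, 0.5))
  expect_equal(unname(prof$values["l1", ]),
               c(max(0.4, 0.7), max(0.3, 0.6), max(0.2, 0.1)))
  expect_error(nearest_control_profile(res, "c1", c("c2", "l1")),
               "at least 2 controls")
  expect_error(nearest_control_profile(res, c("c1", "x"), "l1"), "partition")
})

test_that("a lesion brain identical to a control profiles at exactly 1", {
  cfg <- small_config(pose_jitter = list(rot_deg = 0, trans_vox = 0))
  mask <- make_region_mask(cfg, margin = 3L)
  vols <- make_test_cohort(cfg, c(1L, 2L, 1L), ids = c("c1", "c2", "l1"))
  sim <- masked_slicewise_similarity(vols, mask, ids = c("c1", "c2", "l1"))
  prof <- nearest_control_profile(sim, c("c1", "c2"), "l1")
  expect_true(all(abs(prof$values["l1", ] - 1) < 1e-12))
})

test_that("group summaries follow the inclusive linear-interpolation quantiles", {
  vals <- matrix(c(1, 2, 3, 4, 5), 5, 1)
  rownames(vals) <- paste0("c", 1:5)
  prof <- structure(list(values = vals,
                         slice_info = data.frame(ap = 0, side = "left"),
                         control_ids = paste0("c", 1:5),
                         lesion_ids = character(0),
                         ids = paste0("c", 1:5)),
                    class = "nearest_control_profile")
  s <- summarize_groups(prof)
  expect_equal(s$median, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  # single-subject group: median is the value, zero-width IQR
  prof1 <- prof
  prof1$values <- vals[1, , drop = FALSE]
  prof1$control_ids <- "c1"
  prof1$ids <- "c1"
  s1 <- summarize_groups(prof1)
  expect_equal(s1$median, 1)
  expect_equal(s1$q75 - s1$q25, 0)
  # random profiles match an independent sort-based quantile computation
  set.seed(9)
  vr <- matrix(runif(40), 8, 5, dimnames = list(paste0("c", 1:8), NULL))
  profr <- structure(list(values = vr,
                          slice_info = data.frame(ap = 1:5, side = "left"),
                          control_ids = rownames(vr),
                          lesion_ids = character(0), ids = rownames(vr)),
                     class = "nearest_control_profile")
  sr <- summarize_groups(profr)
  sort_quantile <- function(x, p) {
    x <- unname(sort(x))
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (j in 1:5) {
    expect_equal(sr$median[j], sort_quantile(vr[, j], 0.5), tolerance = 1e-12)
    expect_equal(sr$q25[j], sort_quantile(vr[, j], 0.25), tolerance = 1e-12)
    expect_equal(sr$q75[j], sort_quantile(vr[, j], 0.75), tolerance = 1e-12)
  }
})

test_that("purity counting scores mixed and pure groups correctly", {
  labels <- c("control", "control", "lesion", "lesion", "lesion")
  expect_equal(group_purity_count(c(1, 1, 2, 2, 2), labels), 5L)
  expect_equal(group_purity_count(c(1, 2, 2, 2, 2), labels), 1L)
  expect_equal(group_purity_count(c(1, 1, 1, 1, 1), labels), 0L)
})
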