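#' Configuration for an end-to-end pipeline run
#'
#' @param cohort A [cohort_config()].
#' @param mask_margin Dilation margin of the hippocampal region mask
#'   (voxels).
#' @param window_sigma SSIM Gaussian sigma; `NULL` for the width-scaled
#'   default (see [masked_slicewise_similarity()]).
#' @param cluster_k Number of major groups cut from the dendrogram
#'   (default 2: lesion vs control).
#' @param cluster_extent Fractional septo-temporal window whose slices feed
#'   the clustering average; defaults to the cohort's lesion window (the
#'   lesioned portion of the hippocampal formation).
#' @param profile Compute full-extent nearest-control profiles (adds the
#'   slices outside the clustering window)?
#' @param layout Cannula layout for the electrode pipeline.
#' @param tip_depths Electrode tip depths (DV voxels).
#' @param theta List for the theta pipeline: `offsets` (radians; `NULL`
#'   derives a uniform dorsal-to-intermediate gradient over the occupied
#'   slots), `snr`, `duration` (s), `fs`.
#' @param out_dir Directory for persisted artifacts (`NULL`: keep in
#'   memory only).
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       mask_margin = 4L,
                       window_sigma = NULL,
                       cluster_k = 2L,
                       cluster_extent = NULL,
                       profile = TRUE,
                       layout = NULL,
                       tip_depths = 40,
                       theta = list(offsets = NULL, snr = 10, duration = 600,
                                    fs = 1500),
                       out_dir = NULL) {
  if (is.null(cluster_extent)) cluster_extent <- cohort$lesion_ap_extent
  if (is.null(layout)) {
    layout <- cannula_layout()
    layout$occupied[c(3L, 8L)] <- FALSE     # unoccupied slots ("X" positions)
  }
  stopifnot(cluster_k >= 1L)
  structure(list(cohort = cohort, mask_margin = as.integer(mask_margin),
                 window_sigma = window_sigma, cluster_k = as.integer(cluster_k),
                 cluster_extent = cluster_extent, profile = isTRUE(profile),
                 layout = layout, tip_depths = tip_depths, theta = theta,
                 out_dir = out_dir),
            class = "run_config")
}

#' AP slices covered by a fractional septo-temporal window
#'
#' Maps a fractional window along the model layer to 0-based AP slice
#' indices of the reference grid. The window boundaries generally fall
#' between slices: `"inner"` returns only slices lying entirely inside the
#' window, `"outer"` every slice containing any part of it. Slices in the
#' outer but not the inner set straddle the boundary (e.g. partially
#' lesioned slices at the edge of a lesion window).
#'
#' @param config A [cohort_config()].
#' @param extent Length-2 fractional interval in `[0, 1]`.
#' @param boundary `"inner"` (default) or `"outer"`.
#' @return Integer vector of 0-based AP slice indices.
#' @export
extent_to_slices <- function(config, extent, boundary = c("inner", "outer")) {
  boundary <- match.arg(boundary)
  d <- config$grid_shape
  span <- config$geometry$ap_span * (d[1] - 1)
  w <- span[1] + extent * diff(span)
  if (boundary == "inner") seq(ceiling(w[1]), floor(w[2]))
  else seq(floor(w[1]), ceiling(w[2]))
}

# Reference-grid sub-box covering a region mask (plus padding), as index
# lists for resample_to_reference().
mask_region <- function(mask, pad = 2L) {
  d <- dim(mask$mask)
  idx <- which(mask$mask)
  co <- arrayInd(idx, d)
  lapply(1:3, function(j) {
    r <- range(co[, j])
    max(1L, r[1] - pad):min(d[j], r[2] + pad)
  })
}

#' Align a cohort of volumes into the canonical reference frame
#'
#' Detects the hippocampal-layer landmarks in each subject, estimates the
#' least-squares rigid transform onto the canonical template landmarks, and
#' resamples each volume onto the reference grid (restricted to the region
#' covering the analysis mask, for economy). Only the lesion-robust anchors
#' (anterior tips and posterior-ventral extremes) drive the fit, so lesioned
#' brains align as reliably as controls. No ground-truth information is
#' consumed: alignment runs entirely on image content.
#'
#' @param volumes List of `brain_volume`s.
#' @param config The [cohort_config()] defining the reference template.
#' @param mask Optional [make_region_mask()] result; derived from `config`
#'   when `NULL`.
#' @param region_pad Padding (voxels) around the mask bounding box.
#' @return List with `aligned` (volumes), `transforms`, `landmarks`.
#' @export
align_cohort <- function(volumes, config, mask = NULL, region_pad = 2L) {
  if (is.null(mask)) mask <- make_region_mask(config)
  ref_lm <- canonical_landmark_set(config)
  region <- mask_region(mask, region_pad)
  d <- config$grid_shape
  aligned <- vector("list", length(volumes))
  transforms <- vector("list", length(volumes))
  lms <- vector("list", length(volumes))
  use <- alignment_landmark_names
  ref_sub <- landmark_set(ref_lm$points[use, , drop = FALSE], space = ref_lm$space)
  for (i in seq_along(volumes)) {
    lm <- detect_anatomical_landmarks(volumes[[i]])
    lm_sub <- landmark_set(lm$points[use, , drop = FALSE], space = lm$space)
    tf <- estimate_rigid(lm_sub, ref_sub)
    aligned[[i]] <- resample_to_reference(volumes[[i]], tf, d,
                                          fill_value = config$tissue_intensity,
                                          region = region)
    transforms[[i]] <- tf
    lms[[i]] <- lm
  }
  list(aligned = aligned, transforms = transforms, landmarks = lms)
}

#' Run the lesion quantification pipeline end to end
#'
#' Generates (or accepts) a cohort, aligns all brains to the common
#' reference, computes masked slice-wise SSIM bilaterally, clusters
#' `1 - SSIM` (averaged over the lesioned septo-temporal window) with
#' single linkage, cuts the dendrogram into `cluster_k` major groups, and
#' derives nearest-control profiles with per-slice group medians and
#' interquartile ranges. Surgery labels are consumed only by the final
#' evaluation (group purity, profile grouping), never by the analysis
#' stages.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built [generate_cohort()] result.
#' @return A `lesion_report` list: `similarity`, `cluster_sbar`,
#'   `dendrogram`, `groups`, `purity`, `profile` (when configured),
#'   `summary`, `ids`, `labels`, `config`.
#' @export
run_lesion_pipeline <- function(config = run_config(), cohort = NULL) {
  cc <- config$cohort
  if (is.null(cohort)) cohort <- generate_cohort(cc)
  mask <- make_region_mask(cc, margin = config$mask_margin)
  al <- align_cohort(lapply(cohort$subjects, `[[`, "volume"), cc, mask)
  cluster_slices <- extent_to_slices(cc, config$cluster_extent)
  ap_slices <- if (config$profile) NULL else cluster_slices
  sim <- masked_slicewise_similarity(al$aligned, mask,
                                     window_sigma = config$window_sigma,
                                     ap_slices = ap_slices, ids = cohort$ids)
  in_window <- sim$slice_info$ap %in% cluster_slices
  cluster_sbar <- apply(sim$S_slices[, , in_window, drop = FALSE], c(1, 2), mean)
  dimnames(cluster_sbar) <- dimnames(sim$S_bar)
  dend <- linkage_single(cluster_sbar)
  groups <- cut_groups(dend, config$cluster_k)
  purity <- group_purity_count(groups, cohort$labels)
  report <- list(similarity = sim, cluster_sbar = cluster_sbar,
                 dendrogram = dend, groups = groups, purity = purity,
                 ids = cohort$ids, labels = cohort$labels,
                 transforms = al$transforms, config = config)
  if (config$profile) {
    ctrl <- cohort$ids[cohort$labels == "control"]
    les <- cohort$ids[cohort$labels == "lesion"]
    report$profile <- nearest_control_profile(sim, ctrl, les)
    report$summary <- summarize_groups(report$profile)
  }
  class(report) <- "lesion_report"
  if (!is.null(config$out_dir)) write_lesion_report(report, config$out_dir)
  report
}

#' @export
print.lesion_report <- function(x, ...) {
  cat("<lesion_report> ", length(x$ids), " subjects; k = ",
      x$config$cluster_k, " groups; ", x$purity,
      " subjects in surgery-pure groups\n", sep = "")
  invisible(x)
}

#' Persist a lesion report as CSV/JSON artifacts
#'
#' Deterministic text outputs: rerunning the pipeline with the same config
#' and seed reproduces the files byte for byte.
#'
#' @param report A [run_lesion_pipeline()] result.
#' @param dir Output directory.
#' @export
write_lesion_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_similarity(report$similarity, file.path(dir, "similarity"))
  utils::write.csv(as.data.frame(report$cluster_sbar),
                   file.path(dir, "cluster_sbar.csv"), row.names = TRUE)
  write_dendrogram(report$dendrogram, file.path(dir, "dendrogram"))
  utils::write.csv(data.frame(subject = report$ids, label = report$labels,
                              group = as.integer(report$groups)),
                   file.path(dir, "groups.csv"), row.names = FALSE)
  if (!is.null(report$profile)) write_profiles(report$profile, dir)
  jsonlite::write_json(list(master_seed = report$config$cohort$master_seed,
                            cluster_k = report$config$cluster_k,
                            window_sigma = report$similarity$window_sigma,
                            dynamic_range = report$similarity$dynamic_range,
                            purity = report$purity),
                       file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the electrode localization pipeline end to end
#'
#' Generates a control cohort plus one electrode-implanted subject sharing
#' the same layer geometry, aligns everyone to the canonical frame, builds
#' per-hemisphere normalized frames from each subject's detected
#' landmarks, samples the layer curves of the controls (the normative
#' band), then detects the implanted subject's electrode tips, places them
#' in its normalized frame, and matches them to the cannula layout.
#'
#' @param config A [run_config()].
#' @return An `electrode_report` list: `curves` (controls), `band`,
#'   `implanted_curves`, `tips`, `assignment`, `electrode_table`,
#'   `in_band_fraction`.
#' @export
run_electrode_pipeline <- function(config = run_config()) {
  cc <- config$cohort
  stopifnot(cc$n_control >= 2L)
  ids <- sprintf("C%02d", seq_len(cc$n_control))
  subs <- lapply(seq_len(cc$n_control), function(i)
    generate_brain_volume(cc, derive_seed(cc$master_seed, i), ids[i]))
  imp <- generate_brain_volume(cc, derive_seed(cc$master_seed, 999L), "IMP")
  imp <- insert_electrodes(imp$volume, imp$truth, cc, config$layout,
                           config$tip_depths)
  mask <- make_region_mask(cc, margin = config$mask_margin)
  vols <- c(lapply(subs, `[[`, "volume"), list(imp$volume))
  al <- align_cohort(vols, cc, mask, region_pad = 4L)
  # frames in reference space: detected landmarks carried through the fit
  frames <- lapply(seq_along(vols), function(i) {
    p <- apply_rigid(al$transforms[[i]], al$landmarks[[i]]$points)
    dimnames(p) <- dimnames(al$landmarks[[i]]$points)
    frames_from_landmarks(list(points = p))
  })
  curves <- do.call(rbind, lapply(seq_len(cc$n_control), function(i)
    extract_layer_curves(al$aligned[[i]], frames[[i]])))
  band <- control_band(curves)
  ni <- length(vols)
  implanted_curves <- extract_layer_curves(al$aligned[[ni]], frames[[ni]])
  tips <- detect_electrode_tips(al$aligned[[ni]])
  assignment <- if (nrow(tips$tips) >= 2L)
    match_cannula(as.matrix(tips$tips[, c("ap", "ml")]), config$layout)
  else NULL
  # electrode table in the implanted subject's normalized frame (per side)
  et <- tips$tips
  if (nrow(et) > 0L) {
    mid <- (cc$grid_shape[3] - 1) / 2
    et$side <- ifelse(et$ml > mid, "right", "left")
    norm <- t(vapply(seq_len(nrow(et)), function(r) {
      normalize_points(cbind(et$ap[r], et$ml[r]), frames[[ni]][[et$side[r]]])[1, ]
    }, numeric(2)))
    et$ap_norm <- norm[, 1]
    et$ml_norm <- norm[, 2]
    if (!is.null(assignment)) {
      sl <- rep(NA_character_, nrow(et))
      for (r in seq_len(nrow(assignment$assignment))) {
        arow <- assignment$assignment[r, ]
        if (is.na(arow$det_ap)) next
        hit <- which(abs(et$ap - arow$det_ap) < 1e-9 &
                     abs(et$ml - arow$det_ml) < 1e-9)
        if (length(hit)) sl[hit[1]] <- arow$slot
      }
      et$slot <- sl
    }
  }
  ib <- in_band_fraction(implanted_curves, band)
  structure(list(curves = curves, band = band,
                 implanted_curves = implanted_curves, tips = tips,
                 assignment = assignment, electrode_table = et,
                 in_band_fraction = ib, truth = imp$truth, config = config),
            class = "electrode_report")
}

# Normative band of control lateral/medial curves on a common normalized
# AP grid (linear interpolation within each subject's sampled range).
control_band <- function(curves, grid = seq(0, 1.3, by = 0.05)) {
  out <- list()
  for (side in unique(curves$side)) for (cv in unique(curves$curve)) {
    sub <- curves[curves$side == side & curves$curve == cv, ]
    subj <- split(sub, sub$subject)
    m <- vapply(subj, function(s) {
      s <- s[order(s$ap_norm), ]
      stats::approx(s$ap_norm, s$ml_norm, xout = grid, rule = 1)$y
    }, numeric(length(grid)))
    out[[length(out) + 1L]] <- data.frame(
      side = side, curve = cv, ap_norm = grid,
      ml_min = suppressWarnings(apply(m, 1, min, na.rm = TRUE)),
      ml_max = suppressWarnings(apply(m, 1, max, na.rm = TRUE)))
  }
  b <- do.call(rbind, out)
  b[is.finite(b$ml_min) & is.finite(b$ml_max), ]
}

# Fraction of a subject's curve points lying inside the control band
# (with a small tolerance for discretization).
in_band_fraction <- function(curves, band, tol = 0.05) {
  ok <- 0L; tot <- 0L
  for (r in seq_len(nrow(curves))) {
    b <- band[band$side == curves$side[r] & band$curve == curves$curve[r], ]
    if (nrow(b) < 2L) next
    lo <- stats::approx(b$ap_norm, b$ml_min, xout = curves$ap_norm[r], rule = 1)$y
    hi <- stats::approx(b$ap_norm, b$ml_max, xout = curves$ap_norm[r], rule = 1)$y
    if (!is.finite(lo) || !is.finite(hi)) next
    tot <- tot + 1L
    if (curves$ml_norm[r] >= lo - tol && curves$ml_norm[r] <= hi + tol)
      ok <- ok + 1L
  }
  if (tot == 0L) NA_real_ else ok / tot
}

#' @export
print.electrode_report <- function(x, ...) {
  cat("<electrode_report> ", length(unique(x$curves$subject)),
      " control curve sets; ", nrow(x$tips$tips), " tips detected; ",
      "in-band fraction ", round(x$in_band_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' Run the theta phase-offset pipeline end to end
#'
#' Synthesizes (or accepts) an LFP session whose channels correspond to
#' the occupied cannula slots, estimates pairwise theta offsets with
#' run-period gating, and, when an electrode report is supplied, joins the
#' offsets to the normalized electrode coordinates (the colored-circle
#' map: offset vs position along the septo-temporal axis).
#'
#' @param config A [run_config()]; `config$theta$offsets` gives the true
#'   per-channel offsets (defaults to a uniform 0-60 degree gradient
#'   across the occupied slots, mimicking the dorsal-to-intermediate
#'   theta phase shift).
#' @param electrode_report Optional [run_electrode_pipeline()] result.
#' @param session Optional pre-built [generate_lfp_session()] output.
#' @return A `theta_report` list: `offsets` (matrix object),
#'   `vs_reference` (radians, reference = channel 1), `true_offsets`,
#'   `electrode_join` (data frame when a report was given).
#' @export
run_theta_pipeline <- function(config = run_config(), electrode_report = NULL,
                               session = NULL) {
  th <- config$theta
  n_ch <- sum(config$layout$occupied)
  offs <- th$offsets
  if (is.null(offs)) offs <- seq(0, pi / 3, length.out = n_ch)
  spec <- phase_offset_spec(offs, snr = th$snr %||% 10,
                            duration = th$duration %||% 600)
  if (is.null(session))
    session <- generate_lfp_session(spec, fs = th$fs %||% 1500,
                                    seed = derive_seed(config$cohort$master_seed,
                                                       5000L))
  pom <- pairwise_theta_offsets(session$lfp, session$speed)
  vs_ref <- pom$offsets[, 1]
  join <- NULL
  if (!is.null(electrode_report) && !is.null(electrode_report$electrode_table) &&
      nrow(electrode_report$electrode_table) > 0L &&
      !is.null(electrode_report$electrode_table$slot)) {
    slots <- config$layout$slot[config$layout$occupied]
    et <- electrode_report$electrode_table
    join <- data.frame(channel = seq_along(slots), slot = slots,
                       offset_rad = vs_ref)
    m <- match(join$slot, et$slot)
    join$ap_norm <- et$ap_norm[m]
    join$ml_norm <- et$ml_norm[m]
  }
  structure(list(offsets = pom, vs_reference = vs_ref, true_offsets = offs,
                 electrode_join = join, config = config),
            class = "theta_report")
}

#' @export
print.theta_report <- function(x, ...) {
  cat("<theta_report> ", nrow(x$offsets$offsets), " channels, ",
      x$offsets$n_periods, " run periods\n", sep = "")
  invisible(x)
}
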