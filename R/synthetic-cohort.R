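#' Synthetic brain volumes with known ground truth
#'
#' `generate_brain_volume()` renders one subject: an ellipsoidal tissue
#' region over a dark background, a bright curved bilateral hippocampal
#' cell-layer sheet (two sheets per side anteriorly, fusing into one at a
#' defined septo-temporal fraction), an optional inner dentate sheet and
#' skull shell, additive Gaussian noise, and a small random rigid pose
#' (rotation + translation) emulating placement variability in the scanner.
#' Everything stochastic is a pure function of `(config, subject_seed)`.
#'
#' @param config A [cohort_config()].
#' @param subject_seed Integer seed for this subject's pose and noise.
#' @param subject_id Identifier stored in the volume.
#' @return A list with elements `volume` (a `brain_volume`: `voxels` array in
#'   (AP, DV, ML) order, `voxel_pitch`, `subject_id`, `provenance`) and
#'   `truth` (ground truth: `label`, `true_pose`, `landmark_points`, the
#'   painted `layer` voxel table, `lesioned_voxel_mask`, `electrode_tips`).
#' @export
generate_brain_volume <- function(config, subject_seed, subject_id = "S01") {
  validate_cohort_config(config)
  d <- config$grid_shape
  with_seed(subject_seed, {
    jit <- config$pose_jitter
    rot <- runif(3, -jit$rot_deg, jit$rot_deg) * pi / 180
    trans <- runif(3, -jit$trans_vox, jit$trans_vox)
    pose <- list(rotation = rotation_from_angles(rot), translation = trans)
    vol <- render_canonical_tissue(config, pose)
    tpl <- layer_template_points(config)
    ctr <- (d - 1) / 2
    moved <- sweep(tpl$points, 2, ctr) %*% t(pose$rotation)
    moved <- sweep(moved, 2, ctr + trans, `+`)
    paint <- paint_points(moved, d, config$layer_thickness)
    vol[paint$lin] <- config$layer_intensity
    layer <- data.frame(lin = paint$lin,
                        side = tpl$meta$side[paint$src],
                        sheet = tpl$meta$sheet[paint$src],
                        t = tpl$meta$t[paint$src])
    lm <- lapply(tpl$landmarks, function(p) {
      as.vector(pose$rotation %*% (p - ctr)) + ctr + trans
    })
    # posterior-ventral extreme per side, from the painted (posed) layer
    # itself with the same rule the detector uses: centroid of the side's
    # voxels within one voxel of the ventral-most layer voxel
    co <- arrayInd(paint$lin, d) - 1L
    mid <- (d[3] - 1) / 2
    for (s in c(-1, 1)) {
      side <- if (s < 0) "left" else "right"
      cs <- co[if (s < 0) co[, 3] < mid else co[, 3] > mid, , drop = FALSE]
      vx <- cs[cs[, 2] >= max(cs[, 2]) - 1L, , drop = FALSE]
      lm[[paste0("ventral_", side)]] <- colMeans(vx)
    }
    if (config$noise_sd > 0)
      vol <- vol + rnorm(length(vol), 0, config$noise_sd)
    volume <- new_brain_volume(vol, config$voxel_pitch, subject_id, "synthetic")
    truth <- list(label = "control", true_pose = pose,
                  landmark_points = lm, layer = layer,
                  lesioned_voxel_mask = integer(0),
                  electrode_tips = empty_tips(), dim = d)
    list(volume = volume, truth = truth)
  })
}

new_brain_volume <- function(voxels, pitch, subject_id, provenance) {
  stopifnot(all(is.finite(voxels)), pitch > 0)
  structure(list(voxels = voxels, voxel_pitch = pitch,
                 subject_id = subject_id, provenance = provenance),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<brain_volume> ", x$subject_id, ": ", paste(d, collapse = " x "),
      " (AP x DV x ML), pitch ", x$voxel_pitch, ", ", x$provenance, "\n", sep = "")
  invisible(x)
}

empty_tips <- function() {
  data.frame(slot = character(0), ap = numeric(0), dv = numeric(0),
             ml = numeric(0))
}

# Rotation matrix from per-axis angles (radians), composed AP then DV then ML.
rotation_from_angles <- function(a) {
  c1 <- cos(a[1]); s1 <- sin(a[1])
  c2 <- cos(a[2]); s2 <- sin(a[2])
  c3 <- cos(a[3]); s3 <- sin(a[3])
  r1 <- rbind(c(1, 0, 0), c(0, c1, -s1), c(0, s1, c1))
  r2 <- rbind(c(c2, 0, s2), c(0, 1, 0), c(-s2, 0, c2))
  r3 <- rbind(c(c3, -s3, 0), c(s3, c3, 0), c(0, 0, 1))
  r3 %*% r2 %*% r1
}

# Fill the tissue ellipsoid (and optional skull shell) of a posed subject by
# evaluating the canonical ellipsoid at back-transformed voxel coordinates.
render_canonical_tissue <- function(config, pose) {
  d <- config$grid_shape
  semi <- config$geometry$ellipsoid_semi * d
  ctr <- (d - 1) / 2
  ap <- rep(seq_len(d[1]) - 1 - ctr[1] - pose$translation[1], times = d[2] * d[3])
  dv <- rep(rep(seq_len(d[2]) - 1 - ctr[2] - pose$translation[2], each = d[1]),
            times = d[3])
  ml <- rep(seq_len(d[3]) - 1 - ctr[3] - pose$translation[3], each = d[1] * d[2])
  Rt <- t(pose$rotation)
  u1 <- (Rt[1, 1] * ap + Rt[1, 2] * dv + Rt[1, 3] * ml) / semi[1]
  u2 <- (Rt[2, 1] * ap + Rt[2, 2] * dv + Rt[2, 3] * ml) / semi[2]
  u3 <- (Rt[3, 1] * ap + Rt[3, 2] * dv + Rt[3, 3] * ml) / semi[3]
  e <- u1 * u1 + u2 * u2 + u3 * u3
  vol <- array(0, dim = d)
  vol[e <= 1] <- config$tissue_intensity
  if (config$skull_intensity > 0)
    vol[e > 1.06 & e <= 1.18] <- config$skull_intensity
  vol
}

# Paint a point cloud into voxels with a spherical brush of the given
# radius; returns unique linear indices plus the index of the source point
# that first claimed each voxel.
paint_points <- function(points, d, radius) {
  r <- floor(radius)
  g <- as.matrix(expand.grid(-(r + 1):(r + 1), -(r + 1):(r + 1), -(r + 1):(r + 1)))
  g <- g[sqrt(rowSums(g^2)) <= radius, , drop = FALSE]
  p0 <- round(points)
  n <- nrow(p0)
  lin_all <- integer(0)
  src_all <- integer(0)
  for (k in seq_len(nrow(g))) {
    q <- p0 + matrix(g[k, ], n, 3, byrow = TRUE)
    ok <- q[, 1] >= 0 & q[, 1] <= d[1] - 1 &
          q[, 2] >= 0 & q[, 2] <= d[2] - 1 &
          q[, 3] >= 0 & q[, 3] <= d[3] - 1
    if (!any(ok)) next
    lin <- 1L + q[ok, 1] + d[1] * (q[ok, 2] + d[2] * q[ok, 3])
    lin_all <- c(lin_all, as.integer(lin))
    src_all <- c(src_all, which(ok))
  }
  keep <- !duplicated(lin_all)
  list(lin = lin_all[keep], src = src_all[keep])
}

#' Carve an excitotoxic-style lesion cavity into a synthetic brain
#'
#' Voxels of the hippocampal cell layer (both sheets) whose septo-temporal
#' fraction lies inside `config$lesion_ap_extent`, together with a
#' surrounding margin, are set toward `cavity_intensity` with a randomized
#' ragged boundary, emulating the cavity left by NMDA infusion at the
#' configured sites. The change is strictly confined to the dilated lesion
#' region; the exact set of altered voxels is recorded in the returned
#' ground truth.
#'
#' @param volume,truth Output of [generate_brain_volume()].
#' @param config The generating [cohort_config()].
#' @param rng_seed Integer seed for the ragged boundary and cavity noise.
#' @return A list `(volume, truth)` with the lesion applied; if the lesion
#'   window is empty the input is returned unchanged with
#'   `truth$lesion_warning = TRUE` and a warning.
#' @export
apply_lesion <- function(volume, truth, config, rng_seed) {
  ext <- config$lesion_ap_extent
  if (diff(ext) <= 0) {
    warning("empty lesion_ap_extent interval; volume returned unchanged")
    truth$lesion_warning <- TRUE
    return(list(volume = volume, truth = truth))
  }
  d <- truth$dim
  core_lin <- truth$layer$lin[truth$layer$t >= ext[1] & truth$layer$t <= ext[2]]
  if (length(core_lin) == 0L) {
    warning("no layer voxels inside the lesion window; volume returned unchanged")
    truth$lesion_warning <- TRUE
    return(list(volume = volume, truth = truth))
  }
  with_seed(rng_seed, {
    # dilate within the core's bounding box (plus margin) only
    co <- arrayInd(core_lin, d)
    pad <- config$lesion_margin + 1L
    box <- lapply(1:3, function(j) {
      r <- range(co[, j])
      max(1L, r[1] - pad):min(d[j], r[2] + pad)
    })
    bd <- vapply(box, length, integer(1))
    core <- array(FALSE, dim = bd)
    core[cbind(co[, 1] - box[[1]][1] + 1L, co[, 2] - box[[2]][1] + 1L,
               co[, 3] - box[[3]][1] + 1L)] <- TRUE
    dil <- dilate_mask(core, iterations = config$lesion_margin, connectivity = 26L)
    # the cavity stays within the targeted AP window: no dilation along AP
    # beyond the slices the layer core occupies
    ap_keep <- range(co[, 1]) - box[[1]][1] + 1L
    if (ap_keep[1] > 1L) dil[seq_len(ap_keep[1] - 1L), , ] <- FALSE
    if (ap_keep[2] < bd[1]) dil[(ap_keep[2] + 1L):bd[1], , ] <- FALSE
    shell <- dil & !erode_mask(dil, 1L, connectivity = 26L)
    drop <- which(shell)[runif(sum(shell)) < 0.35]
    dil[drop] <- FALSE
    bco <- arrayInd(which(dil), bd)
    lesioned <- as.integer((bco[, 1] + box[[1]][1] - 2L) + d[1] *
                           ((bco[, 2] + box[[2]][1] - 2L) + d[2] *
                            (bco[, 3] + box[[3]][1] - 2L)) + 1L)
    lesioned <- sort(lesioned)
    volume$voxels[lesioned] <- config$cavity_intensity +
      rnorm(length(lesioned), 0, config$noise_sd)
    truth$label <- "lesion"
    truth$lesioned_voxel_mask <- lesioned
    list(volume = volume, truth = truth)
  })
}

#' Cannula grid layout for electrode insertion
#'
#' Builds an (AP, ML) grid of cannula slots, as carried by a tetrode
#' microdrive, in absolute voxel coordinates of the target volume.
#'
#' @param n_ap,n_ml Grid dimensions (slots).
#' @param spacing Slot pitch in voxels.
#' @param anchor Numeric `(ap, ml)` of the grid's first slot.
#' @param occupied Logical vector (recycled) marking which slots carry a
#'   tetrode; unoccupied slots are skipped at insertion.
#' @return Data frame with columns `slot`, `ap`, `ml`, `occupied`.
#' @export
cannula_layout <- function(n_ap = 4L, n_ml = 3L, spacing = 6,
                           anchor = c(45, 62), occupied = TRUE) {
  g <- expand.grid(i = seq_len(n_ap) - 1L, j = seq_len(n_ml) - 1L)
  out <- data.frame(slot = sprintf("t%02d", seq_len(nrow(g))),
                    ap = anchor[1] + g$i * spacing,
                    ml = anchor[2] + g$j * spacing)
  out$occupied <- rep_len(occupied, nrow(out))
  out
}

#' Insert bright electrode rods into a synthetic brain
#'
#' For each occupied cannula slot a vertical rod at `electrode_intensity`
#' (far above the cell layer) is painted from just above the dorsal tissue
#' surface down to its tip depth, emulating tetrodes descending from a
#' microdrive. Tip coordinates and slot labels are recorded in the ground
#' truth.
#'
#' @param volume,truth Output of [generate_brain_volume()].
#' @param config The generating [cohort_config()].
#' @param layout Slot table from [cannula_layout()]; slots must lie within
#'   the grid.
#' @param tip_depths DV tip coordinate per slot (voxels; recycled). Depths
#'   beyond the grid are clipped with a warning.
#' @return A list `(volume, truth)` with rods painted and
#'   `truth$electrode_tips` filled for occupied slots.
#' @export
insert_electrodes <- function(volume, truth, config, layout, tip_depths = 40) {
  d <- truth$dim
  if (nrow(layout) == 0L) return(list(volume = volume, truth = truth))
  if (any(layout$ap < 0 | layout$ap > d[1] - 1 | layout$ml < 0 | layout$ml > d[3] - 1))
    stop("cannula slots outside the volume grid")
  tip_depths <- rep_len(tip_depths, nrow(layout))
  if (any(tip_depths > d[2] - 1)) {
    warning("tip depth below grid; clipped to the ventral face")
    tip_depths <- pmin(tip_depths, d[2] - 1)
  }
  tips <- list()
  for (k in seq_len(nrow(layout))) {
    if (!layout$occupied[k]) next
    ap <- as.integer(round(layout$ap[k]))
    ml <- as.integer(round(layout$ml[k]))
    tip <- as.integer(round(tip_depths[k]))
    col <- volume$voxels[ap + 1L, , ml + 1L]
    surf <- which(col > config$tissue_intensity / 2)[1]
    start <- max(0L, (if (is.na(surf)) 2L else surf - 1L) - 2L)
    dvs <- start:tip
    for (dap in -1:1) for (dml in -1:1) {
      if (abs(dap) + abs(dml) > 1) next
      a <- ap + dap; m <- ml + dml
      if (a < 0 || a > d[1] - 1 || m < 0 || m > d[3] - 1) next
      volume$voxels[a + 1L, dvs + 1L, m + 1L] <- config$electrode_intensity
    }
    tips[[length(tips) + 1L]] <- data.frame(slot = layout$slot[k],
                                            ap = ap, dv = tip, ml = ml)
  }
  truth$electrode_tips <- if (length(tips)) do.call(rbind, tips) else empty_tips()
  list(volume = volume, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Controls first, then lesioned subjects; per-subject seeds are derived
#' deterministically from `config$master_seed`, so the whole cohort is a
#' pure function of the configuration.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort`: elements `subjects` (list of
#'   `(volume, truth)`), `ids`, `labels`, and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_control + config$n_lesion
  ids <- c(sprintf("C%02d", seq_len(config$n_control)),
           sprintf("L%02d", seq_len(config$n_lesion)))
  labels <- rep(c("control", "lesion"), c(config$n_control, config$n_lesion))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- generate_brain_volume(config, derive_seed(config$master_seed, i), ids[i])
    if (labels[i] == "lesion")
      sub <- apply_lesion(sub$volume, sub$truth, config,
                          derive_seed(config$master_seed, 10000L + i))
    subjects[[i]] <- sub
  }
  structure(list(subjects = subjects, ids = ids, labels = labels,
                 config = config), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$ids), " subjects (",
      sum(x$labels == "control"), " control, ",
      sum(x$labels == "lesion"), " lesion), master_seed ",
      x$config$master_seed, "\n", sep = "")
  invisible(x)
}
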