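#' Configuration for a synthetic micro-CT cohort
#'
#' Collects every knob of the synthetic brain generator: cohort sizes, grid
#' geometry, grayscale levels, noise, rigid pose jitter, and the lesion
#' window. Defaults emulate the imaging study the pipeline targets: 12
#' control and 13 lesioned subjects, a desk-scale 128 x 96 x 96 voxel grid
#' standing in for full-brain scans, and a lesion window anchored to the
#' published bilateral infusion sites ([infusion_sites()]).
#'
#' Axis order is (AP, DV, ML) with index 0 anterior / dorsal / left; world
#' coordinates are 0-based voxel indices times `voxel_pitch` (default 1, so
#' coordinates are in voxel units).
#'
#' @param n_control,n_lesion Cohort sizes (non-negative integers).
#' @param grid_shape Integer vector (AP, DV, ML) voxel counts.
#' @param voxel_pitch Edge length of a voxel (arbitrary units).
#' @param tissue_intensity,layer_intensity,cavity_intensity Grayscale levels;
#'   must satisfy `layer > tissue > cavity >= 0`.
#' @param skull_intensity Grayscale of an optional skull shell; 0 disables
#'   the shell (default; the analysis masks never include skull).
#' @param electrode_intensity Grayscale of implanted electrode rods; must
#'   exceed `layer_intensity`.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param pose_jitter List with `rot_deg` (max rotation per axis, degrees)
#'   and `trans_vox` (max translation per axis, voxels).
#' @param sites Infusion-site table consumed by the lesion generator.
#' @param lesion_ap_extent Fractional septo-temporal interval lesioned;
#'   defaults to the window implied by `sites`.
#' @param lesion_margin Dilation radius (voxels) of the cavity around the
#'   cell layer.
#' @param layer_thickness Half-thickness (voxels) of the painted cell-layer
#'   sheet.
#' @param dentate Render the inner dentate gyrus sheet?
#' @param master_seed Integer master seed; per-subject seeds are derived via
#'   [derive_seed()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 12L,
                          n_lesion = 13L,
                          grid_shape = c(128L, 96L, 96L),
                          voxel_pitch = 1,
                          tissue_intensity = 0.35,
                          layer_intensity = 1,
                          cavity_intensity = 0.05,
                          skull_intensity = 0,
                          electrode_intensity = 4,
                          noise_sd = 0.04,
                          pose_jitter = list(rot_deg = 2, trans_vox = 2),
                          sites = infusion_sites(),
                          lesion_ap_extent = NULL,
                          lesion_margin = 2L,
                          layer_thickness = 1.2,
                          dentate = TRUE,
                          master_seed = 1L) {
  if (is.null(lesion_ap_extent))
    lesion_ap_extent <- lesion_extent_from_sites(sites)$extent
  cfg <- list(
    n_control = as.integer(n_control), n_lesion = as.integer(n_lesion),
    grid_shape = as.integer(grid_shape), voxel_pitch = voxel_pitch,
    tissue_intensity = tissue_intensity, layer_intensity = layer_intensity,
    cavity_intensity = cavity_intensity, skull_intensity = skull_intensity,
    electrode_intensity = electrode_intensity,
    noise_sd = noise_sd, pose_jitter = pose_jitter, sites = sites,
    lesion_ap_extent = lesion_ap_extent, lesion_margin = as.integer(lesion_margin),
    layer_thickness = layer_thickness, dentate = isTRUE(dentate),
    master_seed = as.integer(master_seed),
    # parametric form of the curved layer template (fractions of the grid);
    # recorded here so the exact geometry travels with the config
    geometry = list(
      ap_span = c(0.20, 0.85),       # layer extent along AP, fraction of axis
      ellipsoid_semi = c(0.44, 0.42, 0.44), # tissue ellipsoid, fraction/axis
      dv_center = c(0.30, 0.25),     # coronal arc centre: base + slope * t
      ml_offset = c(0.13, 0.10),     # arc centre lateral offset: base + slope * t
      r_dv = c(0.06, 0.14),          # DV radius: base + slope * t
      r_ml = c(0.05, 0.16),          # ML radius: base + slope * t
      theta_lim = c(0.15, 0.85) * pi, # arc angular span (0 = dorsal pole)
      fuse_t = 0.55,                 # septo-temporal fraction of fusion
      gap0 = 0.45 * pi,              # angular gap between sheets at t = 0
      gap_min_vox = 4,               # residual sheet gap (voxels) before fusion
      dg_radius = 0.55,              # dentate sheet radius, fraction of CA
      dg_theta = c(0.30, 0.70) * pi, # dentate angular span
      dg_from_t = 0.25               # dentate present for t >= this
    )
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_control >= 0L, cfg$n_lesion >= 0L,
            length(cfg$grid_shape) == 3L, cfg$voxel_pitch > 0)
  if (!(cfg$layer_intensity > cfg$tissue_intensity &&
        cfg$tissue_intensity > cfg$cavity_intensity &&
        cfg$cavity_intensity >= 0))
    stop("intensity ordering violated: need layer > tissue > cavity >= 0")
  if (cfg$electrode_intensity <= cfg$layer_intensity)
    stop("electrode_intensity must exceed layer_intensity")
  ext <- cfg$lesion_ap_extent
  if (length(ext) != 2L || any(ext < 0) || any(ext > 1))
    stop("lesion_ap_extent must lie within [0, 1]")
  if (any(cfg$grid_shape < 32L))
    stop("grid too small to contain the layer template (need >= 32 voxels per axis)")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_control, " control + ", x$n_lesion, " lesion; grid ",
      paste(x$grid_shape, collapse = " x "), " (AP x DV x ML); noise_sd ",
      x$noise_sd, "; lesion extent [", round(x$lesion_ap_extent[1], 3), ", ",
      round(x$lesion_ap_extent[2], 3), "]; master_seed ", x$master_seed, "\n",
      sep = "")
  invisible(x)
}

# Continuous description of one coronal section of the layer template at
# septo-temporal fraction t, for one side (s = -1 left, +1 right).
# Returns arc pieces as angle intervals plus the shared geometry.
template_section <- function(cfg, t, s) {
  g <- cfg$geometry
  d <- cfg$grid_shape
  ndv <- d[2]; nml <- d[3]
  mid <- (nml - 1) / 2
  dv_c <- (g$dv_center[1] + g$dv_center[2] * t) * ndv
  ml_c <- mid + s * (g$ml_offset[1] + g$ml_offset[2] * t) * nml
  r_dv <- (g$r_dv[1] + g$r_dv[2] * t) * ndv
  r_ml <- (g$r_ml[1] + g$r_ml[2] * t) * nml
  th_mid <- mean(g$theta_lim)
  if (t >= g$fuse_t) {
    pieces <- list(c(g$theta_lim[1], g$theta_lim[2]))
  } else {
    # keep a fixed physical gap (voxels) between the sheets right up to the
    # fusion slice, so painting thickness can never bridge it early
    gap_min <- g$gap_min_vox / max(r_dv, 1)
    gap <- max(gap_min, g$gap0 * (1 - t / g$fuse_t))
    pieces <- list(c(g$theta_lim[1], th_mid - gap / 2),
                   c(th_mid + gap / 2, g$theta_lim[2]))
  }
  list(dv_c = dv_c, ml_c = ml_c, r_dv = r_dv, r_ml = r_ml,
       pieces = pieces, th_mid = th_mid, s = s)
}

# Sample the full 3-D template point cloud in canonical (un-jittered) voxel
# coordinates. Returns points (ap, dv, ml), per-point side/sheet/t, and the
# canonical landmarks (anterior CA1 tip and lateral fusion point, per side).
layer_template_points <- function(cfg) {
  g <- cfg$geometry
  d <- cfg$grid_shape
  nap <- d[1]
  ap0 <- g$ap_span[1] * (nap - 1)
  ap1 <- g$ap_span[2] * (nap - 1)
  slices <- seq(ceiling(ap0), floor(ap1))
  pts <- vector("list", 2 * length(slices))
  meta <- vector("list", 2 * length(slices))
  k <- 0L
  for (ap in slices) {
    t <- (ap - ap0) / (ap1 - ap0)
    for (s in c(-1, 1)) {
      sec <- template_section(cfg, t, s)
      th <- unlist(lapply(sec$pieces, function(p) {
        if (p[2] <= p[1]) return(numeric(0))
        n <- max(2L, ceiling((p[2] - p[1]) * max(sec$r_dv, sec$r_ml) / 0.5))
        seq(p[1], p[2], length.out = n)
      }))
      dv <- sec$dv_c - sec$r_dv * cos(th)
      ml <- sec$ml_c + s * sec$r_ml * sin(th)
      sheet <- rep("ca", length(th))
      tt <- rep(t, length(th))
      # the dentate sheet needs a clear radial gap to the CA arc (painted
      # thickness on both sides); on coarse grids it only fits posteriorly
      dgr <- g$dg_radius
      dg_fits <- (1 - dgr) * min(sec$r_dv, sec$r_ml) >= 3.5
      if (cfg$dentate && t >= g$dg_from_t && dg_fits) {
        thd <- seq(g$dg_theta[1], g$dg_theta[2],
                   length.out = max(2L, ceiling(diff(g$dg_theta) *
                     dgr * max(sec$r_dv, sec$r_ml) / 0.5)))
        dv <- c(dv, sec$dv_c - dgr * sec$r_dv * cos(thd))
        ml <- c(ml, sec$ml_c + s * dgr * sec$r_ml * sin(thd))
        sheet <- c(sheet, rep("dg", length(thd)))
        tt <- c(tt, rep(t, length(thd)))
      }
      k <- k + 1L
      pts[[k]] <- cbind(ap = rep(ap, length(dv)), dv = dv, ml = ml)
      meta[[k]] <- data.frame(side = if (s < 0) "left" else "right",
                              sheet = sheet, t = tt)
    }
  }
  points <- do.call(rbind, pts[seq_len(k)])
  meta <- do.call(rbind, meta[seq_len(k)])
  # landmarks: anterior tip = centroid of CA points of the first slice;
  # fusion = lateral-most arc point of the first fused slice
  lm <- list()
  ap_fus <- slices[which(( slices - ap0) / (ap1 - ap0) >= g$fuse_t)[1]]
  for (s in c(-1, 1)) {
    side <- if (s < 0) "left" else "right"
    first <- points[, "ap"] == slices[1] & meta$side == side & meta$sheet == "ca"
    lm[[paste0("tip_", side)]] <- colMeans(points[first, , drop = FALSE])
    t_f <- (ap_fus - ap0) / (ap1 - ap0)
    sec <- template_section(cfg, t_f, s)
    lm[[paste0("fusion_", side)]] <- c(ap = ap_fus, dv = sec$dv_c,
                                       ml = sec$ml_c + s * sec$r_ml)
  }
  list(points = points, meta = meta, landmarks = lm,
       ap_range = c(ap0, ap1), slices = slices, fusion_slice = ap_fus)
}

#' Canonical anatomical landmarks of the layer template
#'
#' The four reference landmarks of the un-jittered template (anterior CA1
#' tip and lateral fusion point, each side), used as the fixed target of
#' rigid alignment.
#'
#' @param config A [cohort_config()].
#' @return A [landmark_set()] in canonical voxel coordinates.
#' @export
canonical_landmark_set <- function(config) {
  tpl <- layer_template_points(config)
  d <- config$grid_shape
  p <- paint_points(tpl$points, d, config$layer_thickness)
  co <- arrayInd(p$lin, d) - 1L
  mid <- (d[3] - 1) / 2
  lm <- tpl$landmarks
  for (s in c(-1, 1)) {   # posterior-ventral extreme, same rule as detection
    side <- if (s < 0) "left" else "right"
    cs <- co[if (s < 0) co[, 3] < mid else co[, 3] > mid, , drop = FALSE]
    vx <- cs[cs[, 2] >= max(cs[, 2]) - 1L, , drop = FALSE]
    lm[[paste0("ventral_", side)]] <- colMeans(vx)
  }
  landmark_set(do.call(rbind, lm), names = names(lm), space = "canonical")
}

# Landmarks used for rigid alignment: anterior tips and posterior-ventral
# extremes survive the lesion window; the fusion points (inside it) do not.
alignment_landmark_names <- c("tip_left", "tip_right",
                              "ventral_left", "ventral_right")
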