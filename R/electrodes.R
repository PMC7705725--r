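#' Normalized 2-D anatomical coordinate frame
#'
#' The frame used to compare electrode positions across brains: its origin
#' is the center of the most anterior portion of the hippocampal CA1 cell
#' layer and its (1,1) point is the lateral extent of the cell layer where
#' the dorsal and ventral portions fuse into intermediate hippocampus. The
#' map is per-axis affine (AP and ML scaled independently) — the only
#' reading under which those two points fully determine the map — so it is
#' invariant to axis-aligned translation and scaling of the inputs
#' (rotations are removed beforehand by rigid alignment). DV is deliberately
#' excluded: electrodes move along DV during recordings, making that
#' coordinate unrepresentative.
#'
#' @param origin,unit Numeric `(ap, ml)` of the two defining landmarks.
#' @param side Hemisphere tag (`"left"`/`"right"`); frames are built per
#'   hemisphere.
#' @return An object of class `frame2d`.
#' @export
make_frame <- function(origin, unit, side = "right") {
  origin <- as.numeric(origin)
  unit <- as.numeric(unit)
  stopifnot(length(origin) == 2L, length(unit) == 2L)
  if (unit[1] == origin[1]) stop("degenerate frame: AP axis has zero scale")
  if (unit[2] == origin[2]) stop("degenerate frame: ML axis has zero scale")
  structure(list(origin = origin, unit = unit, side = side), class = "frame2d")
}

#' @export
print.frame2d <- function(x, ...) {
  cat("<frame2d> ", x$side, ": origin (", paste(round(x$origin, 2), collapse = ", "),
      "), unit (", paste(round(x$unit, 2), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Map points into / out of a normalized frame
#'
#' `normalize_points` sends the frame origin to (0,0) and the unit landmark
#' to (1,1) by independent affine maps per axis; `denormalize_points` is its
#' exact inverse.
#'
#' @param points Numeric matrix (n x 2) of `(ap, ml)` coordinates.
#' @param frame A [make_frame()] object.
#' @return Matrix (n x 2) of transformed coordinates, order preserved.
#' @export
normalize_points <- function(points, frame) {
  points <- rbind(points)
  cbind(ap = (points[, 1] - frame$origin[1]) / (frame$unit[1] - frame$origin[1]),
        ml = (points[, 2] - frame$origin[2]) / (frame$unit[2] - frame$origin[2]))
}

#' @rdname normalize_points
#' @export
denormalize_points <- function(points, frame) {
  points <- rbind(points)
  cbind(ap = frame$origin[1] + points[, 1] * (frame$unit[1] - frame$origin[1]),
        ml = frame$origin[2] + points[, 2] * (frame$unit[2] - frame$origin[2]))
}

#' Frames for both hemispheres from detected landmarks
#'
#' @param landmarks A [detect_anatomical_landmarks()] result (or any
#'   [landmark_set()] with `tip_left/right` and `fusion_left/right`).
#' @return Named list of `frame2d` objects (`left`, `right`).
#' @export
frames_from_landmarks <- function(landmarks) {
  p <- landmarks$points
  list(left = make_frame(p["tip_left", c("ap", "ml")],
                         p["fusion_left", c("ap", "ml")], side = "left"),
       right = make_frame(p["tip_right", c("ap", "ml")],
                          p["fusion_right", c("ap", "ml")], side = "right"))
}

#' Sample the cell-layer curves of a brain in normalized coordinates
#'
#' For each AP slice with visible layer, per hemisphere: the lateral curve
#' point is the lateral-most above-threshold layer pixel, and the medial
#' curve point is the medial-most pixel of the inner (dentate gyrus) sheet.
#' The inner sheet is the in-slice connected component that contains neither
#' the dorsal-most nor the ventral-most layer pixel, sits strictly inside
#' the slice's DV range, and lies clearly medial of the lateral envelope
#' (most-medial centroid wins if several qualify); slices without such a
#' component are recorded as gaps, not interpolated. Points are returned in
#' the per-hemisphere normalized frame.
#'
#' @param volume A `brain_volume` (aligned to the reference frame).
#' @param frames Per-side frames from [frames_from_landmarks()].
#' @param intensity_ratio_threshold,min_component As in
#'   [detect_anatomical_landmarks()].
#' @return Data frame with columns `subject`, `side`, `curve`
#'   (`lateral`/`medial`), `ap`, `ap_norm`, `ml_norm`.
#' @export
extract_layer_curves <- function(volume, frames,
                                 intensity_ratio_threshold = 0.5,
                                 min_component = 3L) {
  v <- volume$voxels
  d <- dim(v)
  mx <- stats::quantile(v, 0.995, names = FALSE)
  bg <- stats::median(v[v >= stats::quantile(v, 0.75, names = FALSE)])
  thr <- bg + intensity_ratio_threshold * (mx - bg)
  e_thr <- bg + 1.5 * (mx - bg)
  sel <- which(v > thr & v <= e_thr)
  if (length(sel) == 0L) stop("no layer pixels above threshold")
  co <- arrayInd(sel, d) - 1L
  mid <- (d[3] - 1) / 2
  rows <- list()
  for (s in c(-1, 1)) {
    side <- if (s < 0) "left" else "right"
    fr <- frames[[side]]
    cs <- co[if (s < 0) co[, 3] < mid else co[, 3] > mid, , drop = FALSE]
    for (ap in sort(unique(cs[, 1]))) {
      sl <- cs[cs[, 1] == ap, , drop = FALSE]
      lat <- sl[which.max(s * (sl[, 3] - mid)), ]
      pn <- normalize_points(cbind(ap, lat[3]), fr)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = volume$subject_id, side = side, curve = "lateral",
        ap = ap, ap_norm = pn[1], ml_norm = pn[2])
      m2 <- matrix(FALSE, d[2], d[3])
      m2[cbind(sl[, 2] + 1L, sl[, 3] + 1L)] <- TRUE
      lab <- label_components(m2, connectivity = 4L)
      sizes <- tabulate(lab[lab > 0])
      comps <- which(sizes >= min_component)
      # the inner (dentate) sheet holds neither the dorsal-most nor the
      # ventral-most layer pixel of the slice; the CA sheets always do
      keepm <- lab
      keepm[!(keepm %in% comps)] <- 0L
      px <- which(keepm > 0L, arr.ind = TRUE)
      if (nrow(px) == 0L) next
      extremes <- c(keepm[px[which.min(px[, 1]), , drop = FALSE]],
                    keepm[px[which.max(px[, 1]), , drop = FALSE]])
      inner_comps <- setdiff(comps, extremes)
      # a genuine inner sheet sits between the CA extremes in DV and clearly
      # medial of the lateral envelope; stray CA fragments fail these
      dv_rng <- range(px[, 1])
      lat_max <- max(s * (px[, 2] - 1 - mid))
      inner_comps <- Filter(function(cc) {
        idx <- which(lab == cc, arr.ind = TRUE)
        min(idx[, 1]) > dv_rng[1] + 1 && max(idx[, 1]) < dv_rng[2] - 1 &&
          mean(s * (idx[, 2] - 1 - mid)) < 0.8 * lat_max
      }, inner_comps)
      if (length(inner_comps) >= 1L) {
        cent <- vapply(inner_comps, function(cc) {
          idx <- which(lab == cc, arr.ind = TRUE)
          mean(s * (idx[, 2] - 1 - mid))     # lateral offset of centroid
        }, numeric(1))
        inner <- inner_comps[which.min(cent)]
        idx <- which(lab == inner, arr.ind = TRUE)
        med_ml <- idx[which.min(s * (idx[, 2] - 1 - mid)), 2] - 1
        pn <- normalize_points(cbind(ap, med_ml), fr)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = volume$subject_id, side = side, curve = "medial",
          ap = ap, ap_norm = pn[1], ml_norm = pn[2])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect implanted electrode tips in a volume
#'
#' Voxels above a high intensity quantile are grouped into 26-connected
#' components; components with at least `min_voxels` voxels are taken as
#' electrode rods, and each rod's tip is the centroid of its ventral-most
#' voxels. Components whose horizontal footprint is far larger than the
#' cohort of detected rods (merged neighboring rods) are flagged ambiguous.
#'
#' @param volume A `brain_volume`.
#' @param intensity_quantile Quantile defining "electrode-bright" voxels.
#' @param min_voxels Minimum component size retained.
#' @return An `electrode_set`: data frame `tips` (`ap`, `dv`, `ml`,
#'   `size`, `ambiguous`), possibly empty.
#' @export
detect_electrode_tips <- function(volume, intensity_quantile = 0.9995,
                                  min_voxels = 5L) {
  v <- volume$voxels
  d <- dim(v)
  thr <- stats::quantile(v, intensity_quantile, names = FALSE)
  # resampling blurs rod edges; capping the threshold at half the
  # tissue-to-maximum contrast keeps each partially blurred rod in one piece
  bg <- stats::median(v[v >= stats::quantile(v, 0.75, names = FALSE)])
  thr <- min(thr, bg + 0.5 * (max(v) - bg))
  # guard: the threshold must separate rods from tissue; if the brightest
  # voxels are not well above the bulk, there is nothing to detect
  if (thr <= stats::quantile(v, 0.99, names = FALSE) * 1.5)
    return(structure(list(tips = data.frame(ap = numeric(0), dv = numeric(0),
                                            ml = numeric(0), size = integer(0),
                                            ambiguous = logical(0))),
                     class = "electrode_set"))
  mask <- v >= thr
  lab <- label_components(mask, connectivity = 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  tips <- lapply(keep, function(cc) {
    idx <- arrayInd(which(lab == cc), d) - 1L
    deepest <- idx[idx[, 2] >= max(idx[, 2]) - 1L, , drop = FALSE]
    data.frame(ap = mean(deepest[, 1]), dv = max(idx[, 2]),
               ml = mean(deepest[, 3]), size = nrow(idx),
               foot = max(diff(range(idx[, 1])), diff(range(idx[, 3]))))
  })
  tips <- if (length(tips)) do.call(rbind, tips) else
    data.frame(ap = numeric(0), dv = numeric(0), ml = numeric(0),
               size = integer(0), foot = numeric(0))
  # a single rod's horizontal footprint is the brush diameter (~2-3 voxels);
  # wider components are neighboring rods merged into one
  tips$ambiguous <- if (nrow(tips) > 0L)
    tips$foot >= 3 | tips$foot > 2 * stats::median(tips$foot) + 2
  else logical(0)
  tips$foot <- NULL
  structure(list(tips = tips), class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat("<electrode_set> ", nrow(x$tips), " detected tips (",
      sum(x$tips$ambiguous), " ambiguous)\n", sep = "")
  invisible(x)
}

# Exact 2-D similarity transform (rotation + scale + translation) sending
# two anchor points onto two targets, in complex form z -> a z + b.
similarity_from_two <- function(p1, p2, q1, q2) {
  zp1 <- complex(real = p1[1], imaginary = p1[2])
  zp2 <- complex(real = p2[1], imaginary = p2[2])
  zq1 <- complex(real = q1[1], imaginary = q1[2])
  zq2 <- complex(real = q2[1], imaginary = q2[2])
  a <- (zq2 - zq1) / (zp2 - zp1)
  b <- zq1 - a * zp1
  list(a = a, b = b)
}

apply_similarity <- function(tf, pts) {
  z <- complex(real = pts[, 1], imaginary = pts[, 2])
  w <- tf$a * z + tf$b
  cbind(Re(w), Im(w))
}

# Least-squares complex similarity fit over matched point pairs.
similarity_lsq <- function(P, Q) {
  zp <- complex(real = P[, 1], imaginary = P[, 2])
  zq <- complex(real = Q[, 1], imaginary = Q[, 2])
  zp0 <- mean(zp); zq0 <- mean(zq)
  a <- sum(Conj(zp - zp0) * (zq - zq0)) / sum(Mod(zp - zp0)^2)
  list(a = a, b = zq0 - a * zp0)
}

# Greedy mutual nearest-neighbor assignment of detections to transformed
# slots: process candidate pairs by increasing distance.
greedy_assign <- function(det, slots_t) {
  nd <- nrow(det); ns <- nrow(slots_t)
  dm <- outer(seq_len(nd), seq_len(ns), function(i, j)
    sqrt((det[i, 1] - slots_t[j, 1])^2 + (det[i, 2] - slots_t[j, 2])^2))
  assign_det <- rep(NA_integer_, nd)
  used_slot <- rep(FALSE, ns)
  ord <- order(dm)
  for (o in ord) {
    i <- (o - 1L) %% nd + 1L
    j <- (o - 1L) %/% nd + 1L
    if (is.na(assign_det[i]) && !used_slot[j]) {
      assign_det[i] <- j
      used_slot[j] <- TRUE
    }
  }
  resid <- vapply(seq_len(nd), function(i)
    if (is.na(assign_det[i])) NA_real_ else dm[i, assign_det[i]], numeric(1))
  list(assign = assign_det, resid = resid)
}

#' Match detected electrodes to the cannula layout
#'
#' Finds the similarity transform (rotation, uniform scale, translation)
#' from cannula slot positions to detected electrode centroids and assigns
#' slot labels. Correspondence search is seeded from the two mutually
#' farthest detections, tried against every ordered pair of slots; each
#' candidate transform is scored by greedy nearest-neighbor assignment
#' residuals, the best is refined by least squares over its matches, and
#' the assignment recomputed. Surplus detections and unoccupied slots
#' remain unassigned.
#'
#' @param detected Numeric matrix (n x 2) of detected `(ap, ml)` centroids
#'   (n >= 2).
#' @param layout Cannula table ([cannula_layout()]); only occupied slots
#'   participate.
#' @param anchor_pairs Optional 2 x 2 integer matrix overriding the seeding
#'   heuristic: rows give (detection index, slot row index) anchors.
#' @return List: `assignment` data frame (`slot`, `ap`, `ml`, `det_ap`,
#'   `det_ml`, `residual`; NA rows for unmatched slots), `unassigned`
#'   detection indices, fitted `transform` (complex `a`, `b`), `rms`.
#' @export
match_cannula <- function(detected, layout, anchor_pairs = NULL) {
  detected <- rbind(detected)
  stopifnot(nrow(detected) >= 2L)
  slots <- layout[layout$occupied, , drop = FALSE]
  P <- as.matrix(slots[, c("ap", "ml")])
  if (nrow(detected) > nrow(P))
    warning("more detections than occupied slots; surplus flagged unassigned")
  # farthest detection pair
  dd <- as.matrix(stats::dist(detected))
  far <- which(dd == max(dd), arr.ind = TRUE)[1, ]
  cand_pairs <- if (!is.null(anchor_pairs)) {
    list(list(di = anchor_pairs[, 1], si = anchor_pairs[, 2]))
  } else {
    out <- list()
    for (i in seq_len(nrow(P))) for (j in seq_len(nrow(P))) {
      if (i == j) next
      out[[length(out) + 1L]] <- list(di = c(far[1], far[2]), si = c(i, j))
    }
    out
  }
  best <- NULL
  for (cp in cand_pairs) {
    tf <- similarity_from_two(P[cp$si[1], ], P[cp$si[2], ],
                              detected[cp$di[1], ], detected[cp$di[2], ])
    Pt <- apply_similarity(tf, P)
    g <- greedy_assign(detected, Pt)
    score <- sum(g$resid, na.rm = TRUE) + 1e3 * sum(is.na(g$resid))
    # near-ties (symmetric layouts) resolve to the smallest rotation
    if (is.null(best) || score < best$score - 1e-9 ||
        (score < best$score + 1e-9 && abs(Arg(tf$a)) < abs(Arg(best$tf$a))))
      best <- list(tf = tf, g = g, score = score)
  }
  # refine on the matched pairs and reassign
  m <- !is.na(best$g$assign)
  tf <- similarity_lsq(P[best$g$assign[m], , drop = FALSE],
                       detected[m, , drop = FALSE])
  Pt <- apply_similarity(tf, P)
  g <- greedy_assign(detected, Pt)
  assignment <- data.frame(slot = slots$slot, ap = P[, 1], ml = P[, 2],
                           det_ap = NA_real_, det_ml = NA_real_,
                           residual = NA_real_)
  for (i in seq_len(nrow(detected))) {
    j <- g$assign[i]
    if (is.na(j)) next
    assignment$det_ap[j] <- detected[i, 1]
    assignment$det_ml[j] <- detected[i, 2]
    assignment$residual[j] <- g$resid[i]
  }
  list(assignment = assignment,
       unassigned = which(is.na(g$assign)),
       transform = tf,
       rms = sqrt(mean(g$resid^2, na.rm = TRUE)))
}
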