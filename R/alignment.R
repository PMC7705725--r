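#' Named 3-D landmark sets
#'
#' @param points Numeric matrix (n x 3), columns (AP, DV, ML).
#' @param names Unique landmark names (taken from rownames if missing).
#' @param space Free-text coordinate-space tag (e.g. "voxel", "canonical").
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, names = rownames(points), space = "voxel") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, !is.null(names), !anyDuplicated(names))
  rownames(points) <- names
  colnames(points) <- c("ap", "dv", "ml")
  structure(list(points = points, space = space), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", nrow(x$points), " points in '", x$space, "' space\n",
      sep = "")
  print(round(x$points, 3))
  invisible(x)
}

new_rigid_transform <- function(rotation, translation) {
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rigid transforms: apply, invert, compose
#'
#' A `rigid_transform` maps moving-space points p to reference-space points
#' `R p + t` (rotation `R` proper orthonormal, translation `t` in voxel
#' units of the reference grid).
#'
#' @param transform,a,b `rigid_transform` objects.
#' @param points Numeric matrix (n x 3).
#' @return `apply_rigid`: transformed points; `invert_rigid` /
#'   `compose_rigid`: a `rigid_transform` (`compose_rigid(a, b)` applies `b`
#'   first, then `a`).
#' @export
apply_rigid <- function(transform, points) {
  points <- rbind(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  new_rigid_transform(Rt, -as.vector(Rt %*% transform$translation))
}

#' @rdname apply_rigid
#' @export
compose_rigid <- function(a, b) {
  new_rigid_transform(a$rotation %*% b$rotation,
                      as.vector(a$rotation %*% b$translation) + a$translation)
}

#' Least-squares rigid transform between corresponding landmark sets
#'
#' Closed-form orthogonal-Procrustes (Kabsch) estimate of the rotation and
#' translation mapping `src` onto `dst`, minimizing the sum of squared
#' correspondence distances. No scaling is fitted, and a reflection-optimal
#' solution is corrected to a proper rotation by the standard sign fix on
#' the smallest singular vector.
#'
#' @param src,dst [landmark_set()] objects sharing the same names (matched
#'   by name), with at least 3 non-collinear correspondences.
#' @return A `rigid_transform` mapping `src` coordinates into `dst` space.
#' @export
estimate_rigid <- function(src, dst) {
  stopifnot(inherits(src, "landmark_set"), inherits(dst, "landmark_set"))
  nm <- rownames(src$points)
  if (!setequal(nm, rownames(dst$points)))
    stop("landmark names differ between source and destination")
  P <- src$points[nm, , drop = FALSE]
  Q <- dst$points[nm, , drop = FALSE]
  if (nrow(P) < 3L) stop("need at least 3 correspondences")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  sv <- svd(P0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("degenerate (collinear) landmark configuration")
  H <- crossprod(P0, Q0)
  s <- svd(H)
  sgn <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, sgn))
  R <- s$v %*% D %*% t(s$u)
  new_rigid_transform(R, qc - as.vector(R %*% pc))
}

#' Resample a volume onto a reference grid under a rigid transform
#'
#' Pulls source intensities onto the reference grid by trilinear
#' interpolation at back-transformed coordinates (the transform maps source
#' voxel coordinates into the reference frame; its inverse is applied to
#' each reference voxel). Out-of-domain voxels receive `fill_value`.
#'
#' @param volume A `brain_volume` (the moving image).
#' @param transform `rigid_transform` from `volume` coordinates to the
#'   reference frame.
#' @param reference_dim Integer (AP, DV, ML) shape of the reference grid.
#' @param fill_value Intensity for voxels mapping outside the source.
#' @param region Optional list of three integer index vectors (1-based, per
#'   axis) restricting resampling to a sub-box of the reference grid;
#'   voxels outside the region are left at `fill_value`.
#' @return A `brain_volume` on the reference grid.
#' @export
resample_to_reference <- function(volume, transform,
                                  reference_dim = dim(volume$voxels),
                                  fill_value = 0, region = NULL) {
  src <- volume$voxels
  d <- dim(src)
  rd <- as.integer(reference_dim)
  inv <- invert_rigid(transform)
  if (is.null(region)) region <- lapply(rd, seq_len)
  nap <- length(region[[1]]); ndv <- length(region[[2]]); nml <- length(region[[3]])
  ap <- rep(region[[1]] - 1, times = ndv * nml)
  dv <- rep(rep(region[[2]] - 1, each = nap), times = nml)
  ml <- rep(region[[3]] - 1, each = nap * ndv)
  R <- inv$rotation; tr <- inv$translation
  x <- R[1, 1] * ap + R[1, 2] * dv + R[1, 3] * ml + tr[1]
  y <- R[2, 1] * ap + R[2, 2] * dv + R[2, 3] * ml + tr[2]
  z <- R[3, 1] * ap + R[3, 2] * dv + R[3, 3] * ml + tr[3]
  f1 <- floor(x); f2 <- floor(y); f3 <- floor(z)
  w1 <- x - f1; w2 <- y - f2; w3 <- z - f3
  # voxels sitting exactly on the far face of an axis still interpolate
  edge1 <- f1 == d[1] - 1 & w1 == 0; f1[edge1] <- d[1] - 2; w1[edge1] <- 1
  edge2 <- f2 == d[2] - 1 & w2 == 0; f2[edge2] <- d[2] - 2; w2[edge2] <- 1
  edge3 <- f3 == d[3] - 1 & w3 == 0; f3[edge3] <- d[3] - 2; w3[edge3] <- 1
  ok <- f1 >= 0 & f1 <= d[1] - 2 & f2 >= 0 & f2 <= d[2] - 2 &
        f3 >= 0 & f3 <= d[3] - 2
  vals <- rep(fill_value, length(x))
  if (any(ok)) {
    b1 <- f1[ok]; b2 <- f2[ok]; b3 <- f3[ok]
    u1 <- w1[ok]; u2 <- w2[ok]; u3 <- w3[ok]
    acc <- numeric(sum(ok))
    for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
      lin <- 1 + (b1 + da) + d[1] * ((b2 + db) + d[2] * (b3 + dc))
      w <- (if (da == 1) u1 else 1 - u1) *
           (if (db == 1) u2 else 1 - u2) *
           (if (dc == 1) u3 else 1 - u3)
      acc <- acc + w * src[lin]
    }
    vals[ok] <- acc
  }
  out <- array(fill_value, dim = rd)
  out[region[[1]], region[[2]], region[[3]]] <-
    array(vals, dim = c(nap, ndv, nml))
  new_brain_volume(out, volume$voxel_pitch, volume$subject_id, volume$provenance)
}

#' Detect the anatomical landmarks of the hippocampal cell layer
#'
#' Thresholds the bright cell layer relative to tissue at
#' `tissue + ratio * (layer - tissue)`, with both levels estimated from
#' intensity quantiles so the detection is invariant to global affine
#' intensity rescaling, and extracts, per hemisphere, the centroid of the
#' anterior-most layer voxels (the anterior CA1 tip, "origin" landmark) and
#' the lateral-most layer voxel of the first AP slice at which the dorsal
#' and ventral layer sheets form a single 4-connected in-slice component
#' (the fusion point, "unit" landmark). Voxels far brighter than the layer
#' (implanted electrodes) are excluded before analysis.
#'
#' @param volume A `brain_volume`.
#' @param intensity_ratio_threshold Fraction of the tissue-to-layer contrast
#'   at which to threshold (default 0.5).
#' @param min_contrast Minimum relative contrast `(layer - tissue)/tissue`
#'   required; below it the layer is deemed invisible and an error
#'   "landmarks not found" is thrown.
#' @param min_component Minimum in-slice component size (voxels) considered
#'   when locating the fusion slice (suppresses noise specks).
#' @return A [landmark_set()] with points `tip_left`, `tip_right`,
#'   `fusion_left`, `fusion_right`, `ventral_left`, `ventral_right`
#'   (0-based voxel coordinates). The posterior-ventral extremes
#'   (`ventral_*`: centroid of the side's layer voxels within one voxel of
#'   the ventral-most layer voxel) survive hippocampal lesions, which spare
#'   the ventral-most layer, and are therefore the alignment anchors for
#'   lesioned brains; the fusion points sit inside typical lesion windows
#'   and are reserved for the electrode coordinate frame.
#' @export
detect_anatomical_landmarks <- function(volume, intensity_ratio_threshold = 0.5,
                                        min_contrast = 0.2, min_component = 3L) {
  v <- volume$voxels
  d <- dim(v)
  mx <- stats::quantile(v, 0.995, names = FALSE)
  # tissue level from the upper quartile of all voxels (the ellipsoidal body
  # occupies ~a third of the grid), so the estimate is affine-equivariant
  body <- v[v >= stats::quantile(v, 0.75, names = FALSE)]
  bg <- stats::median(body)
  if (!is.finite(bg) || bg <= 0 || (mx - bg) / bg < min_contrast)
    stop("landmarks not found: no layer brighter than tissue at the required contrast")
  thr <- bg + intensity_ratio_threshold * (mx - bg)
  e_thr <- bg + 1.5 * (mx - bg)     # electrodes are far brighter than the layer
  sel <- which(v > thr & v <= e_thr)
  if (length(sel) == 0L) stop("landmarks not found: empty layer mask")
  co <- arrayInd(sel, d) - 1L        # 0-based (ap, dv, ml)
  mid <- (d[3] - 1) / 2
  out <- matrix(NA_real_, 6, 3,
                dimnames = list(c("tip_left", "tip_right",
                                  "fusion_left", "fusion_right",
                                  "ventral_left", "ventral_right"),
                                c("ap", "dv", "ml")))
  for (s in c(-1, 1)) {
    side <- if (s < 0) "left" else "right"
    rows <- if (s < 0) co[, 3] < mid else co[, 3] > mid
    cs <- co[rows, , drop = FALSE]
    if (nrow(cs) == 0L) stop("landmarks not found on the ", side, " side")
    a0 <- min(cs[, 1])
    tip <- colMeans(cs[cs[, 1] <= a0 + 1, , drop = FALSE])
    out[paste0("tip_", side), ] <- tip
    vx <- cs[cs[, 2] >= max(cs[, 2]) - 1L, , drop = FALSE]
    out[paste0("ventral_", side), ] <- colMeans(vx)
    # fusion: the dorsal-most and ventral-most layer pixels of a slice share
    # one in-slice component once the sheets have fused (the inner dentate
    # sheet, when present, never contains either extreme, so it cannot mask
    # the event). Discretization can bridge the sheets on isolated anterior
    # slices, so the fusion slice is the first slice of the final persistent
    # fused run, not the first fused slice encountered.
    aps <- sort(unique(cs[, 1]))
    fused <- rep(NA, length(aps))
    lat_pt <- vector("list", length(aps))
    for (k in seq_along(aps)) {
      sl <- cs[cs[, 1] == aps[k], , drop = FALSE]
      m2 <- matrix(FALSE, d[2], d[3])
      m2[cbind(sl[, 2] + 1L, sl[, 3] + 1L)] <- TRUE
      lab <- label_components(m2, connectivity = 4L)
      sizes <- tabulate(lab[lab > 0])
      big <- which(sizes >= min_component)
      if (length(big) == 0L) next
      keepm <- lab
      keepm[!(keepm %in% big)] <- 0L
      px <- which(keepm > 0L, arr.ind = TRUE)      # (dv+1, ml+1) of kept pixels
      top <- px[which.min(px[, 1]), ]
      bot <- px[which.max(px[, 1]), ]
      fused[k] <- lab[top[1], top[2]] == lab[bot[1], bot[2]]
      if (isTRUE(fused[k])) {
        ca <- px[lab[px] == lab[top[1], top[2]], , drop = FALSE]
        lat_off <- s * (ca[, 2] - 1 - mid)
        ext <- ca[lat_off >= max(lat_off) - 0.5, , drop = FALSE]
        lat_pt[[k]] <- c(aps[k], mean(ext[, 1]) - 1, mean(ext[, 2]) - 1)
      }
    }
    # first fused slice that starts a persistent (>= 3 known slices) fused
    # run, after at least one split slice; isolated discretization bridges
    # and fragmentary boundary slices are thereby ignored
    known <- which(!is.na(fused))
    fusion <- NULL
    if (length(known) >= 3L && any(!fused[known])) {
      first_split <- known[which(!fused[known])[1]]
      for (k in seq_along(known)) {
        i <- known[k]
        if (i <= first_split || !fused[i]) next
        nxt <- known[known > i]
        if (length(nxt) >= 2L && all(fused[nxt[1:2]])) {
          fusion <- lat_pt[[i]]
          break
        }
      }
    }
    if (is.null(fusion))
      stop("landmarks not found: no fusion slice on the ", side, " side")
    out[paste0("fusion_", side), ] <- fusion
  }
  landmark_set(out, space = "voxel")
}
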