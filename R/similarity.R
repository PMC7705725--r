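#' Generous bilateral region mask over the hippocampal formation
#'
#' Builds a binary mask on the reference grid covering the model
#' hippocampal formation: the canonical (un-jittered) layer template dilated
#' by a margin, deliberately generous so the whole structure is captured in
#' every aligned brain. Used as the crop region for slice-wise similarity.
#'
#' @param config A [cohort_config()] (defines the template geometry).
#' @param margin Dilation radius in voxels.
#' @return An object of class `region_mask`: logical `mask` array, the
#'   nonempty AP `slices` (0-based), and `side` helper info.
#' @export
make_region_mask <- function(config, margin = 4L) {
  d <- config$grid_shape
  tpl <- layer_template_points(config)
  m <- array(FALSE, dim = d)
  p <- paint_points(tpl$points, d, config$layer_thickness)
  m[p$lin] <- TRUE
  m <- dilate_mask(m, iterations = margin, connectivity = 26L)
  ap_any <- which(apply(m, 1, any)) - 1L
  structure(list(mask = m, slices = ap_any, mid = (d[3] - 1) / 2),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> ", sum(x$mask), " voxels over AP slices [",
      min(x$slices), ", ", max(x$slices), "]\n", sep = "")
  invisible(x)
}

#' Masked slice-wise SSIM between all pairs of brains
#'
#' For every AP (coronal) virtual slice intersecting the mask, and for each
#' hemisphere separately, crops all aligned volumes to the mask's bounding
#' box and computes SSIM between every unordered pair of brains. Left and
#' right crops are treated as separate slices pooled with equal weight
#' ("bilateral" averaging), and the averaged matrix is the arithmetic mean
#' of the per-slice matrices. Symmetry and a unit diagonal hold by
#' construction (each pair computed once).
#'
#' The Gaussian window sigma defaults to `50 * crop_width / 1000` pixels,
#' scaling the neighborhood used on full-size micro-CT slices (sigma 50 at
#' ~1000 px) down to the working crop width; the value actually used is
#' recorded in the result. The dynamic range defaults to the cohort-wide
#' max minus min intensity over the masked crops.
#'
#' @param volumes List of `brain_volume`s resampled to the reference grid.
#' @param mask A [make_region_mask()] result (same grid shape).
#' @param window_sigma Gaussian window sigma in pixels; `NULL` for the
#'   scaled default.
#' @param dynamic_range Intensity range `L`; `NULL` for the cohort-wide
#'   default.
#' @param k1,k2 SSIM stabilizing constants.
#' @param ap_slices Optional restriction to a subset of 0-based AP slices
#'   (e.g. the lesioned septo-temporal window for clustering).
#' @param ids Subject identifiers (defaults to the volumes' `subject_id`s).
#' @return An object of class `similarity_result`: `S_bar` (n x n averaged
#'   matrix), `S_slices` (n x n x n_slice array), `slice_info` (data frame
#'   with `ap`, `side`), `ids`, and the SSIM parameters used.
#' @export
masked_slicewise_similarity <- function(volumes, mask, window_sigma = NULL,
                                        dynamic_range = NULL,
                                        k1 = 0.01, k2 = 0.03,
                                        ap_slices = NULL, ids = NULL) {
  stopifnot(inherits(mask, "region_mask"), length(volumes) >= 2L)
  d <- dim(mask$mask)
  for (v in volumes)
    if (!all(dim(v$voxels) == d)) stop("volume and mask shapes differ")
  if (is.null(ids)) ids <- vapply(volumes, function(v) v$subject_id, character(1))
  n <- length(volumes)
  slices <- if (is.null(ap_slices)) mask$slices else intersect(mask$slices, ap_slices)
  mid <- mask$mid
  # per-(slice, side) crop boxes from the mask
  entries <- list()
  for (ap in slices) {
    M <- mask$mask[ap + 1L, , ]
    for (side in c("left", "right")) {
      cols <- if (side == "left") which(seq_len(d[3]) - 1 < mid)
              else which(seq_len(d[3]) - 1 > mid)
      Ms <- M[, cols, drop = FALSE]
      if (!any(Ms)) stop("empty mask slice (ap = ", ap, ", ", side, ")")
      rr <- range(which(apply(Ms, 1, any)))
      cc <- range(which(apply(Ms, 2, any)))
      entries[[length(entries) + 1L]] <-
        list(ap = ap, side = side, rows = rr[1]:rr[2], cols = cols[cc[1]:cc[2]])
    }
  }
  widths <- vapply(entries, function(e) length(e$cols), integer(1))
  if (is.null(window_sigma)) window_sigma <- 50 * max(widths) / 1000
  kern <- gaussian_kernel(window_sigma)
  # crops per entry per volume, cohort-wide dynamic range
  crops <- lapply(entries, function(e)
    lapply(volumes, function(v) v$voxels[e$ap + 1L, e$rows, e$cols, drop = TRUE]))
  if (is.null(dynamic_range)) {
    rng <- range(vapply(crops, function(ce) range(unlist(lapply(ce, range))),
                        numeric(2)))
    dynamic_range <- rng[2] - rng[1]
  }
  if (dynamic_range <= 0) stop("dynamic_range must be positive")
  fcache <- new.env(parent = emptyenv())
  fmat <- function(nn) {
    key <- as.character(nn)
    if (is.null(fcache[[key]])) fcache[[key]] <- filter_matrix(nn, kern)
    fcache[[key]]
  }
  S <- array(NA_real_, dim = c(n, n, length(entries)))
  for (e in seq_along(entries)) {
    ce <- crops[[e]]
    h <- nrow(ce[[1]]); w <- ncol(ce[[1]])
    Kh <- fmat(h); Kw <- fmat(w)
    mus <- lapply(ce, smooth2, Kh = Kh, Kw = Kw)
    vars <- mapply(function(x, mu) smooth2(x * x, Kh, Kw) - mu^2,
                   ce, mus, SIMPLIFY = FALSE)
    Se <- diag(1, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      r <- ssim_from_filters(ce[[i]], ce[[j]], Kh, Kw, dynamic_range, k1, k2,
                             mu_a = mus[[i]], mu_b = mus[[j]],
                             var_a = vars[[i]], var_b = vars[[j]])
      Se[i, j] <- Se[j, i] <- r$mean_ssim
    }
    S[, , e] <- Se
  }
  S_bar <- apply(S, c(1, 2), mean)
  dimnames(S_bar) <- list(ids, ids)
  slice_info <- data.frame(ap = vapply(entries, `[[`, numeric(1), "ap"),
                           side = vapply(entries, `[[`, character(1), "side"))
  structure(list(S_bar = S_bar, S_slices = S, slice_info = slice_info,
                 ids = ids, window_sigma = window_sigma,
                 dynamic_range = dynamic_range, k1 = k1, k2 = k2),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("<similarity_result> ", length(x$ids), " subjects x ",
      nrow(x$slice_info), " slice crops; sigma ", round(x$window_sigma, 3),
      ", L ", round(x$dynamic_range, 3), "; mean off-diagonal S_bar ",
      round(mean(x$S_bar[upper.tri(x$S_bar)]), 4), "\n", sep = "")
  invisible(x)
}

#' Nearest-control similarity profiles
#'
#' For every subject and every slice crop, the maximum similarity to any
#' control brain, excluding the subject itself (otherwise each control
#' would trivially score 1 against itself). Traces how control-like each
#' brain is along the anatomical axis; lesioned slices stand out as dips.
#'
#' @param result A [masked_slicewise_similarity()] result.
#' @param control_ids,lesion_ids Identifiers partitioning `result$ids`;
#'   at least 2 controls are required.
#' @return An object of class `nearest_control_profile`: `values`
#'   (subjects x slices matrix), `slice_info`, id vectors.
#' @export
nearest_control_profile <- function(result, control_ids, lesion_ids) {
  stopifnot(inherits(result, "similarity_result"))
  ids <- result$ids
  if (!setequal(c(control_ids, lesion_ids), ids) ||
      length(intersect(control_ids, lesion_ids)) > 0L)
    stop("control and lesion ids must partition the cohort")
  if (length(control_ids) < 2L)
    stop("need at least 2 controls (controls would have no comparator)")
  ci <- match(control_ids, ids)
  nsl <- dim(result$S_slices)[3]
  vals <- matrix(NA_real_, length(ids), nsl, dimnames = list(ids, NULL))
  for (s in seq_along(ids)) {
    comp <- setdiff(ci, s)
    vals[s, ] <- apply(result$S_slices[s, comp, , drop = FALSE], 3, max)
  }
  structure(list(values = vals, slice_info = result$slice_info,
                 control_ids = control_ids, lesion_ids = lesion_ids,
                 ids = ids),
            class = "nearest_control_profile")
}

#' Per-slice group medians and interquartile ranges
#'
#' Summarizes nearest-control profiles per group (control vs lesion) and
#' slice as median and quartiles, using R's default inclusive
#' linear-interpolation quantile definition (`stats::quantile` type 7).
#'
#' @param profile A [nearest_control_profile()] result.
#' @return Data frame with columns `group`, `slice`, `ap`, `side`,
#'   `median`, `q25`, `q75`.
#' @export
summarize_groups <- function(profile) {
  stopifnot(inherits(profile, "nearest_control_profile"))
  groups <- list(control = profile$control_ids, lesion = profile$lesion_ids)
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  out <- list()
  for (g in names(groups)) {
    sub <- profile$values[groups[[g]], , drop = FALSE]
    qs <- apply(sub, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
                type = 7, names = FALSE)
    out[[g]] <- data.frame(group = g,
                           slice = seq_len(ncol(sub)),
                           ap = profile$slice_info$ap,
                           side = profile$slice_info$side,
                           median = qs[2, ], q25 = qs[1, ], q75 = qs[3, ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count subjects assigned to surgery-pure groups
#'
#' A group is "pure" when all its members carry the same surgery label;
#' the returned count is the number of subjects belonging to pure groups
#' (equal to the cohort size when the cut separates lesion from control
#' perfectly).
#'
#' @param groups Integer group labels from [cut_groups()], named by subject.
#' @param labels Character surgery labels in the same order/naming.
#' @return Integer count.
#' @export
group_purity_count <- function(groups, labels) {
  stopifnot(length(groups) == length(labels))
  total <- 0L
  for (g in unique(groups)) {
    member <- groups == g
    if (length(unique(labels[member])) == 1L) total <- total + sum(member)
  }
  total
}
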