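# Independent oracles and shared fixtures for the test suite.

# Small, fast cohort configuration used by unit tests (the acceptance tests
# use the full-size defaults).
small_config <- function(...) {
  args <- list(n_control = 3L, n_lesion = 3L, grid_shape = c(64L, 48L, 48L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# Quiet, deterministic geometry: no noise, no pose jitter.
frozen_config <- function(...) {
  args <- list(noise_sd = 0, pose_jitter = list(rot_deg = 0, trans_vox = 0))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(small_config, args)
}

# --- brute-force SSIM oracle -------------------------------------------------
# Literal double loop over pixels: gather the (2r+1)^2 neighborhood with
# symmetric reflection, compute Gaussian-weighted moments, apply the SSIM
# formula. Independent of the filter-matrix implementation.
ssim_brute <- function(a, b, sigma, L, k1 = 0.01, k2 = 0.03) {
  r <- max(1L, ceiling(3.5 * sigma))
  w1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  w1 <- w1 / sum(w1)
  W <- outer(w1, w1)
  refl <- function(i, n) {
    p <- (i - 1) %% (2 * n)
    p[p < 0] <- p[p < 0] + 2 * n
    ifelse(p < n, p + 1, 2 * n - p)
  }
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  out <- matrix(NA_real_, nrow(a), ncol(a))
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    ri <- refl((i - r):(i + r), nrow(a))
    rj <- refl((j - r):(j + r), ncol(a))
    na <- a[ri, rj, drop = FALSE]
    nb <- b[ri, rj, drop = FALSE]
    mu_a <- sum(W * na); mu_b <- sum(W * nb)
    va <- sum(W * na^2) - mu_a^2
    vb <- sum(W * nb^2) - mu_b^2
    cab <- sum(W * na * nb) - mu_a * mu_b
    out[i, j] <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
                 ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  }
  list(mean_ssim = mean(out), ssim_map = out)
}

# --- MST-based single-linkage oracle ----------------------------------------
# Single-linkage merge heights equal the sorted edge weights of a minimum
# spanning tree; processing MST edges in ascending order reproduces the
# merge sequence. Prim's algorithm, independent of the package's
# agglomerative implementation.
mst_edges <- function(D) {
  n <- nrow(D)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- D[1, ]
  from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[k, ] <- c(from[j], as.integer(j), best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & D[j, ] < best
    best[upd] <- D[j, upd]
    from[upd] <- j
  }
  edges[order(edges[, 3]), , drop = FALSE]
}

# Partition of leaves after the m smallest MST edges are applied.
mst_partition <- function(D, m) {
  n <- nrow(D)
  e <- mst_edges(D)
  parent <- seq_len(n)
  find <- function(i) {
    i <- as.integer(i)
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (k in seq_len(m)) parent[find(e[k, 2])] <- find(e[k, 1])
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Canonical form of a partition for label-free comparison.
canon_partition <- function(g) {
  match(g, unique(g))
}

# Circular distance in radians.
circ_dist <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
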