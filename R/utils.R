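# Internal helpers: seeded RNG scoping, angle wrapping, connected components,
# morphological dilation/erosion on logical arrays.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a per-subject seed from a master seed
#'
#' Deterministic integer mixing so that every subject (and every stochastic
#' sub-step) of a cohort gets its own reproducible RNG stream. The scheme is
#' stable across platforms and sessions: all arithmetic stays below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param index Non-negative integer stream index.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  a <- as.double(master_seed) %% 2147483647
  b <- as.double(index) %% 2147483647
  s <- (a * 48271) %% 2147483647
  s <- (s + b * 16807 + 12345) %% 2147483647
  as.integer(s)
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Neighbourhood offset matrix (k x ndim) for a given connectivity.
conn_offsets <- function(ndim, connectivity) {
  if (ndim == 2L) {
    stopifnot(connectivity %in% c(4L, 8L))
    g <- as.matrix(expand.grid(-1:1, -1:1))
    g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
    if (connectivity == 4L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  } else if (ndim == 3L) {
    stopifnot(connectivity %in% c(6L, 18L, 26L))
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
    if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
    if (connectivity == 18L) g <- g[rowSums(abs(g)) <= 2L, , drop = FALSE]
  } else stop("only 2-D or 3-D masks supported")
  storage.mode(g) <- "integer"
  unname(g)
}

#' Label connected components of a logical mask
#'
#' Breadth-first labelling of a 2-D or 3-D logical array under a chosen
#' connectivity (4/8 in 2-D, 6/18/26 in 3-D). Intended for the sparse masks
#' that arise here (cell-layer sheets, electrode rods), where the number of
#' foreground voxels is small relative to the grid.
#'
#' @param mask Logical array (2-D or 3-D).
#' @param connectivity Neighbourhood definition; defaults to 8 (2-D) / 26 (3-D).
#' @return Integer array of the same shape; 0 = background, components
#'   numbered from 1 in discovery order (column-major scan of seeds).
#' @export
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  nd <- length(d)
  if (is.null(connectivity)) connectivity <- if (nd == 3L) 26L else 8L
  off <- conn_offsets(nd, as.integer(connectivity))
  lin <- which(mask)
  lbl <- array(0L, dim = d)
  if (length(lin) == 0L) return(lbl)
  coords <- arrayInd(lin, d)
  # position of each foreground voxel in `lin`, addressable by linear index
  pos <- array(0L, dim = d)
  pos[lin] <- seq_along(lin)
  visited <- logical(length(lin))
  # linear-index stride per dimension
  stride <- cumprod(c(1L, d[-nd]))
  off_lin <- as.vector(off %*% stride)
  comp <- 0L
  for (s in seq_along(lin)) {
    if (visited[s]) next
    comp <- comp + 1L
    frontier <- s
    visited[s] <- TRUE
    lbl[lin[s]] <- comp
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      fl <- lin[frontier]
      nxt <- integer(0)
      for (k in seq_len(nrow(off))) {
        nc <- fc + matrix(off[k, ], nrow(fc), nd, byrow = TRUE)
        ok <- rep(TRUE, nrow(nc))
        for (j in seq_len(nd)) ok <- ok & nc[, j] >= 1L & nc[, j] <= d[j]
        if (!any(ok)) next
        nl <- fl[ok] + off_lin[k]
        p <- pos[nl]
        p <- p[p > 0L]
        p <- p[!visited[p]]
        if (length(p)) {
          visited[p] <- TRUE
          lbl[lin[p]] <- comp
          nxt <- c(nxt, p)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lbl
}

# One dilation step: OR of the mask shifted by each neighbourhood offset.
shift_or <- function(mask, off) {
  d <- dim(mask)
  nd <- length(d)
  out <- mask
  for (k in seq_len(nrow(off))) {
    src <- vector("list", nd)
    dst <- vector("list", nd)
    ok <- TRUE
    for (j in seq_len(nd)) {
      o <- off[k, j]
      if (o >= 0) { src[[j]] <- seq_len(d[j] - o); dst[[j]] <- src[[j]] + o }
      else        { dst[[j]] <- seq_len(d[j] + o); src[[j]] <- dst[[j]] - o }
      if (length(src[[j]]) == 0L) { ok <- FALSE; break }
    }
    if (!ok) next
    idx_dst <- do.call(`[`, c(list(out), dst, drop = FALSE))
    idx_src <- do.call(`[`, c(list(mask), src, drop = FALSE))
    out <- do.call(`[<-`, c(list(out), dst, list(idx_dst | idx_src)))
  }
  out
}

#' Morphological dilation / erosion of a logical array
#'
#' @param mask Logical 2-D or 3-D array.
#' @param iterations Number of unit-radius steps.
#' @param connectivity Structuring element (see [label_components()]).
#' @return Logical array of the same shape.
#' @export
dilate_mask <- function(mask, iterations = 1L, connectivity = NULL) {
  nd <- length(dim(mask))
  if (is.null(connectivity)) connectivity <- if (nd == 3L) 26L else 8L
  off <- conn_offsets(nd, as.integer(connectivity))
  for (i in seq_len(iterations)) mask <- shift_or(mask, off)
  mask
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, iterations = 1L, connectivity = NULL) {
  for (i in seq_len(iterations)) mask <- !dilate_mask(!mask, 1L, connectivity)
  mask
}
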