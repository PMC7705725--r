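# Structural similarity (SSIM) on 2-D grayscale images with a Gaussian
# weighting window, the metric used slice-wise for lesion quantification.

# Gaussian weights truncated at 3.5 sigma, normalized to sum 1.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# Reflect a (possibly out-of-range) 1-based index into [1, n] under
# symmetric ("mirror with edge repeat") boundary handling.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- (i - 1) %% (2 * n)
  p[p < 0] <- p[p < 0] + 2 * n
  ifelse(p < n, p + 1, 2 * n - p)
}

# n x n matrix applying the 1-D kernel along one axis with symmetric
# reflection at the borders; smoothing an image X is then Kh %*% X %*% t(Kw).
filter_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- reflect_index((i - r):(i + r), n)
    for (k in seq_along(js)) K[i, js[k]] <- K[i, js[k]] + kernel[k]
  }
  K
}

smooth2 <- function(X, Kh, Kw) Kh %*% X %*% t(Kw)

#' Structural similarity between two images
#'
#' Computes the SSIM map and its mean for a pair of equally shaped 2-D
#' grayscale images. Local means, variances and covariance are weighted by
#' a Gaussian window of the given sigma (truncated at 3.5 sigma, symmetric
#' reflection at the borders), and the map is
#' \deqn{SSIM = \frac{(2\mu_a\mu_b + C_1)(2\sigma_{ab} + C_2)}
#'                   {(\mu_a^2 + \mu_b^2 + C_1)(\sigma_a^2 + \sigma_b^2 + C_2)}}
#' with \eqn{C_1 = (k_1 L)^2}, \eqn{C_2 = (k_2 L)^2} and `L` the dynamic
#' range. The mean is the unweighted average over all pixels.
#'
#' @param img_a,img_b Numeric matrices of identical shape.
#' @param window_sigma Gaussian window sigma in pixels.
#' @param dynamic_range Intensity range `L` (> 0); defaults to the range of
#'   the two images pooled.
#' @param k1,k2 Stabilizing constants (defaults 0.01 and 0.03).
#' @return List with `mean_ssim` (scalar) and `ssim_map` (matrix).
#' @export
ssim_pair <- function(img_a, img_b, window_sigma = 1.5,
                      dynamic_range = NULL, k1 = 0.01, k2 = 0.03) {
  stopifnot(is.matrix(img_a), is.matrix(img_b))
  if (!all(dim(img_a) == dim(img_b))) stop("image shapes differ")
  if (is.null(dynamic_range))
    dynamic_range <- max(img_a, img_b) - min(img_a, img_b)
  if (dynamic_range <= 0) stop("dynamic_range must be positive")
  kern <- gaussian_kernel(window_sigma)
  Kh <- filter_matrix(nrow(img_a), kern)
  Kw <- filter_matrix(ncol(img_a), kern)
  ssim_from_filters(img_a, img_b, Kh, Kw, dynamic_range, k1, k2)
}

# Core SSIM given precomputed filter matrices (reused across a cohort).
ssim_from_filters <- function(a, b, Kh, Kw, L, k1, k2,
                              mu_a = NULL, mu_b = NULL,
                              var_a = NULL, var_b = NULL) {
  C1 <- (k1 * L)^2
  C2 <- (k2 * L)^2
  if (is.null(mu_a)) mu_a <- smooth2(a, Kh, Kw)
  if (is.null(mu_b)) mu_b <- smooth2(b, Kh, Kw)
  if (is.null(var_a)) var_a <- smooth2(a * a, Kh, Kw) - mu_a^2
  if (is.null(var_b)) var_b <- smooth2(b * b, Kh, Kw) - mu_b^2
  cov_ab <- smooth2(a * b, Kh, Kw) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)) /
         ((mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2))
  list(mean_ssim = mean(map), ssim_map = map)
}
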