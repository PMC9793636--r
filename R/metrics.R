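#' Image-quality metrics: MSE, PSNR, SSIM
#'
#' All three metrics expect images on a common [0, 1] scale (see
#' [scale_unit()]); `img_psnr()` uses peak = 1 and therefore equals
#' `10*log10(1/mse)`, reported as `Inf` when the images are identical.
#' `img_ssim()` is the mean local structural similarity with the standard
#' Gaussian window (11 x 11, sigma 1.5) and stabilisers `C1 = (0.01*L)^2`,
#' `C2 = (0.03*L)^2`, `L = 1`; local moments use mirror padding so the
#' map covers the full image.
#'
#' @param ref,cmp numeric matrices of identical shape, values in [0, 1].
#' @return `img_mse()`: mean squared pixel difference; `img_psnr()`:
#'   decibels; `img_ssim()`: mean SSIM in [-1, 1].
#' @examples
#' a <- matrix(runif(64), 8, 8)
#' img_psnr(a, a)  # Inf
#' @export
img_mse <- function(ref, cmp) {
  stop_if_not_matrix(ref)
  stop_if_not_matrix(cmp)
  if (!identical(dim(ref), dim(cmp)))
    stop("ref and cmp must have identical shapes")
  mean((ref - cmp)^2)
}

#' @rdname img_mse
#' @export
img_psnr <- function(ref, cmp) {
  m <- img_mse(ref, cmp)
  if (m == 0) Inf else 10 * log10(1 / m)
}

#' @rdname img_mse
#' @param window odd window size for SSIM.
#' @param sigma Gaussian window standard deviation.
#' @param K constants `c(K1, K2)` for the stabilisers.
#' @export
img_ssim <- function(ref, cmp, window = 11L, sigma = 1.5,
                     K = c(0.01, 0.03)) {
  stop_if_not_matrix(ref)
  stop_if_not_matrix(cmp)
  if (!identical(dim(ref), dim(cmp)))
    stop("ref and cmp must have identical shapes")
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  r <- (window - 1L) %/% 2L
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  f <- function(m) conv_sep(m, k)
  C1 <- K[1]^2; C2 <- K[2]^2
  mu1 <- f(ref); mu2 <- f(cmp)
  s11 <- f(ref * ref) - mu1^2
  s22 <- f(cmp * cmp) - mu2^2
  s12 <- f(ref * cmp) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Min-max scale to the unit interval
#'
#' Scales `image` (and optionally companions) to [0, 1] using the range of
#' `reference` (default: the image itself), the convention applied before
#' computing quality metrics.
#'
#' @param image numeric matrix.
#' @param reference matrix whose range defines the scaling.
#' @return Scaled matrix, clipped to [0, 1].
#' @export
scale_unit <- function(image, reference = image) {
  lo <- min(reference); hi <- max(reference)
  if (hi <= lo) return(matrix(0, nrow(image), ncol(image)))
  pmin(pmax((image - lo) / (hi - lo), 0), 1)
}

#' Horizontal (x-axis) gradient image
#'
#' First difference along columns: central differences in the interior,
#' one-sided at the edge columns. Applied to absorption images it produces
#' the x-axis gradient comparison images whose signature at a step edge is
#' an antisymmetric white-to-black pair.
#'
#' @param image numeric matrix with at least 2 columns.
#' @return Matrix of the same shape.
#' @export
gradient_x <- function(image) {
  image <- as_pixels(image)
  if (ncol(image) < 2L) stop("need at least 2 columns")
  t(apply(image, 1, row_gradient))
}

#' Extract a pixel profile along a row
#'
#' Returns `image[row, col_start:(col_end - 1)]` (1-based indices,
#' half-open column range), the raw material for the profile plots that
#' separate flat soft-tissue stretches from quadratic bone arcs.
#'
#' @param image numeric matrix.
#' @param row row index (1-based).
#' @param col_start,col_end half-open column range `[col_start, col_end)`,
#'   1-based.
#' @return Numeric vector of length `col_end - col_start`.
#' @export
pixel_profile <- function(image, row, col_start, col_end) {
  image <- as_pixels(image)
  if (row < 1 || row > nrow(image) ||
      col_start < 1 || col_end > ncol(image) + 1 || col_end <= col_start)
    stop("profile indices out of bounds")
  image[row, col_start:(col_end - 1)]
}
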