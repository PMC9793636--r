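#' @useDynLib gridpcxi, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif median mad
NULL

# Frequency coordinate of DFT bin k (0-based) for an axis of length n,
# in cycles per pixel, in [-0.5, 0.5).
bin_freq <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= (n - 1L) %/% 2L, k / n, (k - n) / n)
}

# Unshifted frequency grids for a matrix: fy varies along rows, fx along
# columns, matching stats::fft of a matrix.
freq_grids <- function(nr, nc) {
  list(fy = matrix(bin_freq(nr), nr, nc),
       fx = matrix(bin_freq(nc), nr, nc, byrow = TRUE))
}

# DC bin (unshifted index 1) moves to the center position floor(n/2)+1.
shift_order <- function(n, inverse = FALSE) {
  s <- if (inverse) n %/% 2L else n - n %/% 2L
  ((seq_len(n) - 1L + s) %% n) + 1L
}

fftshift2 <- function(m)
  m[shift_order(nrow(m)), shift_order(ncol(m)), drop = FALSE]

ifftshift2 <- function(m)
  m[shift_order(nrow(m), TRUE), shift_order(ncol(m), TRUE), drop = FALSE]

ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Reflect an index vector into 1..n about the edges (no edge repeat:
# 0 -> 2, n+1 -> n-1), the mirror convention used by all spatial filters.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i - 1L) %% p + p) %% p
  ifelse(i >= n, p - i, i) + 1L
}

# Separable 1-D convolution along rows and columns with mirror padding.
conv_sep <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (r == 0L) return(m * kernel)
  idx_r <- reflect_index(seq(1L - r, nr + r), nr)
  idx_c <- reflect_index(seq(1L - r, nc + r), nc)
  pad <- m[idx_r, , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * pad[j:(j + nr - 1L), , drop = FALSE]
  pad <- out[, idx_c, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * pad[, j:(j + nc - 1L), drop = FALSE]
  out
}

gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_smooth2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep(m, gaussian_kernel(sigma))
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  invisible(x)
}

as_pixels <- function(image) {
  if (inherits(image, "raw_grid_image")) return(image$pixels)
  if (inherits(image, "insfreq_image")) return(image$pixels)
  stop_if_not_matrix(image, "image")
  image
}
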