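# Independent brute-force oracles used across the suite. These stay
# deliberately naive (loops, sorts, direct sums) so they share no code
# path with the package internals they check.

# literal transcription of the published unwrapping pseudocode: scan the
# sequence; while the difference to the next value exceeds pi, add + or -
# 2*pi to every remaining value
oracle_unwrap <- function(phi) {
  n <- length(phi)
  for (i in seq_len(n - 1L)) {
    while (phi[i + 1L] - phi[i] > pi)
      phi[(i + 1L):n] <- phi[(i + 1L):n] - 2 * pi
    while (phi[i] - phi[i + 1L] > pi)
      phi[(i + 1L):n] <- phi[(i + 1L):n] + 2 * pi
  }
  phi
}

# mirror index helper shared by the brute-force spatial oracles
oracle_reflect <- function(i, n) {
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  if (i >= n) p - i else i
}

# rank filter by explicit neighbourhood collection and full sort
oracle_rank_filter <- function(img, foot, q) {
  nr <- nrow(img); nc <- ncol(img)
  fr <- nrow(foot); fc <- ncol(foot)
  ry <- fr %/% 2L; rx <- fc %/% 2L
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (i in seq_len(fr)) for (j in seq_len(fc)) {
      if (!foot[i, j]) next
      rr <- oracle_reflect(r - 1L + i - 1L - ry, nr) + 1L
      cc <- oracle_reflect(c - 1L + j - 1L - rx, nc) + 1L
      vals <- c(vals, img[rr, cc])
    }
    vals <- sort(vals)
    out[r, c] <- vals[round(q * (length(vals) - 1)) + 1L]
  }
  out
}

# direct-sum 2-D convolution with a separable Gaussian kernel
oracle_gauss_conv <- function(m, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k <- k / sum(k)
  k2 <- outer(k, k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (i in seq(-rad, rad)) for (j in seq(-rad, rad)) {
      rr <- oracle_reflect(r - 1L + i, nr) + 1L
      cc <- oracle_reflect(c - 1L + j, nc) + 1L
      acc <- acc + k2[i + rad + 1L, j + rad + 1L] * m[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

# the full simple bitonic filter by brute force: disc-footprint rank
# opening/closing, averaged, plus the robustly weighted residual
# convolution evaluated by direct sums
oracle_simple_bitonic <- function(img, diameter, centile = 10,
                                  sigma_factor = 0.33) {
  r <- (diameter - 1L) %/% 2L
  d <- seq(-r, r)
  foot <- outer(d, d, function(dy, dx) dy^2 + dx^2 <= (diameter / 2)^2)
  q <- centile / 100
  er <- oracle_rank_filter(img, foot, q)
  opening <- oracle_rank_filter(er, foot, 1 - q)
  di <- oracle_rank_filter(img, foot, 1 - q)
  closing <- oracle_rank_filter(di, foot, q)
  inter <- (opening + closing) / 2
  res <- img - inter
  s <- stats::mad(res)
  sigma <- sigma_factor * diameter
  if (s <= 0) return(inter + oracle_gauss_conv(res, sigma))
  w <- 1 / (1 + (res / (3 * s))^2)
  inter + oracle_gauss_conv(w * res, sigma) /
    pmax(oracle_gauss_conv(w, sigma), 1e-12)
}

# windowed SSIM by explicit per-pixel loops
oracle_ssim <- function(ref, cmp, window = 11L, sigma = 1.5,
                        K = c(0.01, 0.03)) {
  r <- (window - 1L) %/% 2L
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  k2 <- outer(k, k)
  nr <- nrow(ref); nc <- ncol(ref)
  C1 <- K[1]^2; C2 <- K[2]^2
  total <- 0
  for (rr in seq_len(nr)) for (cc in seq_len(nc)) {
    m1 <- m2 <- s11 <- s22 <- s12 <- 0
    for (i in seq(-r, r)) for (j in seq(-r, r)) {
      ri <- oracle_reflect(rr - 1L + i, nr) + 1L
      ci <- oracle_reflect(cc - 1L + j, nc) + 1L
      w <- k2[i + r + 1L, j + r + 1L]
      a <- ref[ri, ci]; b <- cmp[ri, ci]
      m1 <- m1 + w * a; m2 <- m2 + w * b
      s11 <- s11 + w * a * a; s22 <- s22 + w * b * b; s12 <- s12 + w * a * b
    }
    s11 <- s11 - m1^2; s22 <- s22 - m2^2; s12 <- s12 - m1 * m2
    total <- total + (2 * m1 * m2 + C1) * (2 * s12 + C2) /
      ((m1^2 + m2^2 + C1) * (s11 + s22 + C2))
  }
  total / (nr * nc)
}

# spectral amplitude of a single tone (cycles/pixel) in an image
tone_amplitude <- function(img, fx, fy) {
  nr <- nrow(img); nc <- ncol(img)
  kx <- (round(fx * nc) %% nc) + 1L
  ky <- (round(fy * nr) %% nr) + 1L
  Mod(stats::fft(img))[ky, kx] * 2 / (nr * nc)
}
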