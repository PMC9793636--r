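#' Locate the grid carrier in the spectrum
#'
#' Finds the spatial frequency of the largest amplitude peak outside a
#' DC-exclusion disk and refines it to sub-bin precision by parabolic
#' interpolation of the log-amplitude along each frequency axis. For
#' simulator frames the result agrees with the geometry-derived carrier
#' within one frequency bin. Of the two conjugate peaks of a real image the
#' one in the `fx > 0` half-plane (or `fy > 0` on the `fx = 0` line) is
#' returned.
#'
#' @param raw a `raw_grid_image` or numeric matrix with a visible carrier.
#' @param dc_exclusion_radius radius (cycles/pixel) of the disk around DC
#'   ignored during the search; default 3 bins of the smaller dimension.
#' @return Numeric `c(fx, fy)` in cycles/pixel.
#' @section Errors: if no candidate peak reaches 3x the median non-DC
#'   spectral amplitude the carrier is declared absent ("no carrier found").
#' @export
locate_carrier <- function(raw, dc_exclusion_radius = NULL) {
  px <- as_pixels(raw)
  nr <- nrow(px); nc <- ncol(px)
  if (is.null(dc_exclusion_radius))
    dc_exclusion_radius <- 3 / min(nr, nc)
  # Hann apodization tames leakage so the parabolic sub-bin refinement
  # of the peak is nearly unbiased
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  A <- Mod(stats::fft((px - mean(px)) * outer(wr, wc)))
  fg <- freq_grids(nr, nc)
  fr <- sqrt(fg$fx^2 + fg$fy^2)
  outside <- fr > dc_exclusion_radius
  if (!any(outside)) stop("no carrier found")
  med <- stats::median(A[outside])
  peak <- max(A[outside])
  if (peak <= 0 || peak < 3 * med) stop("no carrier found")
  cand <- which(outside & A == peak, arr.ind = TRUE)
  # prefer the positive-fx conjugate (fy > 0 on the fx = 0 line)
  fx_c <- fg$fx[cand]; fy_c <- fg$fy[cand]
  keep <- which(fx_c > 0 | (fx_c == 0 & fy_c > 0))
  i <- if (length(keep)) cand[keep[1], ] else cand[1, ]
  r0 <- unname(i[1]); c0 <- unname(i[2])

  para <- function(l, c, r) {
    den <- l - 2 * c + r
    if (den == 0) 0 else 0.5 * (l - r) / den
  }
  logA <- function(r, c)
    log(A[reflect_wrap(r, nr), reflect_wrap(c, nc)] + 1e-300)
  dr <- para(logA(r0 - 1L, c0), logA(r0, c0), logA(r0 + 1L, c0))
  dc <- para(logA(r0, c0 - 1L), logA(r0, c0), logA(r0, c0 + 1L))
  dr <- max(min(dr, 0.5), -0.5); dc <- max(min(dc, 0.5), -0.5)
  fy <- bin_to_freq(r0 - 1 + dr, nr)
  fx <- bin_to_freq(c0 - 1 + dc, nc)
  c(fx = fx, fy = fy)
}

# periodic (modular) 1-based index into 1..n
reflect_wrap <- function(i, n) ((i - 1L) %% n) + n * ((i - 1L) %% n < 0) + 1L

# 0-based (possibly fractional) bin -> signed frequency in cycles/pixel
bin_to_freq <- function(k, n) {
  f <- k / n
  if (f > 0.5) f - 1 else f
}

# raised-cosine (Tukey) radial window: 1 for d <= r*(1-taper), cosine
# rolloff to 0 at d = r
tukey_disk <- function(d, radius, taper = 0.5) {
  flat <- radius * (1 - taper)
  w <- numeric(length(d))
  w[d <= flat] <- 1
  ramp <- d > flat & d < radius
  w[ramp] <- 0.5 * (1 + cos(pi * (d[ramp] - flat) / (radius - flat)))
  w
}

#' Separate zeroth and first harmonics of a carrier-modulated frame
#'
#' Windows the frame's 2-D spectrum with raised-cosine (Tukey) disks around
#' DC (zeroth harmonic) and around the +carrier peak (first harmonic). The
#' first harmonic is demodulated to baseband by multiplying the
#' windowed inverse transform with `exp(-2*pi*i*(fx*x + fy*y))`, so its
#' complex angle is the local carrier phase. Only the + conjugate peak is
#' used; for a real image the - peak is redundant.
#'
#' @param raw `raw_grid_image` or numeric matrix.
#' @param carrier numeric `c(fx, fy)` in cycles/pixel; located
#'   automatically when `NULL`.
#' @param band_halfwidth window radius in cycles/pixel, must be positive
#'   and at most half the carrier modulus (otherwise the DC and first bands
#'   overlap and the call is rejected); default 0.4 x carrier modulus.
#' @param taper Tukey taper fraction of the window radius.
#' @return Object of class `harmonic_decomposition`: complex matrices
#'   `zeroth` and `first`, plus `carrier_freq` and `band_halfwidth`.
#' @export
extract_harmonics <- function(raw, carrier = NULL, band_halfwidth = NULL,
                              taper = 0.5) {
  px <- as_pixels(raw)
  nr <- nrow(px); nc <- ncol(px)
  if (is.null(carrier)) carrier <- locate_carrier(raw)
  carrier <- as.numeric(carrier)
  fmod <- sqrt(sum(carrier^2))
  if (fmod <= 0) stop("carrier modulus must be positive")
  if (is.null(band_halfwidth)) band_halfwidth <- 0.4 * fmod
  if (band_halfwidth <= 0 || band_halfwidth > fmod / 2)
    stop("band_halfwidth must be in (0, |carrier|/2]")
  FT <- stats::fft(px)
  fg <- freq_grids(nr, nc)
  d0 <- sqrt(fg$fx^2 + fg$fy^2)
  w0 <- tukey_disk(d0, band_halfwidth, taper)
  zeroth <- ifft2(FT * w0)
  # wrapped distance to the +carrier position
  wdist <- function(f, f0) {
    d <- (f - f0) %% 1
    pmin(d, 1 - d)
  }
  d1 <- sqrt(wdist(fg$fx, carrier[1])^2 + wdist(fg$fy, carrier[2])^2)
  w1 <- tukey_disk(d1, band_halfwidth, taper)
  first_mod <- ifft2(FT * w1)
  x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  y <- matrix(seq_len(nr) - 1, nr, nc)
  first <- first_mod * exp(-2i * pi * (carrier[1] * x + carrier[2] * y))
  structure(list(zeroth = zeroth, first = first,
                 carrier_freq = c(fx = carrier[1], fy = carrier[2]),
                 band_halfwidth = band_halfwidth),
            class = "harmonic_decomposition")
}

#' Demodulate sample+grid against grid-only harmonics
#'
#' The harmonic-ratio retrieval of absorption, scattering and
#' differential-phase contrast:
#' * absorption `= |SG_0h| / |G_0h|` (ratio of zeroth-harmonic envelopes);
#' * complex ratio `= (SG_1h / G_1h) * (G_0h / SG_0h)`;
#' * scattering `= |complex ratio|` (visibility reduction);
#' * phase contrast `= atan2(Im, Re)` of the complex ratio, radians in
#'   (-pi, pi].
#'
#' Pixels where any divisor modulus falls below `eps_frac * max |G_0h|`
#' are flagged FALSE in the validity mask and set to 0 rather than raising
#' an error.
#'
#' @param sg,g `harmonic_decomposition` of the sample+grid and grid-only
#'   frames (identical shapes).
#' @param eps_frac relative divisor floor.
#' @return Object of class `contrast_images`: `absorption`, `scattering`,
#'   `pcxi` (real matrices), `complex_ratio` (complex), `valid` (logical).
#' @export
demodulate <- function(sg, g, eps_frac = 1e-6) {
  stopifnot(inherits(sg, "harmonic_decomposition"),
            inherits(g, "harmonic_decomposition"))
  if (!identical(dim(sg$zeroth), dim(g$zeroth)))
    stop("harmonic decompositions have mismatched shapes")
  eps <- eps_frac * max(Mod(g$zeroth))
  valid <- Mod(g$zeroth) > eps & Mod(g$first) > eps & Mod(sg$zeroth) > eps
  absorption <- matrix(0, nrow(sg$zeroth), ncol(sg$zeroth))
  absorption[valid] <- Mod(sg$zeroth[valid]) / Mod(g$zeroth[valid])
  ratio <- matrix(complex(real = 0), nrow(sg$zeroth), ncol(sg$zeroth))
  ratio[valid] <- (sg$first[valid] / g$first[valid]) *
    (g$zeroth[valid] / sg$zeroth[valid])
  scattering <- Mod(ratio)
  pcxi <- atan2(Im(ratio), Re(ratio))
  pcxi[pcxi == -pi] <- pi                     # principal value in (-pi, pi]
  pcxi[!valid] <- 0
  structure(list(absorption = absorption, scattering = scattering,
                 pcxi = pcxi, complex_ratio = ratio, valid = valid),
            class = "contrast_images")
}

#' @export
print.contrast_images <- function(x, ...) {
  cat(sprintf("contrast_images: %d x %d px (%.1f%% valid)\n",
              nrow(x$absorption), ncol(x$absorption), 100 * mean(x$valid)))
  cat(sprintf("  absorption range [%.3f, %.3f]\n",
              min(x$absorption[x$valid]), max(x$absorption[x$valid])))
  cat(sprintf("  scattering range [%.3f, %.3f]\n",
              min(x$scattering[x$valid]), max(x$scattering[x$valid])))
  cat(sprintf("  pcxi range [%.3f, %.3f] rad\n",
              min(x$pcxi[x$valid]), max(x$pcxi[x$valid])))
  invisible(x)
}
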