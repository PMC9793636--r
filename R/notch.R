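#' Segment periodic-noise peaks in the amplitude spectrum
#'
#' Step 1 of the two-step noise filter. The log-amplitude spectrum is
#' thresholded adaptively (local median plus `k_sigma` times the local
#' MAD-based robust deviation over a sliding window); pixels above the
#' threshold, outside a DC guard disk and outside any protected disks, seed
#' an 8-connected region growing that extends to neighbours above
#' `threshold - grow_margin`. Each detected region is paired with its
#' point-reflected conjugate (the spectrum of a real image is Hermitian)
#' and suppressed by an inverted Gaussian bump centred on the region
#' centroid with `sigma = equivalent radius x spread_factor` and depth 1,
#' yielding a multiplicative suppression mask over frequency space.
#'
#' The mask is stored with zero frequency at the array centre
#' ([fftshift2()] convention), is symmetric under frequency negation (so
#' the filtered image stays real) and is identically 1 inside the DC guard
#' disk.
#'
#' @param image numeric matrix (spatial domain).
#' @param dc_guard_radius guard radius in cycles/pixel; default `NULL`
#'   means 3 spectral bins of the smaller dimension.
#' @param k_sigma threshold constant (default 4).
#' @param window sliding window size in spectral bins (odd, default 31).
#' @param grow_margin region-growing margin in log-amplitude units.
#' @param spread_factor Gaussian sigma as a multiple of the region's
#'   equivalent radius.
#' @param protect list of protected spectral disks, each `c(fx, fy, r)` in
#'   cycles/pixel, that segmentation may never claim (e.g. the carrier).
#' @param max_region_radius_bins compactness cap: grown regions whose
#'   equivalent radius exceeds this many bins are treated as sample
#'   texture, not periodic noise, and are neither listed nor suppressed
#'   (periodic noise is spectrally narrow; broad spectral blobs carry
#'   image structure).
#' @return Object of class `notch_region_set`: `regions` (list with
#'   `centroid` = c(fx, fy), `peak_amplitude`, `equiv_radius_bins`,
#'   `n_pixels`), `suppression_mask` (centred convention, in [0, 1]),
#'   `dc_guard_radius`, and the image dimensions.
#' @examples
#' set.seed(1)
#' img <- matrix(rnorm(64 * 64), 64, 64)
#' ns <- segment_noise_peaks(img)  # white noise: typically empty
#' @export
segment_noise_peaks <- function(image, dc_guard_radius = NULL, k_sigma = 4,
                                window = 31L, grow_margin = 1.0,
                                spread_factor = 1.5, protect = list(),
                                max_region_radius_bins = 5) {
  image <- as_pixels(image)
  if (any(!is.finite(image))) stop("image must be finite")
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(dc_guard_radius)) dc_guard_radius <- 3 / min(nr, nc)
  if (dc_guard_radius <= 0) stop("dc_guard_radius must be > 0")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L

  A <- Mod(stats::fft(image))
  logA <- log(A + 1e-300)
  fg <- freq_grids(nr, nc)
  fr <- sqrt(fg$fx^2 + fg$fy^2)
  guard <- fr <= dc_guard_radius
  protected <- matrix(FALSE, nr, nc)
  for (pd in protect) {
    d <- sqrt(pmin((fg$fx - pd[1]) %% 1, 1 - (fg$fx - pd[1]) %% 1)^2 +
              pmin((fg$fy - pd[2]) %% 1, 1 - (fg$fy - pd[2]) %% 1)^2)
    dneg <- sqrt(pmin((fg$fx + pd[1]) %% 1, 1 - (fg$fx + pd[1]) %% 1)^2 +
                 pmin((fg$fy + pd[2]) %% 1, 1 - (fg$fy + pd[2]) %% 1)^2)
    protected <- protected | d <= pd[3] | dneg <= pd[3]
  }

  st <- cpp_sliding_median_mad(logA, window)
  thr <- st$median + k_sigma * 1.4826 * st$mad
  eligible <- !guard & !protected
  seeds <- logA > thr & eligible
  regions <- list()
  mask_c <- matrix(1, nr, nc)            # centred convention
  if (any(seeds)) {
    allowed <- (logA > (thr - grow_margin)) & eligible
    grown <- grow_regions(seeds, allowed)
    labels <- label_components(grown)
    nlab <- max(labels)
    # pair up conjugate regions so each physical noise component is one
    # region entry with a symmetric pair of bumps
    done <- logical(nlab)
    for (lb in seq_len(nlab)) {
      if (done[lb]) next
      idx <- which(labels == lb, arr.ind = TRUE)
      wts <- A[labels == lb]^2      # energy weighting resists leakage skirts
      cfx <- sum(fg$fx[labels == lb] * wts) / sum(wts)
      cfy <- sum(fg$fy[labels == lb] * wts) / sum(wts)
      # mark the conjugate component as handled if it was detected too
      conj_r <- reflect_wrap(2L - idx[, 1], nr)
      conj_c <- reflect_wrap(2L - idx[, 2], nc)
      conj_lb <- labels[cbind(conj_r, conj_c)]
      done[unique(conj_lb[conj_lb > 0])] <- TRUE
      done[lb] <- TRUE
      er <- sqrt(nrow(idx) / pi)
      if (er > max_region_radius_bins) next
      regions[[length(regions) + 1L]] <- list(
        centroid = c(fx = cfx, fy = cfy),
        peak_amplitude = sqrt(max(wts)),
        equiv_radius_bins = er,
        n_pixels = nrow(idx))
      sig <- er * spread_factor
      mask_c <- mask_c * notch_bump(nr, nc, cfx, cfy, sig)
    }
    # guard disk is never touched
    frc <- fftshift2(fr)
    mask_c[frc <= dc_guard_radius] <- 1
  }
  structure(list(regions = regions, suppression_mask = mask_c,
                 dc_guard_radius = dc_guard_radius, dim = c(nr, nc),
                 k_sigma = k_sigma),
            class = "notch_region_set")
}

# iterative 8-connected growth of `seeds` within `allowed` (toroidal
# neighbourhood, matching the periodic spectrum)
grow_regions <- function(seeds, allowed) {
  shift <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    m[reflect_wrap(seq_len(nr) - dr, nr), reflect_wrap(seq_len(nc) - dc, nc)]
  }
  grown <- seeds & allowed
  repeat {
    nb <- grown
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) nb <- nb | shift(grown, dr, dc)
    nxt <- (nb & allowed) | grown
    if (identical(nxt, grown)) return(grown)
    grown <- nxt
  }
}

# label 8-connected components (toroidal), small foreground expected
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  fg <- which(mask)
  for (start in fg) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- reflect_wrap(r + dr, nr); cc <- reflect_wrap(c + dc, nc)
        q <- (cc - 1L) * nr + rr
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# centred-convention suppression factor: inverted Gaussian bumps at the
# +/- centroid, computed with wrapped bin distance so the mask is
# symmetric under frequency negation by construction
notch_bump <- function(nr, nc, cfx, cfy, sigma_bins) {
  fg <- freq_grids(nr, nc)
  wd <- function(f, f0, n) {
    d <- (f - f0) %% 1
    pmin(d, 1 - d) * n
  }
  d_pos <- sqrt(wd(fg$fx, cfx, nc)^2 + wd(fg$fy, cfy, nr)^2)
  d_neg <- sqrt(wd(fg$fx, -cfx, nc)^2 + wd(fg$fy, -cfy, nr)^2)
  b <- (1 - exp(-d_pos^2 / (2 * sigma_bins^2))) *
       (1 - exp(-d_neg^2 / (2 * sigma_bins^2)))
  fftshift2(b)
}

#' Apply a notch suppression mask to an image
#'
#' Multiplies the image spectrum by the region set's suppression mask and
#' inverse-transforms. The DC bin is inside the guard disk and therefore
#' untouched, so the image mean is preserved (the output is re-anchored to
#' the input mean to absorb FFT round-off of order 1e-13). The imaginary
#' residue of the inverse transform is checked to be below 1e-8 of the
#' output norm and discarded.
#'
#' @param image numeric matrix.
#' @param regions a `notch_region_set` computed on an image of the same
#'   shape.
#' @return Filtered real matrix.
#' @export
apply_notch <- function(image, regions) {
  image <- as_pixels(image)
  stopifnot(inherits(regions, "notch_region_set"))
  if (!identical(dim(image), as.integer(regions$dim)) &&
      !identical(dim(image), regions$dim))
    stop("mask shape does not match image shape")
  mask_u <- ifftshift2(regions$suppression_mask)
  out_c <- ifft2(stats::fft(image) * mask_u)
  res <- sqrt(sum(Im(out_c)^2))
  nrm <- sqrt(sum(Mod(out_c)^2))
  if (nrm > 0 && res > 1e-8 * nrm)
    stop("filtered image has non-negligible imaginary residue")
  out <- Re(out_c)
  out + (mean(image) - mean(out))
}

#' Step-1 convenience wrapper: adaptive notch on an IF image
#'
#' Runs [segment_noise_peaks()] then [apply_notch()] on an
#' instantaneous-frequency image, with the carrier frequency (when known
#' from the source frame's geometry) pre-populated in the protect list so
#' the residual carrier line is never claimed as noise.
#'
#' @param pcxi_orig an `insfreq_image` (or plain matrix).
#' @param ... passed to [segment_noise_peaks()].
#' @param protect_radius radius (cycles/pixel) of the carrier protect
#'   disk; default 2 bins of the smaller dimension.
#' @return List with `filtered` (matrix) and `regions`
#'   (`notch_region_set`).
#' @export
filter_pcxi_step1 <- function(pcxi_orig, ..., protect_radius = NULL) {
  px <- as_pixels(pcxi_orig)
  if (is.null(protect_radius)) protect_radius <- 2 / min(dim(px))
  protect <- list()
  if (inherits(pcxi_orig, "insfreq_image") && !is.null(pcxi_orig$carrier))
    protect <- list(c(pcxi_orig$carrier, 0, protect_radius))
  regions <- segment_noise_peaks(px, protect = protect, ...)
  list(filtered = apply_notch(px, regions), regions = regions)
}

#' @export
print.notch_region_set <- function(x, ...) {
  cat(sprintf("notch_region_set: %d region pair(s), %d x %d spectrum\n",
              length(x$regions), x$dim[1], x$dim[2]))
  for (rg in x$regions)
    cat(sprintf("  (fx = %+.4f, fy = %+.4f) peak %.3g, r = %.2f bins\n",
                rg$centroid[1], rg$centroid[2], rg$peak_amplitude,
                rg$equiv_radius_bins))
  invisible(x)
}
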