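#' Ground-truth phantom description for the simulator
#'
#' Bundles the three per-pixel ground-truth fields that the forward model
#' renders onto the grid carrier, plus the noise recipe:
#' * `transmittance` T in (0, 1]: X-ray transmission of the sample
#'   (absorption contrast; 1 = no sample).
#' * `visibility` V in [0, 1]: carrier modulation depth; reduced from the
#'   bare-grid visibility by small-angle scattering.
#' * `phase` phi_s in radians: differential-phase-induced local shift of the
#'   carrier.
#'
#' @param transmittance,visibility,phase numeric matrices of identical
#'   dimensions (the detector shape).
#' @param periodic_noise list of additive sinusoids, each a list with
#'   elements `amplitude` (detector units), `freq` = c(fx, fy) in
#'   cycles/pixel, and `phase` (radians). Emulates Moire-like beats.
#' @param impulse_noise_prob probability in [0, 1) that a pixel is replaced
#'   by salt (image max) or pepper (0).
#' @param gaussian_noise_sigma standard deviation of additive white
#'   Gaussian noise, detector units, >= 0.
#' @param seed integer seed controlling every random draw during rendering.
#' @return An object of class `phantom_spec`.
#' @seealso [render_raw()], [make_fish_like_phantom()]
#' @export
phantom_spec <- function(transmittance, visibility, phase,
                         periodic_noise = list(),
                         impulse_noise_prob = 0,
                         gaussian_noise_sigma = 0,
                         seed = 1L) {
  stop_if_not_matrix(transmittance)
  stop_if_not_matrix(visibility)
  stop_if_not_matrix(phase)
  if (!identical(dim(transmittance), dim(visibility)) ||
      !identical(dim(transmittance), dim(phase)))
    stop("transmittance, visibility and phase must share dimensions")
  if (any(transmittance <= 0) || any(transmittance > 1))
    stop("transmittance must lie in (0, 1]")
  if (any(visibility < 0) || any(visibility > 1))
    stop("visibility must lie in [0, 1]")
  if (impulse_noise_prob < 0 || impulse_noise_prob >= 1)
    stop("impulse_noise_prob must lie in [0, 1)")
  if (gaussian_noise_sigma < 0)
    stop("gaussian_noise_sigma must be >= 0")
  for (pn in periodic_noise)
    stopifnot(is.list(pn), !is.null(pn$amplitude), length(pn$freq) == 2L)
  structure(
    list(transmittance = transmittance, visibility = visibility,
         phase = phase, periodic_noise = periodic_noise,
         impulse_noise_prob = impulse_noise_prob,
         gaussian_noise_sigma = gaussian_noise_sigma,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Render a raw detector frame from a phantom
#'
#' Forward model of single-grid imaging. With `x` the 0-based column index
#' and `f0` the carrier frequency implied by the geometry, the clean frame is
#'
#' `I(x, y) = B * T(x, y) * (1 + V(x, y) * cos(2*pi*f0*x + phi_s(x, y)))`
#'
#' to which the spec's periodic sinusoids and Gaussian noise are added and
#' impulse (salt-and-pepper) corruption applied last. For
#' `kind = "grid_only"` the sample fields are ignored: T = 1, V =
#' `grid_visibility`, phi_s = 0, so the frame is the bare carrier plus noise.
#' This model makes the harmonic-ratio demodulation of [demodulate()] an
#' exact inverse on noise-free data.
#'
#' @param spec a [phantom_spec()] whose fields match the geometry's
#'   detector shape.
#' @param geometry an [acquisition_geometry()].
#' @param kind `"grid_only"` or `"sample_grid"`.
#' @param base_intensity base (unmodulated) intensity B, detector units.
#' @param grid_visibility bare-grid modulation depth V0 in (0, 1].
#' @return An object of class `raw_grid_image` with elements `pixels`
#'   (rows x cols matrix), `kind`, `geometry`.
#' @examples
#' g <- acquisition_geometry(detector_shape = c(64, 64))
#' sp <- make_fish_like_phantom(g, seed = 1)
#' raw <- render_raw(sp, g, "sample_grid")
#' @export
render_raw <- function(spec, geometry,
                       kind = c("sample_grid", "grid_only"),
                       base_intensity = 1000,
                       grid_visibility = 0.6) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(geometry, "acquisition_geometry"))
  kind <- match.arg(kind)
  shp <- geometry$detector_shape
  if (!identical(dim(spec$transmittance), shp))
    stop(sprintf("phantom fields are %d x %d but detector is %d x %d",
                 nrow(spec$transmittance), ncol(spec$transmittance),
                 shp[1], shp[2]))
  nr <- shp[1]; nc <- shp[2]
  f0 <- carrier_frequency(geometry)
  x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  if (kind == "grid_only") {
    T_ <- 1; V <- grid_visibility; phs <- 0
  } else {
    T_ <- spec$transmittance; V <- spec$visibility; phs <- spec$phase
  }
  img <- base_intensity * T_ * (1 + V * cos(2 * pi * f0 * x + phs))

  # independent noise streams for the two frame kinds
  stream <- spec$seed + if (kind == "grid_only") 0L else 1L
  img <- with_seed(stream, {
    for (pn in spec$periodic_noise) {
      ph <- if (is.null(pn$phase)) 0 else pn$phase
      y <- matrix(seq_len(nr) - 1, nr, nc)
      img <- img + pn$amplitude *
        cos(2 * pi * (pn$freq[1] * x + pn$freq[2] * y) + ph)
    }
    if (spec$gaussian_noise_sigma > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec$gaussian_noise_sigma), nr, nc)
    if (spec$impulse_noise_prob > 0) {
      hit <- runif(nr * nc) < spec$impulse_noise_prob
      salt <- runif(nr * nc) < 0.5
      img[hit & salt] <- max(img)
      img[hit & !salt] <- 0
    }
    img
  })
  structure(list(pixels = img, kind = kind, geometry = geometry),
            class = "raw_grid_image")
}

#' @export
print.raw_grid_image <- function(x, ...) {
  cat(sprintf("raw_grid_image (%s): %d x %d px, range [%.3g, %.3g]\n",
              x$kind, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Smooth ellipse indicator in [0,1]: 1 inside, tanh rolloff of width
# `edge` (in units of the normalized radius) at the boundary.
soft_ellipse <- function(nr, nc, cy, cx, ry, rx, angle = 0, edge = 0.06) {
  y <- matrix(seq_len(nr) - 1, nr, nc) - cy
  x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) - cx
  u <- (x * cos(angle) + y * sin(angle)) / rx
  v <- (-x * sin(angle) + y * cos(angle)) / ry
  d <- sqrt(u^2 + v^2)
  0.5 * (1 - tanh((d - 1) / edge))
}

#' Deterministic fish-like phantom
#'
#' Builds a seeded phantom imitating a small fish: a large soft-tissue body
#' ellipse (mild attenuation, *constant* differential-phase plateau in its
#' interior) crossed by thin rib-like "bones" (strong attenuation, phase
#' following a *quadratic arc* across each rib, with steep edges). This
#' reproduces the two pixel-profile signatures that distinguish soft tissue
#' (flat profile) from bone (parabolic profile) in filtered phase-contrast
#' images. Visibility is mildly reduced inside tissue and more strongly
#' inside bone (scattering).
#'
#' Ribs are confined to the lower ~60% of the body so that rows in the upper
#' body cross soft tissue only; the returned object carries a `landmarks`
#' attribute with a guaranteed soft-tissue-only row, a row crossing ribs,
#' and the rib centres, for profile-based checks.
#'
#' @param geometry an [acquisition_geometry()].
#' @param seed integer; same seed, same phantom, bit for bit.
#' @param n_ribs number of rib ellipses.
#' @return A [phantom_spec()] (no noise terms; add them via
#'   [phantom_spec()] or the `noise` argument of [run_pipeline()] configs).
#' @export
make_fish_like_phantom <- function(geometry, seed = 1L, n_ribs = 5L) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  shp <- geometry$detector_shape
  nr <- shp[1]; nc <- shp[2]
  with_seed(seed, {
    body <- soft_ellipse(nr, nc, cy = nr * 0.52, cx = nc * 0.5,
                         ry = nr * 0.34, rx = nc * 0.40, edge = 0.05)
    T_ <- 1 - 0.15 * body            # soft tissue: mild attenuation
    phs <- 0.40 * body               # constant phase plateau inside body
    vis <- 0.6 * (1 - 0.05 * body)

    rib_cx <- numeric(n_ribs); rib_cy <- numeric(n_ribs)
    rib_w <- numeric(n_ribs)
    for (j in seq_len(n_ribs)) {
      cx <- nc * (0.25 + 0.5 * (j - 0.5) / n_ribs) + rnorm(1, 0, nc * 0.01)
      cy <- nr * 0.66 + rnorm(1, 0, nr * 0.015)
      ry <- nr * 0.14
      rx <- max(2.5, nc * 0.018)     # thin along x
      ang <- rnorm(1, 0, 0.06)
      rib <- soft_ellipse(nr, nc, cy, cx, ry, rx, ang, edge = 0.10)
      # quadratic arc across the rib: peak at the centreline, falling as
      # the squared normalized distance (what (1 - d^2) rasterizes to)
      y <- matrix(seq_len(nr) - 1, nr, nc) - cy
      x <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE) - cx
      u <- (x * cos(ang) + y * sin(ang)) / rx
      v <- (-x * sin(ang) + y * cos(ang)) / ry
      arc <- pmax(0, 1 - (u^2 + v^2))
      T_ <- T_ * (1 - 0.45 * rib)    # bone: strong attenuation
      # quadratic phase arc; its peak slope 2 * 0.3 / rx stays below the
      # carrier phase increment 2*pi*f0 so the analytic phase never
      # stalls (the validity condition of IF demodulation)
      phs <- phs + 0.3 * arc
      vis <- vis * (1 - 0.25 * rib)
      rib_cx[j] <- cx; rib_cy[j] <- cy; rib_w[j] <- rx
    }
    T_ <- pmin(pmax(T_, 1e-3), 1)
    vis <- pmin(pmax(vis, 0), 1)
    sp <- phantom_spec(T_, vis, phs, seed = seed)
    attr(sp, "landmarks") <- list(
      soft_row = as.integer(round(nr * 0.40)),
      rib_row = as.integer(round(mean(rib_cy))) + 1L,
      rib_cx = rib_cx + 1, rib_halfwidth = rib_w,
      body = list(cy = nr * 0.52, cx = nc * 0.5,
                  ry = nr * 0.34, rx = nc * 0.40))
    sp
  })
}

#' Write and read raw frames as TIFF with sidecar metadata
#'
#' `write_raw_tiff()` stores the pixel matrix as a 16-bit grayscale TIFF
#' (clipped/scaled to the stated `max_value`) together with a YAML sidecar
#' (`<path>.yaml`) recording the geometry, kind and scale so the frame can
#' be reloaded losslessly enough for demodulation. `read_raw_tiff()`
#' reverses this.
#'
#' @param raw a `raw_grid_image`.
#' @param path output TIFF path.
#' @param max_value intensity mapped to the top of the 16-bit range;
#'   defaults to the image maximum.
#' @return `write_raw_tiff()` returns `path` invisibly; `read_raw_tiff()`
#'   returns a `raw_grid_image`.
#' @export
write_raw_tiff <- function(raw, path, max_value = max(raw$pixels)) {
  stopifnot(inherits(raw, "raw_grid_image"))
  if (max_value <= 0) max_value <- 1
  m <- pmin(pmax(raw$pixels / max_value, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  meta <- list(kind = raw$kind, max_value = max_value,
               geometry = unclass(raw$geometry))
  meta$geometry$detector_shape <- as.integer(meta$geometry$detector_shape)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_raw_tiff
#' @export
read_raw_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  g <- meta$geometry
  geometry <- acquisition_geometry(g$grid_pitch_mm, g$pixel_size_um,
                                   g$source_grid_mm, g$source_detector_mm,
                                   as.integer(unlist(g$detector_shape)))
  structure(list(pixels = m * meta$max_value, kind = meta$kind,
                 geometry = geometry),
            class = "raw_grid_image")
}

#' Default noise profile emulating the laboratory artefacts
#'
#' One near-carrier sinusoidal beat (a Moire-like artefact at 0.93 x the
#' carrier frequency in x and 0.01 cycles/px in y), additive Gaussian
#' detector noise, and sparse salt-and-pepper corruption.
#'
#' @param geometry an [acquisition_geometry()].
#' @param base_intensity the base intensity B used at render time.
#' @return A list with `periodic_noise`, `impulse_noise_prob`,
#'   `gaussian_noise_sigma`, suitable for splicing into [phantom_spec()].
#' @export
default_noise_profile <- function(geometry, base_intensity = 1000) {
  f0 <- carrier_frequency(geometry)
  list(
    periodic_noise = list(list(amplitude = 0.05 * base_intensity,
                               freq = c(0.93 * f0, 0.01), phase = 0)),
    impulse_noise_prob = 0.02,
    gaussian_noise_sigma = 0.01 * base_intensity)
}
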