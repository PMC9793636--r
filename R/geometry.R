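#' Acquisition geometry of a single-grid imaging system
#'
#' Describes the grid/detector arrangement that determines the spatial
#' carrier frequency on the detector: a one-dimensional absorption grid of
#' pitch `grid_pitch_mm` placed `source_grid_mm` from the source projects a
#' line pattern onto a detector `source_detector_mm` from the source, so the
#' pattern is magnified by `source_detector_mm / source_grid_mm` and sampled
#' at `pixel_size_um`. Defaults reproduce a laboratory setup with a 0.118 mm
#' grid, 7 micron pixels and 700 mm / 1448 mm source-grid / source-detector
#' distances, giving a carrier period of about 34.87 pixels.
#'
#' @param grid_pitch_mm grid pitch in millimetres (> 0).
#' @param pixel_size_um detector pixel size in microns (> 0).
#' @param source_grid_mm source-to-grid distance in millimetres (> 0).
#' @param source_detector_mm source-to-detector distance in millimetres;
#'   must exceed `source_grid_mm`.
#' @param detector_shape integer vector `c(rows, cols)`; defaults to a
#'   desk-scale 512 x 512 frame (the full 3840 x 3072 detector is supported).
#' @return An object of class `acquisition_geometry`.
#' @seealso [carrier_period_px()], [render_raw()]
#' @examples
#' g <- acquisition_geometry()
#' carrier_period_px(g)
#' @export
acquisition_geometry <- function(grid_pitch_mm = 0.118,
                                 pixel_size_um = 7,
                                 source_grid_mm = 700,
                                 source_detector_mm = 1448,
                                 detector_shape = c(512L, 512L)) {
  stopifnot(length(detector_shape) == 2L)
  detector_shape <- as.integer(detector_shape)
  if (any(!is.finite(c(grid_pitch_mm, pixel_size_um, source_grid_mm,
                       source_detector_mm))) ||
      grid_pitch_mm <= 0 || pixel_size_um <= 0 || source_grid_mm <= 0)
    stop("all geometry lengths must be finite and strictly positive")
  if (source_detector_mm <= source_grid_mm)
    stop("source_detector_mm must exceed source_grid_mm")
  if (any(detector_shape < 4L))
    stop("detector_shape entries must be >= 4")
  g <- structure(
    list(grid_pitch_mm = grid_pitch_mm,
         pixel_size_um = pixel_size_um,
         source_grid_mm = source_grid_mm,
         source_detector_mm = source_detector_mm,
         detector_shape = detector_shape),
    class = "acquisition_geometry")
  if (carrier_period_px(g) <= 2)
    stop("carrier period on the detector must exceed 2 pixels (Nyquist)")
  g
}

#' Carrier period and frequency on the detector
#'
#' The grid pattern is magnified geometrically onto the detector, so its
#' period in pixels is
#' `grid_pitch * (source_detector / source_grid) / pixel_size`.
#' `carrier_frequency()` is its reciprocal in cycles/pixel along the x
#' (column) axis.
#'
#' @param geometry an [acquisition_geometry()].
#' @return Period in pixels, or frequency in cycles/pixel.
#' @export
carrier_period_px <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  geometry$grid_pitch_mm *
    (geometry$source_detector_mm / geometry$source_grid_mm) /
    (geometry$pixel_size_um / 1000)
}

#' @rdname carrier_period_px
#' @export
carrier_frequency <- function(geometry) 1 / carrier_period_px(geometry)

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("Single-grid acquisition geometry\n")
  cat(sprintf("  grid pitch      : %.4g mm\n", x$grid_pitch_mm))
  cat(sprintf("  pixel size      : %.4g um\n", x$pixel_size_um))
  cat(sprintf("  source-grid     : %.4g mm\n", x$source_grid_mm))
  cat(sprintf("  source-detector : %.4g mm\n", x$source_detector_mm))
  cat(sprintf("  detector        : %d x %d px\n",
              x$detector_shape[1], x$detector_shape[2]))
  cat(sprintf("  carrier period  : %.3f px (f0 = %.5f cycles/px)\n",
              carrier_period_px(x), carrier_frequency(x)))
  invisible(x)
}
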