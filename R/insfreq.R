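#' Analytic signal of one detector row
#'
#' Forms the complex analytic representation of a row: the row minus its
#' mean plus `i` times its Hilbert transform (the quadrature signal, with
#' negative frequencies suppressed in the DFT). The angle of the result is
#' the wrapped local phase of the carrier along the row. A Hilbert transform
#' maps a cosine into a sine, so for a pure carrier row the analytic signal
#' is the complex exponential of the carrier phase.
#'
#' The DC offset is removed first because a non-zero mean biases the
#' analytic phase toward zero; grid-modulated rows always ride on a large
#' base intensity.
#'
#' @param row numeric vector, length >= 4.
#' @return Complex vector of the same length. If the row is constant (zero
#'   after centring) the result is complex zero with attribute
#'   `degenerate = TRUE`; its phase is defined as 0.
#' @examples
#' x <- 0:255
#' z <- analytic_row(cos(2 * pi * 8 * x / 256))
#' Arg(z[1])  # ~0
#' @export
analytic_row <- function(row) {
  if (!is.numeric(row) || length(row) < 4L)
    stop("row must be a numeric vector of length >= 4")
  if (any(!is.finite(row))) stop("row must be finite")
  n <- length(row)
  centred <- row - mean(row)
  if (max(abs(centred)) == 0) {
    z <- complex(real = rep(0, n))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(centred) * h, inverse = TRUE) / n
}

#' One-dimensional phase unwrapping
#'
#' Removes artificial 2*pi discontinuities from a wrapped phase sequence by
#' scanning left to right: wherever the difference between consecutive
#' values exceeds pi in magnitude, the appropriate multiple of +/-2*pi is
#' added to the remainder of the sequence until that difference is below
#' pi. Inputs outside (-pi, pi] are first reduced into that interval.
#'
#' @param wrapped numeric vector of finite phases (radians).
#' @return Unwrapped phase vector: consecutive differences all have
#'   magnitude <= pi and each element differs from its reduced input by an
#'   integer multiple of 2*pi; the first element is unchanged.
#' @examples
#' unwrap_phase(c(0, 2.0, -2.2))  # -2.2 lifted by 2*pi
#' @export
unwrap_phase <- function(wrapped) {
  if (!is.numeric(wrapped) || any(!is.finite(wrapped)))
    stop("wrapped phases must be finite numeric")
  n <- length(wrapped)
  w <- wrapped
  oor <- w <= -pi | w > pi
  if (any(oor)) {                       # reduce only out-of-range values
    m <- w[oor] %% (2 * pi)
    w[oor] <- ifelse(m > pi, m - 2 * pi, m)
  }
  if (n < 2L) return(w)
  # left-to-right scan; a jump > pi shifts the whole remaining tail by
  # 2*pi, one turn at a time, until the difference is admissible
  for (i in seq_len(n - 1L)) {
    repeat {
      d <- w[i + 1L] - w[i]
      if (d > pi) w[(i + 1L):n] <- w[(i + 1L):n] - 2 * pi
      else if (-d > pi) w[(i + 1L):n] <- w[(i + 1L):n] + 2 * pi
      else break
    }
  }
  w
}

# trapezoid row integral of an instantaneous-frequency row, in radians:
# equals unwrapped-phase(last) - unwrapped-phase(first) exactly for the
# central-difference gradient with one-sided ends
if_row_integral <- function(if_row, fs) {
  n <- length(if_row)
  s <- sum(if_row) - 0.5 * (if_row[1] + if_row[n])
  s * 2 * pi / fs
}

row_gradient <- function(phi, mode = c("central", "forward")) {
  mode <- match.arg(mode)
  n <- length(phi)
  g <- numeric(n)
  if (mode == "central") {
    g[2:(n - 1)] <- (phi[3:n] - phi[1:(n - 2)]) / 2
    g[1] <- phi[2] - phi[1]
    g[n] <- phi[n] - phi[n - 1]
  } else {
    g[1:(n - 1)] <- diff(phi)
    g[n] <- g[n - 1]
  }
  g
}

#' Phase-contrast image from instantaneous frequency
#'
#' The single-frame phase-contrast extraction: every row of the raw
#' sample+grid image is converted to its analytic signal
#' ([analytic_row()]), the wrapped phase is unwrapped ([unwrap_phase()]),
#' and the instantaneous frequency `Insfre(x) = fs/(2*pi) * d phi/dx` is
#' computed with `fs` equal to the row length, so units are cycles per
#' line. For an undisturbed carrier the image is flat at the carrier
#' frequency; sample-induced differential phase appears as local
#' excursions proportional to the x-derivative of the phase shift. Rows are
#' processed independently.
#'
#' @param raw a `raw_grid_image` or a plain numeric matrix (>= 4 columns).
#' @param gradient difference scheme for d phi/dx: `"central"` (one-sided
#'   at the edge columns) or `"forward"`.
#' @return An object of class `insfreq_image`: list with `pixels` (matrix,
#'   cycles/line), `fs` (columns per line), `row_mask` (logical, TRUE for
#'   degenerate all-constant rows, which are emitted as zeros).
#' @examples
#' m <- matrix(rep(cos(2 * pi * 8 * (0:255) / 256), each = 32), 32, 256,
#'             byrow = FALSE)
#' @export
instantaneous_frequency_image <- function(raw,
                                          gradient = c("central", "forward")) {
  gradient <- match.arg(gradient)
  px <- as_pixels(raw)
  if (ncol(px) < 4L) stop("need at least 4 columns")
  nr <- nrow(px); nc <- ncol(px)
  fs <- nc
  out <- matrix(0, nr, nc)
  degen <- logical(nr)
  for (r in seq_len(nr)) {
    z <- analytic_row(px[r, ])
    if (isTRUE(attr(z, "degenerate"))) { degen[r] <- TRUE; next }
    phi <- unwrap_phase(Arg(z))
    out[r, ] <- row_gradient(phi, gradient) * fs / (2 * pi)
  }
  structure(list(pixels = out, fs = fs, row_mask = degen,
                 carrier = if (inherits(raw, "raw_grid_image"))
                   carrier_frequency(raw$geometry) else NULL),
            class = "insfreq_image")
}

#' @export
print.insfreq_image <- function(x, ...) {
  cat(sprintf(
    "insfreq_image: %d x %d px, fs = %d, IF range [%.3f, %.3f] cycles/line\n",
    nrow(x$pixels), ncol(x$pixels), x$fs, min(x$pixels), max(x$pixels)))
  if (any(x$row_mask))
    cat(sprintf("  %d degenerate (constant) row(s)\n", sum(x$row_mask)))
  invisible(x)
}
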