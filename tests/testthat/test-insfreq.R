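test_that("analytic signal turns cosine rows into complex exponentials", {
  n <- 256
  x <- 0:(n - 1)
  z <- analytic_row(cos(2 * pi * 8 * x / n))
  expect_equal(Arg(z[1]), 0, tolerance = 1e-9)
  expect_equal(z, complex(argument = 2 * pi * 8 * x / n), tolerance = 1e-9)
  # sine is a cosine delayed by pi/2
  zs <- analytic_row(sin(2 * pi * 8 * x / n))
  expect_equal(Arg(zs[1]), -pi / 2, tolerance = 1e-9)
})

test_that("analytic signal energy matches the spectral closed form", {
  # |analytic|^2 sums to 2x the centred row energy minus the DC and
  # (for even n) Nyquist contributions kept at unit weight; computed
  # here by brute-force spectral summation
  set.seed(7)
  for (n in c(64L, 129L)) {
    row <- stats::rnorm(n)
    cen <- row - mean(row)
    z <- analytic_row(row)
    sp <- stats::fft(cen) / n
    idx <- seq_len(n) - 1L
    w <- ifelse(idx == 0 | (n %% 2 == 0 & idx == n / 2), 1,
                ifelse(idx < n / 2, 2, 0))
    expect_equal(sum(Mod(z)^2), n * sum((w * Mod(sp))^2), tolerance = 1e-9)
  }
})

test_that("degenerate constant rows are flagged with zero phase", {
  z <- analytic_row(rep(3.2, 16))
  expect_true(isTRUE(attr(z, "degenerate")))
  expect_equal(Arg(z), rep(0, 16), ignore_attr = TRUE)
  expect_error(analytic_row(c(1, 2, NA, 4)), "finite")
  expect_error(analytic_row(1:3), "length")
})

test_that("unwrapping lifts single jumps and leaves smooth ramps alone", {
  expect_equal(unwrap_phase(c(0, 2.0, -2.2)), c(0, 2.0, -2.2 + 2 * pi))
  smooth <- c(0, 0.5, 1.0, 1.5)
  expect_identical(unwrap_phase(smooth)[1], smooth[1])
  expect_equal(unwrap_phase(smooth), smooth)
  expect_error(unwrap_phase(c(0, Inf)), "finite")
})

test_that("unwrapping matches the literal pseudocode oracle bit-for-bit", {
  set.seed(42)
  for (trial in 1:2000) {
    n <- sample(4:32, 1)
    w <- stats::runif(n, -pi, pi)
    got <- unwrap_phase(w)
    expect_identical(got, oracle_unwrap(w))
  }
})

test_that("wrap then unwrap recovers smooth ramps up to a 2*pi constant", {
  set.seed(1)
  for (trial in 1:200) {
    n <- 128
    phi <- cumsum(stats::runif(n, -2.5, 2.5))
    wrapped <- Arg(complex(argument = phi))
    rec <- unwrap_phase(wrapped)
    offs <- (rec - phi) / (2 * pi)
    expect_equal(offs, rep(round(offs[1]), n), tolerance = 1e-9)
    # unwrapped minus wrapped input is always an integer turn count
    turns <- (rec - wrapped) / (2 * pi)
    expect_equal(turns, round(turns), tolerance = 1e-9)
    expect_lt(max(abs(diff(rec))), pi + 1e-12)
  }
})

test_that("instantaneous frequency of a pure tone is the tone frequency", {
  ifi <- instantaneous_frequency_image(tone_image(64, 256, 8))
  expect_s3_class(ifi, "insfreq_image")
  expect_equal(ifi$fs, 256)
  interior <- ifi$pixels[, 5:252]
  expect_lt(max(abs(interior - 8)) / 8, 0.01)
  # doubling the tone frequency doubles the response
  ifi2 <- instantaneous_frequency_image(tone_image(64, 256, 16))
  expect_equal(ifi2$pixels[, 5:252], 2 * interior, tolerance = 1e-6)
})

test_that("a localized carrier-phase step integrates to its height", {
  # a smooth (few-pixel) phase step keeps the signal narrowband, so the
  # analytic phase follows it; a hard step scatters energy row-wide
  n <- 256
  x <- 0:(n - 1)
  delta <- 0.8
  phs <- delta / (1 + exp(-(x - 128) / 2))
  row <- cos(2 * pi * 12 * x / n + phs)
  ifi <- instantaneous_frequency_image(matrix(row, 8, n, byrow = TRUE))
  v <- ifi$pixels[1, ]
  # excursion is localized near the step
  expect_gt(max(abs(v[120:136] - 12)), 1)
  expect_lt(max(abs(v[30:80] - 12)), 0.5)
  # windowed trapezoid integral around the step recovers its height on
  # top of the carrier's contribution
  win <- 100:156
  integral <- (sum(v[win]) - (v[win[1]] + v[win[length(win)]]) / 2) *
    2 * pi / ifi$fs
  carrier_part <- 2 * pi * 12 * (length(win) - 1) / n
  expect_equal(integral - carrier_part, delta, tolerance = 0.05)
})

test_that("rows are processed independently and integrals are exact", {
  set.seed(9)
  m <- matrix(stats::rnorm(32 * 64), 32, 64) +
    tone_image(32, 64, 5)
  ifi <- instantaneous_frequency_image(m)
  # permuting rows permutes the output rows identically
  perm <- sample(32)
  ifp <- instantaneous_frequency_image(m[perm, ])
  expect_identical(ifp$pixels, ifi$pixels[perm, ])
  # trapezoid-consistent integral equals the unwrapped phase span
  for (r in c(1, 17)) {
    phi <- unwrap_phase(Arg(analytic_row(m[r, ])))
    v <- ifi$pixels[r, ]
    lhs <- (sum(v) - (v[1] + v[64]) / 2) * 2 * pi / ifi$fs
    rhs <- phi[64] - phi[1]
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("degenerate rows propagate into the row mask", {
  m <- tone_image(8, 64, 4)
  m[3, ] <- 7
  ifi <- instantaneous_frequency_image(m)
  expect_identical(which(ifi$row_mask), 3L)
  expect_equal(ifi$pixels[3, ], rep(0, 64))
})

test_that("end-to-end IF of a phantom tracks the phase x-derivative", {
  # full-support smooth differential phase, within the carrier pull-in
  # range, so the tracking term dominates the leakage ripple
  nr <- nc <- 256L
  g <- test_geometry(c(nr, nc))
  y <- matrix(0:(nr - 1), nr, nc)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  phs <- 0.7 * sin(2 * pi * 3 * x / nc) * cos(2 * pi * 2 * y / nr)
  sp <- phantom_spec(matrix(1, nr, nc), matrix(0.6, nr, nc), phs, seed = 1)
  ifi <- instantaneous_frequency_image(render_raw(sp, g, "sample_grid"))
  dphs <- t(apply(phs, 1, gridpcxi:::row_gradient))
  i <- 15:242
  a <- as.vector(ifi$pixels[i, i])
  b <- as.vector(dphs[i, i])
  expect_gt(stats::cor(a - mean(a), b), 0.95)
  # the interior level is the carrier frequency in cycles per line
  # (median: the one-sided edge columns carry leakage spikes)
  expect_equal(stats::median(ifi$pixels[i, i]), carrier_frequency(g) * nc,
               tolerance = 0.01)
})
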