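test_that("carrier location finds the geometric frequency", {
  g <- test_geometry(c(256L, 256L))
  sp <- make_fish_like_phantom(g, seed = 1)
  raw <- render_raw(sp, g, "grid_only")
  f <- locate_carrier(raw)
  expect_lt(abs(f["fx"] - carrier_frequency(g)), 1 / 256)
  expect_lt(abs(f["fy"]), 1 / 256)
  # a constant image has no carrier
  expect_error(locate_carrier(matrix(5, 64, 64)), "no carrier found")
  # rotating the image by 90 degrees swaps the frequency components
  ft <- locate_carrier(t(raw$pixels))
  expect_lt(abs(ft["fy"] - carrier_frequency(g)), 1 / 256)
  expect_lt(abs(ft["fx"]), 1 / 256)
})

test_that("harmonic extraction recovers the closed form of a pure carrier", {
  nr <- nc <- 256L
  B <- 1200; V0 <- 0.5; f0 <- 20 / nc   # integer-bin carrier
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  img <- B * (1 + V0 * cos(2 * pi * f0 * x))
  h <- extract_harmonics(img, c(f0, 0), band_halfwidth = f0 / 2)
  interior <- as.matrix(expand.grid(20:236, 20:236))
  expect_equal(max(abs(Mod(h$zeroth[interior]) - B)), 0, tolerance = 1e-6)
  expect_equal(max(abs(Mod(h$first[interior]) - B * V0 / 2)), 0,
               tolerance = 1e-6)
  expect_lt(max(abs(Arg(h$first[interior]))), 1e-6)
  # a constant image has no first-harmonic energy
  h0 <- extract_harmonics(matrix(B, nr, nc), c(f0, 0), f0 / 2)
  expect_lt(max(Mod(h0$first)), 1e-8)
  # overlapping bands are rejected
  expect_error(extract_harmonics(img, c(f0, 0), 0.6 * f0), "band_halfwidth")
})

test_that("demodulation satisfies the harmonic-ratio arithmetic", {
  g <- test_geometry(c(128L, 128L))
  sp <- make_fish_like_phantom(g, seed = 1)
  raw <- render_raw(sp, g, "grid_only")
  f0 <- c(carrier_frequency(g), 0)
  h <- extract_harmonics(raw, f0)
  ci <- demodulate(h, h)
  # identical sample: unit absorption and scattering, zero phase
  expect_equal(max(abs(ci$absorption[ci$valid] - 1)), 0)
  expect_equal(max(abs(ci$scattering[ci$valid] - 1)), 0)
  expect_equal(max(abs(ci$pcxi[ci$valid])), 0)
  # modulus/angle arithmetic at a pixel: ratio 3+4i -> scattering 5,
  # pcxi = atan2(4, 3)
  expect_equal(Mod(3 + 4i), 5)
  expect_equal(atan2(4, 3), 0.9272952, tolerance = 1e-7)
  # scattering * exp(i * pcxi) reconstructs the complex ratio
  sp2 <- make_fish_like_phantom(g, seed = 9)
  raw2 <- render_raw(sp2, g, "sample_grid")
  ci2 <- demodulate(extract_harmonics(raw2, f0), h)
  rec <- ci2$scattering * exp(1i * ci2$pcxi)
  expect_lt(max(Mod(rec[ci2$valid] - ci2$complex_ratio[ci2$valid])), 1e-12)
  expect_true(all(ci2$pcxi > -pi & ci2$pcxi <= pi))
})

test_that("noise-free disk phantom parameters are recovered", {
  g <- test_geometry(c(512L, 512L))
  dp <- disk_phantom()
  raw_g <- render_raw(dp$spec, g, "grid_only")
  raw_sg <- render_raw(dp$spec, g, "sample_grid")
  f0 <- carrier_frequency(g)
  bh <- 0.5 * f0                      # maximal non-overlapping band
  ci <- demodulate(extract_harmonics(raw_sg, c(f0, 0), bh),
                   extract_harmonics(raw_g, c(f0, 0), bh))
  interior <- dp$dist <= dp$radius - 2 * carrier_period_px(g)
  expect_lt(stats::median(abs(ci$absorption[interior] - 0.5)), 0.02)
  expect_lt(stats::median(abs(ci$pcxi[interior] - 0.3)), 0.02)
  expect_lt(stats::median(abs(ci$scattering[interior] - 1)), 0.02)
})

test_that("smooth transmittance round-trips within 2% relative error", {
  nr <- nc <- 256L
  g <- test_geometry(c(nr, nc))
  y <- matrix(0:(nr - 1), nr, nc)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  T_ <- 1 - 0.5 * exp(-((x - 128)^2 + (y - 128)^2) / (2 * 40^2))
  sp <- phantom_spec(T_, matrix(0.6, nr, nc), 0 * T_, seed = 1)
  f0 <- carrier_frequency(g)
  ci <- demodulate(
    extract_harmonics(render_raw(sp, g, "sample_grid"), c(f0, 0), 0.5 * f0),
    extract_harmonics(render_raw(sp, g, "grid_only"), c(f0, 0), 0.5 * f0))
  border <- 2 * carrier_period_px(g)
  i <- ceiling(border):floor(nc - border)
  expect_lt(stats::median(abs(ci$absorption[i, i] / T_[i, i] - 1)), 0.02)
})

test_that("phase injections wrap to the principal value", {
  g <- test_geometry(c(256L, 256L))
  nr <- nc <- 256L
  flat <- matrix(1, nr, nc)
  phs <- matrix(pi + 0.1, nr, nc)     # wraps to -pi + 0.1
  spg <- phantom_spec(flat, 0.6 * flat, 0 * flat, seed = 1)
  sps <- phantom_spec(flat, 0.6 * flat, phs, seed = 1)
  f0 <- carrier_frequency(g)
  ci <- demodulate(
    extract_harmonics(render_raw(sps, g, "sample_grid"), c(f0, 0)),
    extract_harmonics(render_raw(spg, g, "grid_only"), c(f0, 0)))
  interior <- as.matrix(expand.grid(80:176, 80:176))
  expect_equal(stats::median(ci$pcxi[interior]), -pi + 0.1, tolerance = 1e-3)
})

test_that("divisor floors flag pixels instead of erroring", {
  nr <- nc <- 64L
  f0 <- 8 / nc
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  img <- 100 * (1 + 0.5 * cos(2 * pi * f0 * x))
  h <- extract_harmonics(img, c(f0, 0), f0 / 2)
  dead <- h
  dead$first <- h$first * 0           # kill the divisor harmonic
  ci <- demodulate(h, dead)
  expect_false(any(ci$valid))
  expect_true(all(ci$scattering == 0) && all(ci$pcxi == 0))
})
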