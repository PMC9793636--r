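test_that("parameter validation matches the documented domains", {
  expect_error(bitonic_params(parameter = 4), "odd")
  expect_error(bitonic_params(centile = 0), "centile")
  expect_error(bitonic_params(centile = 60), "centile")
  expect_error(bitonic_params(anisotropy_max = 0.5), "anisotropy")
  expect_s3_class(bitonic_params("simple", 9), "bitonic_params")
  expect_error(rank_erode(matrix(0, 4, 4), matrix(FALSE, 3, 3)), "non-empty")
})

test_that("rank morphology removes impulses and keeps ramps and order", {
  foot <- gridpcxi:::disc_footprint(3)
  imp <- matrix(0, 32, 32); imp[16, 16] <- 1
  out <- rank_open_close(imp, foot, 10)
  expect_lt(max(abs(out)), 0.05)
  # monotone ramps pass through untouched in the interior
  ramp <- matrix(rep(seq(0, 1, length.out = 32), each = 32), 32, 32)
  r <- rank_open_close(ramp, foot, 10)
  expect_equal(as.matrix(r)[4:29, 4:29], ramp[4:29, 4:29], tolerance = 1e-12)
  # constant images are fixed points
  cst <- matrix(2.5, 16, 16)
  expect_equal(rank_open_close(cst, foot, 25), cst, ignore_attr = TRUE)
  # erosion never exceeds dilation
  set.seed(8)
  img <- matrix(stats::rnorm(24 * 24), 24, 24)
  for (cen in c(5, 25, 50))
    expect_true(all(rank_erode(img, foot, cen) <=
                    rank_dilate(img, foot, cen)))
  # centile 50 collapses both rank operators to the median
  expect_equal(rank_erode(img, foot, 50), rank_dilate(img, foot, 50))
})

test_that("rank filters agree with the brute-force oracle", {
  set.seed(3)
  img <- matrix(stats::rnorm(16 * 16), 16, 16)
  foot <- gridpcxi:::disc_footprint(5)
  for (q in c(0.1, 0.5, 0.9))
    expect_equal(gridpcxi:::cpp_rank_filter(img, foot, q),
                 oracle_rank_filter(img, foot, q), tolerance = 1e-12)
})

test_that("residual smoothing is anchored and variance-reducing", {
  set.seed(4)
  img <- matrix(stats::rnorm(32 * 32), 32, 32)
  # zero residual: output equals the image
  expect_equal(gaussian_residual_smooth(img, img, 2), img)
  # white-noise residual shrinks by the (weighted) kernel energy; the
  # brute-force convolution of the same scheme is the oracle
  inter <- matrix(0, 32, 32)
  out <- gaussian_residual_smooth(img, inter, 2)
  res <- img - inter
  s <- stats::mad(res)
  w <- 1 / (1 + (res / (3 * s))^2)
  oracle <- inter + oracle_gauss_conv(w * res, 2) /
    pmax(oracle_gauss_conv(w, 2), 1e-12)
  expect_equal(out, oracle, tolerance = 1e-9)
  expect_lt(stats::var(as.vector(out)), 0.25 * stats::var(as.vector(img)))
  # the plain (unweighted) scheme matches the closed-form kernel energy
  out_plain <- gaussian_residual_smooth(img, inter, 2, robust_k = Inf)
  k <- gridpcxi:::gaussian_kernel(2)
  energy <- sum(outer(k, k)^2)
  expect_equal(stats::var(as.vector(out_plain)) /
                 stats::var(as.vector(img)), energy, tolerance = 0.35)
})

test_that("a step edge survives the simple bitonic filter", {
  step <- matrix(rep(c(rep(0, 16), rep(1, 16)), each = 32), 32, 32)
  out <- bitonic_filter(step, bitonic_params("simple", 5))
  # 10-90% rise distance stays within one pixel of the original
  rise <- function(v) {
    i10 <- which(v >= 0.1)[1]; i90 <- which(v >= 0.9)[1]
    i90 - i10
  }
  expect_lte(abs(rise(out[16, ]) - rise(step[16, ])), 1)
})

test_that("structure masks orient along image structure", {
  # constant image: zero tensor, circular footprints
  mf <- structure_masks(matrix(1, 32, 32), 3)
  expect_equal(mf$semi_minor, mf$semi_major)
  # vertical stripes: gradient along x, footprints elongated along y
  x <- matrix(0:63, 64, 64, byrow = TRUE)
  stripes <- cos(2 * pi * x / 8)
  mf2 <- structure_masks(stripes, 3, prefilter = FALSE)
  i <- 20:44
  expect_true(all(mf2$semi_minor[i, i] < mf2$semi_major[i, i]))
  # orientation = gradient angle = x axis, within 5 degrees
  expect_lt(max(abs(mf2$orientation[i, i])), 5 * pi / 180)
  # rotating the image by 90 degrees rotates orientations by 90 degrees
  mf3 <- structure_masks(t(stripes), 3, prefilter = FALSE)
  ang <- abs(abs(mf3$orientation[i, i]) - pi / 2)
  expect_lt(max(ang), 5 * pi / 180)
  expect_error(structure_masks(matrix(c(1, NA, 1, 1), 2, 2), 3), "finite")
})

test_that("all variants fix constants and commute with grey shifts", {
  set.seed(5)
  img <- matrix(stats::rnorm(48 * 48), 48, 48)
  for (v in c("simple", "structvar", "multires_structvar")) {
    p <- bitonic_params(v, 3)
    cst <- matrix(7.25, 48, 48)
    expect_equal(bitonic_filter(cst, p), cst, tolerance = 1e-12)
    shifted <- bitonic_filter(img + 11.5, p)
    expect_equal(shifted, bitonic_filter(img, p) + 11.5, tolerance = 1e-9)
  }
})

test_that("the simple bitonic filter matches its brute-force oracle", {
  set.seed(6)
  for (trial in 1:3) {
    img <- matrix(stats::rnorm(16 * 16), 16, 16)
    got <- bitonic_filter(img, bitonic_params("simple", 3))
    expect_equal(got, oracle_simple_bitonic(img, 3), tolerance = 1e-9)
  }
})

test_that("multires structvar restores salt-and-pepper corruption", {
  scene <- standard_scene()
  cr <- sp_corrupt(scene, p = 0.02, seed = 11)
  rest <- bitonic_filter(cr$image, bitonic_params("multires_structvar", 7))
  relerr <- abs(rest[cr$corrupted] - scene[cr$corrupted]) /
    abs(scene[cr$corrupted])
  expect_gte(mean(relerr <= 0.05), 0.99)
})

test_that("the filter family ranks as selected: multires > simple", {
  fx <- standard_noisy_scene()
  sc <- function(m) scale_unit(m, fx$clean)
  ref <- sc(fx$clean)
  s_m7 <- img_ssim(ref, sc(bitonic_filter(fx$noisy,
                                          bitonic_params("multires_structvar",
                                                         7))))
  s_s7 <- img_ssim(ref, sc(bitonic_filter(fx$noisy,
                                          bitonic_params("simple", 7))))
  s_s9 <- img_ssim(ref, sc(bitonic_filter(fx$noisy,
                                          bitonic_params("simple", 9))))
  expect_gt(s_m7, s_s7)
  expect_gt(s_m7, s_s9)
})

test_that("the parameter sweep produces the full comparison grid", {
  set.seed(7)
  img <- standard_scene(c(64L, 64L)) +
    matrix(stats::rnorm(64 * 64, 0, 20), 64, 64)
  grid <- list()
  for (v in c("simple", "structvar", "multires_structvar"))
    for (p in c(1, 3, 5, 7, 9))
      grid[[paste(v, p)]] <- bitonic_filter(img, bitonic_params(v, p))
  expect_length(grid, 15L)
  expect_true(all(vapply(grid, function(m) all(is.finite(m)), logical(1))))
  # parameter 1 is the identity-diameter mask: morphology is a no-op and
  # only the residual smoother acts, so output stays closest to input
  d <- vapply(grid[paste("simple", c(1, 5, 9))],
              function(m) mean((m - img)^2), numeric(1))
  expect_true(all(diff(d) > 0))
})
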