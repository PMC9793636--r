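# Shared fixtures, all generated in code under fixed seeds.

test_geometry <- function(shape = c(256L, 256L))
  acquisition_geometry(detector_shape = shape)

# the standard piecewise-smooth scene: base intensity x transmittance of
# the fish-like phantom (what an ideal absorption image of the scene
# looks like); ground truth for the denoising criteria
standard_scene <- function(shape = c(256L, 256L), seed = 3L,
                           base_intensity = 1000) {
  g <- test_geometry(shape)
  ph <- make_fish_like_phantom(g, seed = seed)
  base_intensity * ph$transmittance
}

# salt-and-pepper corruption at probability p; returns the corrupted
# image and the corrupted indices
sp_corrupt <- function(img, p = 0.02, seed = 11L) {
  set.seed(seed)
  hit <- which(stats::runif(length(img)) < p)
  salt <- stats::runif(length(hit)) < 0.5
  out <- img
  out[hit[salt]] <- max(img)
  out[hit[!salt]] <- 0
  list(image = out, corrupted = hit)
}

# the standard noisy-phantom fixture: scene + periodic beat + Gaussian
# noise + salt-and-pepper, as the step-2 filters receive it
standard_noisy_scene <- function(shape = c(256L, 256L), seed = 12L) {
  scene <- standard_scene(shape)
  nr <- shape[1]; nc <- shape[2]
  y <- matrix(0:(nr - 1), nr, nc)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  set.seed(seed)
  noisy <- scene + 30 * cos(2 * pi * (0.027 * x + 0.01 * y)) +
    matrix(stats::rnorm(nr * nc, 0, 25), nr, nc)
  hit <- which(stats::runif(nr * nc) < 0.02)
  salt <- stats::runif(length(hit)) < 0.5
  noisy[hit[salt]] <- max(scene)
  noisy[hit[!salt]] <- 0
  list(clean = scene, noisy = noisy)
}

# disk phantom for demodulation recovery: T = 0.5 and phi_s = 0.3 rad
# inside a centred disk, visibility constant
disk_phantom <- function(shape = c(512L, 512L), radius = 150,
                         T_in = 0.5, phs_in = 0.3) {
  nr <- shape[1]; nc <- shape[2]
  y <- matrix(0:(nr - 1), nr, nc)
  x <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  d <- sqrt((x - (nc - 1) / 2)^2 + (y - (nr - 1) / 2)^2)
  T_ <- matrix(1, nr, nc); T_[d <= radius] <- T_in
  phs <- matrix(0, nr, nc); phs[d <= radius] <- phs_in
  V <- matrix(0.6, nr, nc)
  list(spec = phantom_spec(T_, V, phs, seed = 1L),
       inside = d <= radius, dist = d, radius = radius)
}

# rows of a pure cosine tone of integer frequency k
tone_image <- function(nr = 64L, nc = 256L, k = 8) {
  x <- 0:(nc - 1)
  matrix(rep(cos(2 * pi * k * x / nc), each = nr), nr, nc)
}
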