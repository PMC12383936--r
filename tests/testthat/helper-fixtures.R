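# Shared fixtures: small geometries and phantoms built in code.

fan_geometry <- function(theta0 = 0.5, r_min = 40, r_max = 145,
                         apex = c(-20, 63.5), kind = "curvilinear") {
  fov_geometry(kind, apex = apex, theta0 = theta0, r_min = r_min, r_max = r_max)
}

linear_geometry <- function(h = 128, w = 128) {
  fov_geometry("linear", apex = c(0, (w - 1) / 2), theta0 = 0,
               r_min = 0, r_max = h - 1, width = w - 1)
}

fan_phantom <- function(seed = 1, label = "A", shape = c(128, 128), ...) {
  g <- fan_geometry()
  with_seed(seed, generate_phantom(phantom_spec(g, label = label, ...),
                                   shape = shape))
}

linear_phantom <- function(seed = 1, label = "A", shape = c(64, 64), ...) {
  g <- linear_geometry(shape[1], shape[2])
  with_seed(seed, generate_phantom(phantom_spec(g, label = label, ...),
                                   shape = shape))
}

# small all-in-FOV image with uniform noise pixels
noise_image <- function(seed = 1, h = 48, w = 48) {
  us_image(with_seed(seed, matrix(runif(h * w), h, w)))
}

# a smooth band-limited test image (gaussian-filtered noise)
smooth_matrix <- function(seed = 1, h = 96, w = 96, sigma = 3) {
  x <- with_seed(seed, matrix(runif(h * w), h, w))
  x <- gaussian_filter(x, sigma)
  (x - min(x)) / (max(x) - min(x))
}

expect_in_range01 <- function(image) {
  expect_true(all(image$pixels >= 0 & image$pixels <= 1))
}

expect_masked_zero <- function(image) {
  expect_true(all(image$pixels[image$mask == 0] == 0))
}
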