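# Ultrasound-specific operators B00-B11: geometry bookkeeping, closed-form
# intensity examples, and Monte-Carlo checks of the noise models.

test_that("probe type change toggles FOV kinds with consistent masks", {
  lin <- linear_phantom(1, shape = c(96, 96))
  fan <- probe_type_change(lin, draw = list(theta0 = 0.5))
  expect_equal(fan$geometry$kind, "curvilinear")
  nzr <- which(rowSums(fan$mask) > 0)
  expect_gt(sum(fan$mask[max(nzr) - 3, ]), sum(fan$mask[min(nzr) + 3, ]))

  curv <- fan_phantom(2)
  back <- probe_type_change(curv, draw = list(theta0 = 0.5))
  expect_equal(back$geometry$kind, "linear")
  expect_true(all(back$mask == 1))

  # applying twice returns the original kind
  twice <- probe_type_change(fan, draw = list(theta0 = 0.5))
  expect_equal(twice$geometry$kind, "linear")

  no_geom <- noise_image(1)
  no_geom$geometry <- NULL
  expect_error(probe_type_change(no_geom), "geometry")
})

test_that("convexity change rescales theta0 and preserves intensity", {
  ph <- fan_phantom(3)
  same <- convexity_change(ph, draw = list(m = 1))
  expect_lt(mean(abs(same$pixels[ph$mask == 1 & same$mask == 1] -
                     ph$pixels[ph$mask == 1 & same$mask == 1])), 0.01)

  wider <- convexity_change(ph, draw = list(m = 1.2))
  sep0 <- diff(bottom_corners(ph$geometry)[, 2])
  sep1 <- diff(bottom_corners(wider$geometry)[, 2])
  expect_gt(sep1, sep0)
  expect_equal(wider$geometry$theta0, 1.2 * ph$geometry$theta0)

  m0 <- mean(ph$pixels[ph$mask == 1])
  m1 <- mean(wider$pixels[wider$mask == 1])
  expect_lt(abs(m1 - m0) / m0, 0.05)

  lin <- linear_phantom(4)
  expect_identical(convexity_change(lin, draw = list(m = 1.2)), lin)
})

test_that("wavelet denoising reduces noise and has exact limits", {
  cst <- us_image(matrix(0.5, 64, 64))
  expect_equal(wavelet_denoise(cst)$pixels, cst$pixels, tolerance = 1e-10)

  clean <- us_image(smooth_matrix(5, 64, 64))
  noisy <- us_image(pmin(pmax(matrix(clean$pixels +
                                       with_seed(6, rnorm(64 * 64, 0, 0.1)),
                                     64, 64), 0), 1))
  den <- wavelet_denoise(noisy)
  mse_before <- mean((noisy$pixels - clean$pixels)^2)
  mse_after <- mean((den$pixels - clean$pixels)^2)
  expect_lt(mse_after, mse_before)

  # retention covering every band reduces to (near) identity
  img <- noise_image(7, 32, 32)
  all_kept <- wavelet_denoise(img, levels = 3, alpha = 0, m = 32 * 32 * 10)
  expect_lt(max(abs(all_kept$pixels - img$pixels)), 1e-6)

  expect_error(wavelet_denoise(noise_image(1, 4, 4), levels = 3), "2\\^levels")
})

test_that("CLAHE maps constants to constants and expands low contrast", {
  ph <- fan_phantom(8)
  cst <- ph
  cst$pixels <- 0.5 * cst$mask
  out <- clahe_enhance(cst, draw = list(clip = 2))
  vals <- out$pixels[out$mask == 1]
  expect_lt(diff(range(vals)), 1e-6)
  expect_masked_zero(out)

  low <- ph
  low$pixels <- (0.45 + 0.1 * ph$pixels) * ph$mask   # squeeze the dynamic range
  enh <- clahe_enhance(low, draw = list(clip = 3))
  expect_gt(sd(enh$pixels[enh$mask == 1]), sd(low$pixels[low$mask == 1]))
})

test_that("gamma correction matches the closed form and preserves order", {
  img <- us_image(matrix(c(64, 32, 128, 250) / 255, 2, 2))
  expect_identical(gamma_correct(img, draw = list(gamma = 1))$pixels, img$pixels)

  sq <- gamma_correct(img, draw = list(gamma = 2))
  expect_equal(sq$pixels[1, 1], (64 / 255)^2)
  # quantised back to the 8-bit grid this is 16/255
  expect_equal(floor(sq$pixels[1, 1] * 255 + 0.5), 16)

  rnd <- noise_image(9, 16, 16)
  for (g in c(0.5, 2.3)) {
    out <- gamma_correct(rnd, draw = list(gamma = g))
    expect_identical(order(out$pixels), order(rnd$pixels))
  }
})

test_that("brightness/contrast applies clip(a*x + b) inside the FOV", {
  img <- us_image(matrix(c(100, 200, 10, 0) / 255, 2, 2))
  expect_identical(brightness_contrast(img, draw = list(a = 1, b = 0))$pixels,
                   img$pixels)
  out <- brightness_contrast(img, draw = list(a = 2, b = 10 / 255))
  expect_equal(out$pixels[1, 1], 210 / 255)
  out2 <- brightness_contrast(img, draw = list(a = 2, b = 0))
  expect_equal(out2$pixels[2, 1], 1)   # 400/255 clips
})

test_that("depth change preserves the FOV exactly and maps depths by 1/z", {
  lin <- linear_phantom(10, shape = c(100, 60))
  same <- depth_change(lin, draw = list(z = 1))
  expect_equal(same$pixels, lin$pixels, tolerance = 1e-12)

  for (z in c(0.9, 1.25)) {
    out <- depth_change(lin, draw = list(z = z))
    expect_identical(out$mask, lin$mask)
    expect_identical(out$geometry, lin$geometry)
  }

  # a bright band at depth d lands at d/z
  px <- matrix(0.1, 100, 60); px[60:62, ] <- 1
  band <- us_image(px, geometry = linear_geometry(100, 60))
  moved <- depth_change(band, draw = list(z = 1.25))
  peak <- which.max(rowMeans(moved$pixels))
  expect_lt(abs(peak - 61 / 1.25), 1.6)

  fanp <- fan_phantom(11)
  outf <- depth_change(fanp, draw = list(z = 1.1))
  expect_identical(outf$mask, fanp$mask)
  expect_masked_zero(outf)

  no_geom <- noise_image(1); no_geom$geometry <- NULL
  expect_error(depth_change(no_geom), "geometry")
})

test_that("speckle noise is multiplicative with the expected smoothed scale", {
  img <- us_image(matrix(0.5, 256, 256))
  expect_identical(speckle_noise(img, noise_params(speckle_sigma = 0))$pixels,
                   img$pixels)
  zero <- us_image(matrix(0, 32, 32))
  expect_identical(with_seed(1, speckle_noise(zero))$pixels, zero$pixels)

  out <- speckle_noise(img, noise_params(speckle_sigma = 0.25),
                       draw = list(field_seed = 123))
  rel <- (out$pixels - img$pixels) / img$pixels
  # smoothing attenuates the field std by sqrt(sum(k^2)) of the 2-D kernel
  k1 <- exp(-(-3:3)^2 / 2); k1 <- k1 / sum(k1)
  atten <- sqrt(sum(outer(k1, k1)^2))
  expect_lt(abs(sd(rel) - 0.25 * atten) / (0.25 * atten), 0.15)
})

test_that("gaussian noise std matches its parameter on a constant image", {
  img <- us_image(matrix(0.5, 256, 256))
  expect_identical(gaussian_noise(img, noise_params(gauss_sigma = 0))$pixels,
                   img$pixels)
  out <- gaussian_noise(img, draw = list(field_seed = 77))
  rel <- out$pixels / img$pixels - 1
  expect_lt(abs(sd(rel) - 0.1), 0.01)
  zero <- us_image(matrix(0, 16, 16))
  expect_identical(with_seed(2, gaussian_noise(zero))$pixels, zero$pixels)
})

test_that("salt and pepper hits a binomially plausible count of in-FOV pixels", {
  img <- us_image(matrix(0.5, 100, 100))
  expect_identical(salt_pepper(img, noise_params(sp_rate = 0))$pixels, img$pixels)

  out <- salt_pepper(img, noise_params(sp_rate = 0.1), draw = list(field_seed = 5))
  changed <- out$pixels != img$pixels
  expect_gte(sum(changed), qbinom(0.0005, 10000, 0.1))
  expect_lte(sum(changed), qbinom(0.9995, 10000, 0.1))
  expect_true(all(out$pixels[changed] %in% c(0, 1)))

  half <- us_image(matrix(0.5, 50, 50),
                   mask = matrix(rep(c(1, 0), each = 25 * 50), 50, 50))
  outh <- salt_pepper(half, noise_params(sp_rate = 0.1), draw = list(field_seed = 6))
  expect_true(all(outh$pixels[half$mask == 0] == 0))   # out-of-FOV untouched/re-masked
})

test_that("rotation and shift has exact identity and near-inverse behaviour", {
  img <- noise_image(12, 48, 48)
  ident <- rotate_shift(img, draw = list(angle = 0, dr = 0, dc = 0))
  expect_equal(ident$pixels, img$pixels, tolerance = 1e-12)

  sm <- us_image(smooth_matrix(13, 64, 64))
  fwd <- rotate_shift(sm, draw = list(angle = 10, dr = 0, dc = 0))
  back <- rotate_shift(fwd, draw = list(angle = -10, dr = 0, dc = 0))
  inner <- 17:48
  expect_lt(mean(abs(back$pixels[inner, inner] - sm$pixels[inner, inner])), 0.02)

  px <- matrix(0, 32, 32); px[16, 10] <- 1
  dot <- us_image(px)
  shifted <- rotate_shift(dot, draw = list(angle = 0, dr = 0, dc = 10))
  expect_equal(shifted$pixels[16, 20], 1)
})
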