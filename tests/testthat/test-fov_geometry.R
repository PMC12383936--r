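# FOV model: masking, cropping, mask estimation, geometry fitting, and the
# scan-conversion primitives.

test_that("apply_mask zeroes exactly the out-of-FOV pixels", {
  img <- noise_image(1, 16, 16)
  expect_identical(apply_mask(img)$pixels, img$pixels)  # identity mask

  m <- matrix(0, 16, 16); m[6, 6] <- 1
  sparse <- us_image(matrix(runif(256), 16, 16), m)
  sparse$pixels[6, 6] <- 200 / 255
  out <- apply_mask(sparse)
  expect_equal(sum(out$pixels != 0), 1)
  expect_equal(out$pixels[6, 6], 200 / 255)

  ph <- fan_phantom(2, shape = c(64, 64))
  expect_equal(sum(apply_mask(ph)$pixels[ph$mask == 0]), 0)
})

test_that("apply_mask rejects shape mismatch and is idempotent", {
  img <- noise_image(1, 12, 12)
  img$mask <- matrix(1, 10, 12)
  expect_error(apply_mask(img), "shape")
  img2 <- fan_phantom(3, shape = c(64, 64))
  expect_identical(apply_mask(apply_mask(img2)), apply_mask(img2))
})

test_that("crop_to_fov returns the tight bounding box and is idempotent", {
  m <- matrix(0, 10, 10); m[3:8, 4:9] <- 1
  img <- us_image(matrix(runif(100), 10, 10), m)
  out <- crop_to_fov(img)
  expect_equal(dim(out$pixels), c(6, 6))

  full <- noise_image(2, 9, 9)
  expect_identical(crop_to_fov(full)$pixels, full$pixels)

  ph <- fan_phantom(4)
  expect_identical(crop_to_fov(crop_to_fov(ph)), crop_to_fov(ph))

  empty <- us_image(matrix(0, 5, 5), matrix(1, 5, 5))
  empty$mask <- matrix(0, 5, 5)
  expect_error(crop_to_fov(empty), "empty")
})

test_that("estimate_fov_mask recovers the rendered mask and picks the largest blob", {
  ph <- fan_phantom(5)
  masked <- apply_mask(ph)
  est <- estimate_fov_mask(masked$pixels)
  agree <- mean(est == ph$mask)
  expect_gt(agree, 0.99)

  expect_error(estimate_fov_mask(matrix(0, 20, 20)), "threshold")

  # two bright blobs: only the larger survives
  px <- matrix(0, 60, 60)
  px[10:32, 10:32] <- 0.8   # ~529 px
  px[45:51, 45:51] <- 0.8   # 49 px
  est2 <- estimate_fov_mask(px)
  expect_true(all(est2[10:32, 10:32] == 1))
  expect_true(all(est2[45:51, 45:51] == 0))
})

test_that("fit_fov_geometry classifies rectangles as linear", {
  m <- matrix(0, 40, 60); m[5:35, 10:50] <- 1
  g <- fit_fov_geometry(m)
  expect_equal(g$kind, "linear")
  expect_equal(g$theta0, 0)
  expect_equal(g$r_min, 4)   # 0-based rows
  expect_equal(g$r_max, 34)
})

test_that("render/fit round-trip recovers fan parameters within tolerance", {
  set.seed(42)
  for (i in 1:25) {
    theta0 <- runif(1, 0.3, 0.65)
    rho <- runif(1, 0.1, 0.3)
    r_max <- min(127 / (1 - rho), 63.5 / sin(theta0))
    g <- fov_geometry("curvilinear", apex = c(-rho * r_max, 63.5),
                      theta0 = theta0, r_min = rho * r_max, r_max = r_max)
    f <- fit_fov_geometry(render_fov_mask(g, c(128, 128)))
    expect_lt(abs(f$theta0 - theta0), 0.02)
    expect_lt(abs(f$r_max - r_max), 2)
    expect_equal(f$kind, "curvilinear")
  }
  # r_min near zero classifies as phased
  gp <- fov_geometry("phased", apex = c(0, 63.5), theta0 = 0.55,
                     r_min = 1, r_max = 120)
  expect_equal(fit_fov_geometry(render_fov_mask(gp, c(128, 128)))$kind, "phased")
})

test_that("render_fov_mask covers the full frame for a frame-sized rectangle and fans widen with depth", {
  gl <- linear_geometry(32, 40)
  expect_true(all(render_fov_mask(gl, c(32, 40)) == 1))

  g <- fan_geometry()
  m <- render_fov_mask(g, c(128, 128))
  top <- min(which(rowSums(m) > 0)); bottom <- max(which(rowSums(m) > 0))
  expect_gt(sum(m[bottom - 5, ]), sum(m[top + 5, ]))

  far <- fov_geometry("curvilinear", apex = c(-500, 63.5), theta0 = 0.4,
                      r_min = 100, r_max = 200)
  expect_error(render_fov_mask(far, c(64, 64)), "outside")
})

test_that("bottom-corner separation increases with theta0 at fixed r_max", {
  seps <- vapply(c(0.2, 0.4, 0.6, 0.8), function(t0) {
    g <- fov_geometry("curvilinear", apex = c(-20, 63.5), theta0 = t0,
                      r_min = 40, r_max = 145)
    bc <- bottom_corners(g)
    bc[2, 2] - bc[1, 2]
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})

test_that("scan conversion is the identity for linear FOVs and preserves constants", {
  beam <- with_seed(7, matrix(runif(32 * 40), 32, 40))
  gl <- fov_geometry("linear", apex = c(0, 19.5), theta0 = 0,
                     r_min = 0, r_max = 31, width = 39)
  out <- scan_convert(beam, gl, shape = c(32, 40))
  expect_equal(out$pixels, beam, tolerance = 1e-12)

  g <- fan_geometry()
  cst <- scan_convert(matrix(0.6, 105, 139), g, shape = c(128, 128))
  expect_true(all(abs(cst$pixels[cst$mask == 1] - 0.6) <= 1 / 255))
  expect_true(all(cst$pixels[cst$mask == 0] == 0))
})

test_that("scan_convert / inverse_scan_convert round-trip on smooth images", {
  set.seed(11)
  maes <- numeric(10)
  for (i in 1:10) {
    theta0 <- runif(1, 0.35, 0.6)
    rho <- runif(1, 0.12, 0.25)
    r_max <- min(127 / (1 - rho), 63.5 / sin(theta0))
    g <- fov_geometry("curvilinear", apex = c(-rho * r_max, 63.5),
                      theta0 = theta0, r_min = rho * r_max, r_max = r_max)
    n_r <- max(2, round(r_max - rho * r_max))
    n_c <- max(2, round(2 * r_max * sin(theta0)))
    beam <- resize_bilinear(smooth_matrix(i), n_r, n_c)
    img <- scan_convert(beam, g, shape = c(128, 128))
    back <- inverse_scan_convert(img)
    inner_r <- 4:(nrow(beam) - 4); inner_c <- 4:(ncol(beam) - 4)
    maes[i] <- mean(abs(back[inner_r, inner_c] - beam[inner_r, inner_c]))
  }
  expect_lt(max(maes), 0.02)
})

test_that("inverse scan conversion of a linear image is a logged no-op", {
  ph <- linear_phantom(3)
  expect_message(withr::with_options(list(lusaug.verbose = TRUE),
                                     inverse_scan_convert(ph)), "no-op")
  out <- inverse_scan_convert(ph)
  expect_equal(out, ph$pixels)
})

test_that("fit_fov_geometry errors on masks matching neither model", {
  # a cross: row widths jump discontinuously, so neither straight flanks
  # nor a sector boundary can fit
  cross <- matrix(0, 60, 60)
  cross[1:20, 26:35] <- 1; cross[21:40, 2:59] <- 1; cross[41:60, 26:35] <- 1
  expect_error(fit_fov_geometry(cross))
})
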