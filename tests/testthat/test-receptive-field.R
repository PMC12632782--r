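test_that("receptive-field weights are normalized, truncated Gaussians", {
  x <- offtalpha:::grid_coords(110, 6.6)
  rf <- gaussian_rf(50)
  w <- rf_weights(x, x, rf)
  expect_equal(sum(w), 1)
  r2 <- outer(x^2, x^2, "+")
  expect_true(all(w[r2 > 100^2] == 0))

  # center / 2-sigma ratio equals e^2 before truncation effects (grid-exact
  # points: center pixel vs a pixel at exactly 2 sigma along an axis)
  x1 <- offtalpha:::grid_coords(81, 2.5)   # contains 0 and 100 exactly
  w1 <- rf_weights(x1, x1, rf)
  c_idx <- which(x1 == 0)
  off_idx <- which(x1 == 100)
  expect_equal(w1[c_idx, c_idx] / w1[c_idx, off_idx], exp(2))

  expect_error(rf_weights(offtalpha:::grid_coords(20, 2), rf = rf),
               "aperture")
})

test_that("linear-equivalent intensity is the Gaussian-weighted mean", {
  rf <- gaussian_rf(50)
  n <- 110; dx <- 6.6
  uni <- stimulus_field(matrix(-0.3, n, n), dx = dx, dt = 1 / 60, dims = 2)
  expect_equal(linear_equivalent_intensity(uni, rf), -0.3)

  # odd-symmetric patch about the RF center integrates to zero
  x <- offtalpha:::grid_coords(n, dx)
  odd <- outer(rep(1, n), sign(x) * 0.5)
  expect_lt(abs(linear_equivalent_intensity(odd, rf, dx = dx)), 1e-14)

  # brute-force double-loop oracle on a seeded patch
  set.seed(42)
  patch <- matrix(stats::runif(n * n, -0.5, 0.5), n, n)
  w <- rf_weights(x, x, rf)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) acc <- acc + w[i, j] * patch[i, j]
  expect_equal(linear_equivalent_intensity(patch, rf, dx = dx), acc,
               tolerance = 1e-12)

  # linearity
  set.seed(7)
  p1 <- matrix(stats::rnorm(n * n, 0, 0.2), n, n)
  p2 <- matrix(stats::rnorm(n * n, 0, 0.2), n, n)
  lhs <- linear_equivalent_intensity(0.3 * p1 + 1.7 * p2, rf, dx = dx)
  rhs <- 0.3 * linear_equivalent_intensity(p1, rf, dx = dx) +
    1.7 * linear_equivalent_intensity(p2, rf, dx = dx)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("area-summation response follows the closed form", {
  p <- dog_area_params(Kc = 1, Ks = 0.5, sigma_c = 50, sigma_s = 150, R0 = 2)
  expect_equal(area_summation_response(0, p), 2)
  expect_equal(area_summation_response(1e6, p), 1 - 0.5 + 2)

  # independent hand evaluation of the printed formula
  p2 <- dog_area_params(1, 0.5, 50, 150, 0)
  hand <- 1 * (1 - exp(-50^2 / (2 * 50^2))) - 0.5 * (1 - exp(-50^2 / (2 * 150^2)))
  expect_equal(area_summation_response(50, p2), hand)

  # monotone increasing in r when the surround is absent
  p3 <- dog_area_params(1, 0, 40, 4000, 0)
  r <- seq(0, 120, by = 5)
  expect_true(all(diff(area_summation_response(r, p3)) > 0))

  expect_error(area_summation_response(-5, p), "non-negative")
  expect_error(dog_area_params(1, 0.5, 150, 50), "sigma_s > sigma_c")
})

test_that("area-summation fit recovers known parameters", {
  truth <- dog_area_params(Kc = 120, Ks = 45, sigma_c = 55, sigma_s = 180,
                           R0 = 8)
  radii <- c(5, 10, 20, 35, 50, 75, 100, 150, 200, 300, 400, 600)
  clean <- area_summation_response(radii, truth)

  fit <- fit_area_summation(radii, clean)
  expect_s3_class(fit, "dog_area_fit")
  expect_equal(unname(coef(fit)), unlist(truth[c("Kc", "Ks", "sigma_c",
                                                 "sigma_s", "R0")],
                                         use.names = FALSE),
               tolerance = 0.01)
  expect_equal(predict(fit), clean, tolerance = 1e-4)

  # 5% noise: center radius recovered within 15% (fixed seed Monte Carlo)
  set.seed(20)
  errs <- replicate(10, {
    noisy <- clean + stats::rnorm(length(radii), 0, 0.05 * diff(range(clean)))
    f <- fit_area_summation(radii, noisy)
    abs(coef(f)[["sigma_c"]] - truth$sigma_c) / truth$sigma_c
  })
  expect_lt(stats::median(errs), 0.15)

  expect_error(fit_area_summation(radii, rep(3, length(radii))),
               "not identifiable")
  expect_error(fit_area_summation(c(10, 50, 100), c(1, 2, 3)), "5 distinct")
})

test_that("area curves and fitted parameters round-trip through files", {
  truth <- dog_area_params(100, 30, 60, 200, 5)
  radii <- c(10, 25, 50, 100, 200, 400)
  resp <- area_summation_response(radii, truth)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".json")
  write_area_curve(radii, resp, f1)
  back <- read_area_curve(f1)
  expect_equal(back$radius_um, radii)
  expect_equal(back$response, resp)
  write_dog_params(truth, f2)
  expect_equal(read_dog_params(f2), truth)
})
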