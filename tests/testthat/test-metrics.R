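test_that("nonlinearity index follows the printed ratio", {
  expect_equal(nli(10, 10), 0)
  expect_equal(nli(10, 0), 1)
  expect_equal(nli(0, 10), -1)
  expect_equal(nli(6, 2), 0.5)
  expect_equal(nli(0, 0), 0)
  expect_error(nli(-1, 2), ">= 0")

  # antisymmetry and scale invariance
  set.seed(9)
  a <- stats::runif(50, 0, 20); b <- stats::runif(50, 0, 20)
  expect_equal(nli(a, b), -nli(b, a))
  expect_equal(nli(3.7 * a, 3.7 * b), nli(a, b))
  expect_true(all(abs(nli(a, b)) <= 1))
})

test_that("offset exclusion rule zeroes only doubly sub-threshold pairs", {
  r <- offset_nli_with_exclusion(2, 1)
  expect_equal(r$nli, 0)
  expect_true(r$excluded)

  r2 <- offset_nli_with_exclusion(5, 1)
  expect_equal(r2$nli, nli(5, 1))
  expect_equal(r2$nli, 2 / 3, tolerance = 1e-12)
  expect_false(r2$excluded)

  r3 <- offset_nli_with_exclusion(3, 3)   # at threshold: kept, equal -> 0
  expect_equal(r3$nli, 0)
  expect_false(r3$excluded)
})

test_that("paired-pulse ratio uses baseline-subtracted peaks", {
  dt <- 0.01
  tr <- rep(1, 300)
  tr[101:110] <- 1 + 2      # pulse 1 peak amplitude 2
  tr[201:210] <- 1 + 6      # pulse 2 peak amplitude 6
  ppr <- paired_pulse_ratio(tr, dt, c(0.9, 0.4), c(1.9, 0.4), c(0.2, 0.5))
  expect_equal(ppr, 3)
  # identical pulses give 1; global baseline shifts leave the ratio unchanged
  tr2 <- tr; tr2[201:210] <- 1 + 2
  expect_equal(paired_pulse_ratio(tr2, dt, c(0.9, 0.4), c(1.9, 0.4),
                                  c(0.2, 0.5)), 1)
  expect_equal(paired_pulse_ratio(tr + 5, dt, c(0.9, 0.4), c(1.9, 0.4),
                                  c(0.2, 0.5)), 3)
  expect_error(paired_pulse_ratio(rep(1, 300), dt, c(0.9, 0.4), c(1.9, 0.4),
                                  c(0.2, 0.5)), "undefined")
})

test_that("F2 amplitude extracts the frequency-doubled component", {
  dt <- 0.002
  t <- seq(0, 2 - dt, by = dt)
  at2f <- 1.7 * sin(2 * pi * 4 * t + 0.4)
  expect_equal(f2_amplitude(at2f, fundamental = 2, dt = dt), 1.7,
               tolerance = 1e-10)
  atf <- 3 * sin(2 * pi * 2 * t)
  expect_lt(f2_amplitude(atf, 2, dt), 1e-10)
  expect_equal(f2_amplitude(atf + at2f, 2, dt), 1.7, tolerance = 1e-10)

  # phase invariance over integer cycles
  shifted <- 1.7 * sin(2 * pi * 4 * t + 2.1)
  expect_equal(f2_amplitude(shifted, 2, dt), 1.7, tolerance = 1e-10)
  expect_error(f2_amplitude(at2f[1:100], 2, dt), "two full cycles")
})

test_that("E-I temporal offset estimators agree on constructed shifts", {
  dt <- 0.002
  cycle <- 0.5
  t <- seq(0, 4 - dt, by = dt)
  exc <- 1 + pmax(0, sin(2 * pi * t / cycle))^2

  expect_equal(unname(ei_temporal_offset(exc, exc, cycle, dt)), c(0, 0),
               tolerance = 1e-9)

  # inhibition = excitation shifted a quarter cycle earlier -> +0.25
  k <- round(cycle / 4 / dt)
  inh <- c(exc[-(1:k)], exc[1:k])
  off <- ei_temporal_offset(exc, inh, cycle, dt)
  expect_equal(unname(off["xcorr"]), 0.25, tolerance = 0.01)
  expect_equal(unname(off["com"]), 0.25, tolerance = 0.01)

  # half-cycle shift resolves to +0.5
  k2 <- round(cycle / 2 / dt)
  inh2 <- c(exc[-(1:k2)], exc[1:k2])
  off2 <- ei_temporal_offset(exc, inh2, cycle, dt)
  expect_equal(unname(off2["xcorr"]), 0.5, tolerance = 0.01)
  expect_equal(abs(unname(off2["com"])), 0.5, tolerance = 0.01)

  # both estimators agree on smooth asymmetric traces
  smooth_i <- 1 + pmax(0, sin(2 * pi * (t + 0.06) / cycle))^2
  o <- ei_temporal_offset(exc, smooth_i, cycle, dt)
  expect_lt(abs(o["xcorr"] - o["com"]), 0.02)

  expect_error(ei_temporal_offset(rep(1, 1000), exc[1:1000], cycle, dt),
               "flat")
})

test_that("charge transfer integrates baseline-subtracted deflections", {
  dt <- 0.001
  tr <- rep(2, 1000)
  expect_equal(charge_transfer(tr, dt, c(0.2, 0.4), c(0, 0.1)), 0)

  # rectangular deflection of height 3, duration 0.2 s
  tr2 <- tr; tr2[301:500] <- 5
  expect_equal(charge_transfer(tr2, dt, c(0.3, 0.2), 2), 3 * 0.2,
               tolerance = 0.01)

  # triangular deflection: area h*d/2
  tri <- tr
  ramp <- seq(0, 3, length.out = 100)
  tri[301:500] <- 2 + c(ramp, rev(ramp))
  expect_equal(charge_transfer(tri, dt, c(0.3, 0.2), 2), 3 * 0.2 / 2,
               tolerance = 0.01)
})

test_that("I/E ratio is a guarded quotient", {
  expect_equal(ie_ratio(2, 2), 1)
  expect_equal(ie_ratio(4, 1), 0.25)
  expect_equal(ie_ratio(4 * 7, 1 * 7), 0.25)
  expect_error(ie_ratio(0, 1), "positive")
})
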