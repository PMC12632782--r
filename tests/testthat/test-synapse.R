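test_that("the output nonlinearity is piecewise-linear with slope gamma", {
  expect_equal(phi(2, 0.25), 2)
  expect_equal(phi(-2, 0.25), -0.5)
  x <- seq(-3, 3, by = 0.1)
  expect_equal(phi(x, 1), x)
  expect_equal(phi(1e-12, 0.3) - phi(-1e-12, 0.3), 1.3e-12, tolerance = 1e-15)
  expect_error(phi(1, 0), "gamma")
})

test_that("baseline occupancy follows the closed form and the ODE fixed point", {
  p0 <- synapse_params(E0 = 0)
  expect_equal(initial_occupancy(p0), 1)
  # b * E0 * Krel / Krec = 1  ->  n0 = 1/2
  p1 <- synapse_params(Krec = 2, Krel = 10, b = 1, E0 = 0.2)
  expect_equal(initial_occupancy(p1), 0.5)

  # dn/dt residual at n0 under constant drive E0, zero inhibition
  p <- calibration_preset()
  n0 <- initial_occupancy(p)
  resid <- (1 - n0) * p$Krec - p$b * p$Krel * n0 * p$E0
  expect_lt(abs(resid), 1e-12)
})

test_that("release-rate multiplier is bounded and monotone", {
  p <- synapse_params(beta = 4)
  expect_equal(effective_release_rate(0, p), 1)
  expect_equal(effective_release_rate(2, synapse_params(beta = 0)), 1)
  expect_lt(effective_release_rate(0.5, synapse_params(beta = 4)),
            effective_release_rate(0.5, synapse_params(beta = 1)))
  i <- seq(0, 3, by = 0.1)
  m <- effective_release_rate(i, p)
  expect_true(all(m > 0 & m <= 1))
  expect_true(all(diff(m) < 0))
  expect_error(effective_release_rate(-0.1, p), "non-negative")
})

test_that("vesicle integration matches the closed-form solution", {
  # zero drive, Krec = 1/s: n(t) = 1 - 0.5 exp(-t)
  p <- synapse_params(Krec = 1, E0 = 0)
  n <- vesicle_integrate(rep(0, 1000), p, dt = 0.001, n_init = 0.5)
  t <- (1:1000) * 0.001
  expect_equal(n, 1 - 0.5 * exp(-t), tolerance = 1e-12)
  expect_equal(n[1000], 0.81606, tolerance = 1e-5)

  # constant baseline drive from n0 is a fixed point
  p <- calibration_preset()
  n0 <- initial_occupancy(p)
  nf <- vesicle_integrate(rep(p$E0, 500), p, dt = 0.002, n_init = n0)
  expect_equal(nf, rep(n0, 500), tolerance = 1e-10)
})

test_that("vesicle integration agrees with a 100x finer Euler oracle", {
  p <- calibration_preset()
  dt <- 0.001
  for (seed in 1:10) {
    set.seed(seed)
    drive <- stats::runif(300)
    n <- vesicle_integrate(drive, p, dt = dt, check = FALSE)
    ref <- euler_vesicle(drive, p, initial_occupancy(p), dt, refine = 100)
    expect_lt(max(abs(n - ref)), 1e-4)
  }
})

test_that("vesicle integration agrees with an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  p <- calibration_preset()
  dt <- 0.002
  set.seed(3)
  drive <- stats::runif(250)
  tgrid <- (0:250) * dt
  dfun <- function(t, y, parms) {
    d <- drive[pmin(250L, floor(t / dt) + 1L)]   # sample-and-hold
    list((1 - y) * p$Krec - p$b * p$Krel * y * d)
  }
  ref <- deSolve::lsoda(initial_occupancy(p), tgrid, dfun, NULL,
                        rtol = 1e-10, atol = 1e-12)[-1, 2]
  n <- vesicle_integrate(drive, p, dt = dt, check = FALSE)
  expect_lt(max(abs(n - ref)), 1e-6)
})

test_that("occupancy stays in [0, 1] for arbitrary drives", {
  p <- synapse_params(Krec = 0.5, Krel = 80)
  for (seed in 1:5) {
    set.seed(seed)
    drive <- stats::rexp(400, rate = 0.5)
    n <- vesicle_integrate(drive, p, dt = 0.005, n_init = seed / 5,
                           check = FALSE)
    expect_true(all(n >= 0 & n <= 1))
  }
})

test_that("long-run occupancy matches the analytic steady state with
           inhibition scaling the release rate", {
  p <- synapse_params(alpha = 0.4, beta = 4)
  i_eff <- 0.6
  drive <- rep(0.8, 4000)
  n <- vesicle_integrate(drive, p, dt = 0.002, i_eff = i_eff, check = FALSE)
  krel_eff <- p$Krel / (1 + p$beta * i_eff)
  expect_equal(n[4000], 1 / (1 + p$b * 0.8 * krel_eff / p$Krec),
               tolerance = 1e-9)
})

test_that("the resolution guard rejects too-coarse sampling", {
  p <- synapse_params(Krel = 100)
  set.seed(1)
  drive <- stats::runif(40, 0, 5)
  expect_error(vesicle_integrate(drive, p, dt = 0.25), "dt too large")
  expect_silent(vesicle_integrate(drive, p, dt = 0.001))
})

test_that("the hemifield model is stationary at zero contrast", {
  p <- calibration_preset()
  tr <- simulate_hemifield(rep(0, 200), rep(0, 200), p, dt = 0.005)
  n0 <- initial_occupancy(p)
  expect_equal(tr$I_L, rep(0, 200))
  expect_equal(tr$n_L, rep(n0, 200), tolerance = 1e-12)
  expect_equal(tr$E_total, rep(n0 * p$E0 + p$R0, 200), tolerance = 1e-12)
  expect_error(simulate_hemifield(rep(0, 10), rep(0, 20), p), "time grid")
  expect_error(simulate_hemifield(rep(0, 10), rep(0, 10), p, settle = 0.1),
               "unsettled|settle")
})

test_that("flashed gratings suppress excitatory output then rebound", {
  res <- run_grating_flash(synapse_params(alpha = 0.4))
  expect_gt(res$suppression, 0)
  expect_gt(res$rebound, 0)
  # both scale with presynaptic inhibition strength
  reb <- vapply(c(0.1, 0.4, 0.8),
                function(a) run_grating_flash(synapse_params(alpha = a))$rebound,
                numeric(1))
  expect_true(all(diff(reb) > 0))
})

test_that("with gamma = 1, frozen occupancy and no inhibition the pathway is
           a pure LN cascade", {
  # b = 0 freezes n at its initial value (no release term)
  p <- synapse_params(alpha = 0, b = 0, gamma = 1, E0 = 2)
  dt <- 0.002
  t <- seq(0, 6 - dt, by = dt)
  stim <- 0.2 * sin(2 * pi * 2 * t)    # small sinusoid, E stays positive
  tr <- simulate_hemifield(stim, stim, p, dt = dt, settle = 2)
  y <- tr$E_total[tr$t >= 2]           # steady state
  expect_true(all(tr$E_raw_L > 0))
  # harmonic distortion: power at 2f and 3f relative to f
  amp <- function(f) {
    tt <- (seq_along(y) - 1) * dt
    Mod(sum(y * exp(-2i * pi * f * tt)))
  }
  expect_lt(amp(4) / amp(2), 1e-6)
  expect_lt(amp(6) / amp(2), 1e-6)
})

test_that("inhibition and excitation are anti-phase for reversing gratings", {
  dt <- 0.005
  t <- seq(0, 4 - dt, by = dt)
  m <- sin(2 * pi * t)                 # 1 Hz reversal, F2 cycle 0.5 s
  tr <- simulate_hemifield(0.9 * m, -0.9 * m, synapse_params(alpha = 0.4),
                           dt = dt)
  keep <- tr$t >= 1
  off <- ei_temporal_offset(tr$E_total[keep], tr$I_total[keep], cycle = 0.5,
                            dt = dt)
  # nearly half an F2 cycle apart (sign depends on the anti-phase branch)
  expect_true(all(abs(off) >= 0.25))
})

test_that("paired-pulse runs summarize facilitation", {
  res <- run_paired_pulse(synapse_params(alpha = 0.8, beta = 4))
  expect_gt(res$ppr, 1)
  expect_true(all(res$peaks > 0))
  expect_equal(res$baseline_level,
               initial_occupancy(synapse_params()) * synapse_params()$E0,
               tolerance = 1e-9)
  # facilitation grows with intervening contrast
  pprs <- vapply(c(0, 0.6),
                 function(cc) run_paired_pulse(synapse_params(),
                                               interval_contrast = cc)$ppr,
                 numeric(1))
  expect_gt(pprs[2], pprs[1])
})
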