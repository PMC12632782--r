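test_that("uniform and zero stimuli respect the symmetry of the circuit", {
  model <- small_model()
  n <- 70; dx <- 6.6
  dark <- stimulus_field(matrix(-0.4, n, n), dx = dx, dt = model$dt, dims = 2,
                         envelope = c(rep(0, 12), rep(1, 24), rep(0, 12)))
  I <- inhibitory_field(dark, model)
  # translation symmetry: every inhibitory subunit sees the same input
  expect_true(all(abs(I - matrix(I[1, ], nrow(I), ncol(I),
                                 byrow = TRUE)) < 1e-12))

  zero <- stimulus_field(matrix(0, n, n), dx = dx, dt = model$dt, dims = 2,
                         envelope = rep(1, 48))
  expect_true(all(inhibitory_field(zero, model) == 0))

  ex <- excitatory_field(dark, presynaptic_pool(I, model), model)
  expect_true(all(abs(ex$Etilde - matrix(ex$Etilde[1, ], nrow(ex$Etilde),
                                         ncol(ex$Etilde), byrow = TRUE))
                  < 1e-12))
  expect_true(all(ex$n >= 0 & ex$n <= 1))
})

test_that("a temporal impulse reproduces the rectified inhibitory kernel", {
  model <- offt_model(dims = 1, spacing = 10, grid_halfwidth = 0,
                      synapse = synapse_params())
  dt <- model$dt
  nx <- 101
  x <- offtalpha:::grid_coords(nx, 2)
  S <- matrix(0, nx, 80)
  S[, 10] <- -0.5                       # one-frame uniform dark impulse
  stim <- stimulus_field(S, dx = 2, dt = dt, dims = 1)
  I <- inhibitory_field(stim, model)
  # drive of a uniform frame through integral-normalized DoG weights
  d <- -0.5 * (1 - model$inh_rf$delta)
  k <- filter_kernel(model$filters$inh, dt)
  expected <- pmax(d * c(rep(0, 9), k * dt)[1:80], 0)
  expect_equal(as.numeric(I), expected, tolerance = 1e-10)
})

test_that("presynaptic pooling is a normalized Gaussian weighting times alpha", {
  m0 <- small_model(alpha = 0)
  I <- matrix(stats::runif(nrow(m0$positions) * 5), ncol = 5)
  expect_true(all(presynaptic_pool(I, m0) == 0))

  # single co-located inhibitory subunit: w = 1 at zero offset
  m1 <- offt_model(dims = 1, grid_halfwidth = 0,
                   synapse = synapse_params(alpha = 0.4))
  I1 <- matrix(c(0.2, 0.7, 0), 1)
  expect_equal(unname(as.matrix(presynaptic_pool(I1, m1))), 0.4 * I1)

  # hand sum over two equidistant neighbours with equal input
  m3 <- offt_model(dims = 1, spacing = 40, grid_halfwidth = 40,
                   presyn_pool_sigma = 50,
                   synapse = synapse_params(alpha = 0.4))
  Ieq <- matrix(c(1, 0, 1), 3, 1)       # neighbours active, center silent
  w_raw <- exp(-c(40, 0, 40)^2 / (2 * 50^2))
  w_norm <- w_raw / sum(w_raw)
  hand <- 0.4 * (2 * w_norm[1] * 1)
  expect_equal(unname(presynaptic_pool(Ieq, m3)[2, 1]), hand,
               tolerance = 1e-12)
})

test_that("ganglion readout is a rectified weighted difference", {
  expect_equal(ganglion_readout(1, 1, gain = 3), 2)
  expect_equal(ganglion_readout(c(0.5, 1), c(2, 0)), c(0, 3))
  expect_equal(ganglion_readout(1, 3.5), 0)
})

test_that("with linearized nonlinearities the pathway reduces to an LN model", {
  model <- offt_model(dims = 2, spacing = 30, grid_halfwidth = 60,
                      synapse = synapse_params(alpha = 0, b = 0, gamma = 1))
  n <- 70; dx <- 6.6
  set.seed(4)
  frame <- matrix(stats::rnorm(n * n, 0, 0.05), n, n)
  env <- c(rep(0, 12), rep(1, 24), rep(0, 24))
  stim <- stimulus_field(frame, dx = dx, dt = model$dt, dims = 2,
                         envelope = env)
  weights <- spatial_weights(model, stim)
  tr <- response_traces(stim, model, weights, keep_subunits = TRUE)
  sub <- attr(tr, "subunits")
  # direct LN oracle for the center subunit (n frozen at 1, no inhibition)
  ctr <- which(rowSums(abs(model$positions)) == 0)
  d <- sum(weights$exc[ctr, ] * as.vector(frame))
  pad <- offtalpha:::n_steps(3 / model$synapse$Krec, model$dt)
  k <- filter_kernel(model$filters$exc, model$dt)
  r <- apply_filter(c(rep(0, pad), env), k, model$dt)[-(1:pad)]
  oracle <- pmax(model$synapse$E0 + d * r, 0)
  expect_equal(sub$Etilde[ctr, ], oracle, tolerance = 1e-10)
  expect_true(all(sub$n == 1))
})

test_that("responses are equivariant to joint translation of stimulus and model", {
  n <- 110; dx <- 6.6
  set.seed(12)
  frame <- matrix(0, n, n)
  frame[50:60, 48:64] <- stats::rnorm(11 * 17, 0, 0.4)
  env <- c(rep(0, 10), rep(1, 20), rep(0, 20))
  shift <- 3                             # pixels
  frame_s <- matrix(0, n, n)
  frame_s[, (1 + shift):n] <- frame[, 1:(n - shift)]

  base <- offt_model(spacing = 30, grid_halfwidth = 60,
                     synapse = synapse_params(alpha = 0.6))
  moved <- offtalpha:::update_model(base, center = c(shift * dx, 0))
  tr1 <- response_traces(stimulus_field(frame, dx = dx, dt = base$dt,
                                        dims = 2, envelope = env), base)
  tr2 <- response_traces(stimulus_field(frame_s, dx = dx, dt = base$dt,
                                        dims = 2, envelope = env), moved)
  expect_lt(max(abs(tr1$E_total - tr2$E_total)), 1e-10)
  expect_lt(max(abs(tr1$I_total - tr2$I_total)), 1e-10)
  expect_true(all(tr1$rate >= 0))
})

test_that("a linearized whole-RF model cannot distinguish a patch from its
           equivalent disc", {
  model <- offt_model(dims = 2, spacing = 10, grid_halfwidth = 0,
                      exc_rf = subunit_rf(50, 150, 0),
                      synapse = synapse_params(alpha = 0, b = 0, gamma = 1))
  n <- 70; dx <- 6.6
  set.seed(8)
  frame <- matrix(stats::rnorm(n * n, 0, 0.05), n, n)
  env <- c(rep(0, 10), rep(1, 20), rep(0, 10))
  w <- spatial_weights(model, x = offtalpha:::grid_coords(n, dx),
                       y = offtalpha:::grid_coords(n, dx))
  disc_val <- sum(w$exc[1, ] * as.vector(frame))
  tr_patch <- response_traces(stimulus_field(frame, dx = dx, dt = model$dt,
                                             dims = 2, envelope = env),
                              model, w)
  tr_disc <- response_traces(stimulus_field(matrix(disc_val, n, n), dx = dx,
                                            dt = model$dt, dims = 2,
                                            envelope = env), model, w)
  expect_equal(tr_patch$E_total, tr_disc$E_total, tolerance = 1e-10)
})

test_that("identical stimuli give exactly zero NLI", {
  model <- small_model()
  pp <- make_synthetic_patch(0, mean_contrast = -0.3, rf = model$rf,
                             extent = 462)
  res <- image_vs_disc_experiment(model, list(pp))
  expect_identical(res$nli_onset, 0)
  expect_identical(res$nli_offset, 0)
  expect_false(res$excluded_offset)
})

test_that("NLI values are stable under subunit-lattice refinement", {
  pp <- make_synthetic_patch(1, 0, seed = 17, rf = gaussian_rf(50),
                             extent = 462)
  coarse <- offt_model(spacing = 30, grid_halfwidth = 90,
                       synapse = synapse_params(alpha = 0.8))
  fine <- offtalpha:::update_model(coarse, spacing = 15)
  r1 <- image_vs_disc_experiment(coarse, list(pp))
  r2 <- image_vs_disc_experiment(fine, list(pp))
  expect_lt(abs(r1$nli_onset - r2$nli_onset), 0.02)
  expect_lt(abs(r1$nli_offset - r2$nli_offset), 0.02)
})
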