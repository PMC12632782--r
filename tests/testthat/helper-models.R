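# shared fixtures: a small, fast spatiotemporal model and default preset pieces
small_model <- function(alpha = 0.4, ...) {
  offt_model(spacing = 30, grid_halfwidth = 90, pool_sigma = 50,
             synapse = synapse_params(alpha = alpha), ...)
}

# small synthetic patch set reused across spatial tests
small_pairs <- function(n = 4, seed = 101, rf = gaussian_rf(50)) {
  sample_patch_pairs(n, seed = seed, rf = rf, extent = 462)
}

# forward-Euler reference integrator for the vesicle ODE (sample-and-hold
# drive), used as the independent fine-step oracle
euler_vesicle <- function(drive, p, n_init, dt, refine = 100, i_eff = 0) {
  mult <- 1 / (1 + p$beta * i_eff)
  if (length(mult) == 1L) mult <- rep(mult, length(drive))
  h <- dt / refine
  n <- numeric(length(drive))
  cur <- n_init
  for (t in seq_along(drive)) {
    for (k in seq_len(refine)) {
      cur <- cur + h * ((1 - cur) * p$Krec -
                          p$b * p$Krel * mult[t] * cur * drive[t])
    }
    n[t] <- cur
  }
  n
}
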