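#' Dynamic-synapse parameters
#'
#' Parameters of the excitatory pathway's depressing synapse and of the
#' presynaptic inhibition acting on it. Vesicle occupancy n(t) evolves as
#' \deqn{dn/dt = (1 - n) K_{rec} - b\,K_{rel}\,n\,D(t),}
#' where the release drive D(t) is the rectified excitatory drive. Presynaptic
#' inhibition scales the release rate by a divisive factor
#' \eqn{1/(1 + \beta I_{eff})} (see [effective_release_rate()]) and is
#' subtracted from the excitatory drive with overall strength `alpha`.
#'
#' @param Krec vesicle recovery rate, 1/s (> 0).
#' @param Krel vesicle release rate constant, 1/s per unit drive (> 0).
#' @param b release gain, dimensionless (>= 0; 0 freezes occupancy, useful for
#'   linear-regime diagnostics).
#' @param gamma rectification ratio of the output nonlinearity, in (0, 1].
#' @param R0 tonic additive output offset (>= 0).
#' @param alpha presynaptic inhibition strength (>= 0).
#' @param beta inhibition sensitivity coupling inhibition to vesicle release
#'   (>= 0).
#' @param E0 baseline excitatory drive (>= 0); with `R0 = 0` the baseline
#'   occupancy equals the closed form of [initial_occupancy()] exactly.
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(Krec = 2, Krel = 10, b = 1, gamma = 0.5, R0 = 0,
                           alpha = 0.4, beta = 4, E0 = 7 / 15) {
  if (Krec <= 0 || Krel <= 0) stop("Krec and Krel must be positive rates")
  if (b < 0) stop("b must be non-negative")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  if (R0 < 0) stop("R0 must be non-negative")
  if (alpha < 0) stop("alpha must be non-negative")
  if (beta < 0) stop("beta must be non-negative")
  if (E0 < 0) stop("E0 must be non-negative")
  p <- structure(list(Krec = Krec, Krel = Krel, b = b, gamma = gamma, R0 = R0,
                      alpha = alpha, beta = beta, E0 = E0),
                 class = "synapse_params")
  n0 <- initial_occupancy(p)
  if (!(n0 > 0 && n0 <= 1)) stop("derived baseline occupancy outside (0, 1]")
  p
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf(
    "<synapse_params> Krec=%.3g/s Krel=%.3g/s b=%.3g gamma=%.3g R0=%.3g alpha=%.3g beta=%.3g E0=%.4g (n0=%.4g)\n",
    x$Krec, x$Krel, x$b, x$gamma, x$R0, x$alpha, x$beta, x$E0,
    initial_occupancy(x)))
  invisible(x)
}

#' Calibration preset for the dynamic-synapse model
#'
#' The documented parameter set used for all reference simulations: strong
#' tonic depression (baseline occupancy 0.3), recovery over the 0.5-5 s range
#' characteristic of paired-pulse protocols, and Off-pathway biphasic filters
#' with inhibition lagging excitation by one synaptic delay.
#'
#' @param ... overrides forwarded to [synapse_params()].
#' @return a [synapse_params()] object.
#' @export
calibration_preset <- function(...) {
  synapse_params(...)
}

#' Excitatory output nonlinearity
#'
#' Piecewise-linear: identity for non-negative drive, slope `gamma` for
#' negative drive; continuous at zero.
#'
#' @param x drive (vectorized).
#' @param gamma rectification ratio in (0, 1].
#' @return transformed drive.
#' @export
phi <- function(x, gamma) {
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  ifelse(x < 0, gamma * x, x)
}

#' Baseline vesicle occupancy
#'
#' Closed form \eqn{n_0 = 1/(1 + b E_0 K_{rel}/K_{rec})}: the fixed point of
#' the occupancy dynamics under constant baseline drive `E0` with zero
#' inhibition.
#'
#' @param p a [synapse_params()].
#' @return occupancy in (0, 1].
#' @export
initial_occupancy <- function(p) {
  1 / (1 + p$b * p$E0 * p$Krel / p$Krec)
}

#' Release-rate multiplier under presynaptic inhibition
#'
#' Divisive coupling of pooled inhibition to vesicle release:
#' \eqn{1/(1 + \beta I_{eff})}. Equals 1 with no inhibition or `beta = 0` and
#' decreases monotonically in both.
#'
#' @param I_eff pooled inhibitory drive (>= 0; vectorized).
#' @param p a [synapse_params()] (only `beta` is used).
#' @return multiplier in (0, 1].
#' @export
effective_release_rate <- function(I_eff, p) {
  if (any(I_eff < 0)) stop("I_eff must be non-negative")
  1 / (1 + p$beta * I_eff)
}

# one exponential-integrator pass; drive/krel_eff are per-step vectors
# (sample-and-hold within each step, for which the update is exact)
vesicle_recursion <- function(n0, Krec, release_rate, dt) {
  k <- Krec + release_rate
  e <- exp(-k * dt)
  ninf <- Krec / k
  n <- numeric(length(release_rate))
  prev <- n0
  for (t in seq_along(release_rate)) {
    prev <- ninf[t] + (prev - ninf[t]) * e[t]
    n[t] <- prev
  }
  n
}

#' Integrate the vesicle-occupancy dynamics
#'
#' Solves \eqn{dn/dt = (1-n)K_{rec} - b K_{rel,eff} n D(t)} with an
#' exponential integrator: within each step the drive is sample-and-hold, for
#' which the exponential update is exact, so the solution is the exact ODE
#' solution of the piecewise-constant-drive problem. `i_eff` supplies the
#' pooled inhibition that divisively scales the release rate. A resolution
#' guard re-solves with midpoint-refined drive and errors when the time step
#' is too coarse to resolve the dynamics.
#'
#' @param drive non-negative release drive series D(t).
#' @param p a [synapse_params()].
#' @param dt time step, seconds.
#' @param n_init initial occupancy in `[0, 1]` (defaults to the baseline
#'   closed form).
#' @param i_eff pooled inhibitory drive, scalar or series (default 0).
#' @param check run the resolution guard.
#' @return occupancy series in `[0, 1]`, aligned with `drive` (value at the
#'   end of each step).
#' @export
vesicle_integrate <- function(drive, p, dt, n_init = initial_occupancy(p),
                              i_eff = 0, check = TRUE) {
  stopifnot(inherits(p, "synapse_params"))
  if (any(drive < 0) || any(!is.finite(drive)))
    stop("drive must be finite and non-negative")
  if (n_init < 0 || n_init > 1) stop("n_init must lie in [0, 1]")
  release <- p$b * p$Krel * effective_release_rate(i_eff, p) * drive
  if (length(release) == 1L) release <- rep(release, length(drive))
  n <- vesicle_recursion(n_init, p$Krec, release, dt)
  if (check) {
    # refine: split each step in two, first half at the midpoint drive
    r2 <- as.numeric(rbind((release + c(release[1], release[-length(release)])) / 2,
                           release))
    n2 <- vesicle_recursion(n_init, p$Krec, r2, dt / 2)
    if (max(abs(n - n2[seq_along(n) * 2])) > 0.01)
      stop("dt too large to resolve the vesicle dynamics; reduce dt")
  }
  n
}

# matrix variant: drive, release multiplier (subunits x time)
vesicle_integrate_matrix <- function(drive, rel_mult, p, dt, n_init) {
  k <- p$Krec + p$b * p$Krel * rel_mult * drive
  e <- exp(-k * dt)
  ninf <- p$Krec / k
  n <- matrix(0, nrow(drive), ncol(drive))
  prev <- rep(n_init, length.out = nrow(drive))
  for (t in seq_len(ncol(drive))) {
    prev <- ninf[, t] + (prev - ninf[, t]) * e[, t]
    n[, t] <- prev
  }
  n
}

new_model_traces <- function(df, dt, params, protocol = NULL) {
  structure(df, dt = dt, params = params, protocol = protocol,
            class = c("model_traces", "data.frame"))
}

#' @export
print.model_traces <- function(x, ...) {
  cat(sprintf(
    "<model_traces> %d samples, dt=%.4g s (%.3g s)\n columns: %s\n",
    nrow(x), attr(x, "dt"), nrow(x) * attr(x, "dt"),
    paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
plot.model_traces <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$E_total, type = "l", xlab = "", ylab = "E_total", ...)
  graphics::plot(x$t, x$I_total, type = "l", xlab = "", ylab = "I_total", ...)
  nc <- grep("^n_", names(x), value = TRUE)
  graphics::matplot(x$t, as.matrix(x[nc]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "occupancy n")
  invisible(x)
}

#' Simulate the two-hemifield temporal model
#'
#' The reduced (space-collapsed) dynamic LN model: each hemifield holds one
#' excitatory and one inhibitory subunit. Per hemifield j, the inhibitory
#' pathway is a static LN stage, \eqn{I_j = [k_{inh} * S_j]_+}; pooled
#' inhibition \eqn{I_{eff} = \alpha (I_L + I_R)} is subtracted from the
#' filtered excitatory drive before the output nonlinearity,
#' \eqn{E_j = \Phi(E_0 + k_{exc} * S_j - I_{eff})}, and divisively scales the
#' vesicle release rate. The synaptic output is
#' \eqn{\tilde E_j = n_j \max(0, E_j) + R_0} with \eqn{n_j} from
#' [vesicle_integrate()] driven by \eqn{\max(0, E_j) + R_0}. Totals are
#' hemifield averages; the rate proxy is
#' `max(0, readout_gain * E_total - I_total)`.
#'
#' @param stim_left,stim_right contrast time series (numeric vectors of equal
#'   length) or 1-D [stimulus_field()]s (the center pixel's series is used).
#' @param p a [synapse_params()].
#' @param filters list with `exc` and `inh` [temporal_filter()]s.
#' @param dt time step, seconds.
#' @param settle baseline settling time prepended before the series, seconds
#'   (>= 3 recovery time constants recommended; shorter values error).
#' @param readout_gain spike-proxy gain on the excitatory total.
#' @return a `model_traces` data.frame: `t`, per-hemifield `E_raw_*`, `I_*`,
#'   `n_*`, `Etilde_*`, plus `E_total`, `I_total`, `I_eff`, `rate`.
#' @export
simulate_hemifield <- function(stim_left, stim_right, p = calibration_preset(),
                               filters = default_filters(), dt = 0.005,
                               settle = 3 / p$Krec, readout_gain = 3) {
  if (inherits(stim_left, "stimulus_field")) {
    dt <- stim_left$dt
    stim_left <- contrast_series(stim_left)
  }
  if (inherits(stim_right, "stimulus_field"))
    stim_right <- contrast_series(stim_right)
  if (length(stim_left) != length(stim_right))
    stop("hemifield series must share a time grid (dt mismatch or length)")
  if (settle < 1 / p$Krec)
    stop("unsettled baseline: settle must cover at least one recovery time ",
         "constant (3/Krec recommended)")
  pad <- n_steps(settle, dt)
  kexc <- filter_kernel(filters$exc, dt)
  kinh <- filter_kernel(filters$inh, dt)
  n0 <- initial_occupancy(p)

  S <- list(L = c(rep(0, pad), stim_left), R = c(rep(0, pad), stim_right))
  I <- lapply(S, function(s) pmax(0, apply_filter(s, kinh, dt)))
  I_eff <- p$alpha * (I$L + I$R)
  out <- lapply(c("L", "R"), function(j) {
    E_raw <- p$E0 + apply_filter(S[[j]], kexc, dt)
    E <- phi(E_raw - I_eff, p$gamma)
    drive <- pmax(0, E) + p$R0
    n <- vesicle_integrate(drive, p, dt, n_init = n0, i_eff = I_eff,
                           check = FALSE)
    list(E_raw = E_raw, n = n, Etilde = n * pmax(0, E) + p$R0)
  })
  names(out) <- c("L", "R")
  keep <- (pad + 1):length(S$L)
  E_total <- (out$L$Etilde + out$R$Etilde)[keep] / 2
  I_total <- (I$L + I$R)[keep] / 2
  df <- data.frame(
    t = (seq_along(keep) - 1) * dt,
    E_raw_L = out$L$E_raw[keep], E_raw_R = out$R$E_raw[keep],
    I_L = I$L[keep], I_R = I$R[keep],
    n_L = out$L$n[keep], n_R = out$R$n[keep],
    Etilde_L = out$L$Etilde[keep], Etilde_R = out$R$Etilde[keep],
    E_total = E_total, I_total = I_total, I_eff = I_eff[keep],
    rate = pmax(0, readout_gain * E_total - I_total)
  )
  new_model_traces(df, dt, p)
}

#' Paired-pulse protocol on the two-hemifield model
#'
#' Runs two identical uniform pulses (default 300 ms at -90% contrast)
#' separated by an intervening contrast step (default 500 ms at 0%) through
#' [simulate_hemifield()] with both hemifields driven identically, and
#' summarizes the pulse-2/pulse-1 ratio of baseline-subtracted excitatory
#' output peaks.
#'
#' @inheritParams make_paired_pulse
#' @inheritParams simulate_hemifield
#' @param baseline pre-stimulus baseline duration, seconds (the final 100 ms
#'   define the peak-measurement baseline).
#' @return list with `traces` (a `model_traces`), `ppr` (the paired-pulse
#'   ratio of `E_total`), `peaks`, `baseline_level`, and `windows`.
#' @export
run_paired_pulse <- function(p = calibration_preset(),
                             filters = default_filters(),
                             pulse_contrast = -0.9, pulse_duration = 0.3,
                             interval_contrast = 0, interval_duration = 0.5,
                             baseline = 0.5, post = 1, dt = 0.005,
                             settle = 3 / p$Krec) {
  segs <- list(c(baseline, 0), c(pulse_duration, pulse_contrast),
               c(interval_duration, interval_contrast),
               c(pulse_duration, pulse_contrast), c(post, 0))
  s <- segments_to_series(segs, dt)
  tr <- simulate_hemifield(s, s, p = p, filters = filters, dt = dt,
                           settle = settle)
  w1 <- c(baseline, pulse_duration)
  w2 <- c(baseline + pulse_duration + interval_duration, pulse_duration)
  bw <- c(max(0, baseline - 0.1), min(0.1, baseline))
  res <- paired_pulse_ratio(tr$E_total, dt = dt, pulse1_window = w1,
                            pulse2_window = w2, baseline_window = bw,
                            details = TRUE)
  list(traces = tr, ppr = res$ppr, peaks = res$peaks,
       baseline_level = res$baseline,
       windows = list(pulse1 = w1, pulse2 = w2, baseline = bw))
}

#' Flashed-grating analog on the two-hemifield model
#'
#' Emulates a flashed grating by driving the two hemifields with opposing
#' contrast steps (+c and -c) for `flash_duration` seconds. Summarizes the
#' suppression of excitatory output during the flash and the rebound above
#' baseline after flash offset.
#'
#' @param contrast grating contrast (the hemifields see +/- this value).
#' @param flash_duration flash length, seconds.
#' @param baseline,post pre/post zero-contrast segments, seconds.
#' @inheritParams simulate_hemifield
#' @return list with `traces`, `baseline_level` (mean of the final 100 ms
#'   before onset), `suppression` (baseline minus minimum `E_total` during the
#'   flash) and `rebound` (maximum `E_total` after offset minus baseline).
#' @export
run_grating_flash <- function(p = calibration_preset(),
                              filters = default_filters(), contrast = 0.9,
                              flash_duration = 0.5, baseline = 0.5, post = 1,
                              dt = 0.005, settle = 3 / p$Krec) {
  segs_on <- list(c(baseline, 0), c(flash_duration, contrast), c(post, 0))
  segs_off <- list(c(baseline, 0), c(flash_duration, -contrast), c(post, 0))
  sL <- segments_to_series(segs_on, dt)
  sR <- segments_to_series(segs_off, dt)
  tr <- simulate_hemifield(sL, sR, p = p, filters = filters, dt = dt,
                           settle = settle)
  t <- tr$t
  base_idx <- t >= baseline - 0.1 & t < baseline
  flash_idx <- t >= baseline & t < baseline + flash_duration
  post_idx <- t >= baseline + flash_duration
  b <- mean(tr$E_total[base_idx])
  list(traces = tr, baseline_level = b,
       suppression = b - min(tr$E_total[flash_idx]),
       rebound = max(tr$E_total[post_idx]) - b)
}
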