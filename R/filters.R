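#' Biphasic temporal filter
#'
#' Parametric biphasic kernel built as a difference of low-pass cascades
#' (gamma-shaped stages): \eqn{k(t) \propto g(t;\tau_{rise}) - w\,
#' g(t;\tau_{decay})}, where each `g` is a gamma density with `stages` stages
#' whose per-stage scale is `tau/stages`, so `tau` is the lobe's mean
#' (center-of-mass) time and the kernel's overall memory tracks the stated
#' time constants. The kernel is scaled so the peak of its step response
#' equals `gain`, i.e. a
#' unit contrast step produces a transient of peak amplitude `gain` (with the
#' sign set by `polarity`). Off-pathway filters use `polarity = -1`: negative
#' contrast yields positive drive.
#'
#' @param tau_rise,tau_decay mean times of the fast and slow lobes, seconds.
#' @param undershoot relative weight of the slow (opposing) lobe in `[0, 1)`;
#'   `1 - undershoot` of the step response survives at steady state.
#' @param gain peak step-response amplitude.
#' @param polarity +1 or -1 (-1 for Off pathways).
#' @param lag pure delay prepended to the kernel, seconds (>= 0).
#' @param stages number of low-pass stages (integer >= 1).
#' @param kernel_length kernel support, seconds; the continuous form must have
#'   decayed below 1e-4 of its peak by this time (checked at discretization).
#' @return an object of class `temporal_filter`.
#' @export
temporal_filter <- function(tau_rise = 0.03, tau_decay = 0.08,
                            undershoot = 0.3, gain = 1, polarity = -1,
                            lag = 0, stages = 3, kernel_length = 0.6) {
  if (tau_rise <= 0 || tau_decay <= 0) stop("time constants must be positive")
  if (undershoot < 0 || undershoot >= 1) stop("undershoot must lie in [0, 1)")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  if (lag < 0) stop("lag must be non-negative")
  if (stages < 1) stop("stages must be >= 1")
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 undershoot = undershoot, gain = gain, polarity = polarity,
                 lag = lag, stages = as.integer(stages),
                 kernel_length = kernel_length),
            class = "temporal_filter")
}

#' @export
print.temporal_filter <- function(x, ...) {
  cat(sprintf(
    "<temporal_filter> tau_rise=%.3g s tau_decay=%.3g s undershoot=%.3g gain=%.3g polarity=%+d lag=%.3g s (%d stages)\n",
    x$tau_rise, x$tau_decay, x$undershoot, x$gain, x$polarity, x$lag,
    x$stages))
  invisible(x)
}

# continuous kernel before normalization; per-stage scale tau/stages keeps
# tau equal to the lobe's mean time
filter_shape <- function(tf, t) {
  stats::dgamma(t, shape = tf$stages, scale = tf$tau_rise / tf$stages) -
    tf$undershoot *
      stats::dgamma(t, shape = tf$stages, scale = tf$tau_decay / tf$stages)
}

#' Discretize a temporal filter at a given time step
#'
#' Samples the continuous kernel at sample midpoints (so discrete sums match
#' continuous integrals to quadrature accuracy), scales it to the requested
#' step-response gain, and prepends the pure delay as leading zeros. Errors if
#' the kernel has not decayed below 1e-4 of its peak within `kernel_length`.
#'
#' @param tf a [temporal_filter()].
#' @param dt time step, seconds.
#' @return numeric kernel vector; convolving a contrast series with it
#'   (weights times `dt`) gives the filter drive.
#' @export
filter_kernel <- function(tf, dt) {
  stopifnot(inherits(tf, "temporal_filter"))
  nk <- n_steps(tf$kernel_length, dt)
  t <- (seq_len(nk) - 0.5) * dt
  raw <- filter_shape(tf, t)
  pk <- max(abs(raw))
  if (abs(raw[nk]) > 1e-4 * pk)
    stop("kernel has not decayed below 1e-4 of peak within kernel_length; ",
         "increase kernel_length")
  step_resp <- cumsum(raw) * dt
  k <- tf$polarity * tf$gain * raw / max(abs(step_resp))
  if (tf$lag > 0) k <- c(rep(0, round(tf$lag / dt)), k)
  k
}

#' Causal FIR filtering of a time series
#'
#' Convolution \eqn{y_t = \sum_i k_i x_{t-i+1} \Delta t} with zero-padded
#' history before the first sample.
#'
#' @param x input series.
#' @param kernel discrete kernel from [filter_kernel()].
#' @param dt time step, seconds.
#' @return filtered series, same length as `x`.
#' @export
apply_filter <- function(x, kernel, dt) {
  nk <- length(kernel)
  xp <- c(rep(0, nk), x)
  y <- stats::filter(xp, kernel * dt, method = "convolution", sides = 1)
  as.numeric(y[(nk + 1):length(xp)])
}

#' Default excitatory/inhibitory filter pair
#'
#' Biphasic filters sharing one shape. The excitatory filter has Off polarity
#' (negative contrast yields positive drive). The inhibitory filter has ON
#' polarity: the glycinergic inhibition onto Off bipolar terminals and the
#' ganglion cell is relayed by AII amacrine cells driven through the ON rod
#' bipolar pathway (crossover inhibition), so brightening - including the
#' offset of a dark stimulus and the bright bars of gratings - recruits it.
#' This sign inversion is what places inhibition a half reversal cycle ahead
#' of excitation for contrast-reversing gratings and sustains release
#' suppression after dark pulses.
#'
#' The inhibitory kinetics are slower than the excitatory ones (glycinergic
#' input relayed through the AII network is sustained), the inhibitory gain is
#' higher (structured stimuli recruit inhibition exceeding excitation), and
#' inhibition is delayed by `inh_lag` (two additional synapses). The default
#' inhibitory values are the documented calibration reproducing the ~3-fold
#' paired-pulse facilitation under the standard 300 ms / -90% / 500 ms
#' protocol; see the package vignette.
#'
#' @param inh_lag inhibitory delay, seconds.
#' @param inh_gain inhibitory step-response gain.
#' @param inh_polarity inhibitory filter polarity (default +1, ON pathway).
#' @param inh_tau_rise,inh_tau_decay inhibitory lobe mean times, seconds.
#' @param inh_kernel_length inhibitory kernel support, seconds.
#' @param ... common filter arguments passed to [temporal_filter()] (the
#'   excitatory filter, and the inhibitory one for its remaining parameters).
#' @return list with elements `exc` and `inh`.
#' @export
default_filters <- function(inh_lag = 0.02, inh_gain = 3, inh_polarity = 1,
                            inh_tau_rise = 0.06, inh_tau_decay = 0.45,
                            inh_kernel_length = 3, ...) {
  list(exc = temporal_filter(...),
       inh = temporal_filter(tau_rise = inh_tau_rise,
                             tau_decay = inh_tau_decay, lag = inh_lag,
                             gain = inh_gain, polarity = inh_polarity,
                             kernel_length = inh_kernel_length, ...))
}
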