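#' Nonlinearity index
#'
#' \eqn{NLI = (r_{image} - r_{disc}) / (r_{image} + r_{disc})}: the normalized
#' difference between responses to an image patch and to its linear-equivalent
#' disc. Negative at onset indicates a preference for spatial homogeneity;
#' positive at offset indicates enhanced responses to the transition from
#' structure back to homogeneity. Defined as 0 when both responses are 0.
#'
#' @param r_image,r_disc non-negative responses (spike counts, charge, or rate
#'   integrals); vectorized.
#' @return index in `[-1, 1]`.
#' @export
nli <- function(r_image, r_disc) {
  if (any(r_image < 0) || any(r_disc < 0)) stop("responses must be >= 0")
  s <- r_image + r_disc
  ifelse(s == 0, 0, (r_image - r_disc) / s)
}

#' Offset NLI with the low-spike-count exclusion rule
#'
#' Offset responses below `threshold` spikes for *both* the disc and the image
#' carry no usable offset signal; such pairs are excluded by setting the
#' offset NLI to 0 and flagging them. A pair where only one response is below
#' threshold is kept.
#'
#' @param r_image_off,r_disc_off offset spike counts (>= 0); vectorized.
#' @param threshold exclusion threshold, spikes (default 3).
#' @return data.frame with columns `nli` and `excluded`.
#' @export
offset_nli_with_exclusion <- function(r_image_off, r_disc_off, threshold = 3) {
  if (any(r_image_off < 0) || any(r_disc_off < 0))
    stop("spike counts must be >= 0")
  excluded <- r_image_off < threshold & r_disc_off < threshold
  data.frame(nli = ifelse(excluded, 0, nli(r_image_off, r_disc_off)),
             excluded = excluded)
}

# indices of samples falling in a (start, duration) window
window_index <- function(t, window) {
  idx <- which(t >= window[1] & t < window[1] + window[2])
  if (length(idx) == 0) stop("window lies outside the trace")
  idx
}

#' Paired-pulse ratio
#'
#' Ratio of the pulse-2 to pulse-1 peak amplitudes of a response trace, each
#' measured as the maximum above the pre-stimulus baseline level within its
#' window. Values above 1 indicate facilitation.
#'
#' @param trace response series.
#' @param dt time step, seconds (trace times are `(0:(n-1)) * dt`).
#' @param pulse1_window,pulse2_window `c(start_s, duration_s)` windows.
#' @param baseline_window `c(start_s, duration_s)` window defining the
#'   baseline level, or a single number giving the level directly.
#' @param details return peaks and baseline alongside the ratio.
#' @return the ratio, or (with `details = TRUE`) a list with `ppr`, `peaks`,
#'   `baseline`.
#' @export
paired_pulse_ratio <- function(trace, dt, pulse1_window, pulse2_window,
                               baseline_window, details = FALSE) {
  t <- (seq_along(trace) - 1) * dt
  base <- if (length(baseline_window) == 1) baseline_window
          else mean(trace[window_index(t, baseline_window)])
  a1 <- max(trace[window_index(t, pulse1_window)]) - base
  a2 <- max(trace[window_index(t, pulse2_window)]) - base
  if (a1 <= 0)
    stop("pulse-1 amplitude above baseline is not positive; ",
         "paired-pulse ratio undefined")
  if (details) list(ppr = a2 / a1, peaks = c(pulse1 = a1, pulse2 = a2),
                    baseline = base)
  else a2 / a1
}

#' Fourier amplitude at twice a fundamental frequency
#'
#' Amplitude of the frequency-doubled (F2) component of a response to a
#' contrast-reversing stimulus, computed over an integer number of fundamental
#' cycles (trailing partial cycles are dropped).
#'
#' @param trace response series (transients already removed).
#' @param fundamental stimulus modulation frequency, Hz.
#' @param dt time step, seconds.
#' @return non-negative amplitude (peak amplitude of the 2f cosine component).
#' @export
f2_amplitude <- function(trace, fundamental, dt) {
  per <- round(1 / (fundamental * dt))
  ncyc <- floor(length(trace) / per)
  if (ncyc < 2) stop("trace must span at least two full cycles")
  y <- trace[seq_len(ncyc * per)]
  t <- (seq_along(y) - 1) * dt
  z <- sum(y * exp(-2i * pi * 2 * fundamental * t))
  2 * Mod(z) / length(y)
}

# circular shift helper
rotate <- function(x, k) {
  k <- k %% length(x)
  if (k == 0) x else c(x[(k + 1):length(x)], x[1:k])
}

#' Temporal offset between excitatory and inhibitory responses
#'
#' Two estimators of the lag between excitation and inhibition during
#' steady-state cyclic responses, both normalized to the response cycle and
#' reported in `[-0.5, 0.5]` with positive values meaning inhibition leads
#' excitation. The half-cycle wrap ambiguity is resolved to +0.5.
#'
#' `"xcorr"`: lag maximizing the circular cross-correlation.
#' `"com"`: difference of the circular centers of mass (phase of the first
#' Fourier component of the baseline-subtracted, floored-at-zero traces,
#' which handles response peaks straddling cycle boundaries).
#'
#' @param exc,inh series spanning an integer number of response cycles.
#' @param cycle response cycle length, seconds.
#' @param dt time step, seconds.
#' @return named numeric vector with elements `xcorr` and `com`.
#' @export
ei_temporal_offset <- function(exc, inh, cycle, dt) {
  per <- round(cycle / dt)
  ncyc <- floor(length(exc) / per)
  if (ncyc < 1) stop("traces must span at least one full cycle")
  if (stats::sd(exc) == 0 || stats::sd(inh) == 0)
    stop("flat trace: temporal offset undefined")
  n <- ncyc * per
  e <- exc[seq_len(n)] - mean(exc[seq_len(n)])
  i <- inh[seq_len(n)] - mean(inh[seq_len(n)])

  # circular cross-correlation: c(L) = sum_t e(t) i(t - L)
  cc <- vapply(0:(per - 1), function(L) sum(e * rotate(i, -L)), numeric(1))
  lag <- (which.max(cc) - 1)
  xc <- lag / per
  if (xc > 0.5) xc <- xc - 1
  if (xc == -0.5) xc <- 0.5

  # circular centers of mass on floored traces
  base_e <- min(exc[seq_len(n)]); base_i <- min(inh[seq_len(n)])
  theta <- 2 * pi * ((seq_len(n) - 1) %% per) / per
  circ_com <- function(y) Arg(sum(y * exp(1i * theta)))
  ce <- circ_com(pmax(exc[seq_len(n)] - base_e, 0))
  ci <- circ_com(pmax(inh[seq_len(n)] - base_i, 0))
  cm <- (ce - ci) / (2 * pi)
  cm <- cm - round(cm)               # wrap to [-0.5, 0.5]
  if (cm <= -0.5 + 1e-9) cm <- 0.5
  c(xcorr = xc, com = cm)
}

#' Baseline-subtracted charge transfer over a window
#'
#' Trapezoidal integral of a current-like trace above its baseline level over
#' a response window.
#'
#' @inheritParams paired_pulse_ratio
#' @param window `c(start_s, duration_s)`.
#' @return integral in trace units times seconds.
#' @export
charge_transfer <- function(trace, dt, window, baseline_window) {
  t <- (seq_along(trace) - 1) * dt
  base <- if (length(baseline_window) == 1) baseline_window
          else mean(trace[window_index(t, baseline_window)])
  trapz(trace[window_index(t, window)] - base, dt)
}

#' Inhibition-to-excitation ratio
#'
#' @param exc_response excitatory response magnitude (> 0).
#' @param inh_response inhibitory response magnitude.
#' @return `inh_response / exc_response`.
#' @export
ie_ratio <- function(exc_response, inh_response) {
  if (any(exc_response <= 0)) stop("excitatory response must be positive")
  inh_response / exc_response
}
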