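#' Two-stream spatiotemporal ganglion-cell model
#'
#' Constructs the full spatial-temporal circuit model: lattices of excitatory
#' and inhibitory subunits with distinct difference-of-Gaussians receptive
#' fields and biphasic temporal filters; Gaussian presynaptic pooling of
#' rectified inhibitory subunit outputs onto each excitatory subunit (strength
#' `alpha`, sensitivity `beta`); a per-excitatory-subunit vesicle-depletion
#' synapse; and Gaussian soma-centered pooling of both streams into the
#' ganglion-cell readout `max(0, readout_gain * E_total - I_total)`.
#'
#' Subunit spatial weights are integral-normalized (center and surround
#' Gaussians each normalized before the surround is subtracted with weight
#' `delta`), so a spatially uniform stimulus of contrast c drives every
#' excitatory subunit with c and every inhibitory subunit with `(1 - delta) c`
#' regardless of subunit size - homogeneous stimuli recruit little inhibition
#' when the surround is strong. Pooling weights (presynaptic and readout) are
#' normalized to sum to one, which keeps model output invariant to subunit
#' lattice refinement.
#'
#' @param exc_rf,inh_rf [subunit_rf()] for the two subunit populations
#'   (excitatory default: pure Gaussian, `delta = 0`; inhibitory default:
#'   fine center with strong wide surround).
#' @param spacing subunit lattice spacing, micrometers (both populations).
#' @param pool_sigma soma pooling Gaussian SD, micrometers (RF center scale).
#' @param grid_halfwidth lattice half-extent, micrometers (default 3 pooling
#'   SDs).
#' @param presyn_pool_sigma SD of the Gaussian weighting inhibitory subunits
#'   onto each excitatory subunit. Defaults to the soma pooling SD: the
#'   glycinergic output of the AII amacrine network spreads over roughly the
#'   receptive-field center through gap-junction coupling, well beyond a
#'   single inhibitory subunit.
#' @param synapse a [synapse_params()].
#' @param filters list with `exc` and `inh` [temporal_filter()]s.
#' @param readout_gain spike-proxy gain (default 3).
#' @param dims spatial dimensionality, 1 (grating protocols) or 2 (patches).
#' @param dt simulation time step, seconds.
#' @param rf whole-cell [gaussian_rf()] used for linear-equivalent discs and
#'   the stimulus aperture.
#' @param center model center coordinates, micrometers.
#' @return an object of class `offt_model`.
#' @export
offt_model <- function(exc_rf = subunit_rf(25, 75, 0),
                       inh_rf = subunit_rf(12.5, 50, 0.9),
                       spacing = 15, pool_sigma = 50,
                       grid_halfwidth = 3 * pool_sigma,
                       presyn_pool_sigma = pool_sigma,
                       synapse = calibration_preset(),
                       filters = default_filters(),
                       readout_gain = 3, dims = 2, dt = 1 / 120,
                       rf = gaussian_rf(pool_sigma), center = c(0, 0)) {
  stopifnot(inherits(exc_rf, "subunit_rf"), inherits(inh_rf, "subunit_rf"),
            inherits(synapse, "synapse_params"))
  if (!dims %in% c(1L, 2L)) stop("dims must be 1 or 2")
  ax <- seq(-grid_halfwidth, grid_halfwidth, by = spacing)
  if (dims == 2L) {
    pos <- as.matrix(expand.grid(x = center[1] + ax, y = center[2] + ax))
    r2 <- (pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2
  } else {
    pos <- matrix(center[1] + ax, ncol = 1)
    r2 <- (pos[, 1] - center[1])^2
  }
  wpool <- exp(-r2 / (2 * pool_sigma^2))
  wpool <- wpool / sum(wpool)

  # presynaptic pooling: normalized Gaussian weights, exc rows x inh cols
  d2 <- as.matrix(stats::dist(pos))^2
  Wp <- exp(-d2 / (2 * presyn_pool_sigma^2))
  Wp <- Wp / rowSums(Wp)

  structure(list(exc_rf = exc_rf, inh_rf = inh_rf, positions = pos,
                 spacing = spacing, pool_sigma = pool_sigma,
                 grid_halfwidth = grid_halfwidth,
                 presyn_pool_sigma = presyn_pool_sigma,
                 w_exc = wpool, w_inh = wpool, Wp = Wp,
                 synapse = synapse, filters = filters,
                 readout_gain = readout_gain, dims = as.integer(dims),
                 dt = dt, rf = rf, center = center),
            class = "offt_model")
}

#' @export
print.offt_model <- function(x, ...) {
  cat(sprintf(
    "<offt_model> %d-D, %d subunits per pathway (spacing %g um, pooling sigma %g um)\n",
    x$dims, nrow(x$positions), x$spacing, x$pool_sigma))
  cat(sprintf("  exc subunit: sigma %g um (delta %g); inh subunit: sigma %g/%g um (delta %g)\n",
              x$exc_rf$sigma_center, x$exc_rf$delta, x$inh_rf$sigma_center,
              x$inh_rf$sigma_surround, x$inh_rf$delta))
  print(x$synapse)
  invisible(x)
}

# rebuild a model with modified arguments
update_model <- function(model, ...) {
  args <- list(exc_rf = model$exc_rf, inh_rf = model$inh_rf,
               spacing = model$spacing, pool_sigma = model$pool_sigma,
               grid_halfwidth = model$grid_halfwidth,
               presyn_pool_sigma = model$presyn_pool_sigma,
               synapse = model$synapse, filters = model$filters,
               readout_gain = model$readout_gain, dims = model$dims,
               dt = model$dt, rf = model$rf, center = model$center)
  do.call(offt_model, utils::modifyList(args, list(...)))
}

#' Subunit-to-pixel spatial weight matrices
#'
#' Integral-normalized DoG weights of every subunit on a stimulus grid, for
#' both pathways. Computed once per grid and reusable across stimuli sharing
#' it.
#'
#' @param model an [offt_model()].
#' @param stim a [stimulus_field()] defining the grid (or `x`/`y` directly).
#' @param x,y grid coordinates, micrometers.
#' @return list with matrices `exc` and `inh` (subunits by pixels).
#' @export
spatial_weights <- function(model, stim = NULL, x = NULL, y = NULL) {
  if (!is.null(stim)) {
    co <- field_coords(stim)
    x <- co$x; y <- co$y
  }
  if (model$dims == 2L && is.null(y)) stop("2-D model needs a 2-D grid")
  build <- function(p) {
    # stimuli are aperture-confined, so weights are normalized on the grid;
    # require the grid to hold at least two center SDs around every subunit
    reach <- 2 * p$sigma_center
    if (min(model$positions[, 1]) - reach < min(x) ||
        max(model$positions[, 1]) + reach > max(x))
      stop("stimulus grid does not cover the subunit receptive fields")
    if (model$dims == 2L &&
        (min(model$positions[, 2]) - reach < min(y) ||
         max(model$positions[, 2]) + reach > max(y)))
      stop("stimulus grid does not cover the subunit receptive fields")
    n <- nrow(model$positions)
    npix <- if (model$dims == 2L) length(x) * length(y) else length(x)
    W <- matrix(0, n, npix)
    for (i in seq_len(n)) {
      d2 <- if (model$dims == 2L)
        as.vector(outer((y - model$positions[i, 2])^2,
                        (x - model$positions[i, 1])^2, "+"))
      else (x - model$positions[i, 1])^2
      gc <- exp(-d2 / (2 * p$sigma_center^2))
      w <- gc / sum(gc)
      if (p$delta > 0) {
        gs <- exp(-d2 / (2 * p$sigma_surround^2))
        w <- w - p$delta * gs / sum(gs)
      }
      W[i, ] <- w
    }
    W
  }
  list(exc = build(model$exc_rf), inh = build(model$inh_rf))
}

# flatten stimulus to (pixels x time) drives per subunit; separable stimuli
# reduce to an outer product of spatial drives and a filtered envelope
pathway_drive <- function(stim, W, kernel, dt, pad) {
  if (!is.null(stim$envelope)) {
    d <- as.numeric(W %*% as.vector(stim$values))
    r <- apply_filter(c(rep(0, pad), stim$envelope), kernel, dt)
    d %o% r
  } else {
    S <- if (stim$dims == 2L) {
      dd <- dim(stim$values)
      matrix(stim$values, dd[1] * dd[2], dd[3])
    } else stim$values
    D <- W %*% cbind(matrix(0, nrow(S), pad), S)
    t(apply(D, 1, apply_filter, kernel = kernel, dt = dt))
  }
}

#' Per-subunit inhibitory responses
#'
#' Static LN stage of the inhibitory pathway: each inhibitory subunit's
#' space-time separable kernel (DoG spatial weights times the inhibitory
#' temporal filter) is convolved with the stimulus and half-wave rectified.
#'
#' @param stim a [stimulus_field()] (dimensionality matching the model).
#' @param model an [offt_model()].
#' @param weights optional precomputed [spatial_weights()].
#' @param settle baseline padding before the stimulus, seconds.
#' @return matrix of rectified inhibitory series, subunits by time (stimulus
#'   samples only, padding removed).
#' @export
inhibitory_field <- function(stim, model, weights = NULL,
                             settle = 3 / model$synapse$Krec) {
  if (is.null(weights)) weights <- spatial_weights(model, stim)
  dt <- stim$dt
  pad <- n_steps(settle, dt)
  kinh <- filter_kernel(model$filters$inh, dt)
  I <- pmax(pathway_drive(stim, weights$inh, kinh, dt, pad), 0)
  I[, (pad + 1):ncol(I), drop = FALSE]
}

#' Pool inhibitory subunits onto excitatory subunits
#'
#' Gaussian presynaptic weighting (SD `presyn_pool_sigma`, weights normalized
#' across inhibitory subunits) scaled by the global inhibition strength
#' `alpha`.
#'
#' @param I matrix of inhibitory series (subunits by time) from
#'   [inhibitory_field()].
#' @param model an [offt_model()].
#' @return matrix of pooled inhibition per excitatory subunit (subunits by
#'   time).
#' @export
presynaptic_pool <- function(I, model) {
  model$synapse$alpha * (model$Wp %*% I)
}

#' Per-subunit excitatory outputs under presynaptic inhibition
#'
#' Dynamic LN stage of the excitatory pathway: filtered drive minus pooled
#' inhibition through the piecewise-linear nonlinearity, rectified output
#' scaled by per-subunit vesicle occupancy whose release rate inhibition
#' divisively suppresses.
#'
#' @inheritParams inhibitory_field
#' @param I_eff pooled inhibition from [presynaptic_pool()] (subunits by
#'   time, stimulus samples only).
#' @return list with matrices `Etilde` (synaptic outputs), `n` (occupancies),
#'   `E_raw` (filtered drives), subunits by time.
#' @export
excitatory_field <- function(stim, I_eff, model, weights = NULL,
                             settle = 3 / model$synapse$Krec) {
  if (is.null(weights)) weights <- spatial_weights(model, stim)
  p <- model$synapse
  dt <- stim$dt
  pad <- n_steps(settle, dt)
  kexc <- filter_kernel(model$filters$exc, dt)
  E_raw <- p$E0 + pathway_drive(stim, weights$exc, kexc, dt, pad)
  E_raw <- E_raw[, (pad + 1):ncol(E_raw), drop = FALSE]
  E <- phi(E_raw - I_eff, p$gamma)
  drive <- pmax(E, 0) + p$R0
  rel_mult <- 1 / (1 + p$beta * I_eff)
  n <- vesicle_integrate_matrix(drive, rel_mult, p, dt,
                                n_init = initial_occupancy(p))
  list(Etilde = n * pmax(E, 0) + p$R0, n = n, E_raw = E_raw)
}

#' Ganglion-cell rate readout
#'
#' Rectified weighted combination of the pooled streams:
#' `max(0, gain * E_total - I_total)`.
#'
#' @param E_total,I_total pooled excitatory/inhibitory series.
#' @param gain readout gain on excitation (default 3).
#' @return non-negative rate series.
#' @export
ganglion_readout <- function(E_total, I_total, gain = 3) {
  pmax(0, gain * E_total - I_total)
}

#' Simulate the full model response to a stimulus
#'
#' Runs both streams and the readout; the vesicle state starts at its baseline
#' fixed point and `settle` seconds of zero-contrast baseline are prepended
#' (and discarded) before the stimulus.
#'
#' @inheritParams inhibitory_field
#' @param keep_subunits retain per-subunit matrices in the result's
#'   `"subunits"` attribute.
#' @return a `model_traces` data.frame with `t`, `E_total`, `I_total`,
#'   `n_mean`, `rate`.
#' @export
response_traces <- function(stim, model, weights = NULL,
                            settle = 3 / model$synapse$Krec,
                            keep_subunits = FALSE) {
  stopifnot(inherits(stim, "stimulus_field"), inherits(model, "offt_model"))
  if (stim$dims != model$dims) stop("stimulus/model dimensionality mismatch")
  if (is.null(weights)) weights <- spatial_weights(model, stim)
  I <- inhibitory_field(stim, model, weights, settle)
  I_eff <- presynaptic_pool(I, model)
  ex <- excitatory_field(stim, I_eff, model, weights, settle)
  E_total <- as.numeric(crossprod(model$w_exc, ex$Etilde))
  I_total <- as.numeric(crossprod(model$w_inh, I))
  df <- data.frame(t = (seq_along(E_total) - 1) * stim$dt,
                   E_total = E_total, I_total = I_total,
                   n_mean = colMeans(ex$n),
                   rate = ganglion_readout(E_total, I_total,
                                           model$readout_gain))
  out <- new_model_traces(df, stim$dt, model$synapse)
  if (keep_subunits)
    attr(out, "subunits") <- list(I = I, I_eff = I_eff, Etilde = ex$Etilde,
                                  n = ex$n, E_raw = ex$E_raw)
  out
}

#' @export
predict.offt_model <- function(object, stimulus, ...) {
  response_traces(stimulus, object, ...)
}

# mask a frame to the whole-cell aperture (background outside)
aperture_mask <- function(frame, dx, rf) {
  x <- grid_coords(ncol(frame), dx)
  y <- grid_coords(nrow(frame), dx)
  r2 <- outer((y - rf$center[2])^2, (x - rf$center[1])^2, "+")
  frame * (r2 <= (rf$aperture_diameter / 2)^2)
}

# separable flashed presentation of a static frame
flashed_frame <- function(frame, dx, dt, pre, duration, post) {
  env <- c(rep(0, n_steps(pre, dt)), rep(1, n_steps(duration, dt)),
           rep(0, n_steps(post, dt)))
  stimulus_field(frame, dx = dx, dt = dt, dims = 2, envelope = env)
}

#' Image-versus-disc experiment
#'
#' Presents each synthetic patch and its linear-equivalent disc as flashed
#' stimuli confined to the whole-cell aperture, and quantifies nonlinear
#' spatial integration with onset and offset nonlinearity indices. The
#' response scalar is the time integral of the readout rate over the window
#' (onset window = flash duration; offset window = same length from flash
#' offset). Offset NLIs can additionally be subjected to the low-response
#' exclusion rule via `offset_exclusion_threshold` (in rate-integral units; 0
#' disables it - the printed rule applies to spike counts).
#'
#' @param model an [offt_model()] (2-D).
#' @param pairs list of `patch_pair`s from [make_synthetic_patch()] /
#'   [sample_patch_pairs()], all on one grid.
#' @param flash_duration flash length, seconds.
#' @param pre pre-stimulus baseline, seconds.
#' @param offset_exclusion_threshold exclusion threshold for offset responses.
#' @return data.frame (class `nli_result`) with one row per pair:
#'   `patch_id`, `structure_level`, onset/offset responses for image and disc,
#'   `nli_onset`, `nli_offset`, `excluded_offset`.
#' @export
image_vs_disc_experiment <- function(model, pairs, flash_duration = 0.3,
                                     pre = 0.3,
                                     offset_exclusion_threshold = 0) {
  stopifnot(inherits(model, "offt_model"), model$dims == 2L)
  dt <- model$dt
  post <- flash_duration
  frame0 <- pairs[[1]]$patch$values
  dx <- pairs[[1]]$patch$dx
  weights <- spatial_weights(
    model, x = grid_coords(ncol(frame0), dx), y = grid_coords(nrow(frame0), dx))
  on_w <- c(pre, flash_duration)
  off_w <- c(pre + flash_duration, flash_duration)

  rows <- lapply(seq_along(pairs), function(i) {
    pp <- pairs[[i]]
    patch_frame <- aperture_mask(pp$patch$values, dx, model$rf)
    disc_frame <- aperture_mask(
      matrix(pp$disc_intensity, nrow(patch_frame), ncol(patch_frame)),
      dx, model$rf)
    resp <- lapply(list(patch_frame, disc_frame), function(fr) {
      tr <- response_traces(flashed_frame(fr, dx, dt, pre, flash_duration,
                                          post), model, weights)
      c(on = trapz(tr$rate[window_index(tr$t, on_w)], dt),
        off = trapz(tr$rate[window_index(tr$t, off_w)], dt))
    })
    data.frame(patch_id = i, structure_level = pp$structure_level,
               r_image_on = resp[[1]]["on"], r_disc_on = resp[[2]]["on"],
               r_image_off = resp[[1]]["off"], r_disc_off = resp[[2]]["off"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$nli_onset <- nli(out$r_image_on, out$r_disc_on)
  offr <- offset_nli_with_exclusion(out$r_image_off, out$r_disc_off,
                                    threshold = offset_exclusion_threshold)
  out$nli_offset <- offr$nli
  out$excluded_offset <- offr$excluded
  class(out) <- c("nli_result", "data.frame")
  out
}

#' Inhibition-strength sweep of the image-versus-disc experiment
#'
#' @param model an [offt_model()].
#' @param pairs patch pairs as in [image_vs_disc_experiment()].
#' @param alphas inhibition strengths to test.
#' @param ... passed to [image_vs_disc_experiment()].
#' @return data.frame with `alpha`, `mean_nli_onset`, `mean_nli_offset`, and
#'   attribute `"results"` holding the per-patch tables.
#' @export
nli_alpha_sweep <- function(model, pairs, alphas = c(0.1, 0.4, 0.8), ...) {
  results <- lapply(alphas, function(a) {
    syn <- do.call(synapse_params,
                   utils::modifyList(unclass(model$synapse), list(alpha = a)))
    image_vs_disc_experiment(update_model(model, synapse = syn), pairs, ...)
  })
  out <- data.frame(
    alpha = alphas,
    mean_nli_onset = vapply(results, function(r) mean(r$nli_onset), 0),
    mean_nli_offset = vapply(results, function(r) mean(r$nli_offset), 0))
  attr(out, "results") <- results
  out
}

#' Inhibitory/excitatory subunit size-ratio sweep
#'
#' Rescales the inhibitory subunit center SD to `ratio` times the excitatory
#' center SD (the surround scales proportionally; the presynaptic pooling
#' spread, a property of the amacrine network rather than of single subunits,
#' stays fixed) and reruns the image-versus-disc experiment.
#'
#' @inheritParams nli_alpha_sweep
#' @param ratios inhibitory/excitatory subunit size ratios (> 0).
#' @return data.frame with `ratio`, `mean_nli_onset`, `mean_nli_offset`, and
#'   attribute `"results"`.
#' @export
subunit_size_ratio_sweep <- function(model, pairs, ratios = c(0.8, 2, 4),
                                     ...) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  ss_ratio <- model$inh_rf$sigma_surround / model$inh_rf$sigma_center
  results <- lapply(ratios, function(r) {
    sc <- r * model$exc_rf$sigma_center
    m <- update_model(model,
                      inh_rf = subunit_rf(sc, ss_ratio * sc,
                                          model$inh_rf$delta))
    image_vs_disc_experiment(m, pairs, ...)
  })
  out <- data.frame(
    ratio = ratios,
    mean_nli_onset = vapply(results, function(r) mean(r$nli_onset), 0),
    mean_nli_offset = vapply(results, function(r) mean(r$nli_offset), 0))
  attr(out, "results") <- results
  out
}
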