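#' Space-time stimulus container
#'
#' A `stimulus_field` holds luminance contrast (Weber units, \eqn{(I -
#' I_{bg})/I_{bg}}) on a regular grid. One-dimensional fields store a
#' space-by-time matrix; two-dimensional fields store either a static frame
#' (matrix) or a y-by-x-by-time array. Contrast cannot fall below -1 (zero
#' luminance).
#'
#' @param values numeric matrix (1-D: space x time; 2-D static frame: y x x)
#'   or 3-D array (y x x x time) of Weber contrasts.
#' @param dx spatial step in micrometers (> 0).
#' @param dt time step in seconds (> 0).
#' @param background mean luminance the contrasts are relative to (metadata;
#'   arbitrary units, e.g. R*/rod/s).
#' @param dims number of spatial dimensions, 1 or 2.
#' @param envelope optional temporal contrast envelope for separable stimuli
#'   (static frame times a time course); when supplied, `values` must be a
#'   single spatial frame.
#' @return an object of class `stimulus_field`.
#' @export
stimulus_field <- function(values, dx, dt, background = 1, dims = 1,
                           envelope = NULL) {
  if (!is.numeric(values)) stop("values must be numeric")
  if (!all(is.finite(values))) stop("stimulus values must all be finite")
  if (any(values < -1)) stop("contrast below -1 (luminance cannot be negative)")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0) stop("dx must be > 0")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  if (!dims %in% c(1L, 2L)) stop("dims must be 1 or 2")
  if (!is.null(envelope)) {
    if (!all(is.finite(envelope))) stop("envelope must be finite")
    if (dims == 2L && !is.matrix(values))
      stop("separable 2-D stimulus requires a single frame matrix")
    if (dims == 1L && !is.null(dim(values)) && ncol(values) != 1L)
      stop("separable 1-D stimulus requires a single spatial profile")
  }
  structure(
    list(values = values, dx = dx, dt = dt, background = background,
         dims = as.integer(dims), envelope = envelope),
    class = "stimulus_field"
  )
}

#' @export
print.stimulus_field <- function(x, ...) {
  d <- dim(x$values)
  if (is.null(d)) d <- length(x$values)
  cat("<stimulus_field> dims:", x$dims,
      " size:", paste(d, collapse = " x "),
      if (!is.null(x$envelope)) sprintf(" (separable, %d time steps)",
                                        length(x$envelope)) else "",
      "\n  dx:", x$dx, "um  dt:", signif(x$dt, 4), "s  background:",
      x$background, "\n")
  invisible(x)
}

# centered grid coordinates (cell centers), micrometers
grid_coords <- function(n, dx) (seq_len(n) - (n + 1) / 2) * dx

# number of samples covering a duration
n_steps <- function(duration, dt) max(1L, as.integer(round(duration / dt)))

# square-wave grating profile on centered coordinates; bars of equal width,
# first bar starting at the left field edge (plus optional phase shift, um)
square_grating_profile <- function(x, bar_width, contrast, phase = 0) {
  left <- min(x) - 0.5 * (x[2] - x[1])
  idx <- floor((x - left - phase) / bar_width)
  contrast * ifelse(idx %% 2 == 0, 1, -1)
}

#' Flashed square-wave grating (1-D)
#'
#' Equal bright/dark bars at the given Weber contrast, shown for
#' `flash_duration` seconds between zero-contrast baseline segments. When the
#' field extent holds an even number of bars the spatial mean contrast during
#' the flash is exactly zero.
#'
#' @param bar_width bar width, micrometers (> 0).
#' @param contrast Weber contrast of the bright bars, |contrast| <= 1.
#' @param flash_duration flash length, seconds.
#' @param baseline pre-flash baseline, seconds.
#' @param field_extent total spatial extent, micrometers (>= 2 bar widths).
#' @param post post-flash baseline, seconds (defaults to `baseline`).
#' @param dx,dt grid steps (um, s). `dx` should divide `bar_width`.
#' @param phase spatial phase shift of the bar pattern, micrometers.
#' @return a 1-D [stimulus_field()].
#' @export
make_flashed_grating <- function(bar_width, contrast, flash_duration = 0.5,
                                 baseline = 0.5, field_extent = 800,
                                 post = baseline, dx = 2, dt = 1 / 60,
                                 phase = 0) {
  if (bar_width <= 0) stop("bar_width must be positive")
  if (abs(contrast) > 1) stop("contrast out of range [-1, 1]")
  if (field_extent < 2 * bar_width)
    stop("field_extent must cover at least two bars")
  x <- grid_coords(round(field_extent / dx), dx)
  s <- square_grating_profile(x, bar_width, contrast, phase)
  nt <- n_steps(baseline + flash_duration + post, dt)
  t <- (seq_len(nt) - 1) * dt
  b <- as.numeric(t >= baseline & t < baseline + flash_duration)
  stimulus_field(outer(s, b), dx = dx, dt = dt, dims = 1)
}

#' Contrast-reversing grating (1-D)
#'
#' Every pixel's time course is a square-wave (or sinusoidal) modulation at
#' `temporal_freq`; the temporal mean at each pixel over integer reversal
#' cycles is zero.
#'
#' @inheritParams make_flashed_grating
#' @param temporal_freq reversal frequency, Hz (> 0).
#' @param duration total duration, seconds (must cover >= 2 full cycles).
#' @param waveform `"square"` (default, matching bar-reversal protocols) or
#'   `"sine"` for analytic tests.
#' @return a 1-D [stimulus_field()].
#' @export
make_contrast_reversing_grating <- function(bar_width, temporal_freq = 2,
                                            contrast = 0.9, duration = 2,
                                            field_extent = 800, dx = 2,
                                            dt = 1 / 60, phase = 0,
                                            waveform = c("square", "sine")) {
  waveform <- match.arg(waveform)
  if (bar_width <= 0) stop("bar_width must be positive")
  if (abs(contrast) > 1) stop("contrast out of range [-1, 1]")
  if (temporal_freq <= 0) stop("temporal_freq must be positive")
  if (duration < 2 / temporal_freq)
    stop("duration must cover at least two full cycles")
  x <- grid_coords(round(field_extent / dx), dx)
  s <- square_grating_profile(x, bar_width, contrast, phase)
  nt <- n_steps(duration, dt)
  t <- (seq_len(nt) - 1) * dt
  m <- switch(waveform,
              square = ifelse((t * temporal_freq) %% 1 < 0.5, 1, -1),
              sine   = sin(2 * pi * temporal_freq * t))
  stimulus_field(outer(s, m), dx = dx, dt = dt, dims = 1)
}

# piecewise-constant contrast time series from (duration, contrast) segments
segments_to_series <- function(segments, dt) {
  unlist(lapply(segments, function(seg) {
    rep(seg[[2]], n_steps(seg[[1]], dt))
  }), use.names = FALSE)
}

#' Paired-pulse stimulus
#'
#' Spatially uniform field: baseline, first pulse, intervening contrast step,
#' second (identical) pulse, post-baseline. Default values follow the standard
#' paired dark-pulse protocol: two 300 ms pulses at -90% contrast separated by
#' a 500 ms interval.
#'
#' @param pulse_contrast Weber contrast of both pulses (>= -1).
#' @param pulse_duration pulse length, seconds (> 0).
#' @param interval_contrast contrast during the intervening step.
#' @param interval_duration interval length, seconds (> 0).
#' @param baseline,post leading/trailing zero-contrast segments, seconds.
#' @param field_extent,dx,dt grid geometry as in [make_flashed_grating()].
#' @return a 1-D [stimulus_field()] with attribute `"protocol"` describing the
#'   segment boundaries (a `protocol_spec`).
#' @export
make_paired_pulse <- function(pulse_contrast = -0.9, pulse_duration = 0.3,
                              interval_contrast = 0, interval_duration = 0.5,
                              baseline = 0.5, post = 1, field_extent = 800,
                              dx = 2, dt = 1 / 60) {
  if (pulse_duration <= 0 || interval_duration <= 0)
    stop("pulse and interval durations must be positive")
  if (pulse_contrast < -1 || interval_contrast < -1)
    stop("contrast below -1")
  segs <- list(c(baseline, 0), c(pulse_duration, pulse_contrast),
               c(interval_duration, interval_contrast),
               c(pulse_duration, pulse_contrast), c(post, 0))
  series <- segments_to_series(segs, dt)
  x <- grid_coords(round(field_extent / dx), dx)
  out <- stimulus_field(matrix(series, nrow = length(x),
                               ncol = length(series), byrow = TRUE),
                        dx = dx, dt = dt, dims = 1)
  attr(out, "protocol") <- protocol_spec(
    name = "paired_pulse",
    segments = segs[2:4],
    pre = baseline, post = post
  )
  out
}

#' Protocol description
#'
#' Lightweight record of a stimulus protocol's segment geometry (ordered
#' durations and contrasts plus leading/trailing baselines), used to locate
#' response windows.
#'
#' @param name protocol identifier.
#' @param segments list of `c(duration_s, contrast)` pairs.
#' @param pre,post baseline durations, seconds.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(name, segments, pre = 0.5, post = 0.5) {
  durs <- vapply(segments, function(s) s[[1]], numeric(1))
  if (any(durs <= 0) || pre < 0 || post < 0)
    stop("protocol durations must be positive")
  structure(list(name = name, segments = segments, pre = pre, post = post),
            class = "protocol_spec")
}

#' Uniform spot stimulus (2-D)
#'
#' A uniform disc of the given diameter and contrast centered on the grid,
#' zero contrast outside, shown for `duration` seconds.
#'
#' @param diameter spot diameter, micrometers (>= 0).
#' @param contrast Weber contrast of the spot.
#' @param duration presentation time, seconds.
#' @param field_extent,dx,dt grid geometry; default 2-D pixel scale 6.6 um.
#' @return a separable 2-D [stimulus_field()] (frame plus box envelope).
#' @export
make_spot <- function(diameter, contrast, duration = 0.5, field_extent = 660,
                      dx = 6.6, dt = 1 / 60) {
  if (diameter < 0) stop("diameter must be non-negative")
  if (contrast < -1) stop("contrast below -1")
  x <- grid_coords(round(field_extent / dx), dx)
  r <- sqrt(outer(x^2, x^2, "+"))
  frame <- ifelse(r <= diameter / 2, contrast, 0)
  stimulus_field(frame, dx = dx, dt = dt, dims = 2,
                 envelope = rep(1, n_steps(duration, dt)))
}

#' Extract the contrast time course at one location
#'
#' @param stim a [stimulus_field()].
#' @param index spatial index (row for 1-D; `c(row, col)` for 2-D). Defaults
#'   to the grid center.
#' @return numeric vector of contrasts over time.
#' @export
contrast_series <- function(stim, index = NULL) {
  stopifnot(inherits(stim, "stimulus_field"))
  if (!is.null(stim$envelope)) {
    v <- if (stim$dims == 2L) {
      if (is.null(index)) index <- ceiling(dim(stim$values) / 2)
      stim$values[index[1], index[2]]
    } else {
      if (is.null(index)) index <- ceiling(length(stim$values) / 2)
      stim$values[index[1]]
    }
    return(v * stim$envelope)
  }
  if (stim$dims == 1L) {
    if (is.null(index)) index <- ceiling(nrow(stim$values) / 2)
    stim$values[index[1], ]
  } else {
    if (is.null(index)) index <- ceiling(dim(stim$values)[1:2] / 2)
    stim$values[index[1], index[2], ]
  }
}

#' Write / read a 1-D stimulus as delimited text
#'
#' Tab-separated values with one row per spatial sample and one column per
#' time step; grid metadata is stored in `#`-prefixed header lines, making the
#' file self-describing.
#'
#' @param stim a 1-D [stimulus_field()].
#' @param path file path.
#' @return `write_stimulus_field` returns `path` invisibly;
#'   `read_stimulus_field` returns the reconstructed [stimulus_field()].
#' @export
write_stimulus_field <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_field"), stim$dims == 1L,
            is.null(stim$envelope))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dx=%.10g dt=%.10g background=%.10g dims=1",
                     stim$dx, stim$dt, stim$background), con)
  utils::write.table(stim$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_field
#' @export
read_stimulus_field <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("missing stimulus metadata header")
  kv <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  values <- as.matrix(utils::read.table(path, sep = "\t", skip = 1L))
  dimnames(values) <- NULL
  stimulus_field(values, dx = meta[["dx"]], dt = meta[["dt"]],
                 background = meta[["background"]], dims = 1)
}
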