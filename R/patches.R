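#' Synthetic natural-image-like patch with its linear-equivalent disc
#'
#' Generates a seeded 2-D texture emulating a natural image patch: a Gaussian
#' random field with a power-law (1/f-like) spatial amplitude spectrum is
#' passed through an exponential point nonlinearity (natural luminance is
#' log-normal, so patches are bright-skewed: sparse bright points over broad
#' shallow dark regions), then scaled linearly by `structure_level` and offset
#' so that its Gaussian-weighted mean (the linear-equivalent disc intensity)
#' equals `mean_contrast` exactly. The
#' zero-mean texture component is normalized per seed so the darkest pixel at
#' `structure_level = 1` sits 95% of the way from `mean_contrast` to the
#' zero-luminance floor, keeping the field above -1 contrast without clipping
#' (which would bias the weighted mean).
#'
#' @param structure_level amount of spatial structure in `[0, 1]`; 0 gives a
#'   uniform patch, amplitude scales linearly (doubling `structure_level`
#'   doubles the pixel standard deviation).
#' @param mean_contrast target Gaussian-weighted mean Weber contrast.
#' @param seed integer RNG seed (required when `structure_level > 0`).
#' @param scale pixel size, micrometers (default 6.6, the retinal scale at
#'   which natural patches are displayed).
#' @param extent patch side length, micrometers.
#' @param rf [gaussian_rf()] used for the linear-equivalent weighting.
#' @param spectrum_exponent spectral amplitude falls as
#'   `frequency^-spectrum_exponent` (default 1, natural-image-like).
#' @param log_amplitude SD of the log-luminance field before exponentiation
#'   (default 0.5); controls the bright skew of the texture. 0 gives a
#'   symmetric Gaussian field.
#' @return an object of class `patch_pair`: list with elements `patch` (a 2-D
#'   [stimulus_field()] frame), `disc_intensity`, `structure_score`, `seed`,
#'   and the generating arguments.
#' @export
make_synthetic_patch <- function(structure_level, mean_contrast = 0,
                                 seed = NULL, scale = 6.6, extent = 726,
                                 rf = gaussian_rf(50),
                                 spectrum_exponent = 1, log_amplitude = 0.5) {
  if (structure_level < 0 || structure_level > 1)
    stop("structure_level must lie in [0, 1]")
  if (structure_level > 0 && is.null(seed))
    stop("seed is required when structure_level > 0")
  n <- round(extent / scale)
  x <- grid_coords(n, scale)
  w <- rf_weights(x, x, rf)

  if (structure_level == 0) {
    frame <- matrix(mean_contrast, n, n)
  } else {
    if (mean_contrast <= -1) stop("mean_contrast must exceed -1")
    base <- with_seed(seed, power_law_texture(n, spectrum_exponent))
    if (log_amplitude > 0) base <- exp(log_amplitude * base)
    base <- base - sum(w * base)            # exact zero weighted mean
    # headroom: darkest pixel at structure_level = 1 sits 95% of the way to
    # the zero-luminance floor; amplitude stays linear in structure_level
    base <- base * (0.95 * (1 + mean_contrast) / max(-min(base), 1e-12))
    frame <- mean_contrast + structure_level * base
  }
  patch <- stimulus_field(frame, dx = scale, dt = 1 / 60, dims = 2)
  disc <- if (structure_level == 0) mean_contrast
          else linear_equivalent_intensity(patch, rf)
  structure(list(patch = patch,
                 disc_intensity = disc,
                 structure_score = patch_structure_score(patch, rf),
                 seed = seed, structure_level = structure_level,
                 mean_contrast = mean_contrast, rf = rf),
            class = "patch_pair")
}

# Gaussian random field with amplitude spectrum ~ f^-exponent, unit-free scale
power_law_texture <- function(n, exponent) {
  z <- matrix(stats::rnorm(n * n), n, n)
  Z <- stats::fft(z)
  fi <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n
  f <- sqrt(outer(fi^2, fi^2, "+"))
  amp <- ifelse(f > 0, f^(-exponent), 0)
  tex <- Re(stats::fft(Z * amp, inverse = TRUE)) / (n * n)
  tex / stats::sd(tex)
}

#' @export
print.patch_pair <- function(x, ...) {
  cat(sprintf(
    "<patch_pair> %dx%d px, structure_level=%.3g, disc intensity=%.4g, structure score=%.4g\n",
    nrow(x$patch$values), ncol(x$patch$values), x$structure_level,
    x$disc_intensity, x$structure_score))
  invisible(x)
}

#' Spatial-structure score of a patch
#'
#' Absolute difference between the responses of a spatially nonlinear
#' (rectified-subunit) and a spatially linear receptive-field model to the
#' same patch: the statistic used to place image patches on the
#' linear-to-nonlinear spectrum. Both models use Off-pathway sign (negative
#' contrast drives) and half-wave rectified outputs; subunit weights and
#' pooling weights are normalized so the two models agree exactly on
#' spatially uniform patches.
#'
#' @param patch 2-D frame: matrix or single-frame [stimulus_field()].
#' @param rf whole-cell [gaussian_rf()] (pooling and the linear model).
#' @param subunits [subunit_rf()] for the nonlinear model's subunits.
#' @param spacing subunit lattice spacing, micrometers.
#' @param dx pixel size when `patch` is a bare matrix.
#' @return non-negative scalar; zero for uniform patches.
#' @export
patch_structure_score <- function(patch, rf,
                                  subunits = subunit_rf(25, 75, 0),
                                  spacing = 25, dx = NULL) {
  if (inherits(patch, "stimulus_field")) {
    dx <- patch$dx
    frame <- patch$values
  } else {
    if (is.null(dx)) stop("dx required when patch is a bare matrix")
    frame <- patch
  }
  x <- grid_coords(ncol(frame), dx)
  y <- grid_coords(nrow(frame), dx)
  half <- rf$aperture_diameter / 2
  if (half > max(x) || half > max(y)) stop("patch grid does not cover the RF")
  pos <- as.matrix(expand.grid(
    x = seq(-half, half, by = spacing), y = seq(-half, half, by = spacing)))
  pos <- pos[pos[, 1]^2 + pos[, 2]^2 <= half^2, , drop = FALSE]

  # per-subunit local weighted mean (weights normalized to sum 1)
  drives <- vapply(seq_len(nrow(pos)), function(i) {
    d2 <- outer((y - pos[i, 2])^2, (x - pos[i, 1])^2, "+")
    wsub <- exp(-d2 / (2 * subunits$sigma_center^2))
    if (subunits$delta > 0)
      wsub <- wsub / sum(wsub) -
        subunits$delta * {
          ws <- exp(-d2 / (2 * subunits$sigma_surround^2)); ws / sum(ws)
        }
    else wsub <- wsub / sum(wsub)
    s <- sum(wsub * frame)
    if (subunits$delta > 0) s / (1 - subunits$delta) else s
  }, numeric(1))

  pool <- exp(-(pos[, 1]^2 + pos[, 2]^2) / (2 * rf$sigma_center^2))
  pool <- pool / sum(pool)
  lin_input <- sum(pool * drives)
  nonlinear <- sum(pool * pmax(0, -drives))   # Off sign, rectified subunits
  linear <- max(0, -lin_input)
  abs(nonlinear - linear)
}

#' Sample a set of patch/disc pairs across the structure spectrum
#'
#' Draws `n` seeded synthetic patches whose structure levels tile the
#' linear-to-nonlinear spectrum evenly and whose mean contrasts are sampled
#' uniformly from `mean_contrast_range` (weakly negative on average, the
#' regime that drives Off cells).
#'
#' @param n number of pairs (>= 1).
#' @param seed root RNG seed; pair `i` uses `seed + i`.
#' @param rf [gaussian_rf()] for disc construction.
#' @param structure_range range of structure levels tiled evenly.
#' @param mean_contrast_range range from which mean contrasts are drawn.
#' @param ... passed to [make_synthetic_patch()].
#' @return list of [make_synthetic_patch()] results (class `patch_pair`).
#' @export
sample_patch_pairs <- function(n = 30, seed = 1, rf = gaussian_rf(50),
                               structure_range = c(0.2, 1),
                               mean_contrast_range = c(-0.35, 0.05), ...) {
  stopifnot(n >= 1)
  levels <- seq(structure_range[1], structure_range[2], length.out = n)
  means <- with_seed(seed, stats::runif(n, mean_contrast_range[1],
                                        mean_contrast_range[2]))
  lapply(seq_len(n), function(i) {
    make_synthetic_patch(structure_level = levels[i], mean_contrast = means[i],
                         seed = seed + i, rf = rf, ...)
  })
}
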