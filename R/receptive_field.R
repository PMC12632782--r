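#' Circular Gaussian receptive-field description
#'
#' The whole-cell receptive-field center is modelled as an isotropic Gaussian.
#' Following the standard aperture convention, the aperture diameter equals
#' the Gaussian's two-standard-deviation span on each side of the center
#' (diameter = 4 sigma by default).
#'
#' @param sigma_center Gaussian SD, micrometers (> 0).
#' @param center RF center coordinates, micrometers (length 1 or 2).
#' @param aperture_diameter stimulus aperture diameter, micrometers.
#' @return an object of class `gaussian_rf`.
#' @export
gaussian_rf <- function(sigma_center, center = c(0, 0),
                        aperture_diameter = 4 * sigma_center) {
  if (sigma_center <= 0) stop("sigma_center must be positive")
  if (aperture_diameter <= 0) stop("aperture_diameter must be positive")
  structure(list(sigma_center = sigma_center, center = center,
                 aperture_diameter = aperture_diameter),
            class = "gaussian_rf")
}

#' Gaussian receptive-field weights on a grid
#'
#' Isotropic Gaussian evaluated at grid cell centers, truncated at the
#' aperture and renormalized to sum to one (so a spatially uniform patch has a
#' linear-equivalent intensity equal to its own contrast, exactly).
#'
#' @param x,y grid coordinates (cell centers, micrometers); `y = NULL` for a
#'   1-D grid.
#' @param rf a [gaussian_rf()].
#' @return weight vector (1-D) or matrix (2-D, y rows by x columns) summing
#'   to 1; zero outside the aperture.
#' @export
rf_weights <- function(x, y = NULL, rf) {
  stopifnot(inherits(rf, "gaussian_rf"))
  half <- rf$aperture_diameter / 2
  if (is.null(y)) {
    cx <- rf$center[1]
    if (cx - half < min(x) || cx + half > max(x))
      stop("aperture exceeds grid extent")
    d2 <- (x - cx)^2
  } else {
    cx <- rf$center[1]; cy <- rf$center[2]
    if (cx - half < min(x) || cx + half > max(x) ||
        cy - half < min(y) || cy + half > max(y))
      stop("aperture exceeds grid extent")
    d2 <- outer((y - cy)^2, (x - cx)^2, "+")
  }
  w <- exp(-d2 / (2 * rf$sigma_center^2))
  w[d2 > half^2] <- 0
  w / sum(w)
}

# coordinates of a stimulus_field grid
field_coords <- function(stim) {
  if (stim$dims == 1L) {
    n <- if (is.matrix(stim$values)) nrow(stim$values) else length(stim$values)
    list(x = grid_coords(n, stim$dx), y = NULL)
  } else {
    d <- dim(stim$values)
    list(x = grid_coords(d[2], stim$dx), y = grid_coords(d[1], stim$dx))
  }
}

#' Linear-equivalent disc intensity of an image patch
#'
#' The Gaussian-weighted mean pixel contrast of a patch: the intensity of the
#' spatially uniform disc that a linearly integrating receptive field cannot
#' distinguish from the patch.
#'
#' @param patch a static 2-D frame: a matrix of Weber contrasts or a 2-D
#'   [stimulus_field()] (single frame).
#' @param rf a [gaussian_rf()] on the same grid scale.
#' @param dx pixel size in micrometers (taken from `patch` when it is a
#'   `stimulus_field`).
#' @return scalar equivalent contrast.
#' @export
linear_equivalent_intensity <- function(patch, rf, dx = NULL) {
  if (inherits(patch, "stimulus_field")) {
    if (patch$dims != 2L || !is.matrix(patch$values))
      stop("patch must be a single 2-D frame")
    dx <- patch$dx
    frame <- patch$values
  } else {
    if (!is.matrix(patch)) stop("patch must be a matrix or 2-D stimulus_field")
    if (is.null(dx)) stop("dx required when patch is a bare matrix")
    frame <- patch
  }
  w <- rf_weights(grid_coords(ncol(frame), dx), grid_coords(nrow(frame), dx),
                  rf)
  sum(w * frame)
}

#' Difference-of-Gaussians area-summation parameters
#'
#' Parameters of the classical DoG model for the response to centered uniform
#' spots of increasing radius r:
#' \deqn{R(r) = K_c (1 - e^{-r^2/(2\sigma_c^2)}) - K_s (1 - e^{-r^2/(2\sigma_s^2)}) + R_0}
#'
#' @param Kc,Ks center and surround scaling strengths (>= 0).
#' @param sigma_c,sigma_s center and surround radii, micrometers
#'   (`sigma_s > sigma_c > 0`).
#' @param R0 spontaneous response.
#' @return an object of class `dog_area_params`.
#' @export
dog_area_params <- function(Kc, Ks, sigma_c, sigma_s, R0 = 0) {
  if (Kc < 0 || Ks < 0) stop("Kc and Ks must be non-negative")
  if (!(sigma_s > sigma_c && sigma_c > 0))
    stop("require sigma_s > sigma_c > 0")
  structure(list(Kc = Kc, Ks = Ks, sigma_c = sigma_c, sigma_s = sigma_s,
                 R0 = R0),
            class = "dog_area_params")
}

#' Area-summation response to a spot of radius r
#'
#' @param r spot radius, micrometers (>= 0); vectorized.
#' @param p a [dog_area_params()].
#' @return predicted response(s).
#' @export
area_summation_response <- function(r, p) {
  stopifnot(inherits(p, "dog_area_params"))
  if (any(r < 0)) stop("radius must be non-negative")
  p$Kc * (1 - exp(-r^2 / (2 * p$sigma_c^2))) -
    p$Ks * (1 - exp(-r^2 / (2 * p$sigma_s^2))) + p$R0
}

# residual function over the free parametrization
# theta = (Kc, Ks, sigma_c, dsig, R0), sigma_s = sigma_c + dsig
dog_area_residuals <- function(theta, radii, responses) {
  p <- list(Kc = theta[1], Ks = theta[2], sigma_c = theta[3],
            sigma_s = theta[3] + theta[4], R0 = theta[5])
  pred <- p$Kc * (1 - exp(-radii^2 / (2 * p$sigma_c^2))) -
    p$Ks * (1 - exp(-radii^2 / (2 * p$sigma_s^2))) + p$R0
  responses - pred
}

#' Fit the DoG area-summation model
#'
#' Bounded Levenberg-Marquardt least squares on responses to spots of varying
#' radius, with multiple deterministic starting points to avoid the
#' center/surround strength degeneracy. The surround radius is parametrized as
#' `sigma_c + dsig` (`dsig > 0`) so the ordering constraint holds throughout.
#'
#' @param radii spot radii, micrometers (>= 5 distinct values).
#' @param responses measured responses, same length.
#' @param init optional [dog_area_params()] starting point (tried in addition
#'   to the internal heuristics).
#' @return an object of class `dog_area_fit` with methods [coef()],
#'   [predict()], [residuals()] and [print()].
#' @export
fit_area_summation <- function(radii, responses, init = NULL) {
  if (length(radii) != length(responses)) stop("length mismatch")
  if (length(unique(radii)) < 5)
    stop("need at least 5 distinct radii spanning rise and saturation")
  if (any(radii < 0)) stop("radii must be non-negative")
  rng <- diff(range(responses))
  if (rng < 1e-10 * max(1, max(abs(responses))))
    stop("responses are flat across radii: area-summation parameters are ",
         "not identifiable")

  ord <- order(radii)
  r <- radii[ord]; y <- responses[ord]
  R0_init <- y[1]
  peak <- max(y)
  # radius at half of the rise toward the peak
  half_r <- r[which(y >= R0_init + 0.5 * (peak - R0_init))[1]]
  if (is.na(half_r) || half_r <= 0) half_r <- stats::median(r[r > 0])
  starts <- lapply(c(0.5, 1, 2), function(f) {
    c(Kc = peak - R0_init, Ks = max(peak - y[length(y)], 0.1 * (peak - R0_init)),
      sigma_c = f * half_r / 1.18, dsig = 2 * f * half_r, R0 = R0_init)
  })
  if (!is.null(init)) {
    stopifnot(inherits(init, "dog_area_params"))
    starts <- c(starts, list(c(Kc = init$Kc, Ks = init$Ks,
                               sigma_c = init$sigma_c,
                               dsig = init$sigma_s - init$sigma_c,
                               R0 = init$R0)))
  }
  lower <- c(0, 0, 1e-3, 1e-3, -Inf)
  eps <- sqrt(.Machine$double.eps)
  best <- NULL
  for (th0 in starts) {
    th0 <- pmax(th0, lower + eps)
    fit <- try(minpack.lm::nls.lm(
      par = th0, lower = lower, fn = dog_area_residuals,
      radii = r, responses = y,
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("area-summation fit failed from all starting points")
  th <- best$fit$par
  params <- dog_area_params(Kc = th[[1]], Ks = th[[2]], sigma_c = th[[3]],
                            sigma_s = th[[3]] + th[[4]], R0 = th[[5]])
  if (!is.null(init)) {
    rss_init <- sum(dog_area_residuals(
      c(init$Kc, init$Ks, init$sigma_c, init$sigma_s - init$sigma_c,
        init$R0), r, y)^2)
    if (best$rss > rss_init + 1e-8 * (1 + rss_init))
      warning("fit residual exceeds residual at supplied init")
  }
  structure(list(params = params, radii = radii, responses = responses,
                 fitted = area_summation_response(radii, params),
                 rss = best$rss, info = best$fit$info,
                 message = best$fit$message),
            class = "dog_area_fit")
}

#' @export
coef.dog_area_fit <- function(object, ...) {
  unlist(object$params[c("Kc", "Ks", "sigma_c", "sigma_s", "R0")])
}

#' @export
predict.dog_area_fit <- function(object, newdata = NULL, ...) {
  r <- if (is.null(newdata)) object$radii
       else if (is.list(newdata)) newdata$radii else newdata
  area_summation_response(r, object$params)
}

#' @export
residuals.dog_area_fit <- function(object, ...) {
  object$responses - object$fitted
}

#' @export
print.dog_area_fit <- function(x, ...) {
  cat("Difference-of-Gaussians area-summation fit\n")
  print(signif(coef(x), 5))
  cat("residual sum of squares:", signif(x$rss, 5),
      " (", length(x$radii), "radii )\n")
  invisible(x)
}

#' @export
print.dog_area_params <- function(x, ...) {
  cat(sprintf(
    "<dog_area_params> Kc=%.4g Ks=%.4g sigma_c=%.4g um sigma_s=%.4g um R0=%.4g\n",
    x$Kc, x$Ks, x$sigma_c, x$sigma_s, x$R0))
  invisible(x)
}

#' Read/write area-summation curves and fitted parameters
#'
#' Curves are stored as two-column tab-separated text (`radius_um`,
#' `response`); parameters as JSON.
#'
#' @param radii,responses curve data.
#' @param path file path.
#' @return reading functions return the stored object; writers return `path`
#'   invisibly.
#' @export
write_area_curve <- function(radii, responses, path) {
  utils::write.table(data.frame(radius_um = radii, response = responses),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_area_curve
#' @export
read_area_curve <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' @rdname write_area_curve
#' @param p a [dog_area_params()].
#' @export
write_dog_params <- function(p, path) {
  stopifnot(inherits(p, "dog_area_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_area_curve
#' @export
read_dog_params <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  dog_area_params(Kc = v$Kc, Ks = v$Ks, sigma_c = v$sigma_c,
                  sigma_s = v$sigma_s, R0 = v$R0)
}
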