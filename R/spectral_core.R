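#' Construct an absorption spectrum
#'
#' Container for a wavelength-indexed absorption spectrum such as CDOM
#' absorption \eqn{a_g(\lambda)}, detrital absorption \eqn{a_d(\lambda)}, or
#' particulate absorption \eqn{a_p(\lambda)}.
#'
#' @param wavelength numeric vector of wavelengths in nm, strictly increasing,
#'   within 245--715 nm.
#' @param absorption numeric vector of absorption coefficients in m^-1, same
#'   length as `wavelength`.  Negative values are allowed (pre-QC data carry
#'   them); they are flagged via the `has_negative` attribute, not rejected.
#' @param kind one of `"cdom"`, `"detrital"`, `"particulate"`.
#' @param resolution `"hyperspectral"`, `"multispectral"`, or `NULL` to
#'   auto-detect (>= 50 samples with median spacing <= 2 nm counts as
#'   hyperspectral).
#'
#' @return An object of class `absorption_spectrum`: a list with elements
#'   `wavelength`, `absorption`, `kind`, `resolution`.
#' @export
#' @examples
#' sp <- absorption_spectrum(300:600, 0.2 * exp(-0.018 * (300:600 - 300)))
#' sp
absorption_spectrum <- function(wavelength, absorption,
                                kind = c("cdom", "detrital", "particulate"),
                                resolution = NULL) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  absorption <- as.numeric(absorption)
  if (length(wavelength) != length(absorption))
    stop("wavelength and absorption must have equal length", call. = FALSE)
  if (length(wavelength) < 1L)
    stop("empty spectrum", call. = FALSE)
  if (any(!is.finite(wavelength)))
    stop("non-finite wavelengths", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (min(wavelength) < 245 || max(wavelength) > 715)
    stop("wavelengths must lie within 245-715 nm", call. = FALSE)
  if (any(!is.finite(absorption)))
    stop("non-finite absorption values", call. = FALSE)
  if (is.null(resolution)) {
    resolution <- if (length(wavelength) >= 50 &&
                      stats::median(diff(wavelength)) <= 2) "hyperspectral"
                  else "multispectral"
  } else {
    resolution <- match.arg(resolution, c("hyperspectral", "multispectral"))
  }
  structure(
    list(wavelength = wavelength, absorption = absorption,
         kind = kind, resolution = resolution),
    has_negative = any(absorption < 0),
    class = "absorption_spectrum")
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat(sprintf("<absorption_spectrum: %s, %s, %d samples, %g-%g nm>\n",
              x$kind, x$resolution, length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Evaluate the exponential CDOM absorption model
#'
#' Forward model \eqn{a_g(\lambda) = a_g(\lambda_0)\,e^{-S_g(\lambda -
#' \lambda_0)}}, the standard single-exponential description of CDOM
#' absorption decay with wavelength.
#'
#' @param a_ref absorption at the reference wavelength, m^-1 (>= 0).
#' @param lambda0 reference wavelength, nm.
#' @param s_g spectral slope, nm^-1.
#' @param wavelengths wavelengths (nm) at which to evaluate.
#' @param kind passed to [absorption_spectrum()].
#' @return An `absorption_spectrum` over `wavelengths`.
#' @export
#' @examples
#' eval_cdom_model(0.1, 412, 0.02, c(355, 412, 500))
eval_cdom_model <- function(a_ref, lambda0, s_g, wavelengths, kind = "cdom") {
  if (!is.finite(a_ref) || !is.finite(lambda0) || !is.finite(s_g))
    stop("non-finite model parameters", call. = FALSE)
  if (a_ref < 0) stop("a_ref must be >= 0", call. = FALSE)
  absorption_spectrum(wavelengths,
                      a_ref * exp(-s_g * (wavelengths - lambda0)),
                      kind = kind)
}

#' Spectral-slope fitting windows
#'
#' The eight wavelength windows over which CDOM spectral slope is routinely
#' computed: seven hyperspectral ranges plus the six-band multispectral
#' 412--555 nm range.
#'
#' @return Named list of `c(min, max)` windows in nm.
#' @export
slope_windows <- function() {
  list(`275-295` = c(275, 295),
       `290-600` = c(290, 600),
       `300-600` = c(300, 600),
       `350-400` = c(350, 400),
       `350-600` = c(350, 600),
       `380-600` = c(380, 600),
       `412-600` = c(412, 600),
       `412-555` = c(412, 555))
}

window_label <- function(window) sprintf("%g-%g", window[1], window[2])

#' Fit the CDOM spectral slope over a wavelength window
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of the exponential model
#' to measured absorption on the *untransformed* (linear) scale, which weights
#' the short, higher-absorption wavelengths most heavily; a linear regression
#' on log-transformed absorption is biased by the long-wavelength tail and is
#' deliberately not used.  The reference wavelength \eqn{\lambda_0} is the
#' window minimum, and the fitted amplitude `a_ref` is reported there.
#'
#' Window membership is inclusive on both endpoints.  Starting values are
#' `s_g = 0.015` nm^-1 (mid-range of the 0.005--0.05 plausibility band) and
#' the measured value nearest \eqn{\lambda_0}.  Convergence: relative
#' reduction in the residual sum of squares below 1e-10, at most 500
#' iterations; non-convergence is reported via `converged = FALSE` with the
#' best iterate, never an error.
#'
#' @param spectrum an [absorption_spectrum()].
#' @param window length-2 numeric, `c(lambda_min, lambda_max)` in nm, or the
#'   name of one of [slope_windows()].
#' @return An object of class `slope_fit` with elements `window`, `s_g`
#'   (nm^-1), `a_ref` (m^-1 at `lambda0`), `lambda0`, `rss`, `n_points`,
#'   `converged`, plus the data used.  Methods: `print`, `coef`, `predict`,
#'   `residuals`.
#' @export
#' @examples
#' sp <- eval_cdom_model(0.2, 300, 0.018, 300:600)
#' fit <- fit_slope(sp, c(300, 600))
#' coef(fit)
fit_slope <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  if (is.character(window)) {
    wins <- slope_windows()
    if (!window %in% names(wins))
      stop("unknown named window: ", window, call. = FALSE)
    window <- wins[[window]]
  }
  window <- as.numeric(window)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(lambda_min, lambda_max) with min < max",
         call. = FALSE)
  inw <- spectrum$wavelength >= window[1] & spectrum$wavelength <= window[2]
  if (sum(inw) < 3L)
    stop("insufficient-data: fewer than 3 points inside window ",
         window_label(window), call. = FALSE)
  lam <- spectrum$wavelength[inw]
  a   <- spectrum$absorption[inw]
  lambda0 <- window[1]
  a0_start <- a[which.min(abs(lam - lambda0))]
  if (a0_start <= 0) a0_start <- max(mean(a[a > 0], na.rm = TRUE), 1e-6)
  start <- c(a_ref = a0_start, s_g = 0.015)
  resid_fun <- function(p) a - p[1] * exp(-p[2] * (lam - lambda0))
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fun,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500))
  p <- fit$par
  structure(
    list(window = window, s_g = unname(p["s_g"]), a_ref = unname(p["a_ref"]),
         lambda0 = lambda0, rss = sum(resid_fun(p)^2), n_points = sum(inw),
         converged = fit$info %in% 1:3,
         wavelength = lam, absorption = a),
    class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("CDOM slope fit, window %s nm (lambda0 = %g nm)\n",
              window_label(x$window), x$lambda0))
  cat(sprintf("  S_g   = %.6g nm^-1\n  a_ref = %.6g m^-1\n", x$s_g, x$a_ref))
  cat(sprintf("  n = %d, RSS = %.4g, converged = %s\n",
              x$n_points, x$rss, x$converged))
  invisible(x)
}

#' @export
coef.slope_fit <- function(object, ...) {
  c(a_ref = object$a_ref, s_g = object$s_g)
}

#' @param object,newdata `predict.slope_fit` evaluates the fitted exponential
#'   at `newdata` wavelengths (defaults to the wavelengths used in the fit).
#' @rdname fit_slope
#' @param ... unused.
#' @export
predict.slope_fit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$wavelength else as.numeric(newdata)
  object$a_ref * exp(-object$s_g * (lam - object$lambda0))
}

#' @export
residuals.slope_fit <- function(object, ...) {
  object$absorption - predict(object)
}

#' Fit spectral slope over every applicable window
#'
#' Hyperspectral spectra are fitted over all eight windows of
#' [slope_windows()]; multispectral spectra only over the 412--555 and
#' 412--600 nm windows (the six-band visible ranges).  A window is attempted
#' only when the spectrum covers its lower bound (the reference wavelength)
#' and holds at least three samples inside it; omitted windows are reported
#' with a reason rather than an error.
#'
#' @param spectrum an [absorption_spectrum()].
#' @return Named list of `slope_fit` objects, with a `skipped` attribute
#'   (named character vector of reasons) for omitted windows.
#' @export
fit_all_slopes <- function(spectrum) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  wins <- slope_windows()
  if (spectrum$resolution == "multispectral")
    wins <- wins[c("412-555", "412-600")]
  fits <- list()
  skipped <- character(0)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (min(spectrum$wavelength) > w[1]) {
      skipped[nm] <- "no coverage at window minimum"
      next
    }
    n_in <- sum(spectrum$wavelength >= w[1] & spectrum$wavelength <= w[2])
    if (n_in < 3L) {
      skipped[nm] <- "fewer than 3 points in window"
      next
    }
    fits[[nm]] <- fit_slope(spectrum, w)
  }
  attr(fits, "skipped") <- skipped
  fits
}

#' Match spectral samples to target wavebands
#'
#' For each target band, selects the nearest sample within `tolerance` nm
#' (default 2.5 nm, the standard band-matching tolerance); bands with no
#' sample inside the tolerance are flagged absent.
#'
#' @param wavelength,value sample grid and values (an `absorption_spectrum`
#'   may be passed as `wavelength`, in which case `value` is taken from it).
#' @param target_bands numeric vector of band centers, nm.
#' @param tolerance matching tolerance, nm (>= 0).
#' @return data.frame with columns `band`, `wavelength` (matched sample, NA
#'   if absent), `value`, `matched`.
#' @export
band_match <- function(wavelength, value = NULL, target_bands,
                       tolerance = 2.5) {
  if (inherits(wavelength, "absorption_spectrum")) {
    value <- wavelength$absorption
    wavelength <- wavelength$wavelength
  }
  stopifnot(tolerance >= 0, length(wavelength) == length(value))
  out <- data.frame(band = target_bands, wavelength = NA_real_,
                    value = NA_real_, matched = FALSE)
  for (i in seq_along(target_bands)) {
    d <- abs(wavelength - target_bands[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tolerance) {
      out$wavelength[i] <- wavelength[j]
      out$value[i] <- value[j]
      out$matched[i] <- TRUE
    }
  }
  out
}

#' Construct a spectral response function
#'
#' @param band_center nominal band center, nm.
#' @param wavelength,weight response grid (nm) and non-negative weights with
#'   positive sum.
#' @return Object of class `spectral_response`.
#' @export
spectral_response <- function(band_center, wavelength, weight) {
  stopifnot(length(wavelength) == length(weight))
  if (any(weight < 0) || sum(weight) <= 0)
    stop("weights must be >= 0 with positive sum", call. = FALSE)
  structure(list(band_center = band_center,
                 wavelength = as.numeric(wavelength),
                 weight = as.numeric(weight)),
            class = "spectral_response")
}

#' Band-average a hyperspectral quantity through a spectral response function
#'
#' Weighted mean \eqn{\sum w v / \sum w} of the hyperspectral values linearly
#' interpolated onto the response grid, restricted to the overlapping
#' wavelength range.  This is how hyperspectral in-situ reflectances are
#' convolved to instrument bands.  Invariant to uniform scaling of the
#' weights.
#'
#' @param wavelength,value hyperspectral grid and values (an
#'   `absorption_spectrum` may be passed as `wavelength`).
#' @param response a [spectral_response()].
#' @return The band-averaged value (scalar).
#' @export
band_average <- function(wavelength, value = NULL, response) {
  if (inherits(wavelength, "absorption_spectrum")) {
    value <- wavelength$absorption
    wavelength <- wavelength$wavelength
  }
  stopifnot(inherits(response, "spectral_response"))
  keep <- response$wavelength >= min(wavelength) &
          response$wavelength <= max(wavelength)
  if (!any(keep))
    stop("insufficient-data: response does not overlap the spectrum",
         call. = FALSE)
  w <- response$weight[keep]
  if (sum(w) <= 0)
    stop("insufficient-data: zero total weight over the overlap",
         call. = FALSE)
  v <- stats::approx(wavelength, value, xout = response$wavelength[keep])$y
  sum(w * v) / sum(w)
}
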