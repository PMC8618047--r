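#' Closed-form source depth from a single profile point (D-I-R)
#'
#' Algebraic inversion of the point-source surface model: given the
#' temperature T(a) at radial distance a, the hotspot temperature Tmax
#' and the ambient Te, the source depth is
#' \deqn{d = a \sqrt{(T(a) - Te) / (Tmax - T(a))}.}
#'
#' @param T_a surface temperature at distance \code{a}, degC.
#' @param Tmax hotspot temperature, degC.
#' @param Te ambient temperature, degC.
#' @param a radial distance, metres, > 0.
#' @return Depth in metres.
#' @export
dir_depth <- function(T_a, Tmax, Te, a) {
  if (a <= 0) stop("'a' must be > 0")
  if (T_a < Te)
    stop("T(a) below ambient: profile inconsistent with an embedded source")
  if (T_a == Te) {
    warning("flat profile: T(a) = Te, depth is indeterminate; returning 0")
    return(0)
  }
  if (T_a >= Tmax)
    stop("singular inversion: T(a) must be strictly below Tmax")
  a * sqrt((T_a - Te) / (Tmax - T_a))
}

#' Closed-form source intensity from a single profile point (D-I-R)
#'
#' \deqn{q = 4 \pi h_0 a^2 (T(a) - Te)(Tmax - Te) / (Tmax - T(a)),}
#' equal to \code{4 pi h0 d^2 (Tmax - Te)} with \code{d} from
#' \code{\link{dir_depth}}.
#'
#' @inheritParams dir_depth
#' @param h0 heat-exchange coefficient, W/m^2/degC.
#' @return Intensity in W.
#' @export
dir_intensity <- function(T_a, Tmax, Te, a, h0 = 8.77) {
  if (a <= 0) stop("'a' must be > 0")
  if (T_a < Te)
    stop("T(a) below ambient: profile inconsistent with an embedded source")
  if (T_a == Te) return(0)  # no signal at a, zero-intensity source
  if (T_a >= Tmax)
    stop("singular inversion: T(a) must be strictly below Tmax")
  4 * pi * h0 * a^2 * (T_a - Te) * (Tmax - Te) / (Tmax - T_a)
}

#' Source-radius feature from intensity
#'
#' Monotone transform of the intensity used as the fifth component of
#' the pattern vector.  The default algebra is the literal cube root
#' \code{(q/(Qm At))^(1/3)}; \code{radius_form = "sphere"} in the
#' constants selects the sphere-volume form
#' \code{(3q/(4 pi Qm At))^(1/3)}.
#'
#' @param q source intensity, >= 0.
#' @param constants a \code{\link{model_constants}}.
#' @return Radius feature (model units).
#' @export
source_radius <- function(q, constants = model_constants()) {
  if (any(q < 0)) stop("'q' must be >= 0")
  base <- q / (constants$Qm * constants$At)
  if (constants$radius_form == "sphere") base <- 3 * base / (4 * pi)
  base^(1 / 3)
}

#' Inclination angle of the intensity-position ratio
#'
#' \deqn{\theta(a) = \arctan(q(a)/a)} in degrees, with q in the
#' extraction method's own units and a in metres (the ratio is taken
#' numerically).  At a = 0 the angle is defined as 90 degrees for q > 0
#' and 0 for q = 0.
#'
#' @param q intensity value(s).
#' @param a radial distance, metres.
#' @return Angle(s) in degrees, in [0, 90] for q >= 0.
#' @export
theta_angle <- function(q, a) {
  if (a == 0) return(ifelse(q > 0, 90, 0))
  atan(q / a) * 180 / pi
}

#' Coefficient of determination
#'
#' \code{1 - SS_res / SS_tot} between an observed and a fitted vector.
#'
#' @param observed,fitted equal-length numeric vectors (length >= 2);
#'   \code{observed} must not be constant.
#' @return R-squared (<= 1; can be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L)
    stop("'observed' and 'fitted' must have equal length >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("undefined R-squared: 'observed' is constant")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Lorentz-curve least-squares fit of a radial temperature profile
#'
#' Fits \deqn{y(a) = A / (a^2 + w^2) + y_0} to the mean radial
#' surface-temperature distribution by Levenberg-Marquardt least
#' squares.  Under the convention \code{4 pi h0 = 1} the fit inverts the
#' point-source surface model with depth \code{d = |w|} and intensity
#' \code{q = A}.
#'
#' Starting values: \code{y0} at the profile minimum, \code{w} at the
#' half-width at half prominence, \code{A = (Tmax - y0) w^2}; up to 1000
#' iterations at tolerance 1e-12.  \code{w} is reported positive (it
#' enters only squared).
#'
#' @param profile an \code{roi_profile} from
#'   \code{\link{extract_std_profile}}, with >= 4 offsets.
#' @return List with \code{A}, \code{w} (> 0), \code{y0},
#'   \code{fit_r_squared}, \code{fitted} (fitted temperatures on the
#'   profile grid).
#' @export
lorentz_fit <- function(profile) {
  a <- profile$offsets
  y <- profile$mean_temp
  if (length(a) < 4L)
    stop("Lorentz fit needs >= 4 distinct profile offsets")
  if (diff(range(y)) < 1e-12)
    stop("fit failure: constant profile (degenerate, A -> 0)")
  y0_0 <- min(y)
  prom <- max(y) - y0_0
  half <- y0_0 + prom / 2
  below <- which(y <= half)
  w0 <- if (length(below)) a[below[1L]] else max(a) / 2
  if (w0 <= 0) w0 <- a[2L]
  A0 <- prom * w0^2
  dat <- data.frame(a = a, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A / (a^2 + w^2) + y0, data = dat,
                      start = list(A = A0, w = w0, y0 = y0_0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-12, ptol = 1e-12)),
    error = function(e)
      stop("fit failure: Lorentz least squares did not converge (",
           conditionMessage(e), ")", call. = FALSE))
  cf <- stats::coef(fit)
  fitted_vals <- cf[["A"]] / (a^2 + cf[["w"]]^2) + cf[["y0"]]
  list(A = cf[["A"]], w = abs(cf[["w"]]), y0 = cf[["y0"]],
       fit_r_squared = r_squared(y, fitted_vals), fitted = fitted_vals)
}

#' Depth and intensity from Lorentz coefficients
#'
#' Under the \code{4 pi h0 = 1} convention: depth \code{d = |w|},
#' intensity \code{q = A}.
#'
#' @param A,w Lorentz amplitude and width from \code{\link{lorentz_fit}}.
#' @return Named list \code{(d, q)}.
#' @export
lorentz_params <- function(A, w) {
  list(d = abs(w), q = A)
}

#' Fit heat-source parameters to a radial temperature profile
#'
#' The central estimator: inverts the mean radial surface-temperature
#' distribution around the hotspot to the physiological parameters of an
#' embedded heat source, by one of two methods:
#' \describe{
#'   \item{\code{"dir"}}{the closed-form Depth-Intensity-Radius model
#'     evaluated at the single profile point \code{T(a)}
#'     (\code{\link{dir_depth}}, \code{\link{dir_intensity}}); intensity
#'     in W.}
#'   \item{\code{"lorentz"}}{whole-profile Lorentz least squares
#'     (\code{\link{lorentz_fit}}); depth \code{d = |w|} and intensity
#'     \code{q = A} under the \code{4 pi h0 = 1} convention.  The
#'     (d, q) estimates do not depend on \code{a}; \code{Tmax} and
#'     \code{theta(a)} carry the positional dependence.}
#' }
#' Both methods then derive the radius feature \code{R} from \code{q}
#' and the inclination angle \code{theta = arctan(q/a)} in degrees,
#' completing the five-component pattern vector
#' \code{\{Tmax, d, q, R, theta\}}.
#'
#' @param profile an \code{roi_profile}.
#' @param method \code{"dir"} or \code{"lorentz"}.
#' @param a extraction position in metres; must lie exactly on the
#'   profile's offset grid and be > 0 (no interpolation).
#' @param constants a \code{\link{model_constants}}.
#' @param lorentz optional precomputed \code{\link{lorentz_fit}} result
#'   for this profile (used by the position scan to avoid refitting).
#' @return An object of class \code{heat_source_fit} with components
#'   \code{coefficients} (Tmax, d, q, R, theta), \code{method},
#'   \code{a}, \code{profile}, \code{fitted.values},
#'   \code{residuals}, \code{r_squared}, \code{constants}.
#' @examples
#' q <- 4 * pi * 8.77 * 0.01^2 * 12
#' th <- synth_thermogram(c(100, 100), d = 0.01, q = q,
#'                        shape = c(200, 200), noise_sd = 0, seed = 1)
#' pr <- extract_std_profile(th)
#' fit <- heat_source_fit(pr, method = "dir", a = 0.0168)
#' coef(fit)  # recovers d = 0.01 m, q = 0.1322 W
#' @export
heat_source_fit <- function(profile, method = c("dir", "lorentz"),
                            a, constants = model_constants(),
                            lorentz = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "roi_profile"))
  if (a <= 0) stop("'a' must be > 0 (theta is undefined at a = 0)")
  k <- a / profile$pixel_size
  if (abs(k - round(k)) > 1e-6 || round(k) >= length(profile$offsets))
    stop("'a' must lie on the profile's offset grid (no interpolation)")
  k <- as.integer(round(k))
  offs <- profile$offsets
  Tmax <- profile$Tmax
  Te <- profile$Te
  fit_rsq <- NA_real_
  if (method == "dir") {
    T_a <- profile$mean_temp[k + 1L]
    d <- dir_depth(T_a, Tmax, Te, a)
    q <- dir_intensity(T_a, Tmax, Te, a, h0 = constants$h0)
    fitted_vals <- Te + q / (4 * pi * constants$h0 * (d^2 + offs^2))
  } else {
    lf <- if (is.null(lorentz)) lorentz_fit(profile) else lorentz
    dq <- lorentz_params(lf$A, lf$w)
    d <- dq$d; q <- dq$q
    fitted_vals <- lf$fitted
    fit_rsq <- lf$fit_r_squared
  }
  rsq <- tryCatch(r_squared(profile$mean_temp, fitted_vals),
                  error = function(e) NA_real_)  # constant profile
  R <- source_radius(q, constants)
  theta <- theta_angle(q, a)
  structure(list(coefficients = c(Tmax = Tmax, d = d, q = q, R = R,
                                  theta = theta),
                 lorentz = if (method == "lorentz") lf[c("A", "w", "y0")],
                 method = method, a = a, profile = profile,
                 fitted.values = fitted_vals,
                 residuals = profile$mean_temp - fitted_vals,
                 r_squared = rsq, fit_r_squared = fit_rsq,
                 constants = constants),
            class = "heat_source_fit")
}

#' Pattern vector of physiological parameters at a position
#'
#' Convenience wrapper around \code{\link{heat_source_fit}} returning
#' the five-component feature vector \code{\{Tmax, d, q, R, theta\}}.
#'
#' @inheritParams heat_source_fit
#' @return Named numeric vector of length 5.
#' @export
pattern_vector <- function(profile, method = c("dir", "lorentz"), a,
                           constants = model_constants(), lorentz = NULL) {
  stats::coef(heat_source_fit(profile, method, a, constants, lorentz))
}

#' @export
print.heat_source_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Heat-source fit (%s) at a = %.4g m\n",
              if (x$method == "dir") "D-I-R closed form"
              else "Lorentz curve", x$a))
  print(round(x$coefficients, digits))
  cat(sprintf("Profile R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.heat_source_fit <- function(object, ...) object$coefficients

#' @export
fitted.heat_source_fit <- function(object, ...) object$fitted.values

#' @export
residuals.heat_source_fit <- function(object, ...) object$residuals

#' Predict surface temperatures from a heat-source fit
#'
#' Evaluates the fitted surface-temperature curve at new radial
#' distances: the point-source model with the fitted (d, q) for the
#' D-I-R method, the fitted Lorentz curve for the Lorentz method.
#'
#' @param object a \code{heat_source_fit}.
#' @param a radial distances in metres (default: the profile grid).
#' @param ... unused.
#' @return Predicted temperatures in degrees C.
#' @export
predict.heat_source_fit <- function(object, a = NULL, ...) {
  if (is.null(a)) return(object$fitted.values)
  cf <- object$coefficients
  if (object$method == "dir") {
    object$profile$Te +
      cf[["q"]] / (4 * pi * object$constants$h0 * (cf[["d"]]^2 + a^2))
  } else {
    lf <- object$lorentz
    lf$A / (a^2 + lf$w^2) + lf$y0
  }
}

#' @export
summary.heat_source_fit <- function(object, ...) {
  structure(list(fit = object,
                 n_offsets = length(object$profile$offsets),
                 resid_sd = stats::sd(object$residuals)),
            class = "summary.heat_source_fit")
}

#' @export
print.summary.heat_source_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Offsets used: %d (max a = %.4g m); residual sd %.4g degC\n",
              x$n_offsets, max(x$fit$profile$offsets), x$resid_sd))
  invisible(x)
}

#' @export
plot.heat_source_fit <- function(x, ...) {
  pr <- x$profile
  graphics::plot(pr$offsets * 100, pr$mean_temp, pch = 16,
                 xlab = "radial distance a (cm)",
                 ylab = "surface temperature (degC)",
                 main = sprintf("%s fit (R-squared = %.3f)",
                                if (x$method == "dir") "D-I-R" else "Lorentz",
                                x$r_squared), ...)
  graphics::lines(pr$offsets * 100, x$fitted.values, col = 2, lwd = 2)
  invisible(x)
}

#' Simulate noisy profiles from a fitted surface-temperature curve
#'
#' Draws Gaussian sensor noise around the fitted curve on the profile's
#' offset grid.
#'
#' @param object a \code{heat_source_fit}.
#' @param nsim number of simulated profiles.
#' @param seed optional seed.
#' @param noise_sd noise standard deviation, degC.
#' @param ... unused.
#' @return Matrix with one simulated profile per column.
#' @export
simulate.heat_source_fit <- function(object, nsim = 1, seed = NULL,
                                     noise_sd = 0.04, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted.values)
  matrix(stats::rnorm(n * nsim, rep(object$fitted.values, nsim), noise_sd),
         nrow = n)
}
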