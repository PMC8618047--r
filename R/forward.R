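#' Bio-heat model constants
#'
#' Physical constants entering the closed-form inversion: the
#' skin-to-air heat-exchange coefficient \code{h0}, the metabolic heat
#' rate \code{Qm}, the cell-volume constant \code{At}, and the ambient
#' temperature \code{Te}.  \code{radius_form} selects the algebra of the
#' source-radius feature: \code{"linear"} is the literal cube root of
#' \code{q/(Qm*At)}; \code{"sphere"} uses the sphere-volume form
#' \code{(3q/(4*pi*Qm*At))^(1/3)}.  Either way R is a strictly monotone
#' transform of q, which is all classification requires.
#'
#' @param h0 heat-exchange coefficient, W/m^2/degC.
#' @param Qm metabolic heat rate, W/m^3.
#' @param At cell-volume constant (dimensionless scale, configurable).
#' @param Te ambient temperature, degC.
#' @param radius_form \code{"linear"} or \code{"sphere"}.
#' @return An object of class \code{model_constants}.
#' @export
model_constants <- function(h0 = 8.77, Qm = 418.6, At = 1, Te = 22,
                            radius_form = c("linear", "sphere")) {
  radius_form <- match.arg(radius_form)
  stopifnot(h0 > 0, Qm > 0, At > 0)
  structure(list(h0 = h0, Qm = Qm, At = At, Te = Te,
                 radius_form = radius_form),
            class = "model_constants")
}

#' Surface temperature of an embedded point heat source
#'
#' Analytical steady-state surface temperature at radial distance
#' \code{a} from the surface projection of a point source of intensity
#' \code{q} (W) buried at depth \code{d} (m):
#' \deqn{T(a) = Te + q / (4 \pi h_0 (d^2 + a^2)).}
#'
#' @param a radial distance(s) in metres (vectorised).
#' @param d source depth in metres, > 0.
#' @param q source intensity in W, >= 0.
#' @param Te ambient temperature, degC.
#' @param h0 heat-exchange coefficient, W/m^2/degC.
#' @return Temperature(s) in degrees C.
#' @examples
#' # a source 1 cm deep raising the hotspot to 34 degC in a 22 degC room
#' q <- 4 * pi * 8.77 * 0.01^2 * 12
#' forward_temperature_point(0, d = 0.01, q = q)       # 34
#' forward_temperature_point(0.0168, d = 0.01, q = q)  # 25.139
#' @export
forward_temperature_point <- function(a, d, q, Te = 22, h0 = 8.77) {
  if (d <= 0 && any(a == 0))
    stop("singularity: point source at zero depth evaluated at a = 0")
  if (d < 0) stop("'d' must be >= 0")
  if (q < 0) stop("'q' must be >= 0")
  Te + q / (4 * pi * h0 * (d^2 + a^2))
}

#' Surface temperature of an embedded spherical heat source
#'
#' Spherical source of radius \code{R} at depth \code{d}; reduces to the
#' point-source model with effective depth \code{d + R}:
#' \deqn{T(a) = Te + q / (4 \pi h_0 ((d+R)^2 + a^2)).}
#'
#' @inheritParams forward_temperature_point
#' @param R source radius in metres, >= 0.
#' @return Temperature(s) in degrees C.
#' @export
forward_temperature_sphere <- function(a, d, q, R = 0, Te = 22, h0 = 8.77) {
  if (R < 0) stop("'R' must be >= 0")
  if (d + R <= 0 && any(a == 0))
    stop("singularity: spherical source with d + R = 0 evaluated at a = 0")
  forward_temperature_point(a, d = d + R, q = q, Te = Te, h0 = h0)
}

#' Synthesize a thermogram with a known embedded heat source
#'
#' Builds a temperature image as background + point-source increment +
#' Gaussian sensor noise.  The source increment at pixel (i, j) follows
#' the point-source model at the Euclidean pixel distance from the
#' source's surface position, scaled by \code{pixel_size}.  The label is
#' derived from the surface-temperature elevation: \code{delta_T >= 2}
#' degC is abnormal.
#'
#' @param surface_pos 0-based (row, col) of the source's surface
#'   projection.
#' @param d,q,R source depth (m), intensity (W) and radius (m).
#' @param shape image shape \code{c(n_rows, n_cols)}.
#' @param pixel_size metres per pixel.
#' @param Te ambient temperature, degC.
#' @param h0 heat-exchange coefficient.
#' @param background either a single temperature (flat field, degC) or a
#'   matrix of the image shape.
#' @param noise_sd Gaussian sensor-noise standard deviation, degC
#'   (default 0.04, the sensitivity scale of the reference camera).
#' @param seed optional integer seed; when given the output is
#'   reproducible bit-for-bit.
#' @param id optional identifier.
#' @return A \code{\link{thermogram}} with attribute \code{"truth"}
#'   recording the planted parameters.
#' @export
synth_thermogram <- function(surface_pos, d, q, R = 0,
                             shape = c(480L, 640L), pixel_size = 0.0006,
                             Te = 22, h0 = 8.77, background = Te + 10,
                             noise_sd = 0.04, seed = NULL, id = NULL) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  n_rows <- shape[1L]; n_cols <- shape[2L]
  if (surface_pos[1L] < 0 || surface_pos[1L] > n_rows - 1L ||
      surface_pos[2L] < 0 || surface_pos[2L] > n_cols - 1L)
    stop("'surface_pos' outside image")
  if (length(background) == 1L) {
    bg <- matrix(background, n_rows, n_cols)
  } else {
    bg <- as.matrix(background)
    stopifnot(all(dim(bg) == shape))
  }
  rows <- (0:(n_rows - 1L)) - surface_pos[1L]
  cols <- (0:(n_cols - 1L)) - surface_pos[2L]
  a2 <- (outer(rows, cols, function(i, j) i^2 + j^2)) * pixel_size^2
  incr <- if (q > 0)
    q / (4 * pi * h0 * ((d + R)^2 + a2)) else matrix(0, n_rows, n_cols)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (noise_sd > 0)
    matrix(stats::rnorm(n_rows * n_cols, 0, noise_sd), n_rows, n_cols)
  else matrix(0, n_rows, n_cols)
  tm <- bg + incr + noise
  th <- thermogram(tm, pixel_size = pixel_size, Te = Te, id = id)
  th$label <- if (delta_T(th) >= 2) "abnormal" else "normal"
  attr(th, "truth") <- list(surface_pos = as.integer(surface_pos),
                            d = d, q = q, R = R, Te = Te, h0 = h0)
  th
}

#' Specification of a synthetic thermogram cohort
#'
#' Defaults emulate the reference study conditions: 49 normal and 38
#' abnormal frontal thermograms, flat per-subject background drawn in
#' [Te+8, Te+12] degC, sensor noise sd 0.04 degC, ambient 22 degC,
#' 480 x 640 images at 0.0006 m/pixel.  Class parameter ranges are
#' disjoint: normal sources are deep and weak (peak surface elevation
#' 0.6-1.5 degC, below the 2 degC abnormality criterion), abnormal
#' sources shallow and strong (peak elevation 3-8 degC).  Intensities q
#' are derived from the sampled depth and peak elevation via
#' \code{q = 4 pi h0 d^2 peak}.
#'
#' @param n_normal,n_abnormal class counts.
#' @param d_range_normal,d_range_abnormal depth ranges in metres.
#' @param peak_range_normal,peak_range_abnormal peak surface-elevation
#'   ranges (Tmax - background), degC.
#' @param background_range per-subject flat background range, degC.
#' @param noise_sd sensor noise sd, degC.
#' @param Te ambient temperature, degC.
#' @param h0 heat-exchange coefficient.
#' @param shape image shape.
#' @param pixel_size metres per pixel.
#' @param margin minimum hotspot distance from image borders, pixels.
#' @param seed mandatory integer seed for the cohort's random stream.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_normal = 49L, n_abnormal = 38L,
                        d_range_normal = c(0.010, 0.016),
                        d_range_abnormal = c(0.003, 0.008),
                        peak_range_normal = c(0.6, 1.5),
                        peak_range_abnormal = c(3, 8),
                        background_range = c(30, 34),
                        noise_sd = 0.04, Te = 22, h0 = 8.77,
                        shape = c(480L, 640L), pixel_size = 0.0006,
                        margin = 40L, seed) {
  if (missing(seed)) stop("'seed' is mandatory for cohort generation")
  stopifnot(n_normal >= 0L, n_abnormal >= 0L, noise_sd >= 0)
  structure(list(n_normal = as.integer(n_normal),
                 n_abnormal = as.integer(n_abnormal),
                 d_range_normal = d_range_normal,
                 d_range_abnormal = d_range_abnormal,
                 peak_range_normal = peak_range_normal,
                 peak_range_abnormal = peak_range_abnormal,
                 background_range = background_range,
                 noise_sd = noise_sd, Te = Te, h0 = h0, shape = shape,
                 pixel_size = pixel_size, margin = as.integer(margin),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic labeled cohort
#'
#' Draws \code{n_normal + n_abnormal} thermograms from a
#' \code{\link{cohort_spec}} using a single seeded random stream.  Every
#' generated abnormal member must satisfy \code{delta_T >= 2} degC and
#' every normal member \code{delta_T < 2} degC; members violating the
#' criterion are resampled (bounded retries) so that labels stay
#' physically meaningful.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param max_retries resampling bound per member.
#' @return List with \code{thermograms} (list of \code{thermogram}) and
#'   \code{truth} (data frame: id, label, d_m, q_W, row, col, delta_T).
#' @export
synth_cohort <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_normal + spec$n_abnormal
  labels <- rep(c("normal", "abnormal"),
                c(spec$n_normal, spec$n_abnormal))
  thermos <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    abnormal <- labels[i] == "abnormal"
    d_range <- if (abnormal) spec$d_range_abnormal else spec$d_range_normal
    p_range <- if (abnormal) spec$peak_range_abnormal else spec$peak_range_normal
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      d <- stats::runif(1, d_range[1L], d_range[2L])
      peak <- stats::runif(1, p_range[1L], p_range[2L])
      q <- 4 * pi * spec$h0 * d^2 * peak
      bg <- stats::runif(1, spec$background_range[1L],
                         spec$background_range[2L])
      pos <- c(sample(spec$margin:(spec$shape[1L] - 1L - spec$margin), 1L),
               sample(spec$margin:(spec$shape[2L] - 1L - spec$margin), 1L))
      th <- synth_thermogram(pos, d = d, q = q, shape = spec$shape,
                             pixel_size = spec$pixel_size, Te = spec$Te,
                             h0 = spec$h0, background = bg,
                             noise_sd = spec$noise_sd,
                             id = sprintf("synth_%03d", i))
      dT <- delta_T(th)
      if ((abnormal && dT >= 2) || (!abnormal && dT < 2)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("generation error: parameter ranges incompatible with the ",
           "delta-T criterion after ", max_retries, " retries")
    th$label <- labels[i]
    thermos[[i]] <- th
    truth[[i]] <- data.frame(id = th$id, label = labels[i], d_m = d,
                             q_W = q, row = pos[1L], col = pos[2L],
                             delta_T = dT, stringsAsFactors = FALSE)
  }
  list(thermograms = thermos, truth = do.call(rbind, truth))
}

#' Write a synthetic cohort to a directory
#'
#' Emits one text temperature grid per member plus \code{truth.csv}.
#'
#' @param cohort result of \code{\link{synth_cohort}}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (th in cohort$thermograms)
    write_temperature_matrix(th, file.path(out_dir, paste0(th$id, ".txt")))
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
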