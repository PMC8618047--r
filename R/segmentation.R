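#' Fit the inframammary fold as a cubic polynomial
#'
#' Least-squares fit of \code{row = c3*col^3 + c2*col^2 + c1*col + c0}
#' through annotated fold points, used to delimit the breast region from
#' below.
#'
#' @param points a two-column matrix or data frame of (row, col) pixel
#'   coordinates (0-based), at least four points with >= 4 distinct
#'   column values.
#' @return Numeric vector \code{c(c3, c2, c1, c0)} of cubic coefficients
#'   (highest degree first).
#' @export
fit_inframammary_curve <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L)
    stop("insufficient points: need >= 4 annotated fold points")
  row <- points[, 1L]; col <- points[, 2L]
  if (length(unique(col)) < 4L)
    stop("insufficient points: need >= 4 distinct column values")
  fit <- stats::lm.fit(cbind(col^3, col^2, col, 1), row)
  coefs <- fit$coefficients
  names(coefs) <- c("c3", "c2", "c1", "c0")
  coefs
}

eval_cubic <- function(coefs, col) {
  ((coefs[1L] * col + coefs[2L]) * col + coefs[3L]) * col + coefs[4L]
}

#' Build a breast mask from inframammary curves
#'
#' Produces a logical matrix that is TRUE inside the breast region:
#' pixels strictly below the fitted fold curve(s) (larger row index than
#' the curve at that column) or outside the lateral column bounds are
#' FALSE.
#'
#' @param shape integer vector \code{c(n_rows, n_cols)}.
#' @param curves a single coefficient vector from
#'   \code{\link{fit_inframammary_curve}} or a list of them (one per
#'   breast); the region below every curve is removed.
#' @param lateral_bounds 0-based column bounds \code{c(first, last)}
#'   kept in the mask; default spans the image.
#' @return An object of class \code{breast_mask}: list with logical
#'   \code{mask} and \code{curve_coeffs}.
#' @export
build_mask <- function(shape, curves = NULL,
                       lateral_bounds = c(0L, shape[2L] - 1L)) {
  n_rows <- as.integer(shape[1L]); n_cols <- as.integer(shape[2L])
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  if (any(lateral_bounds < 0L) || any(lateral_bounds > n_cols - 1L) ||
      lateral_bounds[1L] > lateral_bounds[2L])
    stop("lateral bounds outside image")
  mask <- matrix(FALSE, n_rows, n_cols)
  cols_keep <- (lateral_bounds[1L]:lateral_bounds[2L]) + 1L
  mask[, cols_keep] <- TRUE
  if (!is.null(curves)) {
    if (!is.list(curves)) curves <- list(curves)
    col0 <- 0:(n_cols - 1L)  # 0-based columns
    for (cf in curves) {
      cut_row <- eval_cubic(cf, col0)
      for (j in seq_len(n_cols)) {
        below <- which((0:(n_rows - 1L)) > cut_row[j])
        if (length(below)) mask[below, j] <- FALSE
      }
    }
  }
  if (!any(mask)) stop("empty mask: curves remove the whole image")
  structure(list(mask = mask, curve_coeffs = curves), class = "breast_mask")
}

as_mask_matrix <- function(mask, shape) {
  if (is.null(mask)) return(matrix(TRUE, shape[1L], shape[2L]))
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  stopifnot(is.logical(m), all(dim(m) == shape))
  m
}

#' Locate the hottest spot within a mask
#'
#' Returns the position and value of the maximum masked temperature.
#' Ties are broken toward the smallest row, then smallest column
#' (row-major first occurrence), so the result is deterministic.
#'
#' @param thermo a \code{\link{thermogram}}.
#' @param mask optional \code{breast_mask} or logical matrix; default is
#'   the whole image.
#' @return List with 0-based \code{row}, \code{col} and \code{Tmax}.
#' @export
locate_hotspot <- function(thermo, mask = NULL) {
  tm <- thermo$temperatures
  m <- as_mask_matrix(mask, dim(tm))
  if (!any(m)) stop("empty mask")
  vals <- ifelse(m, tm, -Inf)
  Tmax <- max(vals)
  hits <- which(vals == Tmax, arr.ind = TRUE)
  # row-major order: smallest row first, then smallest col
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  list(row = unname(hits[1L, 1L]) - 1L, col = unname(hits[1L, 2L]) - 1L,
       Tmax = Tmax)
}

#' Extract the mean radial surface-temperature profile
#'
#' Samples the temperature field along the four axis-aligned rays (up,
#' down, left, right) from the hotspot at integer pixel offsets
#' k = 0, 1, ..., round(a_max / pixel_size) and averages them into the
#' mean surface-temperature distribution T(a) on the offset grid
#' a = k * pixel_size.  A ray that leaves the image or the mask at
#' offset k is excluded from that offset onward; the profile is
#' truncated at the last offset with at least one valid ray.
#'
#' The offset step equals one pixel exactly, so sampling is on-lattice
#' and needs no interpolation.
#'
#' @param thermo a \code{\link{thermogram}}.
#' @param mask optional \code{breast_mask} or logical matrix.
#' @param hotspot optional hotspot list from \code{\link{locate_hotspot}};
#'   computed if missing.
#' @param a_max maximum radial distance in metres (<= 0.018 m, the
#'   largest usable radius before rays typically reach image borders).
#' @return An object of class \code{roi_profile}: list with
#'   \code{offsets} (metres), \code{mean_temp} (degrees C),
#'   \code{n_directions}, \code{Tmax}, \code{hotspot}, \code{Te},
#'   \code{pixel_size}, \code{id}.
#' @export
extract_std_profile <- function(thermo, mask = NULL, hotspot = NULL,
                                a_max = 0.018) {
  if (a_max > 0.018 + 1e-12)
    stop("'a_max' must be <= 0.018 m")
  tm <- thermo$temperatures
  m <- as_mask_matrix(mask, dim(tm))
  if (is.null(hotspot)) hotspot <- locate_hotspot(thermo, m)
  r0 <- hotspot$row + 1L; c0 <- hotspot$col + 1L  # 1-based
  if (!m[r0, c0]) stop("hotspot is outside the mask")
  k_max <- round(a_max / thermo$pixel_size)
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  alive <- rep(TRUE, 4L)
  mean_temp <- numeric(0)
  n_dir <- integer(0)
  for (k in 0:k_max) {
    vals <- numeric(0)
    for (i in seq_along(dirs)) {
      if (!alive[i]) next
      r <- r0 + dirs[[i]][1L] * k; c <- c0 + dirs[[i]][2L] * k
      if (r < 1L || r > nrow(tm) || c < 1L || c > ncol(tm) || !m[r, c]) {
        alive[i] <- FALSE  # dropped at this and all larger offsets
        next
      }
      vals <- c(vals, tm[r, c])
    }
    if (length(vals) == 0L) break
    mean_temp <- c(mean_temp, mean(vals))
    n_dir <- c(n_dir, length(vals))
  }
  if (length(mean_temp) < 2L)
    stop("degenerate profile: no valid offset beyond the hotspot")
  structure(list(offsets = (seq_along(mean_temp) - 1L) * thermo$pixel_size,
                 mean_temp = mean_temp, n_directions = n_dir,
                 Tmax = hotspot$Tmax, hotspot = hotspot[c("row", "col")],
                 Te = thermo$Te, pixel_size = thermo$pixel_size,
                 id = thermo$id, label = thermo$label),
            class = "roi_profile")
}

#' @export
print.roi_profile <- function(x, ...) {
  cat(sprintf("RoI profile%s: %d offsets, step %.4g m, max a = %.4g m\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              length(x$offsets), x$pixel_size, max(x$offsets)))
  cat(sprintf("  Tmax = %.3f degC at (row %d, col %d); Te = %.2f degC\n",
              x$Tmax, x$hotspot$row, x$hotspot$col, x$Te))
  invisible(x)
}

#' @export
plot.roi_profile <- function(x, ...) {
  graphics::plot(x$offsets * 100, x$mean_temp, type = "b", pch = 16,
                 xlab = "radial distance a (cm)",
                 ylab = "mean surface temperature (degC)",
                 main = "Radial surface-temperature distribution", ...)
  invisible(x)
}

#' Surface-temperature elevation of a thermogram
#'
#' Computes \code{delta T = Tmax - Tmean} over the masked region.  A
#' value of 2 degrees C or more flags an abnormal thermal pattern.
#'
#' @param thermo a \code{\link{thermogram}}.
#' @param mask optional \code{breast_mask} or logical matrix.
#' @return Temperature elevation in degrees C.
#' @export
delta_T <- function(thermo, mask = NULL) {
  tm <- thermo$temperatures
  m <- as_mask_matrix(mask, dim(tm))
  if (!any(m)) stop("empty mask")
  vals <- tm[m]
  max(vals) - mean(vals)
}

#' Quantize masked temperatures into equal-width levels
#'
#' Visualization aid: bins the masked temperature range into
#' \code{n_levels} equal-width classes (0-based labels); unmasked pixels
#' get NA.  A degenerate range (constant field) yields a single label 0.
#'
#' @param thermo a \code{\link{thermogram}}.
#' @param mask optional mask.
#' @param n_levels number of levels, >= 2.
#' @return Integer label matrix of the thermogram's shape.
#' @export
quantize_thermal_levels <- function(thermo, mask = NULL, n_levels = 8L) {
  if (n_levels < 2L) stop("'n_levels' must be >= 2")
  tm <- thermo$temperatures
  m <- as_mask_matrix(mask, dim(tm))
  vals <- tm[m]
  lab <- matrix(NA_integer_, nrow(tm), ncol(tm))
  rng <- range(vals)
  if (diff(rng) == 0) {
    lab[m] <- 0L
  } else {
    idx <- pmin(floor((tm[m] - rng[1L]) / diff(rng) * n_levels),
                n_levels - 1L)
    lab[m] <- as.integer(idx)
  }
  lab
}

#' Read inframammary-curve annotations
#'
#' CSV with columns \code{id}, \code{side}, \code{row}, \code{col}
#' (0-based pixel coordinates of fold points).
#'
#' @param path path to the annotation CSV.
#' @return A data frame of annotations.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "side", "row", "col")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  ann
}
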