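#' Camera geometry for thermogram acquisition
#'
#' Describes the thin-lens acquisition geometry of a thermal camera:
#' sensor height, focal length and camera-to-subject distance, together
#' with the image resolution.  The default corresponds to the FLIR
#' acquisition protocol of the DMR-IR frontal breast thermograms
#' (2.16 cm sensor, 7.5 cm focal length, 1 m object distance,
#' 640 x 480 pixels).
#'
#' @param sensor_height sensor height in cm (vertical sensor dimension).
#' @param focal_length focal length in cm.
#' @param object_distance camera-to-subject distance in cm.
#' @param n_rows,n_cols image resolution in pixels (rows x columns).
#' @return An object of class \code{camera_geometry}.
#' @examples
#' geom <- camera_geometry()
#' object_height(geom)            # 28.8 cm
#' pixel_size_object_plane(geom)  # 0.06 cm
#' @export
camera_geometry <- function(sensor_height = 2.16, focal_length = 7.5,
                            object_distance = 100, n_rows = 480L,
                            n_cols = 640L) {
  if (!is.numeric(sensor_height) || length(sensor_height) != 1L ||
      !is.finite(sensor_height) || sensor_height <= 0)
    stop("invalid geometry: 'sensor_height' must be a positive number")
  if (!is.numeric(focal_length) || length(focal_length) != 1L ||
      !is.finite(focal_length) || focal_length <= 0)
    stop("invalid geometry: 'focal_length' must be a positive number")
  if (!is.numeric(object_distance) || length(object_distance) != 1L ||
      !is.finite(object_distance) || object_distance <= 0)
    stop("invalid geometry: 'object_distance' must be a positive number")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L || is.na(n_cols) || n_cols < 1L)
    stop("invalid geometry: 'n_rows' and 'n_cols' must be >= 1")
  structure(list(sensor_height = sensor_height, focal_length = focal_length,
                 object_distance = object_distance, n_rows = n_rows,
                 n_cols = n_cols),
            class = "camera_geometry")
}

#' @export
print.camera_geometry <- function(x, ...) {
  cat("Camera geometry (thin lens)\n")
  cat(sprintf("  sensor height:   %.3f cm\n", x$sensor_height))
  cat(sprintf("  focal length:    %.3f cm\n", x$focal_length))
  cat(sprintf("  object distance: %.1f cm\n", x$object_distance))
  cat(sprintf("  resolution:      %d x %d px (rows x cols)\n",
              x$n_rows, x$n_cols))
  cat(sprintf("  object height:   %.4g cm; pixel size: %.4g cm/px\n",
              object_height(x), pixel_size_object_plane(x)))
  invisible(x)
}

#' Object height in the object plane
#'
#' Thin-lens scaling: the physical height imaged onto the sensor is
#' \code{sensor_height / focal_length * object_distance}.
#'
#' @param geom a \code{\link{camera_geometry}}.
#' @return Object height in cm.
#' @export
object_height <- function(geom) {
  stopifnot(inherits(geom, "camera_geometry"))
  geom$sensor_height / geom$focal_length * geom$object_distance
}

#' Pixel size in the object plane
#'
#' Physical size of one pixel at the subject: \code{object_height / n_rows}.
#' The vertical axis is used; pixels are assumed square (the 45 um sensor
#' pitch of the reference camera is square).
#'
#' @param geom a \code{\link{camera_geometry}}.
#' @return Pixel size in cm per pixel.
#' @export
pixel_size_object_plane <- function(geom) {
  stopifnot(inherits(geom, "camera_geometry"))
  object_height(geom) / geom$n_rows
}

#' Construct a thermogram object
#'
#' A thermogram is a per-pixel surface-temperature matrix in degrees
#' Celsius together with the physical pixel size in the object plane,
#' the ambient (environment) temperature \code{Te}, and an optional
#' class label.  Row 1 of the matrix is the top image row; coordinates
#' used throughout the package are (row, col).
#'
#' @param temperatures numeric matrix of temperatures in degrees C.
#' @param pixel_size pixel size in metres per pixel.
#' @param Te ambient temperature in degrees C (default 22, the reference
#'   acquisition-room temperature).
#' @param label one of \code{"normal"}, \code{"abnormal"}, \code{"unknown"}.
#' @param id optional identifier string.
#' @return An object of class \code{thermogram}.
#' @export
thermogram <- function(temperatures, pixel_size, Te = 22,
                       label = c("unknown", "normal", "abnormal"),
                       id = NULL) {
  label <- match.arg(label)
  if (!is.matrix(temperatures) || !is.numeric(temperatures) ||
      length(temperatures) == 0L)
    stop("'temperatures' must be a non-empty numeric matrix")
  if (any(!is.finite(temperatures)))
    stop("'temperatures' must be all finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a positive number (metres per pixel)")
  if (!is.numeric(Te) || length(Te) != 1L || !is.finite(Te))
    stop("'Te' must be a finite number")
  structure(list(temperatures = temperatures, pixel_size = pixel_size,
                 Te = Te, label = label, id = id),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf("Thermogram%s: %d x %d px, pixel size %.4g m\n",
              if (is.null(x$id)) "" else paste0(" '", x$id, "'"),
              nrow(x$temperatures), ncol(x$temperatures), x$pixel_size))
  cat(sprintf("  T range [%.2f, %.2f] degC, Te = %.2f degC, label = %s\n",
              min(x$temperatures), max(x$temperatures), x$Te, x$label))
  invisible(x)
}

#' Read a temperature matrix from a text grid
#'
#' Reads a whitespace-separated numeric grid (one image row per line,
#' '.' decimal separator; lines starting with '#' are skipped) into a
#' \code{\link{thermogram}}.  Row i of the file is image row i, top-down.
#' The pixel size is derived from the camera geometry and converted to
#' metres.
#'
#' @param path path to the text grid.
#' @param geom a \code{\link{camera_geometry}} (default: DMR-IR geometry).
#' @param Te ambient temperature in degrees C.
#' @param label,id passed to \code{\link{thermogram}}.
#' @return A \code{\link{thermogram}}.
#' @export
read_temperature_matrix <- function(path, geom = camera_geometry(), Te = 22,
                                    label = "unknown", id = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("format error: no data rows in ", path)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v)))
      stop("parse error: non-numeric token in ", path)
    v
  })
  n <- lengths(rows)
  if (length(unique(n)) != 1L)
    stop("format error: ragged rows in ", path,
         " (row lengths ", paste(unique(n), collapse = ", "), ")")
  mat <- do.call(rbind, rows)
  thermogram(mat, pixel_size = pixel_size_object_plane(geom) / 100,
             Te = Te, label = label, id = id)
}

#' Write a temperature matrix as a text grid
#'
#' Writes the temperature matrix of a thermogram as a whitespace-separated
#' text grid at full double precision, readable by
#' \code{\link{read_temperature_matrix}}.
#'
#' @param thermo a \code{\link{thermogram}} or a numeric matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_temperature_matrix <- function(thermo, path) {
  mat <- if (inherits(thermo, "thermogram")) thermo$temperatures else thermo
  if (!is.matrix(mat) || length(mat) == 0L)
    stop("cannot write an empty or non-matrix temperature grid")
  lines <- apply(mat, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a camera-geometry block from a YAML config
#'
#' The config must contain a \code{camera} mapping with keys
#' \code{sensor_height}, \code{focal_length}, \code{object_distance},
#' \code{n_rows}, \code{n_cols}; missing keys fall back to the DMR-IR
#' defaults.
#'
#' @param path path to a YAML file.
#' @return A \code{\link{camera_geometry}}.
#' @export
read_camera_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("package 'yaml' is required to read camera configs")
  cfg <- yaml::read_yaml(path)
  cam <- if (!is.null(cfg$camera)) cfg$camera else cfg
  def <- camera_geometry()
  pick <- function(key) if (!is.null(cam[[key]])) cam[[key]] else def[[key]]
  camera_geometry(pick("sensor_height"), pick("focal_length"),
                  pick("object_distance"), pick("n_rows"), pick("n_cols"))
}

#' Import a 16-bit grayscale PNG as a thermogram
#'
#' Maps gray levels linearly onto \code{[t_min, t_max]} degrees C.
#'
#' @param path path to a grayscale PNG.
#' @param t_min,t_max temperatures mapped to gray 0 and 1.
#' @param geom a \code{\link{camera_geometry}}.
#' @param Te ambient temperature in degrees C.
#' @return A \code{\link{thermogram}}.
#' @export
read_temperature_png <- function(path, t_min, t_max,
                                 geom = camera_geometry(), Te = 22) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("package 'png' is required for PNG import")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel
  thermogram(t_min + img * (t_max - t_min),
             pixel_size = pixel_size_object_plane(geom) / 100, Te = Te)
}
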