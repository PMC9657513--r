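#' Thermal frame: a calibrated 2-D temperature raster
#'
#' A `thermal_frame` holds absolute skin-surface temperatures in degrees
#' Celsius on a regular pixel grid, together with the acquisition geometry
#' needed to convert pixel areas into physical areas: the sensor-to-lesion
#' distance `distance_d`, the optical focal distance `focal_f`, and the
#' physical pixel pitch (`pixel_width_W`, `pixel_length_L`), all in cm.
#'
#' Pixels can be marked invalid (clothes, hair, background removed by the
#' pre-filter, dead sensor cells). Invalid pixels are stored as `NA` in the
#' grid and `FALSE` in the validity mask, so they can never leak into
#' downstream statistics as sentinel values.
#'
#' Coordinate convention used throughout the package: row-major, origin at
#' the top-left pixel, pixel centers at integer coordinates, `x = col - 1`
#' increasing rightwards and `y = row - 1` increasing downwards.
#'
#' @param grid numeric matrix of temperatures in degrees C; non-finite
#'   entries are marked invalid.
#' @param mask optional logical matrix, same shape as `grid`; `FALSE` marks a
#'   pixel invalid in addition to non-finite grid entries.
#' @param distance_d sensor-to-lesion distance in cm (must be > 0 if given).
#' @param focal_f optical focal distance in cm (must be > 0 if given).
#' @param pixel_width_W,pixel_length_L physical pixel pitch in cm.
#' @param session_id identifier of the clinical session.
#' @param timestamp session date (`Date` or anything coercible by
#'   [as.Date()]); may be `NA`.
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(grid, mask = NULL,
                          distance_d = NA_real_, focal_f = NA_real_,
                          pixel_width_W = NA_real_, pixel_length_L = NA_real_,
                          session_id = NA_character_, timestamp = NA) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix", call. = FALSE)
  if (nrow(grid) < 1L || ncol(grid) < 1L)
    stop("`grid` must have at least one row and one column", call. = FALSE)
  storage.mode(grid) <- "double"
  if (is.null(mask)) mask <- is.finite(grid)
  if (!is.logical(mask) || !identical(dim(mask), dim(grid)))
    stop("`mask` must be a logical matrix with the same shape as `grid`",
         call. = FALSE)
  mask <- mask & is.finite(grid)
  grid[!mask] <- NA_real_
  v <- grid[mask]
  if (length(v) && (min(v) < -20 || max(v) > 60))
    stop("valid temperatures must lie within [-20, 60] degrees C; got range [",
         min(v), ", ", max(v), "]", call. = FALSE)
  for (nm in c("distance_d", "focal_f")) {
    val <- get(nm)
    if (!is.na(val) && val <= 0)
      stop("`", nm, "` must be positive", call. = FALSE)
  }
  structure(
    list(grid = grid, mask = mask,
         distance_d = as.numeric(distance_d), focal_f = as.numeric(focal_f),
         pixel_width_W = as.numeric(pixel_width_W),
         pixel_length_L = as.numeric(pixel_length_L),
         session_id = session_id,
         timestamp = if (inherits(timestamp, "Date") || is.na(timestamp[1L]))
           timestamp else as.Date(timestamp)),
    class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  v <- valid_temps(x)
  cat(sprintf("<thermal_frame> %d x %d px, %d valid (%.1f%%)\n",
              nrow(x$grid), ncol(x$grid), length(v),
              100 * length(v) / length(x$grid)))
  if (length(v))
    cat(sprintf("  temperature range [%.2f, %.2f] degC\n", min(v), max(v)))
  if (!is.na(x$distance_d))
    cat(sprintf("  geometry: d=%g cm, f=%g cm, pixel %g x %g cm\n",
                x$distance_d, x$focal_f, x$pixel_width_W, x$pixel_length_L))
  if (!is.na(x$session_id)) cat("  session:", x$session_id, "\n")
  invisible(x)
}

#' @rdname thermal_frame
#' @param frame a `thermal_frame`.
#' @return `valid_temps()`: the vector of temperatures at valid pixels.
#' @export
valid_temps <- function(frame) {
  stopifnot(inherits(frame, "thermal_frame"))
  frame$grid[frame$mask]
}

#' @rdname thermal_frame
#' @return `n_valid()`: the number of valid pixels.
#' @export
n_valid <- function(frame) sum(frame$mask)

#' Raw (uncalibrated) sensor frame
#'
#' Integer radiation counts straight from the microbolometer, before the
#' per-session thermometer calibration maps them to absolute temperature.
#' Geometry metadata mirrors [thermal_frame()].
#'
#' @param counts matrix of non-negative integer sensor counts.
#' @inheritParams thermal_frame
#' @return An object of class `raw_frame`.
#' @export
raw_frame <- function(counts, distance_d = NA_real_, focal_f = NA_real_,
                      pixel_width_W = NA_real_, pixel_length_L = NA_real_,
                      session_id = NA_character_, timestamp = NA) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("`counts` must have positive shape", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE))
    stop("sensor counts must be non-negative", call. = FALSE)
  structure(
    list(counts = counts, distance_d = distance_d, focal_f = focal_f,
         pixel_width_W = pixel_width_W, pixel_length_L = pixel_length_L,
         session_id = session_id, timestamp = timestamp),
    class = "raw_frame")
}

#' Linear radiometric calibration model
#'
#' Maps sensor counts to absolute temperature as `T = gain_a * counts +
#' offset_b`, the standard first-order model for microbolometer response
#' over the narrow physiological temperature range.
#'
#' @param gain_a gain in degrees C per count; must be positive.
#' @param offset_b offset in degrees C.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(gain_a, offset_b) {
  if (!is.numeric(gain_a) || gain_a <= 0)
    stop("`gain_a` must be positive", call. = FALSE)
  structure(list(gain_a = as.numeric(gain_a), offset_b = as.numeric(offset_b)),
            class = "calibration_model")
}

#' Calibrate a raw frame against reference thermometer readings
#'
#' Fits the linear model `T = a * counts + b` through one or two reference
#' regions whose true temperature was measured with an IR thermometer at
#' acquisition time. With two references, both gain and offset are solved
#' from the two (mean counts, known temperature) pairs; with a single
#' reference, the gain is taken from `gain_a` (sensor characterization) and
#' only the offset is solved, which is sufficient when only the ambient
#' drift changes between sessions.
#'
#' @param raw a [raw_frame()].
#' @param references list of references, each a `list(region = <logical
#'   matrix, same shape as counts>, temp = <known temperature, degC>)`.
#' @param gain_a fixed gain in degC/count, required when only one reference
#'   is supplied.
#' @return A `thermal_frame` with the geometry metadata carried over; the
#'   fitted [calibration_model()] is attached as attribute `"calibration"`.
#' @export
calibrate <- function(raw, references, gain_a = NULL) {
  stopifnot(inherits(raw, "raw_frame"))
  if (!is.list(references) || length(references) < 1L || length(references) > 2L)
    stop("`references` must be a list of 1 or 2 reference points", call. = FALSE)
  mu <- vapply(references, function(r) {
    if (!is.logical(r$region) || !identical(dim(r$region), dim(raw$counts)))
      stop("reference region must be a logical matrix matching the frame shape",
           call. = FALSE)
    if (!any(r$region))
      stop("reference region is empty", call. = FALSE)
    mean(raw$counts[r$region])
  }, numeric(1))
  temps <- vapply(references, function(r) as.numeric(r$temp), numeric(1))
  if (length(references) == 2L) {
    if (mu[1] == mu[2])
      stop("reference regions have identical mean counts: singular calibration fit",
           call. = FALSE)
    a <- (temps[2] - temps[1]) / (mu[2] - mu[1])
    if (a <= 0)
      stop("fitted gain is non-positive; check reference assignments", call. = FALSE)
    b <- temps[1] - a * mu[1]
  } else {
    if (is.null(gain_a))
      stop("`gain_a` is required for single-reference calibration", call. = FALSE)
    a <- as.numeric(gain_a)
    if (a <= 0) stop("`gain_a` must be positive", call. = FALSE)
    b <- temps[1] - a * mu[1]
  }
  model <- calibration_model(a, b)
  out <- thermal_frame(a * raw$counts + b,
                       distance_d = raw$distance_d, focal_f = raw$focal_f,
                       pixel_width_W = raw$pixel_width_W,
                       pixel_length_L = raw$pixel_length_L,
                       session_id = raw$session_id, timestamp = raw$timestamp)
  attr(out, "calibration") <- model
  out
}
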