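# Per-session lesion metrics: core temperature inside the boundary
# isotherm, surrounding healthy-skin temperature in an annulus outside it,
# their difference delta_t, and the pixel/absolute areas. delta_t > 0 is
# the thermographic signature of an active hemangioma (increased local
# blood flow warms the skin); its longitudinal decrease indicates a
# favorable response to treatment.

#' Mean (or peak) temperature of the lesion core
#'
#' Averages the valid pixels whose centers fall strictly inside the
#' boundary polygon. Point-in-polygon is decided by even-odd ray casting;
#' pixel centers lying exactly on the outline are excluded, so the result
#' is deterministic. `core = "peak"` returns the hottest interior pixel
#' instead, which tracks the lesion center but is more sensitive to
#' single-pixel noise.
#'
#' @param frame a [thermal_frame()].
#' @param boundary a closed [iso_contour()].
#' @param core `"mean"` (default) or `"peak"`.
#' @return Core temperature in degC.
#' @export
core_temperature <- function(frame, boundary, core = c("mean", "peak")) {
  stopifnot(inherits(frame, "thermal_frame"))
  core <- match.arg(core)
  v <- .poly_vertices(boundary)
  if (!.poly_is_closed(v))
    stop("boundary must be a closed contour", call. = FALSE)
  ar <- tryCatch(shoelace_area(v), error = function(e) 0)
  if (ar <= 1e-9)
    stop("degenerate boundary: polygon has zero area", call. = FALSE)
  idx <- .interior_pixels(frame, v)
  if (!length(idx))
    stop("boundary encloses no valid pixel centers", call. = FALSE)
  if (core == "mean") mean(frame$grid[idx]) else max(frame$grid[idx])
}

# linear indices of valid pixels strictly inside polygon v (on-edge excluded)
.interior_pixels <- function(frame, v, strict_tol = 1e-9) {
  h <- nrow(frame$grid); w <- ncol(frame$grid)
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  cols <- max(1L, floor(xr[1L]) + 1L):min(w, ceiling(xr[2L]) + 1L)
  rows <- max(1L, floor(yr[1L]) + 1L):min(h, ceiling(yr[2L]) + 1L)
  if (!length(cols) || !length(rows)) return(integer(0))
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  lin <- rep((cols - 1L) * h, each = length(rows)) + rep(rows, times = length(cols))
  keep <- frame$mask[lin]
  px <- px[keep]; py <- py[keep]; lin <- lin[keep]
  if (!length(lin)) return(integer(0))
  ins <- point_in_polygon(px, py, v)
  px <- px[ins]; py <- py[ins]; lin <- lin[ins]
  if (!length(lin)) return(integer(0))
  lin[dist_to_polygon(px, py, v) > strict_tol]
}

#' Mean temperature of the surrounding healthy skin
#'
#' Averages valid skin pixels in an annulus outside the lesion boundary:
#' pixels (a) within `ring_px` of the boundary outline, (b) outside the
#' polygon, and (c) inside the skin mask. The annulus keeps the reference
#' local (skin temperature drifts spatially) while the skin-mask
#' intersection excludes background, clothes and hair.
#'
#' @inheritParams core_temperature
#' @param skin a [skin_mask()].
#' @param ring_px annulus width in pixels (>= 1).
#' @return Surround temperature in degC.
#' @export
surround_temperature <- function(frame, boundary, skin, ring_px = 10L) {
  stopifnot(inherits(frame, "thermal_frame"), inherits(skin, "skin_mask"))
  if (ring_px < 1) stop("`ring_px` must be >= 1", call. = FALSE)
  v <- .poly_vertices(boundary)
  if (!.poly_is_closed(v))
    stop("boundary must be a closed contour", call. = FALSE)
  h <- nrow(frame$grid); w <- ncol(frame$grid)
  xr <- range(v[, 1L]); yr <- range(v[, 2L])
  cols <- max(1L, floor(xr[1L] - ring_px) + 1L):min(w, ceiling(xr[2L] + ring_px) + 1L)
  rows <- max(1L, floor(yr[1L] - ring_px) + 1L):min(h, ceiling(yr[2L] + ring_px) + 1L)
  px <- rep(cols - 1, each = length(rows))
  py <- rep(rows - 1, times = length(cols))
  lin <- rep((cols - 1L) * h, each = length(rows)) + rep(rows, times = length(cols))
  keep <- frame$mask[lin] & skin$mask[lin]
  px <- px[keep]; py <- py[keep]; lin <- lin[keep]
  if (length(lin)) {
    outside <- !point_in_polygon(px, py, v)
    px <- px[outside]; py <- py[outside]; lin <- lin[outside]
  }
  if (length(lin)) {
    near <- dist_to_polygon(px, py, v) <= ring_px
    lin <- lin[near]
  }
  if (!length(lin))
    stop("empty surround ring: no healthy skin around the lesion boundary",
         call. = FALSE)
  mean(frame$grid[lin])
}

#' Per-session lesion measurement record
#'
#' @param session_id session identifier.
#' @param core_temp,surround_temp temperatures in degC.
#' @param area_px lesion area in pixel^2 (>= 0).
#' @param area_cm2 absolute area in cm^2 (may be `NA` without geometry).
#' @param boundary_level isotherm level delimiting the lesion, degC.
#' @param touches_border whether the boundary was border-truncated.
#' @param timestamp session date.
#' @return An object of class `lesion_measurement`; `delta_t` is always
#'   `core_temp - surround_temp`.
#' @export
lesion_measurement <- function(session_id, core_temp, surround_temp,
                               area_px, area_cm2 = NA_real_,
                               boundary_level = NA_real_,
                               touches_border = FALSE, timestamp = NA) {
  stopifnot(area_px >= 0)
  structure(list(session_id = session_id,
                 core_temp = as.numeric(core_temp),
                 surround_temp = as.numeric(surround_temp),
                 delta_t = as.numeric(core_temp) - as.numeric(surround_temp),
                 area_px = as.numeric(area_px),
                 area_cm2 = as.numeric(area_cm2),
                 boundary_level = as.numeric(boundary_level),
                 touches_border = isTRUE(touches_border),
                 timestamp = timestamp),
            class = "lesion_measurement")
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat(sprintf(
    "<lesion_measurement> %s: core %.2f, surround %.2f, delta_t %+.2f degC; area %.1f px^2%s\n",
    x$session_id, x$core_temp, x$surround_temp, x$delta_t, x$area_px,
    if (is.na(x$area_cm2)) "" else sprintf(" (%.2f cm^2)", x$area_cm2)))
  invisible(x)
}

#' Measure a lesion in one session
#'
#' Composes the pipeline for a single frame: extract the isotherm at
#' `boundary_level`, take the largest closed contour as the lesion
#' boundary, compute core and surround temperatures and the pixel and
#' absolute areas.
#'
#' @inheritParams surround_temperature
#' @param boundary_level isotherm level (degC) delimiting the lesion; the
#'   same level must be reused across sessions for comparability.
#' @param core `"mean"` or `"peak"`, see [core_temperature()].
#' @param convention see [absolute_area()].
#' @return A [lesion_measurement()].
#' @export
measure <- function(frame, boundary_level, skin, ring_px = 10L,
                    core = "mean", convention = "pinhole") {
  cs <- extract_contours(frame, boundary_level)
  boundary <- lesion_boundary(cs, boundary_level)
  ct <- core_temperature(frame, boundary, core)
  st <- surround_temperature(frame, boundary, skin, ring_px)
  apx <- shoelace_area(boundary)
  acm <- if (anyNA(c(frame$distance_d, frame$focal_f,
                     frame$pixel_width_W, frame$pixel_length_L))) NA_real_
         else absolute_area(apx, frame, convention = convention)
  lesion_measurement(frame$session_id, ct, st, apx, acm,
                     boundary_level, boundary$touches_border,
                     frame$timestamp)
}

#' Classify a temperature variation against the sensor resolution
#'
#' A variation smaller in magnitude than the sensor's temperature
#' resolution (0.1 degC for typical LWIR microbolometers) is not
#' distinguishable from zero and is classified `"null"`; otherwise the
#' sign decides.
#'
#' @param delta_t temperature difference(s) in degC.
#' @param resolution detection resolution in degC (> 0).
#' @return Character vector over `{"positive", "negative", "null"}`.
#' @export
classify_variation <- function(delta_t, resolution = 0.1) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop("`resolution` must be positive", call. = FALSE)
  ifelse(abs(delta_t) < resolution, "null",
         ifelse(delta_t > 0, "positive", "negative"))
}
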