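# Isotherm contour extraction (marching squares with linear interpolation)
# and area computation: shoelace area in pixel units, pinhole projection to
# cm^2. Hotter nested isotherms localize the lesion; the contour at a fixed
# temperature level, reused across sessions, delimits the lesion boundary.

#' Closed isotherm contour
#'
#' An iso-temperature polygon on the thermal raster. Vertices are
#' sub-pixel (x, y) coordinates with the first vertex repeated as the
#' last, so a triangle has 4 coordinate pairs. Contours that had to be
#' closed along the image or validity-mask border are flagged
#' `touches_border`: their area is computable but truncated.
#'
#' @param level temperature level in degC.
#' @param vertices k x 2 numeric matrix of (x, y); first row equals the
#'   last row (closed), k >= 4 including the duplicate.
#' @param touches_border logical flag.
#' @return An object of class `iso_contour`.
#' @export
iso_contour <- function(level, vertices, touches_border = FALSE) {
  stopifnot(is.numeric(level), is.matrix(vertices), ncol(vertices) == 2L)
  if (nrow(vertices) < 4L)
    stop("a closed contour needs >= 4 coordinate pairs (including the closing vertex)",
         call. = FALSE)
  if (!.poly_is_closed(vertices))
    stop("contour must be closed: first vertex must equal the last", call. = FALSE)
  colnames(vertices) <- c("x", "y")
  structure(list(level = as.numeric(level), vertices = vertices,
                 touches_border = isTRUE(touches_border)),
            class = "iso_contour")
}

#' @export
print.iso_contour <- function(x, ...) {
  cat(sprintf("<iso_contour> level %.2f degC, %d vertices%s, area %.1f px^2\n",
              x$level, nrow(x$vertices) - 1L,
              if (x$touches_border) " (border-truncated)" else "",
              shoelace_area(x)))
  invisible(x)
}

#' Set of isotherm contours over requested levels
#'
#' @param contours list of [iso_contour()] objects.
#' @param levels numeric vector of the levels that were requested (a level
#'   with no contour simply contributes none).
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(contours, levels) {
  lv <- vapply(contours, function(ct) ct$level, numeric(1))
  if (length(lv) && !all(vapply(lv, function(l) any(abs(l - levels) < 1e-9), logical(1))))
    stop("every contour's level must be one of the requested levels", call. = FALSE)
  structure(list(contours = contours, levels = as.numeric(levels)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d contours over %d levels [%.2f .. %.2f] degC\n",
              length(x$contours), length(x$levels),
              min(x$levels), max(x$levels)))
  invisible(x)
}

#' Default contour levels
#'
#' Six equally spaced temperature levels spanning 35.5 to 38.0 degC, the
#' range over which skin temperature typically varies in the presence of
#' vascular anomalies.
#'
#' @return Numeric vector of 6 levels.
#' @export
default_levels <- function() seq(35.5, 38.0, length.out = 6L)

# Marching squares on one level. The valid grid is embedded in a 1-pixel
# pad of `level - 1e6`, so every iso-line closes: chains that would run off
# the image (or into masked-out pixels) are pinched shut essentially at the
# outermost valid pixel centers. Segments generated in cells touching a
# padded or invalid pixel mark the contour as border-truncated.
.marching_squares <- function(grid, mask, level) {
  h <- nrow(grid); w <- ncol(grid)
  lowv <- level - 1e6
  V <- matrix(lowv, h + 2L, w + 2L)
  inner <- grid
  inner[!mask] <- lowv
  V[2:(h + 1L), 2:(w + 1L)] <- inner
  realv <- matrix(FALSE, h + 2L, w + 2L)
  realv[2:(h + 1L), 2:(w + 1L)] <- mask

  I <- V >= level
  H <- h + 2L; W <- w + 2L
  A <- I[1:(H - 1L), 1:(W - 1L)]            # top-left corner of each cell
  B <- I[1:(H - 1L), 2:W]                   # top-right
  C <- I[2:H, 2:W]                          # bottom-right
  D <- I[2:H, 1:(W - 1L)]                   # bottom-left
  case <- 8L * A + 4L * B + 2L * C + 1L * D
  active <- which(case > 0L & case < 15L, arr.ind = TRUE)
  if (!nrow(active)) return(list())

  seg_a <- list(); seg_b <- list(); seg_border <- logical(0)
  nseg <- 0L
  for (ii in seq_len(nrow(active))) {
    r <- active[ii, 1L]; cc <- active[ii, 2L]
    v00 <- V[r, cc];        v01 <- V[r, cc + 1L]
    v10 <- V[r + 1L, cc];   v11 <- V[r + 1L, cc + 1L]
    x0 <- cc - 2; y0 <- r - 2
    # edge crossings (linear interpolation between pixel centers)
    ept <- function(edge) {
      switch(edge,
        top    = c(x0 + (level - v00) / (v01 - v00), y0),
        right  = c(x0 + 1, y0 + (level - v01) / (v11 - v01)),
        bottom = c(x0 + (level - v10) / (v11 - v10), y0 + 1),
        left   = c(x0, y0 + (level - v00) / (v10 - v00)))
    }
    cs <- case[r, cc]
    segs <- switch(as.character(cs),
      "1"  = list(c("left", "bottom")),
      "2"  = list(c("bottom", "right")),
      "3"  = list(c("left", "right")),
      "4"  = list(c("top", "right")),
      "5"  = if ((v00 + v01 + v10 + v11) / 4 >= level)
               list(c("top", "left"), c("bottom", "right"))
             else list(c("top", "right"), c("left", "bottom")),
      "6"  = list(c("top", "bottom")),
      "7"  = list(c("top", "left")),
      "8"  = list(c("top", "left")),
      "9"  = list(c("top", "bottom")),
      "10" = if ((v00 + v01 + v10 + v11) / 4 >= level)
               list(c("top", "right"), c("left", "bottom"))
             else list(c("top", "left"), c("bottom", "right")),
      "11" = list(c("top", "right")),
      "12" = list(c("left", "right")),
      "13" = list(c("bottom", "right")),
      "14" = list(c("left", "bottom")))
    brd <- !(realv[r, cc] && realv[r, cc + 1L] &&
             realv[r + 1L, cc] && realv[r + 1L, cc + 1L])
    for (s in segs) {
      p <- ept(s[1L]); q <- ept(s[2L])
      if (all(abs(p - q) < 1e-12)) next   # degenerate zero-length segment
      nseg <- nseg + 1L
      seg_a[[nseg]] <- p; seg_b[[nseg]] <- q
      seg_border[nseg] <- brd
    }
  }
  if (!nseg) return(list())

  key <- function(p) paste0(round(p[1L] * 1e7), "|", round(p[2L] * 1e7))
  ka <- vapply(seg_a, key, character(1))
  kb <- vapply(seg_b, key, character(1))
  # endpoint -> segment incidence
  inc <- split(rep(seq_len(nseg), 2L), c(ka, kb))
  used <- logical(nseg)
  loops <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    used[s0] <- TRUE
    pts <- list(seg_a[[s0]], seg_b[[s0]])
    brd <- seg_border[s0]
    startk <- ka[s0]
    curk <- kb[s0]
    repeat {
      if (identical(curk, startk)) break
      cand <- inc[[curk]]
      nxt <- cand[!used[cand]]
      if (!length(nxt)) break   # open chain (numerically degenerate); drop later
      s <- nxt[1L]
      used[s] <- TRUE
      brd <- brd || seg_border[s]
      if (identical(ka[s], curk)) {
        pts[[length(pts) + 1L]] <- seg_b[[s]]
        curk <- kb[s]
      } else {
        pts[[length(pts) + 1L]] <- seg_a[[s]]
        curk <- ka[s]
      }
    }
    if (!identical(curk, startk)) next
    vmat <- do.call(rbind, pts)
    # drop the duplicated end point if the walk already landed on the start
    if (all(abs(vmat[1L, ] - vmat[nrow(vmat), ]) < 1e-12))
      vmat <- vmat[-nrow(vmat), , drop = FALSE]
    if (nrow(vmat) < 3L) next
    vmat <- rbind(vmat, vmat[1L, ])
    loops[[length(loops) + 1L]] <- list(vertices = vmat, border = brd)
  }
  loops
}

#' Extract isotherm contour lines from a thermal frame
#'
#' Runs marching squares with linear interpolation between pixel centers
#' at each requested level. Iso-lines that would run off the image or into
#' invalid (masked) pixels are closed along that border and flagged
#' `touches_border`. A level outside the observed temperature range simply
#' yields no contours.
#'
#' @param frame a [thermal_frame()] with at least a 2 x 2 block of valid
#'   pixels.
#' @param levels temperature levels in degC; defaults to
#'   [default_levels()].
#' @return A [contour_set()].
#' @export
extract_contours <- function(frame, levels = default_levels()) {
  stopifnot(inherits(frame, "thermal_frame"))
  if (nrow(frame$grid) < 2L || ncol(frame$grid) < 2L || n_valid(frame) < 4L)
    stop("frame too small for contour extraction (need >= 2 x 2 valid pixels)",
         call. = FALSE)
  levels <- sort(as.numeric(levels))
  out <- list()
  for (lv in levels) {
    loops <- .marching_squares(frame$grid, frame$mask, lv)
    for (lp in loops)
      out[[length(out) + 1L]] <- iso_contour(lv, lp$vertices, lp$border)
  }
  contour_set(out, levels)
}

#' Polygon area by the shoelace (coordinate) method
#'
#' For a closed polygon with vertices `P_1 .. P_k`, `P_1 = P_k`, the area
#' is `A = |S1 - S2| / 2` with `S1 = sum(x_i * y_(i+1))` and
#' `S2 = sum(x_(i+1) * y_i)` taken around the closed ring. The absolute
#' value makes the result independent of traversal orientation, and cyclic
#' relabeling of the start vertex leaves both sums unchanged.
#'
#' @param contour an [iso_contour()] or a closed k x 2 vertex matrix.
#' @return Area in pixel^2 units (squared pixel-center spacing).
#' @export
shoelace_area <- function(contour) {
  v <- .poly_vertices(contour)
  if (!.poly_is_closed(v))
    stop("polygon must be closed (first vertex equal to last)", call. = FALSE)
  if (nrow(unique(.poly_open(v))) < 3L)
    stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  n <- nrow(v)
  x <- v[, 1L]; y <- v[, 2L]
  s1 <- sum(x[-n] * y[-1L])
  s2 <- sum(x[-1L] * y[-n])
  abs(s1 - s2) / 2
}

#' Absolute lesion area from pixel area and acquisition geometry
#'
#' Projects an image-plane pixel area onto the object (skin) plane with the
#' pinhole model: a pixel of physical size `W x L` cm at focal distance `f`
#' subtends a skin patch of `(d/f)^2 * W * L` cm^2 at distance `d`, so
#' `A_abs = area_px * (d/f)^2 * W * L`. The alternative
#' `convention = "printed"` applies a `(f/d)^2` factor instead, reproducing
#' a published form of the relation that de-magnifies rather than
#' magnifies; both coincide when `d = f`. See the package vignette for why
#' the pinhole form is the default.
#'
#' @param area_px area in pixel^2, >= 0.
#' @param frame optional [thermal_frame()] supplying the geometry.
#' @param distance_d,focal_f,pixel_width_W,pixel_length_L geometry in cm,
#'   overriding (or replacing) the frame's metadata.
#' @param convention `"pinhole"` (default) or `"printed"`.
#' @return Absolute area in cm^2.
#' @export
absolute_area <- function(area_px, frame = NULL,
                          distance_d = NULL, focal_f = NULL,
                          pixel_width_W = NULL, pixel_length_L = NULL,
                          convention = c("pinhole", "printed")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(area_px), all(area_px >= 0))
  geo <- function(override, field) {
    if (!is.null(override)) return(as.numeric(override))
    if (!is.null(frame)) return(frame[[field]])
    NA_real_
  }
  d <- geo(distance_d, "distance_d"); f <- geo(focal_f, "focal_f")
  W <- geo(pixel_width_W, "pixel_width_W"); L <- geo(pixel_length_L, "pixel_length_L")
  if (anyNA(c(d, f, W, L)))
    stop("absolute area needs distance_d, focal_f, pixel_width_W and pixel_length_L",
         call. = FALSE)
  mag <- if (convention == "pinhole") (d / f)^2 else (f / d)^2
  area_px * mag * W * L
}

#' Select the lesion boundary contour at a level
#'
#' Returns the largest-area closed contour at the requested level: the
#' lesion outline, with any nested hotter contours or small noise loops at
#' the same level discarded. Ties are broken deterministically by the
#' smallest centroid y (row), then x (column).
#'
#' @param contours a [contour_set()].
#' @param level one of the extracted levels.
#' @return An [iso_contour()].
#' @export
lesion_boundary <- function(contours, level) {
  stopifnot(inherits(contours, "contour_set"))
  if (!any(abs(contours$levels - level) < 1e-9))
    stop("level ", level, " was not among the extracted levels", call. = FALSE)
  at <- Filter(function(ct) abs(ct$level - level) < 1e-9, contours$contours)
  if (!length(at))
    stop("no closed contour at level ", level, call. = FALSE)
  areas <- vapply(at, shoelace_area, numeric(1))
  best <- which(areas > max(areas) - 1e-9)
  if (length(best) > 1L) {
    cents <- t(vapply(at[best], function(ct) polygon_centroid(ct$vertices),
                      numeric(2)))
    best <- best[order(cents[, 2L], cents[, 1L])][1L]
  }
  at[[best]]
}

#' Export a contour set as GeoJSON
#'
#' Writes each contour as a GeoJSON Polygon feature with `level`,
#' `area_px` and `touches_border` properties (plus `area_cm2` when the
#' frame geometry is supplied). Coordinates are raster pixel coordinates,
#' not geographic ones.
#'
#' @param contours a [contour_set()].
#' @param path output file.
#' @param frame optional [thermal_frame()] for absolute areas.
#' @param convention area projection convention, see [absolute_area()].
#' @return `path`, invisibly.
#' @export
contours_geojson <- function(contours, path, frame = NULL,
                             convention = "pinhole") {
  stopifnot(inherits(contours, "contour_set"))
  feats <- lapply(contours$contours, function(ct) {
    props <- list(level = ct$level, area_px = shoelace_area(ct),
                  touches_border = ct$touches_border)
    if (!is.null(frame) && !is.na(frame$distance_d))
      props$area_cm2 <- absolute_area(props$area_px, frame,
                                      convention = convention)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ct$vertices)),
                           function(i) unname(ct$vertices[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
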