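# Skin segmentation: temperature histogram -> background pre-filter ->
# Otsu threshold -> binary mask. The scene background (walls, clothes,
# objects) forms a cold histogram mode; discarding everything below a
# physiological floor (34 degC by default) restores the approximate
# bimodality Otsu's method assumes.

#' Temperature histogram of a thermal frame
#'
#' Bins the valid-pixel temperatures into contiguous bins of width
#' `bin_width`. Bins are left-closed `[e_i, e_{i+1})` with the last bin
#' right-closed, and the edges span exactly the observed temperature range,
#' so the counts always conserve the number of valid pixels.
#'
#' @param frame a [thermal_frame()] with at least one valid pixel.
#' @param bin_width bin width in degrees C. The default 0.05 is half the
#'   0.1 degC resolution of typical LWIR microbolometers, so sensor-level
#'   detail is not lost to binning.
#' @return An object of class `temperature_histogram` with fields
#'   `bin_edges` (length `nbins + 1`, ascending) and `counts`.
#' @export
compute_histogram <- function(frame, bin_width = 0.05) {
  stopifnot(inherits(frame, "thermal_frame"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive", call. = FALSE)
  x <- valid_temps(frame)
  if (!length(x))
    stop("frame has no valid pixels to histogram", call. = FALSE)
  lo <- min(x); hi <- max(x)
  # one bin past the maximum so a value on the top edge gets its own bin
  nbins <- max(1L, floor((hi - lo) / bin_width) + 1L)
  edges <- lo + bin_width * (0:nbins)
  if (edges[nbins + 1L] < hi) { # guard against fp shortfall at the top edge
    nbins <- nbins + 1L
    edges <- c(edges, edges[nbins] + bin_width)
  }
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  structure(list(bin_edges = edges, counts = tabulate(idx, nbins),
                 bin_width = bin_width),
            class = "temperature_histogram")
}

#' @export
print.temperature_histogram <- function(x, ...) {
  cat(sprintf("<temperature_histogram> %d bins of %.3g degC over [%.2f, %.2f], %d pixels\n",
              length(x$counts), x$bin_width, x$bin_edges[1L],
              x$bin_edges[length(x$bin_edges)], sum(x$counts)))
  invisible(x)
}

#' Discard sub-physiological background temperatures
#'
#' Marks every pixel colder than `floor` invalid. Inert scene objects are
#' not compatible with body temperature, so removing everything below
#' 34 degC strips the background histogram mode before Otsu thresholding.
#'
#' @param frame a [thermal_frame()].
#' @param floor temperature floor in degC; pixels with `T < floor` become
#'   invalid (pixels exactly at the floor are kept).
#' @return A copy of `frame` with cold pixels invalidated.
#' @export
prefilter_background <- function(frame, floor = 34.0) {
  stopifnot(inherits(frame, "thermal_frame"), is.finite(floor))
  keep <- frame$mask & !is.na(frame$grid) & frame$grid >= floor
  out <- frame
  out$mask <- keep
  out$grid[!keep] <- NA_real_
  out
}

#' Otsu's optimum threshold on a temperature histogram
#'
#' Evaluates every interior bin edge as a candidate threshold and returns
#' the edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`, where `w0`, `w1` are the class pixel counts
#' (bins strictly below / at-or-above the edge) and `mu0`, `mu1` the class
#' mean temperatures taken at bin centers. Ties are broken toward the
#' lowest threshold, which keeps the most skin in the mask.
#'
#' @param hist a [compute_histogram()] result with at least two non-empty
#'   bins (otherwise no bimodal split exists and an error is raised).
#' @return The threshold temperature `TH` in degC (a bin edge). The
#'   attained between-class variance is attached as attribute `"bcv"`.
#' @export
otsu_threshold <- function(hist) {
  stopifnot(inherits(hist, "temperature_histogram"))
  cnt <- as.numeric(hist$counts)
  if (sum(cnt > 0) < 2L)
    stop("Otsu threshold needs at least 2 non-empty bins (no bimodality possible)",
         call. = FALSE)
  edges <- hist$bin_edges
  centers <- (edges[-length(edges)] + edges[-1L]) / 2
  n <- length(cnt)
  # cumulative class-0 statistics for each candidate split k: bins 1..k-1
  cw <- cumsum(cnt)
  cm <- cumsum(cnt * centers)
  total_w <- cw[n]
  total_m <- cm[n]
  k <- 2:n                       # candidate edge indices
  w0 <- cw[k - 1L]
  w1 <- total_w - w0
  ok <- w0 > 0 & w1 > 0
  mu0 <- cm[k - 1L] / w0
  mu1 <- (total_m - cm[k - 1L]) / w1
  bcv <- ifelse(ok, w0 * w1 * (mu0 - mu1)^2, -Inf)
  # lowest edge among ties; the tolerance keeps mathematically exact ties
  # exact despite the cumulative-sum evaluation order
  mx <- max(bcv)
  best <- which(bcv >= mx - 1e-10 * abs(mx))[1L]
  structure(edges[k[best]], bcv = bcv[best])
}

#' Skin mask produced by thresholding
#'
#' @param mask logical matrix; `TRUE` marks skin pixels.
#' @param threshold_TH the Otsu threshold that produced the mask, degC.
#' @return An object of class `skin_mask`.
#' @export
skin_mask <- function(mask, threshold_TH) {
  stopifnot(is.logical(mask), is.matrix(mask), is.numeric(threshold_TH))
  structure(list(mask = mask, threshold_TH = as.numeric(threshold_TH)),
            class = "skin_mask")
}

#' @export
print.skin_mask <- function(x, ...) {
  cat(sprintf("<skin_mask> %d x %d px, %d skin pixels, TH = %.3f degC\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold_TH))
  invisible(x)
}

#' Apply a fixed temperature threshold to a frame
#'
#' @param frame a [thermal_frame()].
#' @param threshold_TH threshold in degC; pixels with `T >= TH` are skin.
#' @return A [skin_mask()].
#' @export
apply_threshold <- function(frame, threshold_TH) {
  stopifnot(inherits(frame, "thermal_frame"))
  m <- frame$mask & !is.na(frame$grid) & frame$grid >= threshold_TH
  skin_mask(m, threshold_TH)
}

#' Segment skin from a thermal frame
#'
#' The four-step segmentation pipeline: (1) histogram of valid
#' temperatures, after (2) pre-filtering everything below `floor`; (3)
#' Otsu's method on the histogram gives the optimum threshold `TH`; (4)
#' pixels at or above `TH` form the skin mask. With the default
#' `floor = 34` the pre-filter removes the scene background and `TH`
#' separates the remaining cooler class from the hotter one; with a floor
#' below the background temperature, `TH` instead separates background
#' from skin. Both uses are legitimate depending on scene content.
#'
#' @inheritParams compute_histogram
#' @inheritParams prefilter_background
#' @return A [skin_mask()] storing the threshold `TH`.
#' @export
segment_skin <- function(frame, floor = 34.0, bin_width = 0.05) {
  pf <- prefilter_background(frame, floor)
  hist <- compute_histogram(pf, bin_width)
  th <- otsu_threshold(hist)
  apply_threshold(pf, as.numeric(th))
}
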