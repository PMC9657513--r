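# Synthetic thermal phantoms. Scene model: a cool inert background, a warm
# skin region at physiological temperature, zero or more hemangioma-like
# hot spots with Gaussian radial profiles, optional sub-physiological hair
# occlusion, and additive Gaussian sensor noise. The Gaussian profile is
# the minimal smooth lesion model producing the nested-isotherm structure
# seen on real lesions, and it has a closed-form iso-area, so the whole
# pipeline can be validated against analytic ground truth.

#' Phantom scene specification
#'
#' Defaults encode a typical acquisition: ~25 degC room background,
#' 36.2 degC skin, lesions 0.1-2 degC warmer than skin, sensor noise with
#' 0.05 degC standard deviation (half the 0.1 degC resolution of the
#' LWIR sensor). The background must stay below the 34 degC pre-filter
#' floor and the skin at or above it, matching the scene assumption the
#' segmentation rests on.
#'
#' @param height,width frame size in pixels.
#' @param T_bg background temperature, degC (< 34).
#' @param T_skin healthy-skin temperature, degC (>= 34).
#' @param skin_margin width in pixels of the background border framing the
#'   rectangular skin region.
#' @param lesions list of lesions, each `list(x =, y =, sigma =,
#'   amplitude =)`: center in pixel coordinates, Gaussian width in px
#'   (> 0), peak temperature elevation above skin in degC (> 0).
#' @param hair_occlusion_frac fraction of skin pixels occluded by hair,
#'   in [0, 1); hair reads as 30-33.9 degC and is removed by the 34 degC
#'   pre-filter.
#' @param noise_sd additive sensor noise standard deviation, degC.
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   phantoms.
#' @param distance_d,focal_f,pixel_width_W,pixel_length_L acquisition
#'   geometry (cm) stamped onto the generated frames; defaults are the
#'   30 cm protocol distance and a 17 um microbolometer pixel pitch.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 120L, width = 120L,
                         T_bg = 25, T_skin = 36.2, skin_margin = 6L,
                         lesions = list(), hair_occlusion_frac = 0,
                         noise_sd = 0.05, seed = 1L,
                         distance_d = 30, focal_f = 0.95,
                         pixel_width_W = 0.0017, pixel_length_L = 0.0017) {
  if (height < 4L || width < 4L) stop("phantom must be at least 4 x 4 px", call. = FALSE)
  if (!(T_bg < 34 && T_skin >= 34))
    stop("phantom requires T_bg < 34 <= T_skin (the pre-filter's scene assumption)",
         call. = FALSE)
  if (hair_occlusion_frac < 0 || hair_occlusion_frac >= 1)
    stop("`hair_occlusion_frac` must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (2L * skin_margin >= min(height, width))
    stop("`skin_margin` leaves no skin region", call. = FALSE)
  for (ls in lesions) {
    if (is.null(ls$x) || is.null(ls$y) || is.null(ls$sigma) || is.null(ls$amplitude))
      stop("each lesion needs x, y, sigma and amplitude", call. = FALSE)
    if (ls$sigma <= 0 || ls$amplitude <= 0)
      stop("lesion sigma and amplitude must be positive", call. = FALSE)
    if (ls$x < skin_margin || ls$x > width - 1L - skin_margin ||
        ls$y < skin_margin || ls$y > height - 1L - skin_margin)
      stop("lesion center must lie inside the skin region", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 T_bg = T_bg, T_skin = T_skin,
                 skin_margin = as.integer(skin_margin), lesions = lesions,
                 hair_occlusion_frac = hair_occlusion_frac,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 distance_d = distance_d, focal_f = focal_f,
                 pixel_width_W = pixel_width_W,
                 pixel_length_L = pixel_length_L),
            class = "phantom_spec")
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic radiometric scene with ground truth
#'
#' Builds `T(x, y) = T_bg` outside the skin region and, inside it,
#' `T_skin + sum_j amplitude_j * exp(-((x - x_j)^2 + (y - y_j)^2) /
#' (2 sigma_j^2))` plus `Normal(0, noise_sd)` sensor noise; a random
#' fraction of skin pixels is then overwritten with hair-like 30-33.9 degC
#' values. All randomness is driven by `spec$seed` (noise first, then hair
#' placement), so a fixed seed reproduces the frame bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @param session_id,timestamp session metadata stamped on the frame.
#' @return A list with `frame` (a [thermal_frame()]) and `truth` (class
#'   `phantom_truth`): per-lesion analytic parameters, the label raster
#'   (`"background"`, `"skin"`, `"hair"`), and the spec.
#' @export
generate_phantom <- function(spec, session_id = "S1", timestamp = NA) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width; m <- spec$skin_margin
  x <- matrix(rep(0:(w - 1L), each = h), h, w)
  y <- matrix(rep(0:(h - 1L), times = w), h, w)
  skin <- x >= m & x <= w - 1L - m & y >= m & y <= h - 1L - m
  g <- matrix(spec$T_bg, h, w)
  base <- matrix(spec$T_skin, h, w)
  for (ls in spec$lesions)
    base <- base + ls$amplitude *
      exp(-((x - ls$x)^2 + (y - ls$y)^2) / (2 * ls$sigma^2))
  labels <- matrix("background", h, w)
  labels[skin] <- "skin"
  g <- .with_seed(spec$seed, {
    if (spec$noise_sd > 0)
      base <- base + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    g[skin] <- base[skin]
    if (spec$hair_occlusion_frac > 0) {
      sk_idx <- which(skin)
      n_hair <- floor(spec$hair_occlusion_frac * length(sk_idx))
      if (n_hair > 0L) {
        hair_idx <- sample(sk_idx, n_hair)
        g[hair_idx] <- stats::runif(n_hair, 30, 33.9)
        labels[hair_idx] <- "hair"
      }
    }
    g
  })
  frame <- thermal_frame(g, distance_d = spec$distance_d,
                         focal_f = spec$focal_f,
                         pixel_width_W = spec$pixel_width_W,
                         pixel_length_L = spec$pixel_length_L,
                         session_id = session_id, timestamp = timestamp)
  truth <- structure(list(lesions = spec$lesions, T_skin = spec$T_skin,
                          T_bg = spec$T_bg, labels = labels,
                          noise_sd = spec$noise_sd, spec = spec),
                     class = "phantom_truth")
  list(frame = frame, truth = truth)
}

#' Analytic iso-area of a Gaussian phantom lesion
#'
#' For a lesion with peak elevation `amplitude` over skin at `T_skin` and
#' Gaussian width `sigma`, the set above level `L` (with
#' `T_skin < L < T_skin + amplitude`) is a disk of radius
#' `rho = sigma * sqrt(2 * log(amplitude / (L - T_skin)))`, so its area is
#' `pi * 2 * sigma^2 * log(amplitude / (L - T_skin))`; 0 outside that
#' level range.
#'
#' @param truth a `phantom_truth` (or a [phantom_spec()]).
#' @param level temperature level in degC.
#' @param lesion index of the lesion.
#' @return Area in pixel^2.
#' @export
phantom_iso_area <- function(truth, level, lesion = 1L) {
  ls <- truth$lesions[[lesion]]
  ts <- truth$T_skin
  if (level <= ts || level >= ts + ls$amplitude) return(0)
  pi * 2 * ls$sigma^2 * log(ls$amplitude / (level - ts))
}

#' Analytic core and surround means of a Gaussian phantom lesion
#'
#' Closed-form expectations of the pipeline's measurements on a noiseless
#' phantom, used as ground truth in recovery tests: the mean temperature
#' over the iso-disk at `level` (the lesion core, as delimited by the
#' boundary isotherm) and over the annulus of width `ring_px` just outside
#' it (the surrounding skin, which still carries the Gaussian tail).
#'
#' @inheritParams phantom_iso_area
#' @param ring_px annulus width in pixels.
#' @return `phantom_core_mean()` / `phantom_surround_mean()`: temperature
#'   in degC; `phantom_delta_t()`: their difference.
#' @export
phantom_core_mean <- function(truth, level, lesion = 1L) {
  ls <- truth$lesions[[lesion]]
  ts <- truth$T_skin
  stopifnot(level > ts, level < ts + ls$amplitude)
  rho2 <- 2 * ls$sigma^2 * log(ls$amplitude / (level - ts))
  # mean of A*exp(-r^2/2s^2) over the disk r <= rho
  ts + ls$amplitude * (2 * ls$sigma^2 / rho2) * (1 - exp(-rho2 / (2 * ls$sigma^2)))
}

#' @rdname phantom_core_mean
#' @export
phantom_surround_mean <- function(truth, level, ring_px = 10, lesion = 1L) {
  ls <- truth$lesions[[lesion]]
  ts <- truth$T_skin
  stopifnot(level > ts, level < ts + ls$amplitude)
  rho <- ls$sigma * sqrt(2 * log(ls$amplitude / (level - ts)))
  ro <- rho + ring_px
  s2 <- ls$sigma^2
  ts + ls$amplitude * 2 * s2 *
    (exp(-rho^2 / (2 * s2)) - exp(-ro^2 / (2 * s2))) / (ro^2 - rho^2)
}

#' @rdname phantom_core_mean
#' @export
phantom_delta_t <- function(truth, level, ring_px = 10, lesion = 1L) {
  phantom_core_mean(truth, level, lesion) -
    phantom_surround_mean(truth, level, ring_px, lesion)
}

#' Generate a longitudinal phantom series emulating treatment response
#'
#' Session `t` scales every lesion's amplitude by `amplitude_scale[t]` and
#' width by `sigma_scale[t]`. Shrinking scales emulate involution under
#' treatment; a scale rebounding above a previous session emulates
#' regrowth after treatment discontinuation. Each session draws fresh
#' noise from a seed derived deterministically from `spec$seed`, and
#' sessions are stamped with dates three months apart, matching the
#' clinical protocol.
#'
#' @param spec a [phantom_spec()]; its lesions define session 1 at scale 1.
#' @param response data.frame (or list of rows) with columns `session`,
#'   `amplitude_scale`, `sigma_scale`, all scales > 0.
#' @param start_date date of the first session.
#' @return List of `list(frame, truth)` pairs, one per session.
#' @export
generate_series <- function(spec, response,
                            start_date = as.Date("2020-01-01")) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.list(response) && !is.data.frame(response))
    response <- do.call(rbind, lapply(response, function(r) as.data.frame(as.list(r))))
  stopifnot(all(c("session", "amplitude_scale", "sigma_scale") %in% names(response)))
  if (any(response$amplitude_scale <= 0) || any(response$sigma_scale <= 0))
    stop("scales must be positive", call. = FALSE)
  response <- response[order(response$session), , drop = FALSE]
  lapply(seq_len(nrow(response)), function(i) {
    sp <- spec
    sp$lesions <- lapply(spec$lesions, function(ls) {
      ls$amplitude <- ls$amplitude * response$amplitude_scale[i]
      ls$sigma <- ls$sigma * response$sigma_scale[i]
      ls
    })
    sp$seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    generate_phantom(sp, session_id = sprintf("S%d", response$session[i]),
                     timestamp = start_date + 90L * (i - 1L))
  })
}
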