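# Longitudinal assessment: a lesion tracked over clinical sessions
# (typically three, spaced three months apart). The thermographic verdict
# rests on the evolution of delta_t (lesion core minus surrounding skin)
# and of the iso-area; it is compared against the dermatologists' clinical
# response through three agreement rules:
#   (i)   temperature increment over time  + negative clinical response,
#   (ii)  temperature decrement over time  + positive clinical response,
#   (iii) null temperature increment, but the lesion area substantially
#         lower than before, + positive clinical response.

#' Time-ordered series of measurements for one lesion
#'
#' @param lesion_id lesion identifier.
#' @param measurements list of [lesion_measurement()] records in session
#'   order; timestamps, where present, must be strictly increasing.
#' @return An object of class `session_series`.
#' @export
session_series <- function(lesion_id, measurements) {
  if (!is.list(measurements) || !length(measurements) ||
      !all(vapply(measurements, inherits, logical(1), "lesion_measurement")))
    stop("`measurements` must be a non-empty list of lesion_measurement records",
         call. = FALSE)
  ts <- lapply(measurements, `[[`, "timestamp")
  num <- suppressWarnings(vapply(ts, function(t)
    if (inherits(t, "Date")) as.numeric(t) else as.numeric(t), numeric(1)))
  if (all(is.finite(num)) && length(num) > 1L && any(diff(num) <= 0))
    stop("measurement timestamps must be strictly increasing", call. = FALSE)
  structure(list(lesion_id = lesion_id, measurements = measurements),
            class = "session_series")
}

#' @export
print.session_series <- function(x, ...) {
  cat(sprintf("<session_series> lesion %s, %d sessions, delta_t: %s degC\n",
              x$lesion_id, length(x$measurements),
              paste(sprintf("%+.2f", delta_ts(x)), collapse = " -> ")))
  invisible(x)
}

#' @rdname session_series
#' @param series a `session_series`.
#' @return `delta_ts()`: numeric vector of per-session delta_t values.
#' @export
delta_ts <- function(series) {
  stopifnot(inherits(series, "session_series"))
  vapply(series$measurements, `[[`, numeric(1), "delta_t")
}

#' Temperature trend of a lesion across sessions
#'
#' Classifies the change in delta_t between the first and last session
#' with [classify_variation()]: a change smaller than the sensor
#' resolution is a null trend. `method = "slope"` instead fits a least
#' squares line to delta_t versus session date (or session index when
#' dates are absent) and classifies the fitted total change over the
#' observation span, which is less sensitive to a single aberrant session.
#'
#' @param series a [session_series()] with >= 2 measurements.
#' @param resolution sensor resolution in degC.
#' @param method `"first_last"` (default) or `"slope"`.
#' @return `"positive"`, `"negative"` or `"null"`.
#' @export
temperature_trend <- function(series, resolution = 0.1,
                              method = c("first_last", "slope")) {
  method <- match.arg(method)
  dts <- delta_ts(series)
  if (length(dts) < 2L)
    stop("temperature trend needs at least 2 measurements", call. = FALSE)
  change <- if (method == "first_last") {
    dts[length(dts)] - dts[1L]
  } else {
    tvec <- vapply(series$measurements, function(m)
      if (inherits(m$timestamp, "Date")) as.numeric(m$timestamp) else NA_real_,
      numeric(1))
    if (anyNA(tvec)) tvec <- seq_along(dts)
    fit <- stats::lm.fit(cbind(1, tvec), dts)
    unname(fit$coefficients[2L]) * (tvec[length(tvec)] - tvec[1L])
  }
  classify_variation(change, resolution)
}

#' Relative area change between first and last session
#'
#' @param series a [session_series()] with >= 2 measurements and a
#'   positive first-session area.
#' @return `(area_last - area_first) / area_first`, dimensionless; -0.5
#'   means the lesion iso-area halved.
#' @export
area_change <- function(series) {
  stopifnot(inherits(series, "session_series"))
  a <- vapply(series$measurements, `[[`, numeric(1), "area_px")
  if (length(a) < 2L)
    stop("area change needs at least 2 measurements", call. = FALSE)
  if (!is.finite(a[1L]) || a[1L] <= 0)
    stop("first-session area must be positive", call. = FALSE)
  (a[length(a)] - a[1L]) / a[1L]
}

#' Agreement between thermographic trend and clinical response
#'
#' Pure rule-based verdict: `"agree"` iff one of the three rules holds —
#' (i) positive temperature trend and negative clinical response,
#' (ii) negative temperature trend and positive clinical response,
#' (iii) null temperature trend, positive clinical response, and an area
#' change at or below `substantial_frac` (the lesion shrank substantially
#' even though the temperature contrast was below the sensor resolution).
#' Anything else is `"disagree"`.
#'
#' @param trend `"positive"`, `"negative"` or `"null"`.
#' @param area_change_frac relative area change, see [area_change()].
#' @param clinical_response `"positive"` (improvement: flattening,
#'   disappearance, decreased erythema) or `"negative"`.
#' @param substantial_frac threshold for a "substantially lower" area;
#'   default -0.2, i.e. at least a 20% reduction.
#' @return `"agree"` or `"disagree"`.
#' @export
agreement <- function(trend, area_change_frac, clinical_response,
                      substantial_frac = -0.2) {
  trend <- match.arg(trend, c("positive", "negative", "null"))
  clinical_response <- match.arg(clinical_response, c("positive", "negative"))
  ok <- (trend == "positive" && clinical_response == "negative") ||
        (trend == "negative" && clinical_response == "positive") ||
        (trend == "null" && clinical_response == "positive" &&
           is.finite(area_change_frac) && area_change_frac <= substantial_frac)
  if (ok) "agree" else "disagree"
}

#' Full longitudinal assessment of one lesion
#'
#' @inheritParams temperature_trend
#' @inheritParams agreement
#' @return An object of class `evolution_assessment` with fields `trend`,
#'   `area_change_frac`, `clinical_response`, `verdict` and the
#'   `substantial_frac` used.
#' @export
assess_evolution <- function(series, clinical_response, resolution = 0.1,
                             substantial_frac = -0.2,
                             method = "first_last") {
  trend <- temperature_trend(series, resolution, method)
  ac <- area_change(series)
  structure(list(lesion_id = series$lesion_id, trend = trend,
                 area_change_frac = ac,
                 clinical_response = clinical_response,
                 verdict = agreement(trend, ac, clinical_response,
                                     substantial_frac),
                 substantial_frac = substantial_frac),
            class = "evolution_assessment")
}

#' @export
print.evolution_assessment <- function(x, ...) {
  cat(sprintf(
    "<evolution_assessment> lesion %s: trend %s, area change %+.1f%%, clinical %s -> %s\n",
    x$lesion_id, x$trend, 100 * x$area_change_frac, x$clinical_response,
    toupper(x$verdict)))
  invisible(x)
}

#' Cohort summary of first-visit temperature variations
#'
#' Tallies per-lesion variation classes and summarizes the delta_t
#' distribution the way a clinical cohort table does: counts by class,
#' percentage of lesions with a detectable variation (positive or
#' negative, to one decimal), mean delta_t with a 90% Student-t confidence
#' interval, and — when per-lesion last-visit values are available — the
#' mean change in delta_t over treatment.
#'
#' @param records either a data.frame with columns `lesion_id`, `delta_t`
#'   (may be `NA` when only classes are known), optionally `class`
#'   (derived from `delta_t` via [classify_variation()] when absent),
#'   optionally `delta_t_last` and `patient_id`; or a list of
#'   [session_series()] objects, from which first/last delta_t and the
#'   class of the first-visit delta_t are taken.
#' @param n_patients number of patients, if not derivable from a
#'   `patient_id` column.
#' @param resolution sensor resolution for class derivation, degC.
#' @param conf_level confidence level of the t-interval (default 0.90).
#' @return An object of class `cohort_summary`. With a single lesion (or
#'   all-`NA` delta_t) the interval is degenerate and reported as `NA`
#'   with `ci_degenerate = TRUE`.
#' @export
summarize_cohort <- function(records, n_patients = NULL, resolution = 0.1,
                             conf_level = 0.90) {
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, inherits, logical(1), "session_series"))) {
    records <- do.call(rbind, lapply(records, function(s) {
      dts <- delta_ts(s)
      data.frame(lesion_id = s$lesion_id, delta_t = dts[1L],
                 delta_t_last = dts[length(dts)])
    }))
  }
  if (!is.data.frame(records) || !nrow(records))
    stop("`records` must be a non-empty data.frame or list of session_series",
         call. = FALSE)
  if (is.null(records$class)) {
    if (is.null(records$delta_t))
      stop("records need a `class` or `delta_t` column", call. = FALSE)
    records$class <- classify_variation(records$delta_t, resolution)
  }
  if (!all(records$class %in% c("positive", "negative", "null")))
    stop("variation classes must be 'positive', 'negative' or 'null'",
         call. = FALSE)
  n_lesions <- nrow(records)
  n_pos <- sum(records$class == "positive")
  n_neg <- sum(records$class == "negative")
  n_null <- sum(records$class == "null")
  pct <- round(100 * (n_pos + n_neg) / n_lesions, 1L)
  dt <- records$delta_t
  dt_ok <- if (is.null(dt)) numeric(0) else dt[is.finite(dt)]
  mean_dt <- if (length(dt_ok)) mean(dt_ok) else NA_real_
  degenerate <- length(dt_ok) < 2L || stats::sd(dt_ok) == 0
  ci <- if (degenerate) c(NA_real_, NA_real_) else {
    half <- stats::qt(1 - (1 - conf_level) / 2, length(dt_ok) - 1L) *
      stats::sd(dt_ok) / sqrt(length(dt_ok))
    mean_dt + c(-half, half)
  }
  treat <- if (!is.null(records$delta_t_last))
    mean(records$delta_t_last - records$delta_t, na.rm = TRUE) else NA_real_
  if (is.null(n_patients))
    n_patients <- if (!is.null(records$patient_id))
      length(unique(records$patient_id)) else NA_integer_
  structure(list(n_patients = n_patients, n_lesions = n_lesions,
                 n_positive = n_pos, n_negative = n_neg, n_null = n_null,
                 pct_with_variation = pct, mean_delta_t = mean_dt,
                 ci90 = ci, ci_degenerate = degenerate,
                 conf_level = conf_level,
                 mean_treatment_change = treat),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s patients, %d lesions: %d positive / %d negative / %d null\n",
              ifelse(is.na(x$n_patients), "?", x$n_patients), x$n_lesions,
              x$n_positive, x$n_negative, x$n_null))
  cat(sprintf("  with variation: %.1f%%\n", x$pct_with_variation))
  if (!is.na(x$mean_delta_t))
    cat(sprintf("  mean delta_t %.2f degC, %d%% CI [%s]\n", x$mean_delta_t,
                round(100 * x$conf_level),
                if (x$ci_degenerate) "degenerate"
                else sprintf("%.2f, %.2f", x$ci90[1L], x$ci90[2L])))
  if (!is.na(x$mean_treatment_change))
    cat(sprintf("  mean treatment change %+.2f degC\n", x$mean_treatment_change))
  invisible(x)
}

#' Expand printed cohort counts into per-lesion class records
#'
#' Clinical summary tables often print only counts per variation class.
#' This helper expands such counts into the per-lesion record form
#' [summarize_cohort()] consumes, with unknown per-lesion delta_t as `NA`.
#'
#' @param n_positive,n_negative,n_null class counts.
#' @param n_patients optional patient count carried through.
#' @return A data.frame of per-lesion records.
#' @export
cohort_from_counts <- function(n_positive, n_negative, n_null,
                               n_patients = NULL) {
  cls <- rep(c("positive", "negative", "null"),
             times = c(n_positive, n_negative, n_null))
  df <- data.frame(lesion_id = sprintf("L%03d", seq_along(cls)),
                   delta_t = NA_real_, class = cls,
                   stringsAsFactors = FALSE)
  attr(df, "n_patients") <- n_patients
  df
}

#' Packaged monitored-lesion fixture
#'
#' Loads the packaged encoding of the 17 monitored hemangiomas from the
#' second (nine-month, nine-patient) phase of the clinical study: one row
#' per lesion with its overall temperature-variation trend, the
#' dermatologists' clinical response (positive = flattening,
#' disappearance or decreased erythema), the relative area trend, and any
#' transient event (regrowth after early treatment discontinuation,
#' ulceration) kept as an annotation that does not enter the verdict.
#'
#' @return A data.frame with columns `case`, `lesion_id`, `trend`,
#'   `clinical_response`, `area_change_frac`, `transient_event`.
#' @export
monitored_lesions <- function() {
  utils::read.csv(system.file("extdata", "table4_lesions.csv",
                              package = "thermolesion"),
                  stringsAsFactors = FALSE)
}

#' Packaged first-phase cohort counts
#'
#' Loads the packaged per-class lesion counts from the first (single
#' visit, 55 patient) phase of the clinical study.
#'
#' @return A list with `n_patients`, `n_positive`, `n_negative`, `n_null`.
#' @export
cohort_counts <- function() {
  jsonlite::read_json(system.file("extdata", "table1_counts.json",
                                  package = "thermolesion"),
                      simplifyVector = TRUE)
}

#' Replay the agreement rules over per-lesion records
#'
#' @param records a data.frame as returned by [monitored_lesions()].
#' @param substantial_frac see [agreement()].
#' @return Character vector of verdicts, one per record.
#' @export
replay_agreement <- function(records, substantial_frac = -0.2) {
  vapply(seq_len(nrow(records)), function(i)
    agreement(records$trend[i], records$area_change_frac[i],
              records$clinical_response[i], substantial_frac),
    character(1))
}
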