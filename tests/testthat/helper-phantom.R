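# Shared phantom shortcuts for tests.

single_lesion_spec <- function(sigma = 15, amplitude = 1.0, size = 140L,
                               noise_sd = 0, seed = 11L, ...) {
  phantom_spec(height = size, width = size, skin_margin = 5L,
               lesions = list(list(x = (size - 1) / 2, y = (size - 1) / 2,
                                   sigma = sigma, amplitude = amplitude)),
               noise_sd = noise_sd, seed = seed, ...)
}

flat_frame <- function(temp = 36.5, size = 80L, ...) {
  thermal_frame(matrix(temp, size, size), ...)
}

# A measurement series with given delta_t (and optionally area) values,
# one session every 90 days.
make_series <- function(dts, areas = rep(100, length(dts)),
                        lesion_id = "L1") {
  ms <- lapply(seq_along(dts), function(i)
    lesion_measurement(sprintf("S%d", i),
                       core_temp = 36.5 + dts[i], surround_temp = 36.5,
                       area_px = areas[i],
                       timestamp = as.Date("2020-01-01") + 90 * (i - 1)))
  session_series(lesion_id, ms)
}
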