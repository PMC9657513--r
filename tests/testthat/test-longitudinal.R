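test_that("temperature trend classifies first-vs-last delta_t change", {
  expect_equal(temperature_trend(make_series(c(0.38, 0.30, 0.27))), "negative")
  expect_equal(temperature_trend(make_series(c(0.2, 0.2, 0.2))), "null")
  expect_equal(temperature_trend(make_series(c(0.1, 0.4))), "positive")
  expect_error(temperature_trend(make_series(0.3)), "at least 2")
  # slope method on a clean monotone series agrees
  expect_equal(temperature_trend(make_series(c(0.5, 0.35, 0.2)),
                                 method = "slope"), "negative")
})

test_that("temperature trend is antisymmetric under time reversal", {
  set.seed(77)
  flip <- c(positive = "negative", negative = "positive", null = "null")
  for (i in 1:20) {
    dts <- runif(sample(2:5, 1), -0.5, 0.5)
    fwd <- temperature_trend(make_series(dts))
    rev <- temperature_trend(make_series(rev(dts)))
    expect_equal(unname(flip[fwd]), rev)
  }
})

test_that("series construction enforces time ordering", {
  ms <- list(
    lesion_measurement("S1", 36.8, 36.5, 100, timestamp = as.Date("2020-04-01")),
    lesion_measurement("S2", 36.7, 36.5, 90, timestamp = as.Date("2020-01-01")))
  expect_error(session_series("L1", ms), "strictly increasing")
})

test_that("area change is the relative first-to-last difference", {
  expect_equal(area_change(make_series(c(0.3, 0.2), areas = c(100, 50))), -0.5)
  expect_equal(area_change(make_series(c(0.3, 0.2), areas = c(80, 80))), 0.0)
  expect_error(area_change(make_series(c(0.3, 0.2), areas = c(0, 50))),
               "positive")
})

test_that("agreement implements the three concordance rules", {
  # rule (ii): temperature decrement + positive clinical response
  expect_equal(agreement("negative", -0.4, "positive"), "agree")
  # rule (i): temperature increment + negative clinical response
  expect_equal(agreement("positive", 0.1, "negative"), "agree")
  # rule (iii): null trend + substantial area reduction + positive response
  expect_equal(agreement("null", -0.5, "positive"), "agree")
  expect_equal(agreement("null", -0.2, "positive"), "agree")  # boundary included
  # complements
  expect_equal(agreement("negative", -0.4, "negative"), "disagree")
  expect_equal(agreement("positive", -0.4, "positive"), "disagree")
  expect_equal(agreement("null", -0.1, "positive"), "disagree")
  expect_equal(agreement("null", -0.5, "negative"), "disagree")
  # configurable substantiality threshold
  expect_equal(agreement("null", -0.1, "positive", substantial_frac = -0.05),
               "agree")
})

test_that("phantom treated series recovers the analytic iso-area ratio", {
  spec <- single_lesion_spec(sigma = 20, amplitude = 1.0, size = 170L,
                             noise_sd = 0, seed = 31L)
  series <- generate_series(spec, data.frame(
    session = 1:2, amplitude_scale = c(1, 1), sigma_scale = c(1, 0.7)))
  sk <- lapply(series, function(s) segment_skin(s$frame, floor = 20))
  lv <- 36.6
  ms <- lapply(seq_along(series), function(i)
    measure(series[[i]]$frame, lv, sk[[i]]))
  ss <- session_series("P1", ms)
  # analytic: iso-area scales with sigma^2 at fixed amplitude
  expect_lt(abs(area_change(ss) - (0.7^2 - 1)), 0.05)
})

test_that("cohort summary counts, percentage and intervals are consistent", {
  df <- data.frame(lesion_id = sprintf("L%d", 1:10),
                   delta_t = c(0.3, 0.25, -0.15, 0.02, 0.4, 0.22, -0.3,
                               0.05, 0.18, 0.33))
  s <- summarize_cohort(df)
  expect_equal(s$n_positive + s$n_negative + s$n_null, s$n_lesions)
  expect_equal(s$n_positive, 6L)
  expect_equal(s$n_negative, 2L)
  expect_equal(s$n_null, 2L)
  expect_equal(s$pct_with_variation, 80.0)
  expect_equal(s$mean_delta_t, mean(df$delta_t))
  expect_true(s$ci90[1] < s$mean_delta_t && s$mean_delta_t < s$ci90[2])
  # class counts conserve for random cohorts (property)
  set.seed(404)
  for (i in 1:10) {
    n <- sample(1:60, 1)
    r <- data.frame(lesion_id = seq_len(n), delta_t = rnorm(n, 0.1, 0.2))
    sm <- summarize_cohort(r)
    expect_equal(sm$n_positive + sm$n_negative + sm$n_null, n)
    expect_true(sm$pct_with_variation >= 0 && sm$pct_with_variation <= 100)
  }
})

test_that("printed first-phase counts give the 87.3% variation rate", {
  cnt <- cohort_counts()
  records <- cohort_from_counts(cnt$n_positive, cnt$n_negative, cnt$n_null,
                                n_patients = cnt$n_patients)
  s <- summarize_cohort(records, n_patients = cnt$n_patients)
  expect_equal(s$n_lesions, 55L)
  expect_equal(s$pct_with_variation, 87.3)
  expect_true(is.na(s$mean_delta_t))   # per-lesion values are unpublished
})

test_that("single-lesion cohorts flag a degenerate confidence interval", {
  s <- summarize_cohort(data.frame(lesion_id = "L1", delta_t = 0.2))
  expect_equal(s$mean_delta_t, 0.2)
  expect_true(s$ci_degenerate)
  expect_true(all(is.na(s$ci90)))
})

test_that("the 90% t-interval covers the true mean at nominal rate", {
  set.seed(505)
  n_rep <- 400
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    r <- data.frame(lesion_id = 1:55, delta_t = rnorm(55, 0.2, 0.05))
    s <- summarize_cohort(r)
    covered[i] <- s$ci90[1] <= 0.2 && 0.2 <= s$ci90[2]
  }
  expect_gt(mean(covered), 0.85)
  expect_lt(mean(covered), 0.95)
})

test_that("summarize_cohort accepts session series and reports treatment change", {
  ser <- list(make_series(c(0.38, 0.30, 0.27), lesion_id = "A"),
              make_series(c(0.30, 0.25, 0.15), lesion_id = "B"))
  s <- summarize_cohort(ser)
  expect_equal(s$n_lesions, 2L)
  expect_equal(s$mean_delta_t, mean(c(0.38, 0.30)))
  expect_equal(s$mean_treatment_change,
               mean(c(0.27 - 0.38, 0.15 - 0.30)))
})

test_that("the packaged 17-lesion fixture replays to unanimous agreement", {
  rec <- monitored_lesions()
  expect_equal(nrow(rec), 17L)
  expect_equal(length(unique(rec$case)), 9L)
  verdicts <- replay_agreement(rec)
  expect_equal(sum(verdicts == "agree"), 17L)
  # trend composition: all negative except the single below-resolution case
  expect_equal(sum(rec$trend == "negative"), 16L)
  expect_equal(sum(rec$trend == "null"), 1L)
})
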