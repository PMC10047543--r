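test_that("identical spec and seed reproduce the dataset bit for bit", {
  spec <- tiny_cohort_spec(n_subjects = 3, reports = c(5, 8), seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$labels, b$labels)
  expect_identical(a$segments, b$segments)
  expect_identical(a$subjects, b$subjects)
  # and a different seed changes the data
  c <- generate_cohort(tiny_cohort_spec(n_subjects = 3, reports = c(5, 8),
                                        seed = 8))
  expect_false(identical(a$segments, c$segments))
})

test_that("cohort spec validation rejects bad configurations", {
  expect_error(cohort_spec("CIS", segment_duration = -1), "positive")
  expect_error(cohort_spec("CIS", sampling_rate = 0), "positive")
  expect_error(cohort_spec("CIS", onoff_attenuation = 1.5), "\\[0, 1\\]")
  expect_error(cohort_spec("CIS", tremor_coupling = -0.1), ">= 0")
  expect_error(cohort_spec("CIS", n_subjects = 0), ">= 1")
})

test_that("all noise sources off yields a constant-gravity signal", {
  spec <- cohort_spec("CIS", n_subjects = 1, reports_per_subject = c(1, 1),
                      sampling_rate = 16, segment_duration = 30,
                      tremor_coupling = 0, dyskinesia_coupling = 0,
                      baseline_motion_sd = 0, sensor_noise_sd = 0,
                      missingness_rate = 0, drift_amplitude = 0, seed = 1)
  prof <- withr::with_seed(1, generate_subject_profiles(spec))
  seg <- synthesize_segment(prof[1, ],
                            list(tremor_h = 0, dyskinesia_h = 0, state_on = TRUE),
                            spec, seed = 5)
  expect_equal(var(seg$x), 0)
  expect_equal(var(seg$y), 0)
  expect_equal(var(seg$z), 0)
  expect_equal(sqrt(seg$x[1]^2 + seg$y[1]^2 + seg$z[1]^2), 1, tolerance = 1e-12)
})

test_that("tremor severity raises 3-7 Hz band power, same substream", {
  spec <- cohort_spec("CIS", n_subjects = 1, reports_per_subject = c(1, 1),
                      sampling_rate = 16, segment_duration = 30,
                      tremor_coupling = 0.05, baseline_motion_sd = 0.01,
                      missingness_rate = 0, seed = 1)
  prof <- withr::with_seed(1, generate_subject_profiles(spec))
  bp <- function(trem) {
    seg <- synthesize_segment(prof[1, ],
                              list(tremor_h = trem, dyskinesia_h = 0,
                                   state_on = FALSE), spec, seed = 42)
    v <- combine_rms(seg$x, seg$y, seg$z)
    unname(generic_features(v, 16)["bandpower_3_7"])
  }
  expect_gt(bp(4), bp(0))
})

test_that("missingness drops the binomially expected number of samples", {
  spec <- cohort_spec("CIS", n_subjects = 1, reports_per_subject = c(1, 1),
                      sampling_rate = 50, segment_duration = 1200,
                      missingness_rate = 0.1, seed = 1)
  prof <- withr::with_seed(1, generate_subject_profiles(spec))
  seg <- synthesize_segment(prof[1, ],
                            list(tremor_h = 1, dyskinesia_h = 1,
                                 state_on = TRUE), spec, seed = 9)
  n <- 60000
  expected <- n * 0.9
  sd3 <- 3 * sqrt(n * 0.1 * 0.9)
  expect_gt(nrow(seg), expected - sd3)
  expect_lt(nrow(seg), expected + sd3)
})

test_that("out-of-range latent labels are clipped with a warning", {
  spec <- tiny_cohort_spec(n_subjects = 1, reports = c(1, 1))
  prof <- withr::with_seed(1, generate_subject_profiles(spec))
  expect_warning(
    synthesize_segment(prof[1, ], list(tremor_h = 9, dyskinesia_h = 0,
                                       state_on = TRUE), spec, seed = 1),
    "clipping")
})

test_that("degenerate label noise reproduces the subject mean exactly", {
  spec <- tiny_cohort_spec(n_subjects = 1, reports = c(12, 12))
  prof <- withr::with_seed(1, generate_subject_profiles(spec))
  prof$theta_tremor <- 2
  prof$label_sd_tremor <- 0
  labs <- withr::with_seed(3, sample_labels(prof[1, ], 12, spec))
  expect_true(all(labs$tremor == 2))
  expect_equal(nrow(labs), 12)
})

test_that("reporting lags are non-negative and slots spaced >= 30 min", {
  spec <- tiny_cohort_spec(n_subjects = 1, reports = c(50, 50))
  prof <- withr::with_seed(1, generate_subject_profiles(spec))
  labs <- withr::with_seed(3, sample_labels(prof[1, ], 50, spec))
  expect_equal(nrow(labs), 50)
  lag <- labs$timestamp_report - (labs$timestamp_slot + spec$segment_duration)
  expect_true(all(lag >= 0))
  expect_true(all(diff(labs$timestamp_slot) >= 1800))
})

test_that("empirical label mean matches the clipped-rounded-Gaussian mean", {
  spec <- cohort_spec("CIS", n_subjects = 1, reports_per_subject = c(500, 500),
                      sampling_rate = 16, segment_duration = 60, seed = 1)
  prof <- withr::with_seed(1, generate_subject_profiles(spec))
  prof$theta_tremor <- 2
  prof$label_sd_tremor <- 1
  labs <- withr::with_seed(11, sample_labels(prof[1, ], 500, spec))
  mu <- oracle_clipped_label_mean(2, 1)
  se <- sd(labs$tremor) / sqrt(500)
  expect_lt(abs(mean(labs$tremor) - mu), 2 * se + 1e-9)
})

test_that("zero coupling leaves band power uncorrelated with tremor labels", {
  spec <- cohort_spec("CIS", n_subjects = 4, reports_per_subject = c(50, 50),
                      sampling_rate = 16, segment_duration = 60,
                      tremor_coupling = 0, dyskinesia_coupling = 0,
                      onoff_attenuation = 1, seed = 21)
  ch <- generate_cohort(spec)
  feats <- extract_features(ch$segments, fs = 16, feature_set = "generic")
  obs <- feats %>%
    dplyr::group_by(measurement_id) %>%
    dplyr::summarise(bp = mean(bandpower_3_7), .groups = "drop") %>%
    dplyr::inner_join(ch$labels, by = "measurement_id")
  expect_lt(abs(cor(obs$bp, obs$tremor)), 0.15)
})

test_that("strong coupling makes per-label mean band power increase", {
  spec <- cohort_spec("CIS", n_subjects = 4, reports_per_subject = c(50, 50),
                      sampling_rate = 16, segment_duration = 60,
                      tremor_coupling = 0.05, baseline_motion_sd = 0.02,
                      seed = 22)
  ch <- generate_cohort(spec)
  # independent oracle band power on a subsample of raw segments; condition on
  # the OFF state so the medication attenuation does not add between-bin noise
  picks <- ch$labels %>%
    dplyr::left_join(ch$latent, by = "measurement_id") %>%
    dplyr::filter(!state_on) %>%
    dplyr::group_by(tremor) %>%
    dplyr::slice_head(n = 15) %>%
    dplyr::ungroup()
  bp <- vapply(seq_len(nrow(picks)), function(i) {
    seg <- ch$segments %>%
      dplyr::filter(measurement_id == picks$measurement_id[i]) %>%
      dplyr::slice_head(n = 480)
    v <- combine_rms(seg$x, seg$y, seg$z)
    oracle_band_power(v[seq_len(min(480, length(v)))], 16, 3, 7)
  }, 0)
  mean_bp <- tapply(bp, picks$tremor, mean)
  expect_true(all(diff(mean_bp) > 0))
})

test_that("REAL cohort emits native scales and optional phone streams", {
  spec <- cohort_spec("REAL", n_subjects = 3, reports_per_subject = c(20, 20),
                      sampling_rate = 16, segment_duration = 60,
                      second_device_prob = 0.5, seed = 5)
  ch <- generate_cohort(spec)
  expect_true(all(ch$labels$tremor %in% 1:5))
  expect_true(is.character(ch$labels$on_off))
  expect_setequal(unique(ch$segments$device), c("watch", "phone"))
  counts <- ch$segments %>%
    dplyr::distinct(measurement_id, device) %>%
    dplyr::count(measurement_id)
  expect_true(any(counts$n == 2))
})

test_that("UPDRS covariates correlate positively with latent severity", {
  spec <- cohort_spec("CIS", n_subjects = 40, reports_per_subject = c(1, 1),
                      sampling_rate = 16, segment_duration = 1,
                      seed = 30)
  prof <- withr::with_seed(2, generate_subject_profiles(spec))
  sev <- prof$theta_tremor / 4 + prof$theta_on_off / 4 + prof$theta_dyskinesia / 4
  p3 <- rowSums(prof[grep("^updrs3_off_", names(prof))])
  expect_gt(cor(sev, p3), 0.3)
  expect_gt(cor(sev, prof$updrs2_total), 0.2)
  expect_true(all(as.matrix(prof[grep("^updrs3_", names(prof))]) %in% 0:4))
})
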