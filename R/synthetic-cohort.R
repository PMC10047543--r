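#' Specify a synthetic wearable cohort
#'
#' A `cohort_spec` holds every free parameter of the simulator: study size,
#' device sampling, and the couplings that tie the generated accelerometer
#' signal to the diary labels. Two cohorts are supported, mirroring the two
#' study protocols the package emulates: `"CIS"` (all three symptoms reported
#' on 0-4 diary scales, single smartwatch) and `"REAL"` (tremor reported on a
#' native 1-5 scale, medication state as a four-category response, optional
#' second device stream per report).
#'
#' @param cohort_id `"CIS"` or `"REAL"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param reports_per_subject Integer pair; each subject's diary count is drawn
#'   uniformly from this closed range.
#' @param sampling_rate Device sampling rate in Hz.
#' @param segment_duration Segment length in seconds (default 1200 = 20 min).
#' @param tremor_coupling Tremor amplitude in g per harmonized severity unit.
#' @param dyskinesia_coupling Dyskinesia band-noise SD in g per severity unit.
#' @param onoff_attenuation Multiplier in `[0, 1]` applied to the tremor
#'   amplitude while medication is effective (ON); 1 removes the ON/OFF effect.
#' @param dyskinesia_off_expression Multiplier in `[0, 1]` applied to the
#'   dyskinesia amplitude while OFF. Dyskinesia is a levodopa side effect and
#'   expresses mainly in the ON state; the diary still reports the period's
#'   severity, so the label-signal coupling is state-confounded just as tremor
#'   is (in the opposite direction).
#' @param baseline_motion_sd SD (g) of band-limited (0.5-8 Hz) baseline motion.
#' @param activity_variability Log-normal SD of the per-segment baseline-motion
#'   intensity multiplier (0 = every segment equally active). Free-living
#'   activity varies strongly between 20-minute windows; this variation
#'   overlaps the dyskinesia band and is what makes dyskinesia intrinsically
#'   harder to read from the wrist than tremor.
#' @param sensor_noise_sd SD (g) of white sensor noise.
#' @param missingness_rate Fraction of samples dropped uniformly at random.
#' @param drift_amplitude Amplitude (g) of the slow gravity-orientation drift;
#'   0 freezes the orientation.
#' @param second_device_prob Probability that a REAL report also carries a
#'   second (phone) accelerometer stream; ignored for CIS. Default 0.5 for
#'   REAL, 0 for CIS.
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   dataset.
#' @return A `cohort_spec` object (a validated list).
#' @export
#' @examples
#' cohort_spec("CIS", n_subjects = 3, reports_per_subject = c(10, 10))
cohort_spec <- function(cohort_id = c("CIS", "REAL"),
                        n_subjects = 8,
                        reports_per_subject = c(40, 60),
                        sampling_rate = 50,
                        segment_duration = 1200,
                        tremor_coupling = 0.02,
                        dyskinesia_coupling = 0.009,
                        onoff_attenuation = 0.3,
                        dyskinesia_off_expression = 0.25,
                        baseline_motion_sd = 0.02,
                        activity_variability = 0.25,
                        sensor_noise_sd = 0.005,
                        missingness_rate = 0.02,
                        drift_amplitude = 0.02,
                        second_device_prob = NULL,
                        seed = 1L) {
  cohort_id <- match.arg(cohort_id)
  if (is.null(second_device_prob)) {
    second_device_prob <- if (cohort_id == "REAL") 0.5 else 0
  }
  spec <- list(
    cohort_id = cohort_id,
    n_subjects = as.integer(n_subjects),
    reports_per_subject = as.integer(reports_per_subject),
    sampling_rate = sampling_rate,
    segment_duration = segment_duration,
    tremor_coupling = tremor_coupling,
    dyskinesia_coupling = dyskinesia_coupling,
    onoff_attenuation = onoff_attenuation,
    dyskinesia_off_expression = dyskinesia_off_expression,
    baseline_motion_sd = baseline_motion_sd,
    activity_variability = activity_variability,
    sensor_noise_sd = sensor_noise_sd,
    missingness_rate = missingness_rate,
    drift_amplitude = drift_amplitude,
    second_device_prob = second_device_prob,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (length(spec$reports_per_subject) != 2 ||
      any(spec$reports_per_subject < 1) ||
      spec$reports_per_subject[1] > spec$reports_per_subject[2]) {
    abort("`reports_per_subject` must be an increasing integer pair >= 1.")
  }
  if (spec$sampling_rate <= 0 || spec$segment_duration <= 0) {
    abort("`sampling_rate` and `segment_duration` must be positive.")
  }
  for (nm in c("tremor_coupling", "dyskinesia_coupling", "baseline_motion_sd",
               "sensor_noise_sd", "drift_amplitude", "activity_variability")) {
    if (spec[[nm]] < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  if (spec$onoff_attenuation < 0 || spec$onoff_attenuation > 1) {
    abort("`onoff_attenuation` must lie in [0, 1].")
  }
  if (spec$dyskinesia_off_expression < 0 || spec$dyskinesia_off_expression > 1) {
    abort("`dyskinesia_off_expression` must lie in [0, 1].")
  }
  if (spec$missingness_rate < 0 || spec$missingness_rate >= 1) {
    abort("`missingness_rate` must lie in [0, 1).")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec %s: %d subjects, %d-%d reports, %g Hz x %g s, seed %d>\n",
    x$cohort_id, x$n_subjects, x$reports_per_subject[1],
    x$reports_per_subject[2], x$sampling_rate, x$segment_duration, x$seed
  ))
  invisible(x)
}

# Number of MDS-UPDRS Part III items and Part IV items carried per subject.
N_UPDRS3_ITEMS <- 33L
N_UPDRS4_ITEMS <- 6L

#' Draw subject profiles for a cohort
#'
#' Each subject gets a latent mean severity per symptom (`theta_*`), a
#' per-symptom diary noise SD, a mean diary reporting lag, a subject-specific
#' tremor frequency in 4-6 Hz, plus demographics and MDS-UPDRS covariates
#' constructed to correlate positively with the latent severities (the
#' covariate-association analysis downstream relies on that coupling).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject.
#' @export
generate_subject_profiles <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  dysk_max <- label_range(spec$cohort_id, "dyskinesia")[2]
  subject_id <- sprintf("%s%02d", tolower(spec$cohort_id), seq_len(n))

  theta_on_off <- runif(n, 1.2, 3.4)
  theta_dyskinesia <- runif(n, 0.3, dysk_max - 0.3)
  theta_tremor <- runif(n, 0.8, 3.2)
  sev <- (theta_on_off / 4 + theta_dyskinesia / dysk_max + theta_tremor / 4) / 3

  item_block <- function(center, k) {
    m <- matrix(
      clip(round(rnorm(n * k, mean = rep(center, each = k), sd = 0.9)), 0, 4),
      nrow = n, byrow = TRUE
    )
    m
  }
  p3_off <- item_block(1 + 3 * sev, N_UPDRS3_ITEMS)
  p3_on <- item_block(0.6 + 2.2 * sev, N_UPDRS3_ITEMS)
  p4 <- item_block(0.5 + 2.5 * theta_dyskinesia / dysk_max, N_UPDRS4_ITEMS)

  profiles <- tibble(
    subject_id = subject_id,
    cohort_id = spec$cohort_id,
    age = clip(round(rnorm(n, 63, 9)), 35, 90),
    gender = sample(c("female", "male"), n, replace = TRUE),
    updrs1_total = clip(round(rnorm(n, 4 + 14 * sev, 2.5)), 0, 52),
    updrs2_total = clip(round(rnorm(n, 5 + 18 * sev, 3)), 0, 52),
    theta_on_off = theta_on_off,
    theta_dyskinesia = theta_dyskinesia,
    theta_tremor = theta_tremor,
    label_sd_on_off = runif(n, 0.6, 1.0),
    label_sd_dyskinesia = runif(n, 0.6, 1.0),
    label_sd_tremor = runif(n, 0.6, 1.0),
    mean_reporting_lag = runif(n, 5, 60),
    tremor_freq_hz = runif(n, 4, 6),
    med_phase = runif(n, 0, 14400)
  )
  colnames(p3_on) <- sprintf("updrs3_on_%02d", seq_len(N_UPDRS3_ITEMS))
  colnames(p3_off) <- sprintf("updrs3_off_%02d", seq_len(N_UPDRS3_ITEMS))
  colnames(p4) <- sprintf("updrs4_%02d", seq_len(N_UPDRS4_ITEMS))
  bind_cols(profiles, as_tibble(p3_on), as_tibble(p3_off), as_tibble(p4))
}

#' Sample a subject's diary label sequence
#'
#' Diary slots are spaced 30 minutes apart; medication effectiveness alternates
#' in 4-hour cycles (2 h ON, 2 h OFF) with a subject-specific phase. Each
#' symptom label is `round(theta + N(0, label_sd))` clipped to the cohort's
#' native range; the on/off diary response collapses toward 0 while ON. The
#' reporting lag (minutes between the end of the reported slot and when the
#' diary entry was made) is exponential with the subject's mean.
#'
#' Returned latent columns (`state_on`, `tremor_h`, `dyskinesia_h`) drive the
#' signal synthesis and are dropped from the emitted label files.
#'
#' @param profile One row of [generate_subject_profiles()].
#' @param n_reports Number of diary reports (>= 1).
#' @param spec The [cohort_spec()].
#' @return Tibble of raw, cohort-native label records.
#' @export
sample_labels <- function(profile, n_reports, spec) {
  stopifnot(n_reports >= 1)
  slot <- (seq_len(n_reports) - 1) * 1800
  state_on <- ((slot + profile$med_phase) %% 14400) < 7200

  draw <- function(theta, sd, lo, hi) {
    clip(round(theta + rnorm(n_reports, 0, sd)), lo, hi)
  }
  tremor_h <- draw(profile$theta_tremor, profile$label_sd_tremor, 0, 4)
  dysk_rng <- label_range(spec$cohort_id, "dyskinesia")
  dysk_h <- draw(profile$theta_dyskinesia, profile$label_sd_dyskinesia,
                 dysk_rng[1], dysk_rng[2])
  onoff_theta <- ifelse(state_on, 0.3, profile$theta_on_off)
  onoff_cis <- clip(round(onoff_theta + rnorm(n_reports, 0, profile$label_sd_on_off)),
                    0, 4)

  lag_min <- rexp(n_reports, rate = 1 / profile$mean_reporting_lag)

  out <- tibble(
    measurement_id = sprintf("%s_m%04d", profile$subject_id, seq_len(n_reports)),
    subject_id = profile$subject_id,
    timestamp_slot = slot,
    timestamp_report = slot + spec$segment_duration + lag_min * 60,
    state_on = state_on,
    tremor_h = tremor_h,
    dyskinesia_h = dysk_h
  )
  if (spec$cohort_id == "CIS") {
    out$on_off <- onoff_cis
    out$dyskinesia <- dysk_h
    out$tremor <- tremor_h
  } else {
    # REAL native scales: 4-category medication state, tremor 1-5. Harmonized
    # REAL dyskinesia uses levels {0, 1, 3} only (level 2 unused by mapping).
    out$on_off <- ifelse(
      !state_on, "off",
      ifelse(dysk_h == 0, "on_without_dyskinesia",
             ifelse(dysk_h >= 3, "on_troublesome_dyskinesia",
                    "on_nontroublesome_dyskinesia"))
    )
    out$dyskinesia <- NA_real_
    out$tremor <- tremor_h + 1
  }
  out
}

# Band-limited Gaussian noise via FFT masking: exact passband, no edge
# transients, deterministic under the ambient RNG stream.
bandlimited_noise <- function(n, fs, lo, hi, sd) {
  if (sd == 0 || n < 4) return(numeric(n))
  w <- rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  keep <- (f >= lo & f <= hi) | (f >= fs - hi & f <= fs - lo)
  x <- Re(fft(fft(w) * keep, inverse = TRUE)) / n
  s <- sd(x)
  if (s > 0) x * sd / s else numeric(n)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Synthesize one accelerometer segment
#'
#' The signal model per axis is: gravity projection (a random orientation with
#' optional slow sinusoidal drift), band-limited (0.5-8 Hz) baseline motion,
#' a narrowband tremor sinusoid at the subject's tremor frequency with
#' random-walk phase and amplitude `tremor_coupling * tremor * (attenuation if
#' ON)`, a 1-3 Hz band-noise dyskinesia component with SD
#' `dyskinesia_coupling * dyskinesia`, and white sensor noise. A fraction
#' `missingness_rate` of samples is then deleted at random; timestamps are
#' seconds relative to segment start.
#'
#' @param profile Subject profile row (uses `tremor_freq_hz`).
#' @param labels One latent label record: a list/row with `tremor_h`,
#'   `dyskinesia_h`, `state_on`. Out-of-range values are clipped with a
#'   warning.
#' @param spec The [cohort_spec()].
#' @param seed Optional integer; when given, the draw is made reproducible in
#'   isolation (otherwise the ambient RNG stream is used).
#' @return Tibble with columns `t`, `x`, `y`, `z`.
#' @export
synthesize_segment <- function(profile, labels, spec, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, synthesize_segment(profile, labels, spec)))
  }
  fs <- spec$sampling_rate
  n <- round(spec$segment_duration * fs)
  t <- (seq_len(n) - 1) / fs

  tremor <- labels$tremor_h
  dysk <- labels$dyskinesia_h
  if (tremor < 0 || tremor > 4 || dysk < 0 || dysk > 4) {
    warn("label value outside native range; clipping")
    tremor <- clip(tremor, 0, 4)
    dysk <- clip(dysk, 0, 4)
  }

  g_dir <- random_unit_vector()
  drift_phase <- runif(3, 0, 2 * pi)
  # per-segment activity intensity (mean-one log-normal)
  act <- if (spec$activity_variability > 0) {
    exp(rnorm(1, -spec$activity_variability^2 / 2, spec$activity_variability))
  } else {
    1
  }
  amp_t <- spec$tremor_coupling * tremor *
    (if (isTRUE(labels$state_on)) spec$onoff_attenuation else 1)
  tremor_dir <- random_unit_vector()
  phase_walk <- cumsum(rnorm(n, 0, 0.05))
  tremor_sig <- amp_t * sin(2 * pi * profile$tremor_freq_hz * t + phase_walk)
  dysk_sd <- spec$dyskinesia_coupling * dysk *
    (if (isTRUE(labels$state_on)) 1 else spec$dyskinesia_off_expression)

  axes <- lapply(1:3, function(i) {
    g_dir[i] +
      spec$drift_amplitude * sin(2 * pi * 0.01 * t + drift_phase[i]) +
      bandlimited_noise(n, fs, 0.5, min(8, fs / 2 * 0.99),
                        act * spec$baseline_motion_sd) +
      tremor_dir[i] * tremor_sig +
      bandlimited_noise(n, fs, 1, min(3, fs / 2 * 0.99), dysk_sd) +
      (if (spec$sensor_noise_sd > 0) rnorm(n, 0, spec$sensor_noise_sd) else 0)
  })

  keep <- if (spec$missingness_rate > 0) {
    runif(n) >= spec$missingness_rate
  } else {
    rep(TRUE, n)
  }
  tibble(t = t[keep], x = axes[[1]][keep], y = axes[[2]][keep],
         z = axes[[3]][keep])
}

#' Generate a complete synthetic cohort
#'
#' Draws subject profiles, per-subject diary label sequences on the cohort's
#' native scales, and one synthetic accelerometer segment per diary report
#' (REAL reports additionally carry a second device stream with probability
#' `second_device_prob`). The whole dataset is a deterministic function of the
#' spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `pd_cohort`: a list with `spec`, `subjects`
#'   (profiles incl. latent simulation truth), `labels` (raw cohort-native
#'   records), and `segments` (long tibble `measurement_id`, `device`, `t`,
#'   `x`, `y`, `z`).
#' @export
#' @examples
#' ch <- generate_cohort(cohort_spec("CIS", n_subjects = 2,
#'   reports_per_subject = c(3, 3), segment_duration = 10, sampling_rate = 20))
#' dplyr::count(ch$labels, subject_id)
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  withr::with_seed(spec$seed, {
    subjects <- generate_subject_profiles(spec)
    n_reports <- resample(
      seq(spec$reports_per_subject[1], spec$reports_per_subject[2]),
      spec$n_subjects
    )
    all_labels <- vector("list", spec$n_subjects)
    all_segments <- vector("list", spec$n_subjects)
    for (i in seq_len(spec$n_subjects)) {
      prof <- subjects[i, ]
      labs <- sample_labels(prof, n_reports[i], spec)
      segs <- vector("list", nrow(labs))
      for (j in seq_len(nrow(labs))) {
        seg <- synthesize_segment(prof, labs[j, ], spec)
        seg$measurement_id <- labs$measurement_id[j]
        seg$device <- "watch"
        if (spec$cohort_id == "REAL" && spec$second_device_prob > 0 &&
            runif(1) < spec$second_device_prob) {
          seg2 <- synthesize_segment(prof, labs[j, ], spec)
          seg2$measurement_id <- labs$measurement_id[j]
          seg2$device <- "phone"
          seg <- bind_rows(seg, seg2)
        }
        segs[[j]] <- seg
      }
      all_labels[[i]] <- labs
      all_segments[[i]] <- bind_rows(segs)
    }
    labels <- bind_rows(all_labels)
    segments <- bind_rows(all_segments) %>%
      select("measurement_id", "device", "t", "x", "y", "z")
    structure(
      list(
        spec = spec,
        subjects = subjects,
        labels = labels %>% select(-"state_on", -"tremor_h", -"dyskinesia_h"),
        latent = labels %>%
          select("measurement_id", "state_on", "tremor_h", "dyskinesia_h"),
        segments = segments
      ),
      class = "pd_cohort"
    )
  })
}

#' @export
print.pd_cohort <- function(x, ...) {
  cat(sprintf(
    "<pd_cohort %s: %d subjects, %d reports, %d segment streams>\n",
    x$spec$cohort_id, nrow(x$subjects), nrow(x$labels),
    nrow(distinct(x$segments, .data$measurement_id, .data$device))
  ))
  invisible(x)
}
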