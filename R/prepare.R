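#' Harmonize diary labels across cohorts
#'
#' CIS records already use the harmonized scales (on/off 0-4, dyskinesia 0-4,
#' tremor 0-4) and pass through unchanged. REAL records are converted: tremor
#' is rescaled from its native 1-5 scale to 0-4 by subtracting one, and the
#' four-category medication response maps onto a binary on/off code plus a
#' 0-3 dyskinesia scale:
#'
#' * `off` -> `on_off = 1`, `dyskinesia = 0`
#' * `on_without_dyskinesia` -> `on_off = 0`, `dyskinesia = 0`
#' * `on_nontroublesome_dyskinesia` -> `on_off = 0`, `dyskinesia = 1`
#' * `on_troublesome_dyskinesia` -> `on_off = 0`, `dyskinesia = 3`
#'
#' Higher values therefore mean greater symptom burden on every scale
#' (0 = ON, 1 = OFF). The mapping is a bijection of the four categories onto
#' the `(on_off, dyskinesia)` codes, and harmonization is idempotent: records
#' with a numeric `on_off` column are treated as already harmonized.
#' A `reporting_lag` column (minutes between the end of the reported slot and
#' the report time) is added when the timestamp columns are present.
#'
#' @param labels Raw label tibble with columns `measurement_id`, `subject_id`,
#'   `on_off`, `dyskinesia`, `tremor` (+ optional timestamps).
#' @param cohort_id `"CIS"` or `"REAL"`.
#' @param segment_duration Segment length in seconds, used for the lag.
#' @return Harmonized label tibble with a `cohort_id` column.
#' @export
harmonize_labels <- function(labels, cohort_id, segment_duration = 1200) {
  cohort_id <- match.arg(cohort_id, c("CIS", "REAL"))
  out <- as_tibble(labels)
  raw_real <- is.character(out$on_off) || is.factor(out$on_off)
  if (cohort_id == "REAL" && raw_real) {
    med <- as.character(out$on_off)
    map <- c(off = "1/0", on_without_dyskinesia = "0/0",
             on_nontroublesome_dyskinesia = "0/1",
             on_troublesome_dyskinesia = "0/3")
    unknown <- setdiff(unique(med[!is.na(med)]), names(map))
    if (length(unknown) > 0) {
      abort(sprintf("unknown REAL medication categor%s: %s",
                    if (length(unknown) > 1) "ies" else "y",
                    paste(unknown, collapse = ", ")))
    }
    codes <- strsplit(unname(map[med]), "/")
    out$on_off <- as.numeric(vapply(codes, `[`, "", 1))
    out$dyskinesia <- as.numeric(vapply(codes, `[`, "", 2))
    if (any(!is.na(out$tremor) & (out$tremor < 1 | out$tremor > 5))) {
      abort("REAL tremor values must lie in the native 1-5 range")
    }
    out$tremor <- out$tremor - 1
  } else {
    for (sym in SYMPTOMS) {
      rng <- label_range(cohort_id, sym)
      v <- out[[sym]]
      if (any(!is.na(v) & (v < rng[1] | v > rng[2]))) {
        abort(sprintf("%s values outside harmonized range [%d, %d]",
                      sym, rng[1], rng[2]))
      }
    }
  }
  out$cohort_id <- cohort_id
  if (all(c("timestamp_report", "timestamp_slot") %in% names(out)) &&
      !("reporting_lag" %in% names(out))) {
    out$reporting_lag <-
      (out$timestamp_report - (out$timestamp_slot + segment_duration)) / 60
  }
  out
}

#' Activity duration of a segment
#'
#' Activity is defined as the presence of data: the duration is the number of
#' distinct 1-second epochs (half-open windows `[k, k+1)`) that contain at
#' least one sample. An alternative motion-based criterion (epoch
#' vector-magnitude SD above a threshold) is available via `criterion`.
#'
#' @param segment Tibble with column `t` (and `x`, `y`, `z` for the motion
#'   criterion).
#' @param criterion `"presence"` (default) or `"motion"`.
#' @param motion_sd_threshold Epoch VM SD threshold in g for `"motion"`.
#' @return Duration in seconds (integer count of active epochs).
#' @export
activity_duration <- function(segment, criterion = c("presence", "motion"),
                              motion_sd_threshold = 0.01) {
  criterion <- match.arg(criterion)
  epoch <- floor(segment$t)
  if (criterion == "presence") {
    return(length(unique(epoch)))
  }
  vm <- combine_rms(segment$x, segment$y, segment$z)
  sds <- tapply(vm, epoch, sd, default = 0)
  sum(!is.na(sds) & sds > motion_sd_threshold)
}

#' Remove segments with insufficient activity
#'
#' Segment streams showing less than `min_activity` seconds of activity are
#' removed (the boundary is inclusive: exactly `min_activity` seconds is
#' retained). Removals are reported via a message naming the measurement.
#'
#' @param segments Long segment tibble (`measurement_id`, `device`, `t`, ...).
#' @param min_activity Minimum activity in seconds (default 120 = 2 minutes).
#' @inheritParams activity_duration
#' @return Filtered segment tibble.
#' @export
filter_segments <- function(segments, min_activity = 120,
                            criterion = c("presence", "motion"),
                            motion_sd_threshold = 0.01) {
  criterion <- match.arg(criterion)
  durations <- segments %>%
    group_by(.data$measurement_id, .data$device) %>%
    summarise(duration = activity_duration(
      dplyr::pick("t", "x", "y", "z"),
      criterion = criterion, motion_sd_threshold = motion_sd_threshold
    ), .groups = "drop")
  dropped <- durations %>% filter(.data$duration < min_activity)
  if (nrow(dropped) > 0) {
    inform(sprintf("removing %d segment stream(s) with < %g s activity: %s",
                   nrow(dropped), min_activity,
                   paste(utils::head(dropped$measurement_id, 5), collapse = ", ")))
  }
  segments %>%
    semi_join(durations %>% filter(.data$duration >= min_activity),
              by = c("measurement_id", "device"))
}

#' Subject eligibility for one symptom
#'
#' A subject is eligible for a symptom if they have at least 40 non-missing
#' observations of it, and either at least 2 label categories with 10 or more
#' observations each, or at least 3 label categories with 5 or more
#' observations each.
#'
#' @param labels Harmonized label tibble.
#' @param symptom `"on_off"`, `"dyskinesia"`, or `"tremor"`.
#' @param min_n,cat2_min,cat3_min Rule constants (defaults 40, 10, 5).
#' @return Character vector of eligible `subject_id`s.
#' @export
filter_subjects <- function(labels, symptom, min_n = 40, cat2_min = 10,
                            cat3_min = 5) {
  symptom <- match.arg(symptom, SYMPTOMS)
  labels %>%
    filter(!is.na(.data[[symptom]])) %>%
    group_by(.data$subject_id) %>%
    summarise(
      n = n(),
      n_cat_big = sum(table(.data[[symptom]]) >= cat2_min),
      n_cat_mid = sum(table(.data[[symptom]]) >= cat3_min),
      .groups = "drop"
    ) %>%
    filter(.data$n >= min_n,
           .data$n_cat_big >= 2 | .data$n_cat_mid >= 3) %>%
    pull("subject_id")
}

#' Stratified within-subject train/test split
#'
#' Observations are split per subject into train/test, stratified on the joint
#' tuple of the three symptom labels (missing values form their own stratum)
#' so the same split serves all symptoms. The per-subject test count is
#' exactly `round((1 - ratio) * n)`, distributed over strata by largest
#' remainder; strata of size 1 go to train.
#'
#' @param labels Harmonized label tibble (eligible subjects).
#' @param ratio Training fraction (default 0.75).
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @return Tibble `measurement_id`, `subject_id`, `partition` (`"train"` /
#'   `"test"`).
#' @export
split_train_test <- function(labels, ratio = 0.75, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  withr::with_seed(as.integer(seed), {
    labels %>%
      mutate(.stratum = paste(
        tidyr::replace_na(as.character(.data$on_off), "NA"),
        tidyr::replace_na(as.character(.data$dyskinesia), "NA"),
        tidyr::replace_na(as.character(.data$tremor), "NA"),
        sep = "|"
      )) %>%
      arrange(.data$subject_id, .data$measurement_id) %>%
      group_by(.data$subject_id) %>%
      dplyr::group_modify(~ split_one_subject(.x, ratio)) %>%
      ungroup() %>%
      select("measurement_id", "subject_id", "partition")
  })
}

split_one_subject <- function(df, ratio) {
  n <- nrow(df)
  n_test <- round((1 - ratio) * n)
  strata <- split(seq_len(n), df$.stratum)
  strata <- strata[order(names(strata))]
  sizes <- vapply(strata, length, 0L)
  eligible <- sizes >= 2
  quota <- (1 - ratio) * sizes
  quota[!eligible] <- 0
  take <- floor(quota)
  rem <- n_test - sum(take)
  if (rem > 0) {
    frac <- quota - floor(quota)
    frac[!eligible] <- -1
    # cap at stratum size - 1 so strata keep at least one training obs
    room <- sizes - 1 - take
    ord <- order(-frac, names(strata))
    for (i in ord) {
      if (rem <= 0) break
      if (eligible[i] && room[i] > 0) {
        add <- min(room[i], 1L)
        take[i] <- take[i] + add
        rem <- rem - add
      }
    }
  } else if (rem < 0) {
    ord <- order(quota - floor(quota))
    for (i in ord) {
      if (rem >= 0) break
      if (take[i] > 0) {
        take[i] <- take[i] - 1L
        rem <- rem + 1L
      }
    }
  }
  partition <- rep("train", n)
  for (s in seq_along(strata)) {
    if (take[s] > 0) {
      idx <- sample(strata[[s]], take[s])
      partition[idx] <- "test"
    }
  }
  tibble(measurement_id = df$measurement_id, partition = partition)
}
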