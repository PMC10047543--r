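test_that("segment CSV round-trips and validates", {
  seg <- tibble::tibble(t = c(0, 0.02, 0.04), x = c(0.1, 0.2, 0.3),
                        y = c(-1, -1, -1), z = c(0.5, 0.5, 0.6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_segment(seg, path)
  back <- read_segment(path)
  expect_equal(nrow(back), 3)
  expect_equal(back, seg)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_segment(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("segment reader names the offending row and missing columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 1000
  t <- seq(0, by = 0.02, length.out = n)
  t[812] <- t[811] - 1 # descending at row 812 of the data
  readr::write_csv(tibble::tibble(t = t, x = 0, y = 0, z = 1), path)
  expect_error(read_segment(path), "row 812")
  readr::write_csv(tibble::tibble(t = 1:3, x = 0, y = 0), path)
  expect_error(read_segment(path), "z")
  writeLines("t,x,y,z", path)
  expect_error(read_segment(path), "empty")
})

test_that("readers tolerate CRLF and BOM", {
  path <- withr::local_tempfile(fileext = ".csv")
  con <- file(path, "wb")
  writeBin(c(as.raw(c(0xEF, 0xBB, 0xBF)),
             charToRaw("t,x,y,z\r\n0,0.1,0.2,1\r\n0.5,0.2,0.3,1\r\n")), con)
  close(con)
  seg <- read_segment(path)
  expect_equal(seg$t, c(0, 0.5))
})

test_that("REAL harmonization follows the subtract-one and medication mapping", {
  raw <- tibble::tibble(
    measurement_id = sprintf("m%d", 1:4), subject_id = "s1",
    on_off = c("off", "on_without_dyskinesia",
               "on_nontroublesome_dyskinesia", "on_troublesome_dyskinesia"),
    dyskinesia = NA_real_, tremor = c(1, 5, 3, 2))
  h <- harmonize_labels(raw, "REAL")
  expect_equal(h$tremor, c(0, 4, 2, 1))
  expect_equal(h$on_off, c(1, 0, 0, 0))
  expect_equal(h$dyskinesia, c(0, 0, 1, 3))
  # the category -> (on_off, dyskinesia) mapping is injective
  codes <- paste(h$on_off, h$dyskinesia)
  expect_equal(length(unique(codes)), 4)
  # and idempotent: a second pass is the identity
  h2 <- harmonize_labels(h, "REAL")
  expect_equal(h2$on_off, h$on_off)
  expect_equal(h2$tremor, h$tremor)
  expect_equal(h2$dyskinesia, h$dyskinesia)
})

test_that("harmonization rejects out-of-range and unknown values", {
  raw <- tibble::tibble(measurement_id = "m1", subject_id = "s1",
                        on_off = "off", dyskinesia = NA_real_, tremor = 6)
  expect_error(harmonize_labels(raw, "REAL"), "1-5")
  raw$tremor <- 2
  raw$on_off <- "sort_of_on"
  expect_error(harmonize_labels(raw, "REAL"), "unknown")
  cis <- tibble::tibble(measurement_id = "m1", subject_id = "s1",
                        on_off = 5, dyskinesia = 1, tremor = 1)
  expect_error(harmonize_labels(cis, "CIS"), "outside harmonized range")
})

test_that("activity duration counts 1-second epochs with data", {
  seg90 <- tibble::tibble(t = rep(0:89, each = 2) + c(0.1, 0.6), x = 0, y = 0, z = 1)
  expect_equal(activity_duration(seg90), 90)
  seg120 <- tibble::tibble(t = 0:119 + 0.5, x = 0, y = 0, z = 1)
  expect_equal(activity_duration(seg120), 120)

  segs <- dplyr::bind_rows(
    seg90 %>% dplyr::mutate(measurement_id = "short", device = "watch"),
    seg120 %>% dplyr::mutate(measurement_id = "boundary", device = "watch"),
    tibble::tibble(t = seq(0, 1199.9, by = 0.5), x = 0, y = 0, z = 1,
                   measurement_id = "full", device = "watch"))
  expect_message(kept <- filter_segments(segs), "short")
  expect_setequal(unique(kept$measurement_id), c("boundary", "full"))
})

test_that("motion-based activity criterion is available behind a flag", {
  still <- tibble::tibble(t = seq(0, 59.9, by = 0.1), x = 0, y = 0, z = 1)
  moving <- still %>% dplyr::mutate(x = sin(10 * t) * 0.5)
  expect_equal(activity_duration(still, criterion = "motion"), 0)
  expect_equal(activity_duration(moving, criterion = "motion"), 60)
})

test_that("eligibility reproduces the count-profile truth table", {
  mk <- function(counts) {
    tibble::tibble(subject_id = "s1",
                   tremor = rep(as.numeric(names(counts)), counts))
  }
  expect_equal(filter_subjects(mk(c(`0` = 30, `1` = 10)), "tremor"), "s1")
  expect_equal(filter_subjects(mk(c(`0` = 30, `1` = 5, `2` = 5)), "tremor"), "s1")
  expect_length(filter_subjects(mk(c(`0` = 35, `1` = 5)), "tremor"), 0)
  expect_length(filter_subjects(mk(c(`0` = 25, `1` = 14)), "tremor"), 0)

  # property: 50 random count profiles against the rule stated directly
  withr::with_seed(99, {
    for (i in 1:50) {
      k <- sample(1:5, 1)
      counts <- sample(0:30, k, replace = TRUE)
      counts <- counts[counts > 0]
      if (length(counts) == 0) counts <- 5
      names(counts) <- as.character(seq_along(counts) - 1)
      labels <- mk(counts)
      eligible <- length(filter_subjects(labels, "tremor")) == 1
      rule <- sum(counts) >= 40 &&
        (sum(counts >= 10) >= 2 || sum(counts >= 5) >= 3)
      expect_identical(eligible, rule)
    }
  })
})

test_that("missing labels do not count toward eligibility", {
  labels <- tibble::tibble(subject_id = "s1",
                           tremor = c(rep(0, 30), rep(1, 9), NA))
  expect_length(filter_subjects(labels, "tremor"), 0)
})

test_that("within-subject split is stratified and exactly sized", {
  labels <- tibble::tibble(
    measurement_id = sprintf("m%02d", 1:40), subject_id = "s1",
    on_off = 0, dyskinesia = 0, tremor = rep(c(0, 2), each = 20))
  sp <- split_train_test(labels, seed = 4)
  test_ids <- sp$measurement_id[sp$partition == "test"]
  expect_length(test_ids, 10)
  by_label <- labels %>% dplyr::filter(measurement_id %in% test_ids)
  expect_equal(unname(table(by_label$tremor)), c(5L, 5L), ignore_attr = TRUE)

  # 41 observations: round(0.25 * 41) = 10 test, 31 train
  labels41 <- tibble::tibble(measurement_id = sprintf("m%02d", 1:41),
                             subject_id = "s1", on_off = 1, dyskinesia = 0,
                             tremor = 1)
  sp41 <- split_train_test(labels41, seed = 4)
  expect_equal(sum(sp41$partition == "test"), 10)
  expect_equal(sum(sp41$partition == "train"), 31)

  # determinism
  expect_identical(split_train_test(labels, seed = 4), sp)
  expect_false(identical(split_train_test(labels, seed = 5), sp))
})

test_that("split keeps per-stratum proportions within one observation", {
  withr::with_seed(12, {
    labels <- tibble::tibble(
      measurement_id = sprintf("m%03d", 1:120),
      subject_id = rep(c("a", "b"), each = 60),
      on_off = sample(0:1, 120, TRUE),
      dyskinesia = sample(0:2, 120, TRUE),
      tremor = sample(0:2, 120, TRUE))
  })
  sp <- split_train_test(labels, seed = 7)
  joined <- labels %>% dplyr::inner_join(sp, by = c("measurement_id", "subject_id"))
  strata <- joined %>%
    dplyr::group_by(subject_id, on_off, dyskinesia, tremor) %>%
    dplyr::summarise(n = dplyr::n(),
                     n_test = sum(partition == "test"), .groups = "drop")
  expect_true(all(abs(strata$n_test - 0.25 * strata$n) <= 1))
  # singleton strata always train
  singles <- strata %>% dplyr::filter(n == 1)
  expect_true(all(singles$n_test == 0))
  # per-subject totals exact
  totals <- joined %>% dplyr::group_by(subject_id) %>%
    dplyr::summarise(n_test = sum(partition == "test"), n = dplyr::n())
  expect_equal(totals$n_test, round(0.25 * totals$n))
})

test_that("write_cohort/read_cohort round-trip the observable dataset", {
  ch <- generate_cohort(tiny_cohort_spec(n_subjects = 2, reports = c(3, 3),
                                         seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir, "CIS")
  expect_equal(nrow(back$labels), nrow(ch$labels))
  expect_equal(sort(unique(back$segments$measurement_id)),
               sort(unique(ch$segments$measurement_id)))
  expect_false(any(grepl("theta", names(back$covariates))))
  expect_equal(back$covariates$age, ch$subjects$age)
  # numeric fidelity at written precision
  one <- ch$segments %>% dplyr::filter(measurement_id == ch$labels$measurement_id[1])
  two <- back$segments %>% dplyr::filter(measurement_id == ch$labels$measurement_id[1])
  expect_equal(two$x, one$x, tolerance = 1e-9)
})
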