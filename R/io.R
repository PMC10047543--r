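#' Read and write one accelerometer segment CSV
#'
#' Segment files are CSVs with header `t,x,y,z`: `t` in seconds from segment
#' start, axes in g. Readers tolerate CRLF line endings and an optional BOM.
#' A write -> read round trip is lossless at the written float precision.
#'
#' @param path File path.
#' @return `read_segment()`: tibble with columns `t`, `x`, `y`, `z`.
#' @export
read_segment <- function(path) {
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE),
    error = function(e) abort(sprintf("cannot parse segment file '%s': %s",
                                      path, conditionMessage(e)))
  )
  missing_cols <- setdiff(c("t", "x", "y", "z"), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("segment file '%s' lacks column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0) abort(sprintf("segment file '%s' is empty", path))
  bad <- which(diff(df$t) < 0)
  if (length(bad) > 0) {
    abort(sprintf("segment file '%s': timestamp decreases at row %d",
                  path, bad[1] + 1L))
  }
  if (df$t[1] < 0) abort(sprintf("segment file '%s': negative start time", path))
  as_tibble(df[c("t", "x", "y", "z")])
}

#' @param segment Tibble with columns `t`, `x`, `y`, `z`.
#' @rdname read_segment
#' @export
write_segment <- function(segment, path) {
  stopifnot(all(c("t", "x", "y", "z") %in% names(segment)))
  readr::write_csv(segment[c("t", "x", "y", "z")], path, progress = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to the on-disk dataset layout
#'
#' Emits one `<measurement_id>[_phone].csv` per segment stream, a
#' `labels_<cohort>.csv` with cohort-native label records, and a
#' `covariates_<cohort>.csv` with the observable demographics and MDS-UPDRS
#' covariates (simulation-truth columns such as `theta_*` are not written).
#'
#' @param cohort A `pd_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pd_cohort"))
  dir.create(file.path(dir, "segments"), recursive = TRUE, showWarnings = FALSE)
  streams <- cohort$segments %>%
    group_by(.data$measurement_id, .data$device) %>%
    tidyr::nest() %>%
    ungroup() %>%
    arrange(.data$measurement_id, .data$device)
  purrr::pwalk(streams, function(measurement_id, device, data) {
    suffix <- if (device == "watch") "" else paste0("_", device)
    write_segment(data, file.path(dir, "segments",
                                  paste0(measurement_id, suffix, ".csv")))
  })
  cohort_tag <- tolower(cohort$spec$cohort_id)
  readr::write_csv(cohort$labels,
                   file.path(dir, paste0("labels_", cohort_tag, ".csv")),
                   progress = FALSE)
  covariates <- cohort$subjects %>%
    select(-dplyr::starts_with("theta_"), -dplyr::starts_with("label_sd_"),
           -"tremor_freq_hz", -"med_phase")
  readr::write_csv(covariates,
                   file.path(dir, paste0("covariates_", cohort_tag, ".csv")),
                   progress = FALSE)
  invisible(dir)
}

#' Read a cohort dataset from disk
#'
#' Inverse of [write_cohort()] for the observable files (labels, covariates,
#' segment streams).
#'
#' @param dir Dataset directory.
#' @param cohort_id `"CIS"` or `"REAL"`.
#' @return List with `labels`, `covariates`, `segments` tibbles.
#' @export
read_cohort <- function(dir, cohort_id) {
  tag <- tolower(cohort_id)
  labels <- readr::read_csv(file.path(dir, paste0("labels_", tag, ".csv")),
                            show_col_types = FALSE, progress = FALSE)
  covariates <- readr::read_csv(file.path(dir, paste0("covariates_", tag, ".csv")),
                                show_col_types = FALSE, progress = FALSE)
  files <- sort(list.files(file.path(dir, "segments"), pattern = "\\.csv$",
                           full.names = TRUE))
  ids <- sub("\\.csv$", "", basename(files))
  keep <- sub("_phone$", "", ids) %in% labels$measurement_id
  files <- files[keep]
  ids <- ids[keep]
  segments <- purrr::map2_dfr(files, ids, function(f, id) {
    seg <- read_segment(f)
    seg$measurement_id <- sub("_phone$", "", id)
    seg$device <- if (grepl("_phone$", id)) "phone" else "watch"
    seg
  })
  list(labels = labels, covariates = covariates,
       segments = segments %>% select("measurement_id", "device",
                                      "t", "x", "y", "z"))
}
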