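PIPELINE_STAGES <- c("simulate", "prepare", "featurize", "train", "score",
                     "ensemble", "posthoc")

#' Configure an end-to-end benchmark run
#'
#' A single structured configuration drives every stage; one global seed fans
#' out deterministically to per-stage seeds (stage seed =
#' `derive(seed, stage index)`), so a fixed config yields byte-identical
#' artifacts.
#'
#' @param cohorts List of [cohort_spec()]s (typically one CIS and one REAL).
#' @param out_dir Run directory for artifacts and manifests.
#' @param symptoms Symptoms to model.
#' @param split_ratio Training fraction of the within-subject split.
#' @param scoring_B Bootstrap iterations for scoring (default 1000).
#' @param alpha Nominal significance level in (0, 1).
#' @param ensemble_k Nested-CV folds (default 6: 5 inner + 1 evaluation).
#' @param lift_B Bootstrap resamples for subject-level lift (default 100).
#' @param search_iterations Random-search draws for the main model archetypes.
#' @param base_search_iterations Random-search draws for ensemble base models.
#' @param min_activity Minimum per-stream activity in seconds for
#'   [filter_segments()] (default 120 = the benchmark's 2-minute rule).
#' @param eligibility List of [filter_subjects()] rule constants
#'   (`min_n`, `cat2_min`, `cat3_min`); the defaults are the benchmark's
#'   published rule.
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(cohorts, out_dir, symptoms = SYMPTOMS,
                       split_ratio = 0.75, scoring_B = 1000, alpha = 0.05,
                       ensemble_k = 6, lift_B = 100,
                       search_iterations = 25L, base_search_iterations = 1L,
                       min_activity = 120,
                       eligibility = list(min_n = 40, cat2_min = 10,
                                          cat3_min = 5),
                       seed = 1L) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (split_ratio <= 0 || split_ratio >= 1) abort("`split_ratio` must lie in (0, 1)")
  stopifnot(length(cohorts) >= 1,
            all(vapply(cohorts, inherits, TRUE, "cohort_spec")))
  rates <- unique(vapply(cohorts, `[[`, 0, "sampling_rate"))
  if (length(rates) > 1) {
    inform("cohorts use different sampling rates; features use each cohort's own rate")
  }
  structure(list(
    cohorts = cohorts, out_dir = out_dir, symptoms = symptoms,
    split_ratio = split_ratio, scoring_B = as.integer(scoring_B),
    alpha = alpha, ensemble_k = as.integer(ensemble_k),
    lift_B = as.integer(lift_B),
    search_iterations = as.integer(search_iterations),
    base_search_iterations = as.integer(base_search_iterations),
    min_activity = min_activity,
    eligibility = eligibility,
    seed = as.integer(seed)
  ), class = "run_config")
}

stage_seed <- function(config, stage) {
  derive_seed(config$seed, match(stage, PIPELINE_STAGES))
}

stage_dir <- function(config, stage) file.path(config$out_dir, stage)

manifest_path <- function(config, stage) {
  file.path(config$out_dir, paste0("manifest_", stage, ".json"))
}

hash_files <- function(paths) {
  paths <- as.character(paths %||% character())
  paths <- sort(paths[file.exists(paths)])
  h <- tools::md5sum(paths)
  as.list(setNames(unname(h), basename(paths)))
}

stage_outputs <- function(config, stage) {
  d <- stage_dir(config, stage)
  list.files(d, recursive = TRUE, full.names = TRUE)
}

write_manifest <- function(config, stage, inputs) {
  manifest <- list(
    stage = stage,
    seed = stage_seed(config, stage),
    inputs = inputs,
    outputs = hash_files(stage_outputs(config, stage))
  )
  jsonlite::write_json(manifest, manifest_path(config, stage),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_inputs <- function(config, stage) {
  upstream <- PIPELINE_STAGES[seq_len(match(stage, PIPELINE_STAGES) - 1)]
  unlist(lapply(upstream, function(s) stage_outputs(config, s)))
}

stage_is_current <- function(config, stage, inputs) {
  mp <- manifest_path(config, stage)
  if (!file.exists(mp)) return(FALSE)
  manifest <- jsonlite::read_json(mp)
  outs <- stage_outputs(config, stage)
  if (length(outs) == 0 && length(manifest$outputs) > 0) return(FALSE)
  identical(hash_files(if (length(inputs)) inputs else character()),
            manifest$inputs) &&
    identical(hash_files(outs), manifest$outputs)
}

#' Run one pipeline stage
#'
#' Stages run in the fixed order simulate, prepare, featurize, train, score,
#' ensemble, posthoc. Each stage reads only the artifacts of earlier stages,
#' writes its outputs under `<out_dir>/<stage>/`, and records a manifest with
#' input/output hashes and its derived seed. A stage whose manifest matches
#' the current input and output hashes is a no-op; a non-initial stage whose
#' upstream manifest is missing refuses to run.
#'
#' @param stage Stage name.
#' @param config A [run_config()].
#' @param force Rerun even if current.
#' @return Invisibly, the stage manifest.
#' @export
run_stage <- function(stage, config, force = FALSE) {
  if (!stage %in% PIPELINE_STAGES) {
    abort(sprintf("unknown stage '%s'; stages are: %s", stage,
                  paste(PIPELINE_STAGES, collapse = ", ")))
  }
  idx <- match(stage, PIPELINE_STAGES)
  if (idx > 1) {
    prev <- PIPELINE_STAGES[idx - 1]
    if (!file.exists(manifest_path(config, prev))) {
      abort(sprintf("stage '%s' requires upstream stage '%s' to have run",
                    stage, prev))
    }
  }
  inputs <- stage_inputs(config, stage)
  if (!force && stage_is_current(config, stage, inputs)) {
    inform(sprintf("stage '%s' is up to date; skipping", stage))
    return(invisible(jsonlite::read_json(manifest_path(config, stage))))
  }
  inform(sprintf("running stage '%s'", stage))
  dir.create(stage_dir(config, stage), recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = stage_simulate(config),
    prepare = stage_prepare(config),
    featurize = stage_featurize(config),
    train = stage_train(config),
    score = stage_score(config),
    ensemble = stage_ensemble(config),
    posthoc = stage_posthoc(config)
  )
  invisible(write_manifest(config, stage, hash_files(inputs)))
}

#' Run the full pipeline
#'
#' Runs every stage in order (skipping up-to-date stages) and returns the
#' aggregated run report: leaderboards, ensemble evaluations and post-hoc
#' tables, plus an overall report hash for determinism checks.
#'
#' @param config A [run_config()].
#' @return List with `leaderboards`, `ensembles`, `posthoc`, and
#'   `report_hash`.
#' @export
run_all <- function(config) {
  for (stage in PIPELINE_STAGES) run_stage(stage, config)
  report_files <- sort(unlist(lapply(c("score", "ensemble", "posthoc"),
                                     function(s) stage_outputs(config, s))))
  leaderboards <- lapply(setNames(config$symptoms, config$symptoms),
                         function(sym) {
    readr::read_csv(file.path(stage_dir(config, "score"),
                              paste0("leaderboard_", sym, ".csv")),
                    show_col_types = FALSE, progress = FALSE)
  })
  list(
    leaderboards = leaderboards,
    report_hash = unname(tools::md5sum(report_file_concat(report_files,
                                                          config$out_dir)))
  )
}

# concatenate report files into one temp file for a stable overall hash
report_file_concat <- function(files, out_dir) {
  target <- file.path(out_dir, "report_digest.txt")
  con <- file(target, "wb")
  on.exit(close(con))
  for (f in files) {
    writeLines(basename(f), con)
    writeBin(readBin(f, "raw", file.size(f)), con)
  }
  target
}

stage_simulate <- function(config) {
  d <- stage_dir(config, "simulate")
  for (spec in config$cohorts) {
    cohort <- generate_cohort(spec)
    write_cohort(cohort, file.path(d, tolower(spec$cohort_id)))
    # latent columns are simulation truth; persist for diagnostics only
    readr::write_csv(cohort$latent,
                     file.path(d, tolower(spec$cohort_id), "latent_truth.csv"),
                     progress = FALSE)
  }
}

read_stage_cohorts <- function(config) {
  d <- stage_dir(config, "simulate")
  lapply(config$cohorts, function(spec) {
    ch <- read_cohort(file.path(d, tolower(spec$cohort_id)), spec$cohort_id)
    ch$spec <- spec
    ch
  })
}

stage_prepare <- function(config) {
  d <- stage_dir(config, "prepare")
  cohorts <- read_stage_cohorts(config)
  all_labels <- purrr::map_dfr(cohorts, function(ch) {
    harmonize_labels(ch$labels, ch$spec$cohort_id,
                     segment_duration = ch$spec$segment_duration)
  })
  retained <- purrr::map_dfr(cohorts, function(ch) {
    filter_segments(ch$segments, min_activity = config$min_activity) %>%
      distinct(.data$measurement_id, .data$device)
  })
  labels <- all_labels %>%
    semi_join(retained %>% distinct(.data$measurement_id),
              by = "measurement_id")
  if (nrow(labels) == 0) {
    abort(paste0(
      "no segments survive the activity filter (min_activity = ",
      config$min_activity, " s); segments shorter than the threshold are ",
      "always removed - lower `min_activity` in run_config()"))
  }
  eligible <- purrr::map_dfr(config$symptoms, function(sym) {
    tibble(symptom = sym,
           subject_id = filter_subjects(labels, sym,
                                        min_n = config$eligibility$min_n,
                                        cat2_min = config$eligibility$cat2_min,
                                        cat3_min = config$eligibility$cat3_min))
  })
  split <- split_train_test(
    labels %>% filter(.data$subject_id %in% unique(eligible$subject_id)),
    ratio = config$split_ratio, seed = stage_seed(config, "prepare")
  )
  readr::write_csv(labels, file.path(d, "labels_harmonized.csv"), progress = FALSE)
  readr::write_csv(retained, file.path(d, "retained_streams.csv"), progress = FALSE)
  readr::write_csv(eligible, file.path(d, "eligible_subjects.csv"), progress = FALSE)
  readr::write_csv(split, file.path(d, "split.csv"), progress = FALSE)
}

stage_featurize <- function(config) {
  d <- stage_dir(config, "featurize")
  cohorts <- read_stage_cohorts(config)
  retained <- readr::read_csv(
    file.path(stage_dir(config, "prepare"), "retained_streams.csv"),
    show_col_types = FALSE, progress = FALSE)
  feats <- purrr::map(c("generic", "actigraphy"), function(fset) {
    purrr::map_dfr(cohorts, function(ch) {
      segs <- ch$segments %>%
        semi_join(retained, by = c("measurement_id", "device"))
      extract_features(segs, fs = ch$spec$sampling_rate, feature_set = fset) %>%
        mutate(cohort_id = ch$spec$cohort_id)
    })
  })
  readr::write_csv(feats[[1]], file.path(d, "features_generic.csv"), progress = FALSE)
  readr::write_csv(feats[[2]], file.path(d, "features_actigraphy.csv"), progress = FALSE)
}

read_prepared <- function(config) {
  pd <- stage_dir(config, "prepare")
  fd <- stage_dir(config, "featurize")
  list(
    labels = readr::read_csv(file.path(pd, "labels_harmonized.csv"),
                             show_col_types = FALSE, progress = FALSE),
    eligible = readr::read_csv(file.path(pd, "eligible_subjects.csv"),
                               show_col_types = FALSE, progress = FALSE),
    split = readr::read_csv(file.path(pd, "split.csv"),
                            show_col_types = FALSE, progress = FALSE),
    generic = readr::read_csv(file.path(fd, "features_generic.csv"),
                              show_col_types = FALSE, progress = FALSE),
    actigraphy = readr::read_csv(file.path(fd, "features_actigraphy.csv"),
                                 show_col_types = FALSE, progress = FALSE),
    covariates = purrr::map_dfr(config$cohorts, function(spec) {
      readr::read_csv(file.path(stage_dir(config, "simulate"),
                                tolower(spec$cohort_id),
                                paste0("covariates_", tolower(spec$cohort_id),
                                       ".csv")),
                      show_col_types = FALSE, progress = FALSE)
    })
  )
}

# design matrices for the two archetypes, restricted to eligible subjects
# for one symptom
symptom_designs <- function(prep, config, sym) {
  elig <- prep$eligible %>% filter(.data$symptom == sym) %>% pull("subject_id")
  labels <- prep$labels %>% filter(.data$subject_id %in% elig,
                                   !is.na(.data[[sym]]))
  gen <- assemble_design_matrix(
    prep$generic %>% select(-"cohort_id"), labels, mode = "sensor_only")
  act <- assemble_design_matrix(
    prep$actigraphy %>% select(-"cohort_id"), labels,
    covariates = prep$covariates, mode = "with_covariates")
  list(labels = labels, generic = gen, actigraphy = act)
}

fit_and_predict_archetypes <- function(designs, labels, sym, train_ids,
                                       test_ids, config, seed) {
  train_labels <- labels %>% filter(.data$measurement_id %in% train_ids)
  test_obs <- labels %>% filter(.data$measurement_id %in% test_ids) %>%
    distinct(.data$measurement_id, .data$subject_id, .data$cohort_id)
  null_model <- fit_null(train_labels, sym)
  ps_model <- fit_per_subject(
    designs$generic %>% filter(.data$measurement_id %in% train_ids),
    model_spec("per_subject", sym,
               search_iterations = config$search_iterations,
               seed = derive_seed(seed, 1)))
  gl_model <- fit_global(
    designs$actigraphy %>% filter(.data$measurement_id %in% train_ids),
    model_spec("global", sym,
               search_iterations = config$search_iterations,
               seed = derive_seed(seed, 2)),
    allow_small_cohorts = TRUE)
  list(
    null = predict(null_model, test_obs),
    per_subject = predict(
      ps_model, designs$generic %>% filter(.data$measurement_id %in% test_ids),
      observations = test_obs),
    global = predict(
      gl_model, designs$actigraphy %>% filter(.data$measurement_id %in% test_ids),
      observations = test_obs),
    models = list(null = null_model, per_subject = ps_model, global = gl_model)
  )
}

stage_train <- function(config) {
  d <- stage_dir(config, "train")
  prep <- read_prepared(config)
  seed0 <- stage_seed(config, "train")
  for (sym in config$symptoms) {
    designs <- symptom_designs(prep, config, sym)
    split <- prep$split %>%
      semi_join(designs$labels, by = "measurement_id")
    train_ids <- split %>% filter(.data$partition == "train") %>%
      pull("measurement_id")
    test_ids <- split %>% filter(.data$partition == "test") %>%
      pull("measurement_id")
    preds <- fit_and_predict_archetypes(
      designs, designs$labels, sym, train_ids, test_ids, config,
      derive_seed(seed0, match(sym, SYMPTOMS)))
    for (m in c("null", "per_subject", "global")) {
      readr::write_csv(preds[[m]],
                       file.path(d, sprintf("predictions_%s_%s.csv", m, sym)),
                       progress = FALSE)
    }
    card <- list(
      symptom = sym,
      per_subject_importance = head(feature_importance(preds$models$per_subject), 10),
      global_importance = head(feature_importance(preds$models$global), 10)
    )
    jsonlite::write_json(card, file.path(d, sprintf("model_card_%s.json", sym)),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
}

stage_score <- function(config) {
  d <- stage_dir(config, "score")
  prep <- read_prepared(config)
  td <- stage_dir(config, "train")
  seed0 <- stage_seed(config, "score")
  for (sym in config$symptoms) {
    sets <- lapply(setNames(c("null", "per_subject", "global"),
                            c("null", "per_subject", "global")), function(m) {
      readr::read_csv(file.path(td, sprintf("predictions_%s_%s.csv", m, sym)),
                      show_col_types = FALSE, progress = FALSE)
    })
    truth <- prep$labels %>%
      semi_join(prep$split %>% filter(.data$partition == "test"),
                by = "measurement_id") %>%
      semi_join(sets$null, by = "measurement_id")
    lb <- leaderboard(sets, truth, sym, B = config$scoring_B,
                      seed = derive_seed(seed0, match(sym, SYMPTOMS)),
                      alpha = config$alpha)
    readr::write_csv(as_tibble(lb), file.path(d, paste0("leaderboard_", sym, ".csv")),
                     progress = FALSE)
    for (m in names(sets)) {
      st <- score_predictions(sets[[m]], truth, sym)
      report <- list(
        submission_id = m, symptom = sym,
        wmse = attr(st, "wmse"),
        per_subject = purrr::pmap(st, function(subject_id, n, mse)
          list(subject = subject_id, n = n, mse = mse)),
        p_vs_null = if (m == "null") NULL else
          pvalue_vs_null(attr(lb, "bootstrap"), m),
        B = config$scoring_B, seed = derive_seed(seed0, match(sym, SYMPTOMS))
      )
      jsonlite::write_json(report,
                           file.path(d, sprintf("score_%s_%s.json", m, sym)),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
}

# five heterogeneous base configurations standing in for independent teams
base_archetype_specs <- function(sym, config, seed) {
  list(
    ps_median = model_spec("per_subject", sym,
                           search_iterations = config$base_search_iterations,
                           seed = derive_seed(seed, 11)),
    ps_mean = model_spec("per_subject", sym, aggregation = "mean",
                         n_trees_range = c(150L, 300L),
                         search_iterations = config$base_search_iterations,
                         seed = derive_seed(seed, 12)),
    global_cov = model_spec("global", sym,
                            search_iterations = config$base_search_iterations,
                            seed = derive_seed(seed, 13)),
    global_sensor = model_spec("global", sym,
                               search_iterations = config$base_search_iterations,
                               seed = derive_seed(seed, 14)),
    null_noise = model_spec("null", sym, seed = derive_seed(seed, 15))
  )
}

fit_base_on <- function(name, spec, designs, labels, fit_ids, predict_ids,
                        sym, noise_seed) {
  train_labels <- labels %>% filter(.data$measurement_id %in% fit_ids)
  pred_obs <- labels %>% filter(.data$measurement_id %in% predict_ids) %>%
    distinct(.data$measurement_id, .data$subject_id, .data$cohort_id)
  if (name == "null_noise") {
    nm <- fit_null(train_labels, sym)
    p <- predict(nm, pred_obs)
    p$prediction <- p$prediction +
      withr::with_seed(noise_seed, rnorm(nrow(p), 0, 0.15))
    return(p)
  }
  design_name <- if (startsWith(name, "ps_")) "generic" else
    if (name == "global_sensor") "actigraphy_sensor" else "actigraphy"
  dmat <- switch(design_name,
    generic = designs$generic,
    actigraphy = designs$actigraphy,
    actigraphy_sensor = designs$actigraphy %>%
      select(all_of(c("measurement_id", "device", "window_index", "subject_id",
                      "cohort_id", SYMPTOMS[SYMPTOMS %in% names(designs$actigraphy)])),
             all_of(actigraphy_feature_names()))
  )
  dmat_fit <- dmat %>% filter(.data$measurement_id %in% fit_ids)
  model <- if (spec$archetype == "per_subject") {
    fit_per_subject(dmat_fit, spec)
  } else {
    fit_global(dmat_fit, spec, allow_small_cohorts = TRUE)
  }
  predict(model, dmat %>% filter(.data$measurement_id %in% predict_ids),
          observations = pred_obs)
}

build_base_matrices <- function(designs, labels, sym, train_ids, test_ids,
                                config, seed) {
  train_labels <- labels %>% filter(.data$measurement_id %in% train_ids)
  folds <- nested_cv(train_labels, k = config$ensemble_k,
                     seed = derive_seed(seed, 1))
  k <- config$ensemble_k
  specs <- base_archetype_specs(sym, config, seed)
  oof <- folds %>% left_join(train_labels %>%
                               select("measurement_id", truth = all_of(sym),
                                      "cohort_id"),
                             by = "measurement_id")
  for (nm in names(specs)) oof[[nm]] <- NA_real_
  inner_folds <- seq_len(k - 1)
  for (f in inner_folds) {
    fit_ids <- folds %>% filter(.data$fold %in% setdiff(inner_folds, f)) %>%
      pull("measurement_id")
    out_ids <- folds %>% filter(.data$fold == f) %>% pull("measurement_id")
    for (nm in names(specs)) {
      p <- fit_base_on(nm, specs[[nm]], designs, labels, fit_ids, out_ids, sym,
                       derive_seed(seed, 100 + f))
      oof[[nm]][match(p$measurement_id, oof$measurement_id)] <- p$prediction
    }
  }
  # evaluation fold: bases trained on all inner folds
  inner_ids <- folds %>% filter(.data$fold < k) %>% pull("measurement_id")
  eval_ids <- folds %>% filter(.data$fold == k) %>% pull("measurement_id")
  for (nm in names(specs)) {
    p <- fit_base_on(nm, specs[[nm]], designs, labels, inner_ids, eval_ids, sym,
                     derive_seed(seed, 200))
    oof[[nm]][match(p$measurement_id, oof$measurement_id)] <- p$prediction
  }
  # test matrix: bases refit on the full training data
  test_tbl <- labels %>% filter(.data$measurement_id %in% test_ids) %>%
    select("measurement_id", "subject_id", "cohort_id", truth = all_of(sym))
  for (nm in names(specs)) {
    p <- fit_base_on(nm, specs[[nm]], designs, labels, train_ids, test_ids, sym,
                     derive_seed(seed, 300))
    test_tbl[[nm]] <- p$prediction[match(test_tbl$measurement_id,
                                         p$measurement_id)]
  }
  list(train = oof %>% select(-"cohort_id") %>%
         left_join(train_labels %>% distinct(.data$measurement_id,
                                             .data$cohort_id),
                   by = "measurement_id"),
       test = test_tbl)
}

stage_ensemble <- function(config) {
  d <- stage_dir(config, "ensemble")
  prep <- read_prepared(config)
  seed0 <- stage_seed(config, "ensemble")
  for (sym in config$symptoms) {
    designs <- symptom_designs(prep, config, sym)
    split <- prep$split %>% semi_join(designs$labels, by = "measurement_id")
    train_ids <- split %>% filter(.data$partition == "train") %>%
      pull("measurement_id")
    test_ids <- split %>% filter(.data$partition == "test") %>%
      pull("measurement_id")
    sseed <- derive_seed(seed0, match(sym, SYMPTOMS))
    mats <- build_base_matrices(designs, designs$labels, sym, train_ids,
                                test_ids, config, sseed)
    readr::write_csv(mats$train, file.path(d, paste0("base_matrix_", sym, ".csv")),
                     progress = FALSE)
    report <- select_and_finalize(mats$train, test_matrix = mats$test,
                                  seed = derive_seed(sseed, 2))
    truth <- designs$labels %>%
      filter(.data$measurement_id %in% test_ids)
    base_wmse <- vapply(base_model_columns(mats$test), function(b) {
      attr(score_predictions(
        tibble(measurement_id = mats$test$measurement_id,
               prediction = mats$test[[b]]), truth, sym), "wmse")
    }, 0)
    ens_wmse <- vapply(report$test_predictions, function(p) {
      p$prediction <- clip(p$prediction, 0, 4)
      attr(score_predictions(p, truth, sym), "wmse")
    }, 0)
    out <- list(
      symptom = sym,
      evaluation = report$evaluation,
      unsupervised_winner = report$unsupervised,
      supervised_winner = report$supervised,
      base_test_wmse = as.list(base_wmse),
      ensemble_test_wmse = as.list(ens_wmse)
    )
    jsonlite::write_json(out, file.path(d, paste0("ensemble_", sym, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (cls in names(report$test_predictions)) {
      readr::write_csv(report$test_predictions[[cls]],
                       file.path(d, sprintf("predictions_ensemble_%s_%s.csv",
                                            cls, sym)),
                       progress = FALSE)
    }
  }
}

stage_posthoc <- function(config) {
  d <- stage_dir(config, "posthoc")
  prep <- read_prepared(config)
  td <- stage_dir(config, "train")
  seed0 <- stage_seed(config, "posthoc")
  for (sym in config$symptoms) {
    truth <- prep$labels %>%
      semi_join(prep$split %>% filter(.data$partition == "test"),
                by = "measurement_id") %>%
      filter(!is.na(.data[[sym]]))
    sets <- lapply(setNames(c("null", "per_subject", "global"),
                            c("null", "per_subject", "global")), function(m) {
      readr::read_csv(file.path(td, sprintf("predictions_%s_%s.csv", m, sym)),
                      show_col_types = FALSE, progress = FALSE)
    })
    truth <- truth %>% semi_join(sets$null, by = "measurement_id")
    null_scores <- score_predictions(sets$null, truth, sym)
    lift_tbl <- purrr::map_dfr(c("per_subject", "global"), function(m) {
      compute_lift(score_predictions(sets[[m]], truth, sym), null_scores) %>%
        mutate(model = m)
    })
    boot <- purrr::map_dfr(c("per_subject", "global"), function(m) {
      bootstrap_lift(sets[[m]], sets$null, truth, sym, B = config$lift_B,
                     seed = derive_seed(seed0, match(sym, SYMPTOMS))) %>%
        mutate(model = m)
    })
    train_labels <- prep$labels %>%
      semi_join(prep$split %>% filter(.data$partition == "train"),
                by = "measurement_id")
    covs <- posthoc_covariates(train_labels, truth, prep$covariates, sym)
    assoc <- covariate_association_suite(
      lift_tbl %>% select("subject_id", "model", "lift"), covs)
    readr::write_csv(lift_tbl, file.path(d, paste0("lift_", sym, ".csv")),
                     progress = FALSE)
    readr::write_csv(boot, file.path(d, paste0("lift_bootstrap_", sym, ".csv")),
                     progress = FALSE)
    readr::write_csv(assoc$per_model,
                     file.path(d, paste0("association_", sym, ".csv")),
                     progress = FALSE)
    jsonlite::write_json(
      list(symptom = sym, pooled = assoc$pooled),
      file.path(d, paste0("association_pooled_", sym, ".json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
}

#' Subject-level covariates for the lift association analysis
#'
#' Assembles, per subject: training-label variance for the symptom, test
#' observation count, mean reporting lag, age, and the MDS-UPDRS part
#' summaries (I/II totals, III on/off item sums, IV item sum).
#'
#' @param train_labels,test_labels Harmonized labels of the two partitions.
#' @param covariates Covariate tibble from the dataset.
#' @param symptom Symptom column.
#' @return Tibble keyed by `subject_id`.
#' @export
posthoc_covariates <- function(train_labels, test_labels, covariates, symptom) {
  lv <- train_labels %>%
    filter(!is.na(.data[[symptom]])) %>%
    group_by(.data$subject_id) %>%
    summarise(label_variance = var(.data[[symptom]]),
              reporting_lag = if ("reporting_lag" %in% names(train_labels))
                mean(.data$reporting_lag) else NA_real_,
              .groups = "drop")
  nt <- test_labels %>%
    filter(!is.na(.data[[symptom]])) %>%
    count(.data$subject_id, name = "n_test")
  p3on <- grep("^updrs3_on_", names(covariates), value = TRUE)
  p3off <- grep("^updrs3_off_", names(covariates), value = TRUE)
  p4 <- grep("^updrs4_", names(covariates), value = TRUE)
  cv <- tibble(
    subject_id = covariates$subject_id,
    age = covariates$age,
    updrs1_total = covariates$updrs1_total,
    updrs2_total = covariates$updrs2_total,
    updrs3_on_sum = rowSums(covariates[p3on]),
    updrs3_off_sum = rowSums(covariates[p3off]),
    updrs4_sum = rowSums(covariates[p4])
  )
  lv %>% left_join(nt, by = "subject_id") %>% left_join(cv, by = "subject_id")
}
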