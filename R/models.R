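#' Model specification for a severity archetype
#'
#' Three archetypes are supported: `"null"` (subject-specific training-label
#' mean), `"per_subject"` (one random-forest regressor per subject, windows
#' aggregated to an observation by the median), and `"global"` (one
#' random-forest per cohort with covariates, windows aggregated by the mean).
#' Hyperparameters are tuned by random search over grouped 5-fold CV.
#'
#' @param archetype `"null"`, `"per_subject"`, or `"global"`.
#' @param symptom Target symptom.
#' @param n_trees_range,max_depth_range,min_node_range Random-search space
#'   (depth 0 means unlimited).
#' @param cv_folds Cross-validation folds for the search (default 5).
#' @param search_iterations Random-search draws (default 25).
#' @param aggregation Window-to-observation aggregation; defaults to median
#'   for `per_subject` and mean for `global`.
#' @param seed Integer seed.
#' @return A `model_spec` list.
#' @export
model_spec <- function(archetype = c("per_subject", "global", "null"),
                       symptom = SYMPTOMS,
                       n_trees_range = c(100L, 500L),
                       max_depth_range = c(0L, 15L),
                       min_node_range = c(1L, 20L),
                       cv_folds = 5L,
                       search_iterations = 25L,
                       aggregation = NULL,
                       seed = 1L) {
  archetype <- match.arg(archetype)
  symptom <- match.arg(symptom)
  if (is.null(aggregation)) {
    aggregation <- if (archetype == "global") "mean" else "median"
  }
  aggregation <- match.arg(aggregation, c("median", "mean"))
  structure(list(
    archetype = archetype, symptom = symptom,
    n_trees_range = as.integer(n_trees_range),
    max_depth_range = as.integer(max_depth_range),
    min_node_range = as.integer(min_node_range),
    cv_folds = as.integer(cv_folds),
    search_iterations = as.integer(search_iterations),
    aggregation = aggregation,
    seed = as.integer(seed)
  ), class = "model_spec")
}

feature_columns <- function(design) {
  id_cols <- c("measurement_id", "device", "window_index", "subject_id",
               "cohort_id", SYMPTOMS)
  setdiff(names(design), id_cols)
}

#' Fit the Null model
#'
#' Predicts, for every test observation of a subject, the mean of that
#' subject's training labels — the best prediction in the absence of sensor
#' data.
#'
#' @param train_labels Harmonized training labels.
#' @param symptom Target symptom.
#' @return A `pd_null_model`.
#' @export
fit_null <- function(train_labels, symptom) {
  symptom <- match.arg(symptom, SYMPTOMS)
  means <- train_labels %>%
    filter(!is.na(.data[[symptom]])) %>%
    group_by(.data$subject_id) %>%
    summarise(prediction = mean(.data[[symptom]]), .groups = "drop")
  if (nrow(means) == 0) abort("no non-missing training labels")
  structure(list(symptom = symptom, means = means), class = "pd_null_model")
}

#' Predict from a Null model
#'
#' @param object A `pd_null_model`.
#' @param new_labels Tibble with `measurement_id`, `subject_id` for the
#'   observations to predict.
#' @param ... Unused.
#' @return Tibble `measurement_id`, `prediction`.
#' @export
predict.pd_null_model <- function(object, new_labels, ...) {
  unseen <- setdiff(unique(new_labels$subject_id), object$means$subject_id)
  if (length(unseen) > 0) {
    abort(sprintf("no training labels for subject(s): %s",
                  paste(unseen, collapse = ", ")))
  }
  new_labels %>%
    distinct(.data$measurement_id, .data$subject_id) %>%
    left_join(object$means, by = "subject_id") %>%
    select("measurement_id", "prediction")
}

# Grouped k-fold assignment: all windows of one measurement share a fold.
grouped_folds <- function(measurement_id, k) {
  ids <- unique(measurement_id)
  fold_of <- setNames(rep_len(seq_len(k), length(ids)), sample(ids))
  unname(fold_of[measurement_id])
}

draw_hyperparams <- function(spec) {
  list(
    num.trees = resample(seq(spec$n_trees_range[1], spec$n_trees_range[2])),
    max.depth = resample(seq(spec$max_depth_range[1], spec$max_depth_range[2])),
    min.node.size = resample(seq(spec$min_node_range[1], spec$min_node_range[2]))
  )
}

fit_ranger <- function(x, y, hp, seed) {
  ranger::ranger(
    x = x, y = y,
    num.trees = hp$num.trees,
    max.depth = if (hp$max.depth == 0) NULL else hp$max.depth,
    min.node.size = hp$min.node.size,
    importance = "impurity",
    num.threads = 1,
    seed = seed
  )
}

# Random search over grouped CV; returns the fitted final model and the
# winning hyperparameters. Degenerate constant targets shortcut to a constant.
tune_and_fit <- function(x, y, groups, spec, seed) {
  if (length(unique(y)) == 1) {
    return(list(constant = y[1], hp = NULL))
  }
  n_candidates <- max(1L, spec$search_iterations)
  folds <- grouped_folds(groups, min(spec$cv_folds, length(unique(groups))))
  best <- NULL
  best_mse <- Inf
  for (i in seq_len(n_candidates)) {
    hp <- draw_hyperparams(spec)
    errs <- numeric(0)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (!any(tr) || !any(!tr)) next
      fit <- fit_ranger(x[tr, , drop = FALSE], y[tr], hp,
                        derive_seed(seed, i * 10 + f))
      pred <- predict(fit, x[!tr, , drop = FALSE], num.threads = 1)$predictions
      errs <- c(errs, (pred - y[!tr])^2)
    }
    mse <- mean(errs)
    if (is.finite(mse) && mse < best_mse) {
      best_mse <- mse
      best <- hp
    }
  }
  if (is.null(best)) best <- draw_hyperparams(spec)
  list(model = fit_ranger(x, y, best, derive_seed(seed, 1)), hp = best)
}

#' Fit per-subject severity models
#'
#' One regressor per subject on that subject's labelled windows (windows
#' inherit their observation's label). Hyperparameters are tuned per subject
#' by random search over CV grouped by `measurement_id`, so windows of one
#' observation never straddle folds; the final model is refit on all of the
#' subject's training windows. Subjects with a single label value get a
#' degenerate constant model (equivalent to the Null), with a message.
#'
#' @param design Window-level design tibble from [assemble_design_matrix()].
#' @param spec A [model_spec()] with `archetype = "per_subject"`.
#' @return A `pd_severity_model` holding one fit per subject.
#' @export
fit_per_subject <- function(design, spec) {
  stopifnot(inherits(spec, "model_spec"))
  symptom <- spec$symptom
  fcols <- feature_columns(design)
  design <- design %>% filter(!is.na(.data[[symptom]]))
  fits <- list()
  for (sid in sort(unique(design$subject_id))) {
    d <- design %>% filter(.data$subject_id == sid)
    y <- d[[symptom]]
    if (length(unique(y)) == 1) {
      inform(sprintf("subject %s has a single %s label value; constant model",
                     sid, symptom))
    }
    fits[[sid]] <- withr::with_seed(derive_seed(spec$seed, match(sid, sort(unique(design$subject_id)))), {
      tune_and_fit(as.matrix(d[fcols]), y, d$measurement_id, spec,
                   derive_seed(spec$seed, 1000 + match(sid, sort(unique(design$subject_id)))))
    })
  }
  structure(list(spec = spec, fits = fits, feature_cols = fcols,
                 null = fit_null(
                   distinct(design[, c("measurement_id", "subject_id", symptom)]),
                   symptom)),
            class = c("pd_per_subject_model", "pd_severity_model"))
}

#' Fit global (per-cohort) severity models
#'
#' One random-forest regressor per cohort over all subjects' windows,
#' expecting covariate columns in the design (the archetype's personalization
#' mechanism). Refuses cohorts with fewer than 2 subjects (a global model over
#' one subject is meaningless); with `allow_small_cohorts = TRUE` such cohorts
#' are skipped with a message and their observations fall back to the Null
#' prediction at predict time.
#'
#' @inheritParams fit_per_subject
#' @param allow_small_cohorts Skip (rather than refuse) cohorts with fewer
#'   than 2 subjects.
#' @return A `pd_severity_model` holding one fit per cohort.
#' @export
fit_global <- function(design, spec, allow_small_cohorts = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  symptom <- spec$symptom
  fcols <- feature_columns(design)
  design <- design %>% filter(!is.na(.data[[symptom]]))
  fits <- list()
  for (ch in sort(unique(design$cohort_id))) {
    d <- design %>% filter(.data$cohort_id == ch)
    if (length(unique(d$subject_id)) < 2) {
      if (allow_small_cohorts) {
        inform(sprintf("cohort %s has < 2 subjects; skipping its global model", ch))
        next
      }
      abort(sprintf("cohort %s has < 2 subjects; a global model is meaningless", ch))
    }
    fits[[ch]] <- withr::with_seed(derive_seed(spec$seed, match(ch, c("CIS", "REAL"))), {
      tune_and_fit(as.matrix(d[fcols]), d[[symptom]], d$measurement_id, spec,
                   derive_seed(spec$seed, 2000 + match(ch, c("CIS", "REAL"))))
    })
  }
  if (length(fits) == 0) abort("no cohort has >= 2 subjects; global model impossible")
  structure(list(spec = spec, fits = fits, feature_cols = fcols,
                 null = fit_null(
                   distinct(design[, c("measurement_id", "subject_id", symptom)]),
                   symptom)),
            class = c("pd_global_model", "pd_severity_model"))
}

predict_windows <- function(object, design) {
  fcols <- object$feature_cols
  key <- if (inherits(object, "pd_per_subject_model")) "subject_id" else "cohort_id"
  preds <- rep(NA_real_, nrow(design))
  for (k in names(object$fits)) {
    idx <- which(design[[key]] == k)
    if (length(idx) == 0) next
    fit <- object$fits[[k]]
    preds[idx] <- if (!is.null(fit$constant)) {
      fit$constant
    } else {
      predict(fit$model, as.matrix(design[idx, fcols, drop = FALSE]),
              num.threads = 1)$predictions
    }
  }
  preds
}

#' Predict observation-level severity
#'
#' Window predictions are aggregated per device stream (median for the
#' per-subject archetype, mean for the global archetype), multi-device
#' observations average their per-device predictions, and the result is
#' clipped to the symptom's harmonized label range. Observations with no
#' surviving windows fall back to the subject's Null prediction (with a
#' message).
#'
#' @param object A fitted `pd_severity_model`.
#' @param design Window-level design tibble for the observations to predict.
#' @param observations Optional tibble `measurement_id`, `subject_id`,
#'   `cohort_id` defining the complete requested prediction set (defaults to
#'   the observations present in `design`).
#' @param ... Unused.
#' @return Tibble `measurement_id`, `prediction` (complete and finite).
#' @export
predict.pd_severity_model <- function(object, design, observations = NULL, ...) {
  agg_fun <- if (object$spec$aggregation == "median") median else mean
  design$`.wpred` <- predict_windows(object, design)
  obs_pred <- design %>%
    filter(!is.na(.data$.wpred)) %>%
    group_by(.data$measurement_id, .data$device, .data$cohort_id) %>%
    summarise(dev_pred = agg_fun(.data$.wpred), .groups = "drop") %>%
    group_by(.data$measurement_id, .data$cohort_id) %>%
    summarise(prediction = mean(.data$dev_pred), .groups = "drop")
  if (is.null(observations)) {
    observations <- design %>%
      distinct(.data$measurement_id, .data$subject_id, .data$cohort_id)
  }
  out <- observations %>%
    distinct(.data$measurement_id, .data$subject_id, .data$cohort_id) %>%
    left_join(obs_pred %>% select("measurement_id", "prediction"),
              by = "measurement_id")
  if (anyNA(out$prediction)) {
    inform(sprintf("%d observation(s) had no surviving windows; using Null fallback",
                   sum(is.na(out$prediction))))
    fb <- predict(object$null, out %>% filter(is.na(.data$prediction)))
    out <- out %>%
      left_join(fb %>% rename(fallback = "prediction"), by = "measurement_id") %>%
      mutate(prediction = dplyr::coalesce(.data$prediction, .data$fallback)) %>%
      select(-"fallback")
  }
  out %>%
    rowwise_clip(object$spec$symptom) %>%
    select("measurement_id", "prediction")
}

rowwise_clip <- function(df, symptom) {
  rng <- vapply(df$cohort_id, function(ch) label_range(ch, symptom), integer(2))
  df$prediction <- clip(df$prediction, rng[1, ], rng[2, ])
  df
}

#' Feature importances of a fitted severity model
#'
#' Impurity (Gini-style) importances of the underlying tree ensembles,
#' averaged across the per-subject or per-cohort fits and normalized to sum
#' to 1. The Null model has no features and returns an empty table.
#'
#' @param model A fitted `pd_severity_model` or `pd_null_model`.
#' @return Tibble `feature`, `importance`, sorted decreasing.
#' @export
feature_importance <- function(model) {
  if (inherits(model, "pd_null_model")) {
    return(tibble(feature = character(), importance = numeric()))
  }
  imps <- purrr::map(model$fits, function(fit) {
    if (!is.null(fit$constant)) return(NULL)
    ranger::importance(fit$model)
  })
  imps <- purrr::compact(imps)
  if (length(imps) == 0) {
    return(tibble(feature = model$feature_cols,
                  importance = rep(1 / length(model$feature_cols),
                                   length(model$feature_cols))))
  }
  total <- Reduce(`+`, imps) / length(imps)
  total <- pmax(total, 0)
  total <- if (sum(total) > 0) total / sum(total) else
    rep(1 / length(total), length(total))
  tibble(feature = names(total), importance = unname(total)) %>%
    arrange(dplyr::desc(.data$importance))
}
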