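#' Per-subject MSE score table
#'
#' Joins a complete prediction set against the test truth and computes, per
#' subject, the observation count `n` and mean squared error `mse`. Missing
#' predictions are an error: every requested test observation must receive
#' exactly one finite prediction.
#'
#' @param predictions Tibble `measurement_id`, `prediction`.
#' @param truth Tibble `measurement_id`, `subject_id`, and the truth column.
#' @param symptom Name of the truth column in `truth`.
#' @return A `score_table`: tibble `subject_id`, `n`, `mse` with the weighted
#'   MSE as attribute `wmse` (see [weighted_mse()]).
#' @export
score_predictions <- function(predictions, truth, symptom) {
  truth <- truth %>% filter(!is.na(.data[[symptom]]))
  joined <- truth %>%
    left_join(predictions, by = "measurement_id")
  if (anyNA(joined$prediction) || any(!is.finite(joined$prediction))) {
    abort("missing or non-finite prediction(s); complete predictions are required")
  }
  tab <- joined %>%
    group_by(.data$subject_id) %>%
    summarise(n = n(),
              mse = mean((.data$prediction - .data[[symptom]])^2),
              .groups = "drop")
  structure(tab, class = c("score_table", class(tab)),
            wmse = weighted_mse(tab), symptom = symptom)
}

#' Square-root-weighted mean squared error
#'
#' `WMSE = sum_k sqrt(n_k) * MSE_k / sum_k sqrt(n_k)`: per-subject MSEs are
#' averaged with square-root-of-count weights, down-weighting subjects with
#' many test observations so a few data-rich subjects cannot dominate the
#' benchmark.
#'
#' @param score_table Tibble with columns `n` and `mse` (one row per subject).
#' @return The weighted MSE (scalar).
#' @export
#' @examples
#' weighted_mse(tibble::tibble(n = c(99, 11), mse = c(1, 0))) # 0.75
weighted_mse <- function(score_table) {
  if (nrow(score_table) == 0) abort("empty score table")
  if (any(score_table$n < 1)) abort("subject counts must be >= 1")
  w <- sqrt(score_table$n)
  sum(w * score_table$mse) / sum(w)
}

#' Paired bootstrap of weighted MSE across prediction sets
#'
#' For each of `B` iterations, every subject's test observations are resampled
#' with replacement keeping the same within-subject count, and the *same*
#' resampled index multiset is applied to every model (including the Null),
#' so per-iteration scores are paired. WMSE is recomputed per model per
#' iteration.
#'
#' @param prediction_sets Named list of prediction tibbles
#'   (`measurement_id`, `prediction`); must include one named `"null"`.
#' @param truth Tibble `measurement_id`, `subject_id`, truth column.
#' @param symptom Truth column name.
#' @param B Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return A `bootstrap_result`: list with `wmse` (named point estimates),
#'   `boot` (B x models matrix of bootstrap WMSEs), `B`, `seed`.
#' @export
bootstrap_scores <- function(prediction_sets, truth, symptom, B = 1000,
                             seed = 1L) {
  if (B < 1) abort("B must be >= 1")
  if (is.null(names(prediction_sets)) || any(names(prediction_sets) == "")) {
    abort("`prediction_sets` must be a named list")
  }
  truth <- truth %>% filter(!is.na(.data[[symptom]])) %>%
    arrange(.data$subject_id, .data$measurement_id)
  models <- names(prediction_sets)
  # observation-by-model squared-error matrix, aligned to `truth`
  err <- vapply(models, function(m) {
    p <- truth %>%
      left_join(prediction_sets[[m]], by = "measurement_id")
    if (anyNA(p$prediction)) {
      abort(sprintf("model '%s' is missing predictions", m))
    }
    (p$prediction - p[[symptom]])^2
  }, numeric(nrow(truth)))
  err <- matrix(err, nrow = nrow(truth),
                dimnames = list(NULL, models))
  subj <- truth$subject_id
  subjects <- unique(subj)
  point <- apply(err, 2, function(e) {
    weighted_mse(tibble(n = as.integer(table(subj)[subjects]),
                        mse = tapply(e, subj, mean)[subjects]))
  })
  boot_mse <- withr::with_seed(as.integer(seed), {
    num <- matrix(0, B, length(models), dimnames = list(NULL, models))
    den <- 0
    for (k in subjects) {
      idx <- which(subj == k)
      n_k <- length(idx)
      w <- sqrt(n_k)
      den <- den + w
      resamp <- matrix(sample.int(n_k, B * n_k, replace = TRUE), nrow = B)
      for (m in models) {
        e_k <- err[idx, m]
        num[, m] <- num[, m] + w * rowMeans(matrix(e_k[resamp], nrow = B))
      }
    }
    num / den
  })
  structure(list(wmse = point, boot = boot_mse, B = B, seed = as.integer(seed),
                 symptom = symptom),
            class = "bootstrap_result")
}

#' Bootstrap p-value of a model versus the Null
#'
#' The proportion of bootstrap iterations in which the Null model outperformed
#' the model. Iterations where the two scores tie count one half by default
#' (under a strict reading a submission identical to the Null would score
#' p = 0, which is pathological); set `ties = "strict"` to count ties as wins
#' for the submission.
#'
#' @param result A [bootstrap_scores()] result containing both the model and
#'   `"null"`.
#' @param model Model name.
#' @param ties `"half"` (default) or `"strict"`.
#' @return p-value in `[0, 1]`.
#' @export
pvalue_vs_null <- function(result, model, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  stopifnot(inherits(result, "bootstrap_result"))
  if (!model %in% colnames(result$boot)) {
    abort(sprintf("model '%s' not present in bootstrap result", model))
  }
  if (!"null" %in% colnames(result$boot)) {
    abort("bootstrap result does not contain the null model")
  }
  d_null <- result$boot[, "null"]
  d_model <- result$boot[, model]
  wins <- sum(d_null < d_model)
  tie_n <- sum(d_null == d_model)
  if (ties == "half") (wins + 0.5 * tie_n) / result$B else wins / result$B
}

#' Distinguishability of two models
#'
#' One-sided Wilcoxon signed-rank test on the paired per-iteration bootstrap
#' WMSEs, testing whether model A's scores are systematically lower (better)
#' than model B's. Zero differences are dropped (standard practice); if every
#' difference is zero the models are identical and p = 1 by convention.
#'
#' @param result A [bootstrap_scores()] result.
#' @param model_a,model_b Model names.
#' @return One-sided p-value.
#' @export
distinguishability <- function(result, model_a, model_b) {
  stopifnot(inherits(result, "bootstrap_result"))
  a <- result$boot[, model_a]
  b <- result$boot[, model_b]
  d <- a - b
  if (all(d == 0)) {
    inform("all bootstrap score differences are zero; returning p = 1")
    return(1)
  }
  suppressWarnings(
    wilcox.test(a, b, paired = TRUE, alternative = "less", exact = FALSE)$p.value
  )
}

#' Rank prediction sets against the Null model
#'
#' Scores every prediction set, bootstraps them jointly ([bootstrap_scores()]),
#' and reports WMSE, bootstrap p versus Null, rank, and the two flags the
#' benchmark tracks separately: strictly better than Null, and significantly
#' better at the nominal level. Ties in WMSE are broken lexicographically by
#' submission id; the Null row carries `NA` for its own p-value.
#'
#' @inheritParams bootstrap_scores
#' @param alpha Nominal significance level (default 0.05).
#' @return A `leaderboard` tibble, with the `bootstrap_result` in attribute
#'   `"bootstrap"`.
#' @export
leaderboard <- function(prediction_sets, truth, symptom, B = 1000, seed = 1L,
                        alpha = 0.05) {
  if (!"null" %in% names(prediction_sets)) {
    abort("`prediction_sets` must include a 'null' entry")
  }
  bs <- bootstrap_scores(prediction_sets, truth, symptom, B = B, seed = seed)
  tab <- tibble(
    submission = names(prediction_sets),
    wmse = unname(bs$wmse[names(prediction_sets)])
  ) %>%
    mutate(
      p_vs_null = purrr::map_dbl(.data$submission, function(m) {
        if (m == "null") NA_real_ else pvalue_vs_null(bs, m)
      }),
      beats_null = .data$wmse < bs$wmse[["null"]],
      significant = !is.na(.data$p_vs_null) & .data$p_vs_null < alpha
    ) %>%
    arrange(.data$wmse, .data$submission) %>%
    mutate(rank = row_number())
  structure(tab, class = c("leaderboard", class(tab)), bootstrap = bs)
}
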