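#' Tidy a score table
#'
#' @param x A `score_table` from [score_predictions()].
#' @param ... Unused.
#' @return Tibble `subject_id`, `n`, `mse`, `weight` (normalized sqrt-n).
#' @export
tidy.score_table <- function(x, ...) {
  as_tibble(x) %>%
    mutate(weight = sqrt(.data$n) / sum(sqrt(.data$n)))
}

#' @rdname tidy.score_table
#' @export
glance.score_table <- function(x, ...) {
  tibble(wmse = attr(x, "wmse"), n_subjects = nrow(x),
         n_observations = sum(x$n), symptom = attr(x, "symptom"))
}

#' Tidy a bootstrap result
#'
#' @param x A `bootstrap_result` from [bootstrap_scores()].
#' @param ... Unused.
#' @return Long tibble `model`, `iteration`, `wmse`.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  as_tibble(x$boot) %>%
    mutate(iteration = row_number()) %>%
    tidyr::pivot_longer(-"iteration", names_to = "model", values_to = "wmse")
}

#' @rdname tidy.bootstrap_result
#' @export
glance.bootstrap_result <- function(x, ...) {
  tibble(B = x$B, seed = x$seed, n_models = ncol(x$boot),
         symptom = x$symptom)
}

#' Tidy a clinical validation result
#'
#' @param x A `clinical_validation`.
#' @param ... Unused.
#' @return The per-subject correlation table.
#' @export
tidy.clinical_validation <- function(x, ...) x$per_subject

#' @rdname tidy.clinical_validation
#' @export
glance.clinical_validation <- function(x, ...) {
  tibble(statistic = x$combined$statistic, df = x$combined$df,
         p_value = x$combined$p_value, n_subjects = nrow(x$per_subject))
}

#' Tidy an ensemble report
#'
#' @param x An `ensemble_report` from [select_and_finalize()].
#' @param ... Unused.
#' @return The candidate evaluation table with winner flags.
#' @export
tidy.ensemble_report <- function(x, ...) {
  x$evaluation %>%
    mutate(winner = .data$candidate %in% c(x$unsupervised, x$supervised))
}

#' Box plot of bootstrap score distributions
#'
#' Mirrors the benchmark's model-comparison display: one box per model over
#' the paired bootstrap WMSE distributions, ordered by point WMSE, with the
#' Null model highlighted.
#'
#' @param object A `bootstrap_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(model = factor(.data$model,
                          levels = names(sort(object$wmse))),
           is_null = .data$model == "null")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$wmse,
                                   fill = .data$is_null)) +
    ggplot2::geom_boxplot(show.legend = FALSE, outlier.size = 0.4) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey35", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "bootstrap weighted MSE",
                  title = sprintf("Bootstrap scores (%s, B = %d)",
                                  object$symptom %||% "", object$B)) +
    ggplot2::theme_minimal()
}

#' Per-subject lift plot
#'
#' Bars of per-subject lift (Null MSE minus model MSE) with bootstrap
#' percentile intervals when present; positive bars indicate subjects the
#' model predicts better than the subject-mean baseline.
#'
#' @param lift_tbl Output of [compute_lift()] or [bootstrap_lift()] (optionally
#'   with a `model` column for faceting).
#' @return A ggplot object.
#' @export
plot_lift <- function(lift_tbl) {
  p <- ggplot2::ggplot(lift_tbl,
                       ggplot2::aes(x = stats::reorder(.data$subject_id,
                                                       .data$lift),
                                    y = .data$lift)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "subject", y = "lift (Null MSE - model MSE)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (all(c("boot_lo", "boot_hi") %in% names(lift_tbl))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$boot_lo, ymax = .data$boot_hi), width = 0.3)
  }
  if ("model" %in% names(lift_tbl)) {
    p <- p + ggplot2::facet_wrap(~model)
  }
  p
}

#' Feature-importance plot
#'
#' @param importance_tbl Output of [feature_importance()].
#' @param top_n Number of features shown (default 15).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance_tbl, top_n = 15) {
  df <- importance_tbl %>% slice(seq_len(min(top_n, nrow(importance_tbl))))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature,
                                                      .data$importance),
                                   y = .data$importance)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized impurity importance") +
    ggplot2::theme_minimal()
}
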