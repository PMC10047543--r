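#' Subject-level lift over the Null model
#'
#' `Lift = MSE_Null - MSE_model` per subject: positive lift means the model
#' beats the subject-mean baseline for that subject. The percent lift is
#' `Lift / MSE_Null` (reported missing when `MSE_Null = 0`).
#'
#' @param model_scores,null_scores `score_table`s ([score_predictions()])
#'   computed on identical test observations.
#' @return Tibble `subject_id`, `n`, `mse_model`, `mse_null`, `lift`,
#'   `lift_percent`.
#' @export
compute_lift <- function(model_scores, null_scores) {
  joined <- model_scores %>%
    rename(mse_model = "mse") %>%
    inner_join(null_scores %>% select("subject_id", mse_null = "mse"),
               by = "subject_id")
  if (nrow(joined) != nrow(model_scores)) {
    abort("model and Null score tables cover different subjects")
  }
  joined %>%
    mutate(lift = .data$mse_null - .data$mse_model,
           lift_percent = ifelse(.data$mse_null > 0,
                                 100 * .data$lift / .data$mse_null, NA_real_))
}

#' Bootstrap distribution of per-subject lift
#'
#' Resamples each subject's test observations with replacement (the same
#' indices for model and Null, keeping the pairing) `B` times and recomputes
#' the lift. A subject's lift is flagged significant when the 2.5th
#' percentile of its bootstrap distribution is above 0.
#'
#' @param predictions,null_predictions Prediction tibbles
#'   (`measurement_id`, `prediction`).
#' @param truth Tibble `measurement_id`, `subject_id`, truth column.
#' @param symptom Truth column name.
#' @param B Bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @return Tibble `subject_id`, `lift`, `boot_mean`, `boot_lo` (2.5th pct),
#'   `boot_hi` (97.5th pct), `significant`.
#' @export
bootstrap_lift <- function(predictions, null_predictions, truth, symptom,
                           B = 100, seed = 1L) {
  truth <- truth %>% filter(!is.na(.data[[symptom]])) %>%
    arrange(.data$subject_id, .data$measurement_id)
  err <- function(p) {
    j <- truth %>% left_join(p, by = "measurement_id")
    if (anyNA(j$prediction)) abort("incomplete predictions")
    (j$prediction - j[[symptom]])^2
  }
  e_model <- err(predictions)
  e_null <- err(null_predictions)
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(unique(truth$subject_id), function(k) {
      idx <- which(truth$subject_id == k)
      n_k <- length(idx)
      resamp <- matrix(sample.int(n_k, B * n_k, replace = TRUE), nrow = B)
      lifts <- rowMeans(matrix(e_null[idx][resamp], nrow = B)) -
        rowMeans(matrix(e_model[idx][resamp], nrow = B))
      qs <- quantile(lifts, c(0.025, 0.975), names = FALSE)
      tibble(subject_id = k,
             lift = mean(e_null[idx]) - mean(e_model[idx]),
             boot_mean = mean(lifts), boot_lo = qs[1], boot_hi = qs[2],
             significant = qs[1] > 0)
    })
  })
}

#' Kendall rank correlation (tau-b) with p-value
#'
#' Tie-corrected tau-b via [stats::cor.test()], two-sided p. Constant inputs
#' give a missing tau.
#'
#' @param x,y Paired numeric vectors (>= 3 pairs).
#' @return List with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(tau = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Convert Kendall's tau to Pearson's r
#'
#' Greiner's relation `r = sin(pi * tau / 2)`, the standard mapping for
#' bivariate-normal data; odd and monotone on `[-1, 1]`.
#'
#' @param tau Kendall's tau in `[-1, 1]`.
#' @return Pearson correlation.
#' @export
#' @examples
#' tau_to_r(0.5) # sin(pi/4)
tau_to_r <- function(tau) {
  if (any(abs(tau) > 1, na.rm = TRUE)) abort("|tau| must be <= 1")
  sin(pi * tau / 2)
}

#' Fixed-effect meta-analysis of correlations
#'
#' Correlations are Fisher z-transformed (`z = atanh(r)`), weighted by
#' `w = n - 3`, pooled as `sum(w z) / sum(w)` with `SE = 1 / sqrt(sum(w))`,
#' and the two-sided p comes from the normal; the pooled correlation is
#' `tanh` of the pooled z.
#'
#' @param r Correlations (each strictly inside (-1, 1); |r| = 1 has infinite
#'   z and is an error — shrink such values by a small epsilon first).
#' @param n Sample sizes (all >= 4).
#' @return List with `r_pooled`, `z_pooled`, `se`, `p_value`, `k`.
#' @export
fixed_effect_meta <- function(r, n) {
  ok <- !is.na(r)
  r <- r[ok]; n <- n[ok]
  if (length(r) == 0) abort("no correlations to pool")
  if (any(abs(r) >= 1)) {
    abort("|r| = 1 gives infinite z; shrink boundary correlations by epsilon")
  }
  if (any(n < 4)) abort("all sample sizes must be >= 4")
  z <- atanh(r)
  w <- n - 3
  z_pooled <- sum(w * z) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(r_pooled = tanh(z_pooled), z_pooled = z_pooled, se = se,
       p_value = 2 * pnorm(-abs(z_pooled / se)), k = length(r))
}

#' Fisher's combined probability
#'
#' `X^2 = -2 * sum(log(p_i))` on `2m` degrees of freedom; the combined p is
#' the chi-square upper tail.
#'
#' @param p Vector of p-values in (0, 1].
#' @return List with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' fisher_combine(c(0.05, 0.05)) # X^2 ~ 11.98, p ~ 0.0175
fisher_combine <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) abort("no p-values to combine")
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p))
  df <- 2 * length(p)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Validate model predictions against clinician ratings
#'
#' On short clinician-rated task segments, accuracy is evaluated
#' within-subject by Pearson correlation between the model's predictions and
#' the clinician's severity ratings, with a one-sided p (alternative:
#' correlation > 0); per-subject p-values are then combined across subjects
#' with Fisher's log-p method. Subjects with fewer than `min_segments` rated
#' segments or zero-variance ratings are excluded (with a message). For the
#' medication on/off target the caller should supply the overall-severity
#' rating as the comparison column, since clinicians do not rate on/off
#' directly.
#'
#' @param data Tibble with columns `subject_id`, `prediction`, `rating`.
#' @param min_segments Minimum rated segments per subject (default 3).
#' @return A `clinical_validation`: list with `per_subject` tibble
#'   (`subject_id`, `n`, `r`, `p_value`) and `combined` (Fisher statistic,
#'   df, combined p).
#' @export
clinical_validation <- function(data, min_segments = 3) {
  stopifnot(all(c("subject_id", "prediction", "rating") %in% names(data)))
  per_subject <- data %>%
    group_by(.data$subject_id) %>%
    summarise(n = n(), sd_rating = sd(.data$rating),
              sd_pred = sd(.data$prediction), .groups = "drop")
  excluded <- per_subject %>%
    filter(.data$n < min_segments | .data$sd_rating == 0 | .data$sd_pred == 0)
  if (nrow(excluded) > 0) {
    inform(sprintf("excluding %d subject(s) with too few segments or zero-variance ratings",
                   nrow(excluded)))
  }
  keep <- setdiff(per_subject$subject_id, excluded$subject_id)
  res <- data %>%
    filter(.data$subject_id %in% keep) %>%
    group_by(.data$subject_id) %>%
    dplyr::group_modify(function(d, key) {
      ct <- cor.test(d$prediction, d$rating, alternative = "greater")
      tibble(n = nrow(d), r = unname(ct$estimate), p_value = ct$p.value)
    }) %>%
    ungroup()
  if (nrow(res) == 0) abort("no subjects left after exclusions")
  # a perfect correlation yields an exact-zero one-sided p whose log is
  # infinite; clamp at the smallest positive double before combining
  p_clamped <- pmax(res$p_value, .Machine$double.xmin)
  structure(list(per_subject = res, combined = fisher_combine(p_clamped)),
            class = "clinical_validation")
}

#' Covariate associations with subject-level lift
#'
#' For every model and covariate, the Kendall tau-b correlation between
#' per-subject lift and the covariate with its two-sided p; the per-model
#' taus for a covariate are then converted to Pearson r (Greiner) and pooled
#' across models by fixed-effect meta-analysis. Constant covariates are
#' skipped.
#'
#' @param lift_tbl Tibble `subject_id`, `model`, `lift`.
#' @param covariates Tibble `subject_id` plus numeric covariate columns (e.g.
#'   label variance, n, reporting lag, age, UPDRS part totals).
#' @return List with `per_model` tibble (`model`, `covariate`, `tau`,
#'   `p_value`, `n`) and `pooled` tibble (`covariate`, `r_pooled`,
#'   `p_value`, `k`).
#' @export
covariate_association_suite <- function(lift_tbl, covariates) {
  cov_cols <- setdiff(names(covariates), "subject_id")
  cov_cols <- cov_cols[vapply(covariates[cov_cols], is.numeric, TRUE)]
  cov_cols <- cov_cols[vapply(cov_cols, function(cl)
    sd(covariates[[cl]], na.rm = TRUE) > 0, TRUE)]
  if (length(cov_cols) == 0) {
    return(list(per_model = tibble(model = character(), covariate = character(),
                                   tau = numeric(), p_value = numeric(),
                                   n = integer()),
                pooled = tibble(covariate = character(), r_pooled = numeric(),
                                p_value = numeric(), k = integer())))
  }
  per_model <- tidyr::expand_grid(model = unique(lift_tbl$model),
                                  covariate = cov_cols) %>%
    purrr::pmap_dfr(function(model, covariate) {
      d <- lift_tbl %>% filter(.data$model == !!model) %>%
        inner_join(covariates %>% select("subject_id", all_of(covariate)),
                   by = "subject_id")
      kt <- kendall_tau(d$lift, d[[covariate]])
      tibble(model = model, covariate = covariate, tau = kt$tau,
             p_value = kt$p_value, n = kt$n)
    })
  poolable <- per_model %>%
    filter(!is.na(.data$tau), .data$n >= 4)
  pooled <- if (nrow(poolable) == 0) {
    tibble(covariate = character(), r_pooled = numeric(),
           p_value = numeric(), k = integer())
  } else {
    poolable %>%
      group_by(.data$covariate) %>%
      dplyr::group_modify(function(d, key) {
        r <- clip(tau_to_r(d$tau), -0.9999, 0.9999)
        fm <- fixed_effect_meta(r, d$n)
        tibble(r_pooled = fm$r_pooled, p_value = fm$p_value, k = fm$k)
      }) %>%
      ungroup()
  }
  list(per_model = per_model, pooled = pooled)
}
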