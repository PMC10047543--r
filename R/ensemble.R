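#' Nested cross-validation fold plan
#'
#' Assigns every training observation to one of `k` folds, stratified within
#' subject on the joint label tuple. The convention downstream is that folds
#' `1..k-1` form the inner cross-validation used to generate out-of-fold base
#' predictions and tune ensembles, while fold `k` is the untouched evaluation
#' fold used only to pick the final ensemble per class.
#'
#' @param labels Harmonized training labels (`measurement_id`, `subject_id`,
#'   symptom columns).
#' @param k Number of folds (default 6: 5 inner + 1 evaluation).
#' @param seed Integer seed.
#' @return Tibble `measurement_id`, `subject_id`, `fold`.
#' @export
nested_cv <- function(labels, k = 6, seed = 1L) {
  small <- labels %>% count(.data$subject_id) %>% filter(.data$n < k)
  if (nrow(small) > 0) {
    abort(sprintf(
      "subject(s) %s have fewer than k = %d observations; reduce k",
      paste(small$subject_id, collapse = ", "), k))
  }
  sym_cols <- intersect(SYMPTOMS, names(labels))
  stratum <- do.call(paste, c(
    list(labels$subject_id),
    lapply(sym_cols, function(s) tidyr::replace_na(as.character(labels[[s]]), "NA")),
    sep = "|"
  ))
  withr::with_seed(as.integer(seed), {
    # round-robin over stratum-sorted observations: per-subject fold sizes
    # balanced to +/- 1 while each stratum spreads over distinct folds
    labels %>%
      mutate(.stratum = stratum) %>%
      arrange(.data$subject_id, .data$.stratum, .data$measurement_id) %>%
      group_by(.data$subject_id) %>%
      mutate(fold = sample.int(k)[rep_len(seq_len(k), n())]) %>%
      ungroup() %>%
      select("measurement_id", "subject_id", "fold")
  })
}

base_model_columns <- function(matrix_tbl) {
  setdiff(names(matrix_tbl),
          c("measurement_id", "subject_id", "cohort_id", "truth", "fold"))
}

#' Unsupervised ensemble aggregation
#'
#' Row-wise mean or median of the base predictions; permutation-invariant in
#' base-model order and idempotent on identical columns.
#'
#' @param matrix_tbl Base-prediction tibble: `measurement_id`, `subject_id`,
#'   `truth`, one column per base model (optionally `fold`).
#' @param method `"mean"` or `"median"`.
#' @return Tibble `measurement_id`, `prediction`.
#' @export
aggregate_unsupervised <- function(matrix_tbl, method = c("mean", "median")) {
  method <- match.arg(method)
  bases <- base_model_columns(matrix_tbl)
  if (length(bases) == 0) abort("no base model columns")
  m <- as.matrix(matrix_tbl[bases])
  fun <- if (method == "mean") rowMeans else function(x) apply(x, 1, median)
  tibble(measurement_id = matrix_tbl$measurement_id,
         prediction = as.numeric(fun(m)))
}

meta_learner_families <- function() {
  c("linear", "lasso", "ridge", "random_forest", "boosted_trees")
}

fit_meta_learner <- function(family, x, y, foldid, seed) {
  n_lam <- 30
  switch(family,
    linear = {
      df <- as.data.frame(x)
      qrx <- qr(cbind(1, as.matrix(df)))
      if (qrx$rank < ncol(x) + 1) {
        inform("singular design for unregularized linear meta-learner; skipped")
        return(NULL)
      }
      fit <- stats::lm(y ~ ., data = cbind(y = y, df))
      list(kind = "lm", fit = fit)
    },
    lasso = ,
    ridge = {
      alpha <- if (family == "lasso") 1 else 0
      fit <- glmnet::cv.glmnet(as.matrix(x), y, alpha = alpha, foldid = foldid,
                               nlambda = n_lam)
      list(kind = "glmnet", fit = fit)
    },
    random_forest = {
      # a stacking meta-learner should be strongly regularized: few inputs,
      # noisy out-of-fold targets
      fit <- ranger::ranger(x = as.matrix(x), y = y, num.trees = 300,
                            max.depth = 3, min.node.size = 20,
                            num.threads = 1, seed = seed)
      list(kind = "ranger", fit = fit)
    },
    boosted_trees = {
      fit <- xgboost::xgboost(
        x = as.matrix(x), y = y, nrounds = 50, max_depth = 2,
        learning_rate = 0.1, subsample = 0.8, reg_lambda = 5,
        nthreads = 1, verbosity = 0,
        objective = "reg:squarederror", seed = seed
      )
      list(kind = "xgboost", fit = fit)
    },
    abort(sprintf("unknown meta-learner family '%s'", family))
  )
}

predict_meta_learner <- function(obj, x) {
  switch(obj$kind,
    lm = as.numeric(predict(obj$fit, as.data.frame(x))),
    glmnet = as.numeric(predict(obj$fit, as.matrix(x), s = "lambda.min")),
    ranger = predict(obj$fit, as.matrix(x), num.threads = 1)$predictions,
    xgboost = as.numeric(predict(obj$fit, as.matrix(x)))
  )
}

#' Fit stacking ensembles over base predictions
#'
#' Learns meta-predictors over the out-of-fold base predictions. Each
#' meta-learner family in `families` is fitted (unregularized linear, L1 and
#' L2 linear with inner-CV-selected regularization, random forest, gradient
#' boosted trees), under one of three input variants: `"raw"` predictions,
#' `"z_scored"` per-base standardization (invariant to affine rescaling of
#' any base column), or `"per_subject"` separate meta-models per subject with
#' a pooled fallback for subjects with fewer than `min_subject_n`
#' observations.
#'
#' @param matrix_tbl Base-prediction tibble including `truth`, `subject_id`,
#'   and `fold` (inner folds only; never pass the evaluation fold).
#' @param variant `"raw"`, `"z_scored"`, or `"per_subject"`.
#' @param families Character vector of meta-learner families.
#' @param min_subject_n Minimum per-subject observations for a subject-level
#'   meta-model (default 10).
#' @param seed Integer seed.
#' @return Named list of `stacking_ensemble` objects (one per family that
#'   could be fitted).
#' @export
fit_stacking <- function(matrix_tbl,
                         variant = c("raw", "z_scored", "per_subject"),
                         families = meta_learner_families(),
                         min_subject_n = 10, seed = 1L) {
  variant <- match.arg(variant)
  bases <- base_model_columns(matrix_tbl)
  y <- matrix_tbl$truth
  x <- as.matrix(matrix_tbl[bases])
  scale_info <- NULL
  if (variant == "z_scored") {
    mu <- colMeans(x)
    sig <- apply(x, 2, sd)
    sig[sig == 0] <- 1
    scale_info <- list(mu = mu, sig = sig)
    x <- sweep(sweep(x, 2, mu), 2, sig, "/")
  }
  foldid <- if ("fold" %in% names(matrix_tbl)) {
    as.integer(factor(matrix_tbl$fold))
  } else {
    rep_len(1:5, nrow(matrix_tbl))
  }
  out <- list()
  for (fam in families) {
    fam_seed <- derive_seed(seed, match(fam, meta_learner_families()))
    obj <- withr::with_seed(fam_seed, {
      if (variant == "per_subject") {
        subj_fits <- list()
        pooled <- fit_meta_learner(fam, x, y, foldid, fam_seed)
        for (sid in unique(matrix_tbl$subject_id)) {
          idx <- which(matrix_tbl$subject_id == sid)
          if (length(idx) >= min_subject_n) {
            f <- fit_meta_learner(fam, x[idx, , drop = FALSE], y[idx],
                                  as.integer(factor(foldid[idx])), fam_seed)
            if (!is.null(f)) subj_fits[[sid]] <- f
          }
        }
        if (is.null(pooled)) NULL else list(pooled = pooled, subjects = subj_fits)
      } else {
        f <- fit_meta_learner(fam, x, y, foldid, fam_seed)
        if (is.null(f)) NULL else list(pooled = f, subjects = list())
      }
    })
    if (!is.null(obj)) {
      out[[fam]] <- structure(
        list(family = fam, variant = variant, bases = bases,
             scale_info = scale_info, fits = obj),
        class = "stacking_ensemble"
      )
    }
  }
  out
}

#' @export
predict.stacking_ensemble <- function(object, matrix_tbl, ...) {
  x <- as.matrix(matrix_tbl[object$bases])
  if (!is.null(object$scale_info)) {
    x <- sweep(sweep(x, 2, object$scale_info$mu), 2, object$scale_info$sig, "/")
  }
  pred <- predict_meta_learner(object$fits$pooled, x)
  if (length(object$fits$subjects) > 0) {
    for (sid in names(object$fits$subjects)) {
      idx <- which(matrix_tbl$subject_id == sid)
      if (length(idx) > 0) {
        pred[idx] <- predict_meta_learner(object$fits$subjects[[sid]],
                                          x[idx, , drop = FALSE])
      }
    }
  }
  tibble(measurement_id = matrix_tbl$measurement_id,
         prediction = as.numeric(pred))
}

matrix_wmse <- function(matrix_tbl, pred) {
  tab <- tibble(subject_id = matrix_tbl$subject_id,
                err = (pred - matrix_tbl$truth)^2) %>%
    group_by(.data$subject_id) %>%
    summarise(n = n(), mse = mean(.data$err), .groups = "drop")
  weighted_mse(tab)
}

#' Greedy forward ensemble selection (with replacement)
#'
#' Starts from the single best base model by weighted MSE, then repeatedly
#' adds the base model (repeats allowed) that minimizes the WMSE of the
#' running mean of selected members, stopping when no addition strictly
#' improves the score. The greedy guarantee means the selection's WMSE never
#' exceeds the best single base's on the selection data.
#'
#' @param matrix_tbl Base-prediction tibble with `truth` and `subject_id`.
#' @param max_iter Cap on selection steps (default 50).
#' @return A `ces_ensemble`: list with `members` (selected multiset of base
#'   names), `wmse`, and `predictions` on the selection data.
#' @export
ces_select <- function(matrix_tbl, max_iter = 50) {
  bases <- base_model_columns(matrix_tbl)
  x <- as.matrix(matrix_tbl[bases])
  scores <- vapply(bases, function(b) matrix_wmse(matrix_tbl, x[, b]), 0)
  members <- names(which.min(scores))
  current_sum <- x[, members]
  current_score <- min(scores)
  for (i in seq_len(max_iter)) {
    cand <- vapply(bases, function(b) {
      matrix_wmse(matrix_tbl, (current_sum + x[, b]) / (length(members) + 1))
    }, 0)
    if (min(cand) < current_score) {
      pick <- names(which.min(cand))
      members <- c(members, pick)
      current_sum <- current_sum + x[, pick]
      current_score <- min(cand)
    } else {
      break
    }
  }
  structure(list(members = members, wmse = current_score, bases = bases,
                 predictions = tibble(
                   measurement_id = matrix_tbl$measurement_id,
                   prediction = as.numeric(current_sum / length(members)))),
            class = "ces_ensemble")
}

#' @export
predict.ces_ensemble <- function(object, matrix_tbl, ...) {
  x <- as.matrix(matrix_tbl[object$bases])
  counts <- table(object$members)
  w <- setNames(rep(0, length(object$bases)), object$bases)
  w[names(counts)] <- as.numeric(counts)
  w <- w / sum(w)
  tibble(measurement_id = matrix_tbl$measurement_id,
         prediction = as.numeric(x %*% w))
}

#' Exhaustive regularized-subset linear ensemble
#'
#' Enumerates every non-empty subset of base models (up to 12 bases); for each
#' subset an L2-regularized linear combination is fitted on a `learn_fraction`
#' split of the rows and scored on the remainder; the best subset and weights
#' win. This is a transparent exhaustive-search stand-in for sequential
#' ensemble-search procedures whose reported optimum is a full-set
#' L2-regularized linear blend — at this scale the brute force *is* the
#' search.
#'
#' @param matrix_tbl Base-prediction tibble with `truth` and `subject_id`.
#' @param learn_fraction Fraction of rows used to fit each candidate
#'   (default 0.8).
#' @param lambda Ridge penalty grid searched per subset.
#' @param seed Integer seed for the learn/score split.
#' @return A `subset_linear_ensemble`: list with `subset`, `coefficients`
#'   (incl. intercept), `holdout_wmse`, `n_subsets`.
#' @export
subset_linear_select <- function(matrix_tbl, learn_fraction = 0.8,
                                 lambda = c(0.001, 0.01, 0.1, 1), seed = 1L) {
  bases <- base_model_columns(matrix_tbl)
  if (length(bases) > 12) {
    abort("more than 12 base models: use ces_select() or fit_stacking()")
  }
  x <- as.matrix(matrix_tbl[bases])
  y <- matrix_tbl$truth
  n <- nrow(x)
  withr::with_seed(as.integer(seed), {
    learn_idx <- sort(sample.int(n, round(learn_fraction * n)))
  })
  score_idx <- setdiff(seq_len(n), learn_idx)
  ridge_fit <- function(xm, yv, lam) {
    # closed-form ridge with unpenalized intercept
    xm1 <- cbind(1, xm)
    p <- ncol(xm1)
    pen <- diag(lam, p)
    pen[1, 1] <- 0
    solve(crossprod(xm1) + pen, crossprod(xm1, yv))
  }
  best <- NULL
  n_subsets <- 0L
  for (bits in seq_len(2^length(bases) - 1)) {
    sel <- bases[bitwAnd(bits, 2^(seq_along(bases) - 1)) > 0]
    n_subsets <- n_subsets + 1L
    for (lam in lambda) {
      beta <- ridge_fit(x[learn_idx, sel, drop = FALSE], y[learn_idx], lam)
      pred <- cbind(1, x[score_idx, sel, drop = FALSE]) %*% beta
      sc <- matrix_wmse(matrix_tbl[score_idx, ], as.numeric(pred))
      if (is.null(best) || sc < best$holdout_wmse) {
        best <- list(subset = sel, lambda = lam,
                     coefficients = setNames(as.numeric(beta),
                                             c("(intercept)", sel)),
                     holdout_wmse = sc)
      }
    }
  }
  # final weights refit on all rows with the winning subset and penalty
  beta <- ridge_fit(x[, best$subset, drop = FALSE], y, best$lambda)
  structure(list(subset = best$subset, lambda = best$lambda,
                 coefficients = setNames(as.numeric(beta),
                                         c("(intercept)", best$subset)),
                 holdout_wmse = best$holdout_wmse, n_subsets = n_subsets),
            class = "subset_linear_ensemble")
}

#' @export
predict.subset_linear_ensemble <- function(object, matrix_tbl, ...) {
  x <- cbind(1, as.matrix(matrix_tbl[object$subset]))
  tibble(measurement_id = matrix_tbl$measurement_id,
         prediction = as.numeric(x %*% object$coefficients))
}

#' Select and finalize one unsupervised and one supervised ensemble
#'
#' Candidates (mean/median aggregation; stacking variants; greedy selection;
#' exhaustive subset-linear) are fitted on the inner folds of `matrix_tbl`
#' (`fold < k`) and scored on the untouched evaluation fold (`fold == k`).
#' The per-class evaluation-fold WMSE argmin wins; winners are then refit on
#' the full training matrix and, if `test_matrix` is supplied, produce test
#' predictions.
#'
#' @param matrix_tbl Base-prediction tibble with `truth`, `subject_id`,
#'   `fold`.
#' @param test_matrix Optional base-prediction tibble for the test set
#'   (base predictions from models refit on the full training data).
#' @param stacking_variants Variants to include (default all three).
#' @param seed Integer seed.
#' @return An `ensemble_report`: list with `evaluation` (tibble of candidate
#'   eval-fold WMSEs), `unsupervised`/`supervised` winner names, final fitted
#'   objects, and `test_predictions` (named list) when `test_matrix` given.
#' @export
select_and_finalize <- function(matrix_tbl, test_matrix = NULL,
                                stacking_variants = c("raw", "z_scored",
                                                      "per_subject"),
                                seed = 1L) {
  if (!"fold" %in% names(matrix_tbl)) abort("`matrix_tbl` must carry a fold column")
  k <- max(matrix_tbl$fold)
  inner <- matrix_tbl %>% filter(.data$fold < k)
  eval_fold <- matrix_tbl %>% filter(.data$fold == k)

  fitted <- list()
  evals <- list()
  for (m in c("mean", "median")) {
    nm <- paste0("unsup_", m)
    pred <- aggregate_unsupervised(eval_fold, m)
    evals[[nm]] <- tibble(candidate = nm, class = "unsupervised",
                          eval_wmse = matrix_wmse(eval_fold, pred$prediction))
  }
  for (v in stacking_variants) {
    stk <- fit_stacking(inner, variant = v, seed = derive_seed(seed, 10 + match(v, stacking_variants)))
    for (fam in names(stk)) {
      nm <- paste0("stack_", v, "_", fam)
      fitted[[nm]] <- stk[[fam]]
      pred <- predict(stk[[fam]], eval_fold)
      evals[[nm]] <- tibble(candidate = nm, class = "supervised",
                            eval_wmse = matrix_wmse(eval_fold, pred$prediction))
    }
  }
  ces <- ces_select(inner)
  fitted[["ces"]] <- ces
  pred <- predict(ces, eval_fold)
  evals[["ces"]] <- tibble(candidate = "ces", class = "supervised",
                           eval_wmse = matrix_wmse(eval_fold, pred$prediction))
  sls <- subset_linear_select(inner, seed = derive_seed(seed, 99))
  fitted[["subset_linear"]] <- sls
  pred <- predict(sls, eval_fold)
  evals[["subset_linear"]] <- tibble(candidate = "subset_linear",
                                     class = "supervised",
                                     eval_wmse = matrix_wmse(eval_fold,
                                                             pred$prediction))
  evaluation <- bind_rows(evals) %>% arrange(.data$class, .data$eval_wmse,
                                             .data$candidate)
  pick <- function(cls) {
    evaluation %>% filter(.data$class == cls) %>% slice(1) %>% pull("candidate")
  }
  unsup_winner <- pick("unsupervised")
  sup_winner <- pick("supervised")

  # refit winners on the full training matrix
  refit <- function(nm) {
    if (startsWith(nm, "unsup_")) {
      sub("unsup_", "", nm)
    } else if (startsWith(nm, "stack_")) {
      parts <- sub("stack_", "", nm)
      v <- stacking_variants[vapply(stacking_variants, function(s)
        startsWith(parts, s), TRUE)][1]
      fam <- sub(paste0(v, "_"), "", parts)
      fit_stacking(matrix_tbl, variant = v, families = fam,
                   seed = derive_seed(seed, 500))[[fam]]
    } else if (nm == "ces") {
      ces_select(matrix_tbl)
    } else {
      subset_linear_select(matrix_tbl, seed = derive_seed(seed, 501))
    }
  }
  final_unsup <- refit(unsup_winner)
  final_sup <- refit(sup_winner)

  test_predictions <- NULL
  if (!is.null(test_matrix)) {
    unsup_pred <- aggregate_unsupervised(test_matrix, final_unsup)
    sup_pred <- if (inherits(final_sup, "stacking_ensemble") ||
                    inherits(final_sup, "ces_ensemble") ||
                    inherits(final_sup, "subset_linear_ensemble")) {
      predict(final_sup, test_matrix)
    } else {
      aggregate_unsupervised(test_matrix, final_sup)
    }
    test_predictions <- list(unsupervised = unsup_pred, supervised = sup_pred)
  }
  structure(list(evaluation = evaluation,
                 unsupervised = unsup_winner, supervised = sup_winner,
                 final_unsupervised = final_unsup, final_supervised = final_sup,
                 test_predictions = test_predictions, seed = as.integer(seed)),
            class = "ensemble_report")
}
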