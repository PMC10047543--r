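# synthetic base-prediction matrix: truth plus bases of varying quality
mk_base_matrix <- function(n_per_subject = 30, n_subjects = 4, seed = 17,
                           with_fold = TRUE, k = 6) {
  withr::with_seed(seed, {
    n <- n_per_subject * n_subjects
    truth <- pmax(pmin(round(rnorm(n, 2, 1.2)), 4), 0)
    tb <- tibble::tibble(
      measurement_id = sprintf("m%04d", seq_len(n)),
      subject_id = rep(sprintf("s%d", seq_len(n_subjects)),
                       each = n_per_subject),
      truth = truth,
      good = truth + rnorm(n, 0, 0.3),
      fair = truth + rnorm(n, 0, 0.8),
      noisy = truth + rnorm(n, 0, 1.5),
      biased = truth * 0.5 + 1 + rnorm(n, 0, 0.4),
      junk = rnorm(n, 2, 1))
    if (with_fold) tb$fold <- rep_len(seq_len(k), n)
    tb
  })
}

test_that("nested CV partitions observations and respects the seed", {
  labels <- tibble::tibble(
    measurement_id = sprintf("m%03d", 1:60),
    subject_id = rep(c("a", "b"), each = 30),
    on_off = rep(0:1, 30), dyskinesia = 0, tremor = rep(0:2, 20))
  plan <- nested_cv(labels, k = 6, seed = 2)
  expect_equal(nrow(plan), 60)
  expect_equal(anyDuplicated(plan$measurement_id), 0L)
  expect_equal(sort(unique(plan$fold)), 1:6)
  expect_equal(unname(table(plan$fold)), rep(10L, 6), ignore_attr = TRUE)
  expect_identical(nested_cv(labels, k = 6, seed = 2), plan)
  few <- labels %>% dplyr::slice(1:4)
  expect_error(nested_cv(few, k = 6), "reduce k")
})

test_that("unsupervised aggregation is row-wise mean/median and idempotent", {
  tb <- tibble::tibble(measurement_id = "m1", subject_id = "s1", truth = 1,
                       a = 0, b = 1, c = 5)
  expect_equal(aggregate_unsupervised(tb, "median")$prediction, 1)
  expect_equal(aggregate_unsupervised(tb, "mean")$prediction, 2)
  same <- tibble::tibble(measurement_id = c("m1", "m2"), subject_id = "s1",
                         truth = c(1, 2), a = c(0.5, 3), b = c(0.5, 3))
  expect_equal(aggregate_unsupervised(same, "mean")$prediction, c(0.5, 3))
  solo <- same %>% dplyr::select(-b)
  expect_equal(aggregate_unsupervised(solo, "median")$prediction, c(0.5, 3))
  # permutation invariance in base order
  tb2 <- mk_base_matrix()
  shuffled <- tb2 %>% dplyr::relocate(junk, noisy, good, fair, biased,
                                      .after = truth)
  expect_equal(aggregate_unsupervised(tb2, "median")$prediction,
               aggregate_unsupervised(shuffled, "median")$prediction)
})

test_that("median aggregation resists one corrupted base column", {
  tb <- mk_base_matrix()
  corrupted <- tb
  corrupted$junk <- 1e6
  med1 <- aggregate_unsupervised(tb %>% dplyr::select(-junk), "median")
  med2 <- aggregate_unsupervised(corrupted %>% dplyr::select(-junk), "median")
  expect_equal(med1$prediction, med2$prediction)
})

test_that("stacking recovers an exactly-informative base model", {
  tb <- mk_base_matrix(seed = 5)
  tb$oracle <- tb$truth
  stk <- fit_stacking(tb, variant = "raw", families = c("ridge", "linear"),
                      seed = 1)
  p <- predict(stk$ridge, tb)
  mse_stack <- mean((p$prediction - tb$truth)^2)
  base_mses <- vapply(c("good", "fair", "noisy", "biased", "junk"),
                      function(b) mean((tb[[b]] - tb$truth)^2), 0)
  expect_lt(mse_stack, min(base_mses))
  # the L2 weight vector concentrates on the oracle column
  cf <- coef(stk$ridge$fits$pooled$fit, s = "lambda.min")
  w <- setNames(as.numeric(cf)[-1], rownames(cf)[-1])
  expect_equal(names(which.max(abs(w))), "oracle")
})

test_that("z-scored stacking is invariant to affine rescaling of a base", {
  tb <- mk_base_matrix(seed = 6)
  stk1 <- fit_stacking(tb, variant = "z_scored", families = "ridge", seed = 2)
  rescaled <- tb
  rescaled$good <- 10 * rescaled$good - 7
  stk2 <- fit_stacking(rescaled, variant = "z_scored", families = "ridge",
                       seed = 2)
  p1 <- predict(stk1$ridge, tb)
  p2 <- predict(stk2$ridge, rescaled)
  expect_equal(p1$prediction, p2$prediction, tolerance = 1e-8)
})

test_that("per-subject stacking falls back to the pooled model for small subjects", {
  tb <- mk_base_matrix(n_per_subject = 30, n_subjects = 3, seed = 7)
  tiny <- tibble::tibble(
    measurement_id = sprintf("x%d", 1:3), subject_id = "tiny",
    truth = c(1, 2, 3), good = c(1, 2, 3), fair = c(1, 2, 3),
    noisy = c(0, 0, 0), biased = c(2, 2, 2), junk = c(1, 1, 1),
    fold = 1:3)
  stk <- fit_stacking(dplyr::bind_rows(tb, tiny), variant = "per_subject",
                      families = "ridge", min_subject_n = 10, seed = 3)
  expect_false("tiny" %in% names(stk$ridge$fits$subjects))
  expect_setequal(names(stk$ridge$fits$subjects),
                  c("s1", "s2", "s3"))
  p <- predict(stk$ridge, tiny)
  expect_true(all(is.finite(p$prediction)))
})

test_that("a singular design skips the unregularized linear meta-learner", {
  tb <- mk_base_matrix(seed = 8)
  tb$dup <- tb$good # exact collinearity
  expect_message(stk <- fit_stacking(tb, variant = "raw",
                                     families = "linear", seed = 4),
                 "singular")
  expect_length(stk, 0)
})

test_that("greedy selection starts at the best base and never degrades", {
  tb <- mk_base_matrix(seed = 9)
  ces <- ces_select(tb)
  base_wmse <- vapply(c("good", "fair", "noisy", "biased", "junk"),
                      function(b) {
                        st <- tb %>% dplyr::group_by(subject_id) %>%
                          dplyr::summarise(n = dplyr::n(),
                                           mse = mean((.data[[b]] - truth)^2))
                        oracle_wmse(st$n, st$mse)
                      }, 0)
  expect_lte(ces$wmse, min(base_wmse))
  expect_true("good" %in% ces$members)
  # a single base selects itself
  solo <- tb %>% dplyr::select(measurement_id, subject_id, truth, fold, good)
  ces1 <- ces_select(solo)
  expect_equal(unique(ces1$members), "good")
  # one informative base among pure noise gets picked
  withr::with_seed(10, {
    noise_tb <- tb %>%
      dplyr::mutate(fair = rnorm(dplyr::n(), 2, 1),
                    noisy = rnorm(dplyr::n(), 2, 1),
                    biased = rnorm(dplyr::n(), 2, 1),
                    junk = rnorm(dplyr::n(), 2, 1))
  })
  ces2 <- ces_select(noise_tb)
  expect_equal(names(sort(table(ces2$members), decreasing = TRUE))[1], "good")
})

test_that("subset search enumerates all 31 subsets of 5 bases", {
  tb <- mk_base_matrix(seed = 11)
  sls <- subset_linear_select(tb, seed = 2)
  expect_equal(sls$n_subsets, 31L)
  tb$oracle <- tb$truth
  sls2 <- subset_linear_select(tb, seed = 2)
  expect_equal(sls2$n_subsets, 63L)
  expect_true("oracle" %in% sls2$subset)
  expect_lt(sls2$holdout_wmse, 0.01)
  too_many <- tb
  for (i in 1:8) too_many[[paste0("extra", i)]] <- rnorm(nrow(tb))
  expect_error(subset_linear_select(too_many), "more than 12")
})

test_that("final selection picks the evaluation-fold argmin per class", {
  tb <- mk_base_matrix(n_per_subject = 36, seed = 12)
  test_tb <- mk_base_matrix(n_per_subject = 12, seed = 13, with_fold = FALSE)
  rep <- select_and_finalize(tb, test_matrix = test_tb, seed = 3)
  ev <- rep$evaluation
  for (cls in c("unsupervised", "supervised")) {
    winner <- if (cls == "unsupervised") rep$unsupervised else rep$supervised
    cls_tab <- ev %>% dplyr::filter(class == cls)
    expect_equal(cls_tab$candidate[which.min(cls_tab$eval_wmse)], winner)
  }
  expect_named(rep$test_predictions, c("unsupervised", "supervised"))
  expect_true(all(is.finite(rep$test_predictions$supervised$prediction)))
  td <- generics::tidy(rep)
  expect_equal(sum(td$winner), 2)
})

test_that("fitting never reads the evaluation fold (poisoning test)", {
  tb <- mk_base_matrix(n_per_subject = 36, seed = 14)
  k <- max(tb$fold)
  poisoned <- tb
  poisoned$truth[poisoned$fold == k] <- 99
  inner <- tb %>% dplyr::filter(fold < k)
  inner_poisoned <- poisoned %>% dplyr::filter(fold < k)
  stk1 <- fit_stacking(inner, variant = "raw", families = "ridge", seed = 5)
  stk2 <- fit_stacking(inner_poisoned, variant = "raw", families = "ridge",
                       seed = 5)
  newdata <- mk_base_matrix(n_per_subject = 10, seed = 15, with_fold = FALSE)
  expect_equal(predict(stk1$ridge, newdata)$prediction,
               predict(stk2$ridge, newdata)$prediction)
  expect_identical(ces_select(inner)$members,
                   ces_select(inner_poisoned)$members)
})

test_that("complementary bases stack better than either alone", {
  withr::with_seed(16, {
    n <- 240
    part1 <- rnorm(n); part2 <- rnorm(n)
    truth <- part1 + part2
    tb <- tibble::tibble(
      measurement_id = sprintf("m%04d", 1:n),
      subject_id = rep(c("a", "b", "c"), each = n / 3),
      truth = truth,
      half1 = part1 + rnorm(n, 0, 0.2),
      half2 = part2 + rnorm(n, 0, 0.2),
      fold = rep_len(1:6, n))
  })
  stk <- fit_stacking(tb %>% dplyr::filter(fold < 6), variant = "raw",
                      families = "ridge", seed = 6)
  eval_tb <- tb %>% dplyr::filter(fold == 6)
  p <- predict(stk$ridge, eval_tb)
  mse_stack <- mean((p$prediction - eval_tb$truth)^2)
  mse_half1 <- mean((eval_tb$half1 - eval_tb$truth)^2)
  mse_half2 <- mean((eval_tb$half2 - eval_tb$truth)^2)
  expect_lt(mse_stack, mse_half1)
  expect_lt(mse_stack, mse_half2)
})
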