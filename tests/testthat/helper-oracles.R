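suppressMessages(library(dplyr))

# Independent brute-force oracles, written with explicit loops and kept free
# of any package internals so they can arbitrate the implementations.

oracle_wmse <- function(n, mse) {
  num <- 0
  den <- 0
  for (k in seq_along(n)) {
    num <- num + sqrt(n[k]) * mse[k]
    den <- den + sqrt(n[k])
  }
  num / den
}

oracle_mse <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[i] - truth[i])^2
  s / length(pred)
}

# Kendall tau-b from explicit pair enumeration with tie correction.
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_fisher <- function(p) {
  stat <- 0
  for (pi in p) stat <- stat - 2 * log(pi)
  list(statistic = stat, p_value = pchisq(stat, df = 2 * length(p),
                                          lower.tail = FALSE))
}

oracle_fixed_effect_meta <- function(r, n) {
  num <- 0; den <- 0
  for (i in seq_along(r)) {
    w <- n[i] - 3
    num <- num + w * atanh(r[i])
    den <- den + w
  }
  z <- num / den
  list(r_pooled = tanh(z), z_pooled = z,
       p_value = 2 * pnorm(-abs(z * sqrt(den))))
}

# Band power in [lo, hi) Hz via a direct DFT double loop (independent of the
# package's FFT path); same one-sided normalization: a sinusoid of amplitude
# A at an in-band frequency contributes A^2/2.
oracle_band_power <- function(v, fs, lo, hi) {
  n <- length(v)
  v <- v - mean(v)
  total <- 0
  for (k in 1:floor(n / 2)) {
    f <- k * fs / n
    if (f >= lo && f < hi) {
      re <- 0; im <- 0
      for (i in seq_len(n)) {
        ang <- -2 * pi * k * (i - 1) / n
        re <- re + v[i] * cos(ang)
        im <- im + v[i] * sin(ang)
      }
      total <- total + 2 * (re^2 + im^2) / n^2
    }
  }
  total
}

# Mean of round(clip(theta + N(0, sd))) by numerical integration over a fine
# grid of the normal density.
oracle_clipped_label_mean <- function(theta, sd, lo = 0, hi = 4) {
  z <- seq(theta - 8 * sd, theta + 8 * sd, length.out = 20001)
  dens <- dnorm(z, theta, sd)
  lab <- pmin(pmax(round(z), lo), hi)
  sum(lab * dens) / sum(dens)
}

# Small fully in-memory cohort used across tests: short segments so feature
# extraction stays fast.
tiny_cohort_spec <- function(cohort_id = "CIS", n_subjects = 3,
                             reports = c(8, 8), seed = 1, ...) {
  cohort_spec(cohort_id, n_subjects = n_subjects,
              reports_per_subject = reports, sampling_rate = 16,
              segment_duration = 60, seed = seed, ...)
}

# Random per-subject score tables for oracle comparisons.
random_score_table <- function(n_subjects) {
  tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n_subjects)),
    n = sample(11:99, n_subjects, replace = TRUE),
    mse = runif(n_subjects, 0, 2)
  )
}
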