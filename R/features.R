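#' Combine triaxial acceleration into a single channel
#'
#' Per-sample Euclidean norm `sqrt(x^2 + y^2 + z^2)` — the standard
#' accelerometry vector magnitude (VM).
#'
#' @param x,y,z Equal-length numeric axis vectors (g).
#' @return Numeric vector of vector magnitudes.
#' @export
#' @examples
#' combine_rms(1, 1, 1) # sqrt(3)
combine_rms <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    abort("axis vectors must have equal length")
  }
  sqrt(x^2 + y^2 + z^2)
}

#' Partition a segment into fixed-width windows
#'
#' Samples are bucketed into consecutive half-open windows
#' `[k*width, (k+1)*width)`. Windows holding fewer than `min_frac` of the
#' expected `width * fs` samples are dropped (this also removes a trailing
#' partial window).
#'
#' @param segment Tibble with columns `t`, `x`, `y`, `z`.
#' @param width Window width in seconds (default 30).
#' @param fs Nominal sampling rate in Hz.
#' @param min_frac Minimum retained fraction of expected samples (default 0.5).
#' @return Input tibble with a `window_index` column (0-based), restricted to
#'   retained windows.
#' @export
window_segment <- function(segment, width = 30, fs, min_frac = 0.5) {
  w <- floor(segment$t / width)
  counts <- table(w)
  keep_w <- as.numeric(names(counts))[counts >= min_frac * width * fs]
  out <- segment[w %in% keep_w, , drop = FALSE]
  out$window_index <- as.integer(floor(out$t / width))
  as_tibble(out)
}

# Interpolate one column per retained window onto the uniform grid; returns an
# (width*fs) x n_windows matrix. `approx` with rule 2 extends constantly at
# window edges.
window_matrix <- function(t, v, windows, width, fs) {
  m <- round(width * fs)
  rel <- (seq_len(m) - 1) / fs
  vapply(windows, function(w) {
    idx <- which(t >= w * width & t < (w + 1) * width)
    approx(t[idx], v[idx], xout = w * width + rel, rule = 2)$y
  }, numeric(m))
}

# One-sided power spectrum columns (DC excluded) of a (m x k) window matrix.
# Power of an in-band sinusoid of amplitude A is A^2/2 under this scaling.
power_matrix <- function(V, fs) {
  m <- nrow(V)
  centered <- sweep(V, 2, colMeans(V))
  X <- stats::mvfft(centered)
  half <- 2:(floor(m / 2) + 1)
  P <- 2 * Mod(X[half, , drop = FALSE])^2 / m^2
  list(P = P, f = (half - 1) * fs / m)
}

band_power_cols <- function(spec, lo, hi) {
  mask <- spec$f >= lo & spec$f < hi
  colSums(spec$P[mask, , drop = FALSE])
}

spectral_summary_cols <- function(spec, dom_lo = 0.3, dom_hi = 15) {
  P <- spec$P
  tot <- colSums(P)
  k <- ncol(P)
  entropy <- numeric(k)
  dom_f <- numeric(k)
  dom_p <- numeric(k)
  pos <- tot > .Machine$double.eps
  if (any(pos)) {
    pr <- sweep(P[, pos, drop = FALSE], 2, tot[pos], "/")
    plogp <- ifelse(pr > 0, pr * log(pr), 0)
    entropy[pos] <- -colSums(plogp) / log(max(nrow(P), 2))
    in_dom <- spec$f >= dom_lo & spec$f <= dom_hi
    if (!any(in_dom)) in_dom <- rep(TRUE, length(spec$f))
    Pd <- P[in_dom, pos, drop = FALSE]
    rows <- apply(Pd, 2, which.max)
    dom_f[pos] <- spec$f[in_dom][rows]
    dom_p[pos] <- Pd[cbind(rows, seq_len(ncol(Pd)))]
  }
  list(entropy = entropy, dominant_freq = dom_f, dominant_power = dom_p)
}

# Interior peaks of support 1 per column: strictly greater than both
# neighbours.
peak_count_cols <- function(V) {
  m <- nrow(V)
  if (m < 3) return(numeric(ncol(V)))
  mid <- V[2:(m - 1), , drop = FALSE]
  colSums(mid > V[1:(m - 2), , drop = FALSE] & mid > V[3:m, , drop = FALSE])
}

zero_crossing_cols <- function(V) {
  centered <- sweep(V, 2, colMeans(V))
  apply(centered, 2, function(c) {
    s <- sign(c[c != 0])
    if (length(s) < 2) 0 else sum(diff(s) != 0)
  })
}

generic_feature_names <- function() {
  c("mean", "median", "sd", "var", "min", "max", "sum_values",
    sprintf("quantile_%s", c("0.1", "0.2", "0.3", "0.4", "0.6", "0.7",
                             "0.8", "0.9")),
    "iqr", "rms", "abs_energy", "mean_abs_change", "skewness", "kurtosis",
    "number_peaks_1", "zero_crossings", "fft_coef0_real", "fft_coef0_abs",
    "bandpower_0.5_3", "bandpower_3_7", "bandpower_7_12",
    "rel_bandpower_0.5_3", "rel_bandpower_3_7", "rel_bandpower_7_12",
    "spectral_entropy", "dominant_freq", "dominant_power")
}

# Matrix implementation over (m samples) x (k windows); returns k x 31.
generic_features_matrix <- function(V, fs) {
  m <- nrow(V)
  mu <- colMeans(V)
  sums <- colSums(V)
  ss <- colSums(V^2)
  vr <- if (m > 1) (ss - m * mu^2) / (m - 1) else rep(0, ncol(V))
  vr <- pmax(vr, 0)
  s <- sqrt(vr)
  qs <- apply(V, 2, quantile,
              probs = c(0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.6, 0.7, 0.75, 0.8, 0.9),
              names = FALSE, type = 7)
  centered <- sweep(V, 2, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  skew <- ifelse(sd_pop > 0, colMeans(centered^3) / sd_pop^3, 0)
  kurt <- ifelse(sd_pop > 0, colMeans(centered^4) / sd_pop^4 - 3, 0)
  spec <- power_matrix(V, fs)
  summ <- spectral_summary_cols(spec)
  tot_power <- colSums(spec$P)
  bp1 <- band_power_cols(spec, 0.5, 3)
  bp2 <- band_power_cols(spec, 3, 7)
  bp3 <- band_power_cols(spec, 7, 12)
  rel <- function(bp) ifelse(tot_power > 0, bp / tot_power, 0)
  out <- cbind(
    mu, qs[6, ], s, vr,
    apply(V, 2, min), apply(V, 2, max), sums,
    t(qs[c(1, 2, 4, 5, 7, 8, 10, 11), , drop = FALSE]),
    qs[9, ] - qs[3, ],
    sqrt(colMeans(V^2)), ss,
    if (m > 1) colMeans(abs(diff(V))) else rep(0, ncol(V)),
    skew, kurt,
    peak_count_cols(V), zero_crossing_cols(V),
    sums, abs(sums),
    bp1, bp2, bp3, rel(bp1), rel(bp2), rel(bp3),
    summ$entropy, summ$dominant_freq, summ$dominant_power
  )
  colnames(out) <- generic_feature_names()
  out
}

#' Generic single-channel window features
#'
#' A documented 34-feature set over one mono (VM-combined) window, covering
#' the named high-importance features of the per-subject model archetype:
#' quantiles at 0.2/0.3/0.4/0.7/0.8 (plus the remaining deciles), number of
#' peaks of support 1 (samples strictly greater than both neighbours),
#' `sum_values`, mean, and the real part and magnitude of the 0th FFT
#' coefficient (the DC term, i.e. the sample sum), together with dispersion,
#' shape, zero-crossing, band-power (0.5-3, 3-7, 7-12 Hz, absolute and as a
#' fraction of total power — the relative versions separate narrowband tremor
#' from overall movement intensity), spectral-entropy
#' and dominant-frequency summaries. All-constant windows get
#' `number_peaks_1 = 0` and `spectral_entropy = 0` by convention.
#'
#' @param v Numeric vector: one uniformly sampled mono window.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector (see [generic_feature_names()]).
#' @export
generic_features <- function(v, fs) {
  stopifnot(length(v) >= 2)
  generic_features_matrix(matrix(v, ncol = 1), fs)[1, ]
}

actigraphy_feature_names <- function() {
  c("vm_mean", "vm_sd", "vm_max", "dominant_freq", "dominant_power",
    "spectral_entropy", "bandpower_3_7", "cpm", "corr_xy", "corr_xz",
    "corr_yz", "mean_x", "mean_y", "mean_z", "axis_sd_mean", "jerk_rms")
}

col_sds <- function(M) {
  m <- nrow(M)
  if (m < 2) return(rep(0, ncol(M)))
  mu <- colMeans(M)
  sqrt(pmax((colSums(M^2) - m * mu^2) / (m - 1), 0))
}

# Pearson correlation per column pair with zero-variance convention 0.
cor_cols <- function(A, B) {
  m <- nrow(A)
  sa <- col_sds(A)
  sb <- col_sds(B)
  ca <- sweep(A, 2, colMeans(A))
  cb <- sweep(B, 2, colMeans(B))
  r <- colSums(ca * cb) / ((m - 1) * sa * sb)
  ifelse(sa == 0 | sb == 0, 0, r)
}

actigraphy_features_matrix <- function(X, Y, Z, fs) {
  VM <- sqrt(X^2 + Y^2 + Z^2)
  spec <- power_matrix(VM, fs)
  summ <- spectral_summary_cols(spec)
  m <- nrow(VM)
  jerk <- if (m > 1) sqrt(colMeans((diff(VM) * fs)^2)) else rep(0, ncol(VM))
  out <- cbind(
    colMeans(VM), col_sds(VM), apply(VM, 2, max),
    summ$dominant_freq, summ$dominant_power, summ$entropy,
    band_power_cols(spec, 3, 7),
    colMeans(abs(VM - 1)) * 60,
    cor_cols(X, Y), cor_cols(X, Z), cor_cols(Y, Z),
    colMeans(X), colMeans(Y), colMeans(Z),
    (col_sds(X) + col_sds(Y) + col_sds(Z)) / 3,
    jerk
  )
  colnames(out) <- actigraphy_feature_names()
  out
}

#' Actigraphy-style triaxial window features
#'
#' Exactly 16 features per window on the raw triaxial data: vector-magnitude
#' mean/SD/max, dominant frequency of the VM in 0.3-15 Hz (DC excluded) and
#' its power, spectral entropy, 3-7 Hz band power, a counts-per-minute proxy
#' (`cpm = mean(|VM - 1 g|) * 60`, an activity-count surrogate for
#' conventional actigraphy reports), the three inter-axis correlations,
#' per-axis means, the mean of the per-axis SDs, and the RMS jerk of the VM.
#' A zero-variance axis yields correlation 0 by convention.
#'
#' @param x,y,z Uniformly sampled axis vectors for one window.
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector (see [actigraphy_feature_names()]).
#' @export
actigraphy_features <- function(x, y, z, fs) {
  if (length(x) != length(y) || length(x) != length(z)) {
    abort("axis vectors must have equal length")
  }
  actigraphy_features_matrix(matrix(x, ncol = 1), matrix(y, ncol = 1),
                             matrix(z, ncol = 1), fs)[1, ]
}

#' Extract window features for a set of segments
#'
#' Windows each segment stream ([window_segment()]), linearly interpolates
#' each retained window onto a uniform grid at `fs` (the FFT path requires
#' uniform sampling; raw samples may be irregular after missingness), and
#' computes the requested feature family: `"generic"` on the VM-combined mono
#' signal or `"actigraphy"` on the triaxial data.
#'
#' @param segments Long tibble `measurement_id`, `device`, `t`, `x`, `y`, `z`.
#' @param fs Nominal sampling rate in Hz.
#' @param feature_set `"generic"` or `"actigraphy"`.
#' @param width Window width in seconds.
#' @return Tibble: `measurement_id`, `device`, `window_index`, one column per
#'   feature. Column order is fixed by the feature-name helpers.
#' @export
extract_features <- function(segments, fs,
                             feature_set = c("generic", "actigraphy"),
                             width = 30) {
  feature_set <- match.arg(feature_set)
  key <- paste(segments$measurement_id, segments$device, sep = "\r")
  groups <- split(seq_len(nrow(segments)), key)
  xs <- list(); ys <- list(); zs <- list()
  ids <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    win <- window_segment(segments[idx, c("t", "x", "y", "z")],
                          width = width, fs = fs)
    if (nrow(win) == 0) next
    windows <- sort(unique(win$window_index))
    xs[[g]] <- window_matrix(win$t, win$x, windows, width, fs)
    ys[[g]] <- window_matrix(win$t, win$y, windows, width, fs)
    zs[[g]] <- window_matrix(win$t, win$z, windows, width, fs)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    ids[[g]] <- tibble(measurement_id = parts[1], device = parts[2],
                       window_index = windows)
  }
  if (length(ids) == 0) {
    return(tibble(measurement_id = character(), device = character(),
                  window_index = integer()))
  }
  X <- do.call(cbind, xs)
  Y <- do.call(cbind, ys)
  Z <- do.call(cbind, zs)
  feats <- if (feature_set == "generic") {
    generic_features_matrix(sqrt(X^2 + Y^2 + Z^2), fs)
  } else {
    actigraphy_features_matrix(X, Y, Z, fs)
  }
  bind_cols(bind_rows(ids), as_tibble(feats)) %>%
    arrange(.data$measurement_id, .data$device, .data$window_index)
}

#' Assemble the modelling design matrix
#'
#' Joins window features with observation labels and, in `with_covariates`
#' mode, appends the subject-level covariates: age, gender (coded
#' `gender_male`), MDS-UPDRS Part I/II totals, Part IV items, Part III on/off
#' item sums, and the first principal-direction score of the Part III items
#' (computed across the supplied subjects; all-identical items give score 0).
#' Multi-device observations stay as separate rows. Missing covariates are
#' imputed with the cohort median.
#'
#' @param features Feature tibble from [extract_features()].
#' @param labels Harmonized label tibble.
#' @param covariates Covariate tibble (one row per subject), required for
#'   `mode = "with_covariates"`.
#' @param mode `"sensor_only"` or `"with_covariates"`.
#' @return Window-level design tibble: identifiers, label columns, features
#'   (and covariates).
#' @export
assemble_design_matrix <- function(features, labels, covariates = NULL,
                                   mode = c("sensor_only", "with_covariates")) {
  mode <- match.arg(mode)
  label_cols <- intersect(c("subject_id", "cohort_id", SYMPTOMS), names(labels))
  out <- features %>%
    inner_join(labels %>% select("measurement_id", all_of(label_cols)),
               by = "measurement_id")
  if (mode == "sensor_only") return(out)
  if (is.null(covariates)) abort("`covariates` required for with_covariates mode")

  p3on <- grep("^updrs3_on_", names(covariates), value = TRUE)
  p3off <- grep("^updrs3_off_", names(covariates), value = TRUE)
  p4 <- grep("^updrs4_", names(covariates), value = TRUE)
  items <- as.matrix(covariates[c(p3on, p3off)])
  pc1 <- if (nrow(items) > 1 && any(apply(items, 2, sd) > 0)) {
    as.numeric(prcomp(items, center = TRUE, scale. = FALSE)$x[, 1])
  } else {
    rep(0, nrow(covariates))
  }
  cov_tbl <- tibble(
    subject_id = covariates$subject_id,
    age = covariates$age,
    gender_male = as.numeric(covariates$gender == "male"),
    updrs1_total = covariates$updrs1_total,
    updrs2_total = covariates$updrs2_total,
    updrs3_on_sum = rowSums(covariates[p3on]),
    updrs3_off_sum = rowSums(covariates[p3off]),
    updrs3_pc1 = pc1
  ) %>%
    bind_cols(covariates[p4])
  num_cols <- setdiff(names(cov_tbl), "subject_id")
  for (cl in num_cols) {
    v <- cov_tbl[[cl]]
    if (anyNA(v)) {
      inform(sprintf("imputing missing covariate '%s' with cohort median", cl))
      cov_tbl[[cl]][is.na(v)] <- median(v, na.rm = TRUE)
    }
  }
  out %>% left_join(cov_tbl, by = "subject_id")
}
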