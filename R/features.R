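# The 18 signal parameters (amplitude, frequency, statistics, entropy) and the
# assembly of the 324-column feature grid (18 parameters x 6 sensors x 3 tasks).

.PARAMS <- c("MAV", "MAVFD", "MAVSD", "RMS", "Peak",
             "ZC", "FMean", "FPeak", "F50", "F80", "Power3.5_7.5",
             "ApEn", "FuzzyEn",
             "VAR", "RANGE", "INTQ", "SKEWNESS", "KURTOSIS")
.PARAM_GROUPS <- c(MAV = "amplitude", MAVFD = "amplitude", MAVSD = "amplitude",
                   RMS = "amplitude", Peak = "amplitude",
                   ZC = "frequency", FMean = "frequency", FPeak = "frequency",
                   F50 = "frequency", F80 = "frequency",
                   "Power3.5_7.5" = "frequency",
                   ApEn = "entropy", FuzzyEn = "entropy",
                   VAR = "statistic", RANGE = "statistic", INTQ = "statistic",
                   SKEWNESS = "statistic", KURTOSIS = "statistic")

#' Parameter-extraction configuration
#'
#' Collects the tunable conventions of the feature extractor. Defaults are the
#' field-standard choices: entropy window length `m = 2` with tolerance
#' `r = 0.2 * SD`, fuzzy membership `exp(-d^2 / r)` on mean-centered windows,
#' Welch power spectra (Hann window, 256-sample segments, 50 percent overlap),
#' linear-interpolation quartiles, and the literal unnormalized variance
#' (no `1/N`; a `sample_variance` switch restores the conventional estimator).
#'
#' @param apen_m,apen_r_coeff Window length and SD-relative tolerance for
#'   approximate entropy.
#' @param fuzzy_m,fuzzy_r_coeff,fuzzy_gradient Same for fuzzy entropy, plus the
#'   exponent of the membership function.
#' @param psd_method `"welch"` (default) or `"periodogram"`.
#' @param welch_segment Welch segment length in samples.
#' @param quartile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @param sample_variance Use `1/(N-1)` variance instead of the literal
#'   unnormalized sum of squared deviations.
#' @param population_moments Use population SD in skewness/kurtosis (default).
#' @return An object of class `param_config`.
#' @export
param_config <- function(apen_m = 2L, apen_r_coeff = 0.2,
                         fuzzy_m = 2L, fuzzy_r_coeff = 0.2,
                         fuzzy_gradient = 2,
                         psd_method = c("welch", "periodogram"),
                         welch_segment = 256L, quartile_type = 7L,
                         sample_variance = FALSE, population_moments = TRUE) {
  stopifnot(apen_m >= 1, fuzzy_m >= 1, apen_r_coeff > 0, fuzzy_r_coeff > 0)
  structure(list(apen_m = as.integer(apen_m), apen_r_coeff = apen_r_coeff,
                 fuzzy_m = as.integer(fuzzy_m), fuzzy_r_coeff = fuzzy_r_coeff,
                 fuzzy_gradient = fuzzy_gradient,
                 psd_method = match.arg(psd_method),
                 welch_segment = as.integer(welch_segment),
                 quartile_type = as.integer(quartile_type),
                 sample_variance = sample_variance,
                 population_moments = population_moments),
            class = "param_config")
}

#' Amplitude parameters
#'
#' Mean absolute value (MAV), mean absolute first and second differences
#' (MAVFD, MAVSD), root mean square (RMS) and Peak (maximum over positive
#' samples; 0 with a warning if none are positive).
#'
#' @param x Numeric series of length >= 3.
#' @return Named numeric vector `MAV, MAVFD, MAVSD, RMS, Peak`.
#' @examples
#' amplitude_features(c(1, -1, 1, -1))
#' @export
amplitude_features <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples (second difference undefined)")
  pos <- x[x > 0]
  if (length(pos) == 0) {
    warning("no positive samples; Peak set to 0")
    peak <- 0
  } else {
    peak <- max(pos)
  }
  c(MAV = mean(abs(x)),
    MAVFD = mean(abs(diff(x))),
    MAVSD = mean(abs(diff(x, lag = 2))),
    RMS = sqrt(mean(x^2)),
    Peak = peak)
}

#' Zero-crossing count
#'
#' Counts consecutive sample pairs of strictly opposite sign. Exact zeros never
#' contribute (strict inequalities).
#'
#' @param x Numeric series of length >= 2.
#' @return Integer count.
#' @examples
#' zero_crossings(c(1, -1, 1, -1))  # 3
#' zero_crossings(c(1, 0, -1))      # 0: the zero sample blocks both tests
#' @export
zero_crossings <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  a <- x[-length(x)]
  b <- x[-1]
  sum((a > 0 & b < 0) | (a < 0 & b > 0))
}

#' Power spectral density estimate
#'
#' One-sided PSD via Welch's method (Hann window, 50 percent overlap) or the plain
#' periodogram. The segment length is capped at the series length.
#'
#' @param x Numeric series.
#' @param fs Sampling frequency, Hz.
#' @param method `"welch"` or `"periodogram"`.
#' @param segment Welch segment length, samples.
#' @return List with `freq` (Hz) and `power`.
#' @export
psd_estimate <- function(x, fs, method = c("welch", "periodogram"),
                         segment = 256L) {
  method <- match.arg(method)
  n <- length(x)
  if (method == "periodogram") {
    segs <- list(x)
    w <- rep(1, n)
  } else {
    L <- min(segment, n)
    step <- max(1L, floor(L / 2))
    starts <- seq(1L, n - L + 1L, by = step)
    segs <- lapply(starts, function(s) x[s:(s + L - 1L)])
    w <- 0.5 * (1 - cos(2 * pi * seq(0, L - 1) / L))   # periodic Hann
  }
  L <- length(segs[[1]])
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in segs) {
    X <- stats::fft(s * w)
    acc <- acc + (Mod(X[seq_len(nf)])^2) / scale
  }
  p <- acc / length(segs)
  # one-sided: double the interior bins
  if (L %% 2 == 0) {
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  } else if (nf > 1) {
    p[2:nf] <- 2 * p[2:nf]
  }
  list(freq = (seq_len(nf) - 1) * fs / L, power = p)
}

#' Spectral parameters
#'
#' Mean frequency (power-weighted), peak frequency, median frequency (first
#' grid frequency where cumulative power reaches half the total), F80 (same at
#' 80 percent), and band power over 3.5--7.5 Hz. The DC bin is excluded: the
#' resultant magnitude has a large positive mean that would otherwise dominate
#' every spectral summary. A degenerate all-zero spectrum yields zeros with a
#' warning.
#'
#' @param x Numeric series (length >= 64 recommended).
#' @param fs Sampling frequency, Hz; must exceed 15 Hz so the 7.5 Hz band edge
#'   is below Nyquist.
#' @param cfg A [param_config()].
#' @return List with the five named features and the `spectrum` used.
#' @export
spectral_features <- function(x, fs, cfg = param_config()) {
  if (fs <= 15) stop("fs must exceed 15 Hz (band edge 7.5 Hz below Nyquist)")
  sp <- psd_estimate(x, fs, cfg$psd_method, cfg$welch_segment)
  keep <- sp$freq > 0
  f <- sp$freq[keep]
  p <- sp$power[keep]
  tot <- sum(p)
  if (tot <= 0) {
    warning("all-zero spectrum; spectral features set to 0")
    feats <- c(FMean = 0, FPeak = 0, F50 = 0, F80 = 0, "Power3.5_7.5" = 0)
    return(list(features = feats, spectrum = sp))
  }
  cum <- cumsum(p)
  feats <- c(
    FMean = sum(p * f) / tot,
    FPeak = f[which.max(p)],
    F50 = f[which(cum >= 0.5 * tot)[1]],
    F80 = f[which(cum >= 0.8 * tot)[1]],
    "Power3.5_7.5" = sum(p[f >= 3.5 & f <= 7.5]))
  list(features = feats, spectrum = sp)
}

#' Statistical parameters
#'
#' Variance as the literal unnormalized sum of squared deviations (the scale
#' is irrelevant downstream of min-max normalization; `cfg$sample_variance`
#' restores `1/(N-1)`), range, interquartile range under the configured
#' quantile convention, and skewness/kurtosis with population SD. A constant
#' series makes skewness and kurtosis undefined; they are returned as `NaN`
#' with a warning.
#'
#' @param x Numeric series of length >= 4.
#' @param cfg A [param_config()].
#' @return Named vector `VAR, RANGE, INTQ, SKEWNESS, KURTOSIS`.
#' @export
statistical_features <- function(x, cfg = param_config()) {
  if (length(x) < 4) stop("need at least 4 samples")
  n <- length(x)
  dev <- x - mean(x)
  vr <- if (cfg$sample_variance) sum(dev^2) / (n - 1) else sum(dev^2)
  q <- stats::quantile(x, c(0.25, 0.75), type = cfg$quartile_type, names = FALSE)
  sigma2 <- if (cfg$population_moments) mean(dev^2) else sum(dev^2) / (n - 1)
  if (sigma2 == 0) {
    warning("constant series: skewness/kurtosis undefined (NaN)")
    sk <- NaN
    ku <- NaN
  } else {
    sk <- mean(dev^3) / sigma2^1.5
    ku <- mean(dev^4) / sigma2^2
  }
  c(VAR = vr, RANGE = max(x) - min(x), INTQ = q[2] - q[1],
    SKEWNESS = sk, KURTOSIS = ku)
}

#' Approximate entropy
#'
#' Regularity measure: the negative log conditional probability that windows
#' close at length `m` (Chebyshev distance within tolerance `r`) remain close
#' at length `m + 1`. The literal counting construction is used: self-matches
#' are included, so the value is non-negative for non-degenerate series and 0
#' for perfectly predictable (constant) ones.
#'
#' @param x Numeric series of length >= `2 * (m + 1)`.
#' @param cfg A [param_config()]; tolerance is `apen_r_coeff * SD(x)`.
#' @param r Absolute tolerance overriding the SD-relative default.
#' @return ApEn value.
#' @export
approximate_entropy <- function(x, cfg = param_config(), r = NULL) {
  m <- cfg$apen_m
  if (length(x) < 2 * (m + 1)) stop("series too short for ApEn")
  if (is.null(r)) r <- cfg$apen_r_coeff * stats::sd(x)
  if (r <= 0) {
    # constant series: every window matches every other at both lengths
    if (stats::sd(x) == 0) return(0)
    stop("tolerance r must be positive")
  }
  .apen_cpp(as.numeric(x), m, r)
}

#' Fuzzy entropy
#'
#' Like approximate entropy but with a smooth membership function
#' `exp(-d^gradient / r)` in place of the hard threshold, computed on
#' mean-centered windows with self-matches excluded; more stable on short
#' series.
#'
#' @inheritParams approximate_entropy
#' @return FuzzyEn value (>= 0 up to numerical tolerance).
#' @export
fuzzy_entropy <- function(x, cfg = param_config(), r = NULL) {
  m <- cfg$fuzzy_m
  if (length(x) < 2 * (m + 1)) stop("series too short for FuzzyEn")
  if (is.null(r)) r <- cfg$fuzzy_r_coeff * stats::sd(x)
  if (r <= 0) {
    if (stats::sd(x) == 0) return(0)
    stop("tolerance r must be positive")
  }
  .fuzzyen_cpp(as.numeric(x), m, r, cfg$fuzzy_gradient)
}

#' All 18 parameters of one resultant series
#'
#' @param x Numeric series (a preprocessed resultant).
#' @param fs Sampling frequency, Hz.
#' @param cfg A [param_config()].
#' @return Named numeric vector of length 18. Undefined moments on degenerate
#'   (constant) input are mapped to 0 so assembled feature vectors stay finite;
#'   the constant column is dropped later in reduction anyway.
#' @export
extract_features <- function(x, fs, cfg = param_config()) {
  amp <- amplitude_features(x)
  zc <- zero_crossings(x)
  spec <- suppressWarnings(spectral_features(x, fs, cfg))$features
  st <- suppressWarnings(statistical_features(x, cfg))
  st[!is.finite(st)] <- 0
  if (stats::sd(x) == 0) {
    en <- c(ApEn = 0, FuzzyEn = 0)
  } else {
    en <- c(ApEn = approximate_entropy(x, cfg),
            FuzzyEn = fuzzy_entropy(x, cfg))
  }
  out <- c(amp, ZC = zc, spec, en, st)
  out[.PARAMS]
}

#' Feature-grid column names
#'
#' @return The 324 canonical column names `<param>_<sensor>_T<task>` in
#'   canonical (parameter, sensor, task) order.
#' @export
feature_grid <- function() {
  as.vector(vapply(1:3, function(task) {
    vapply(.SENSORS, function(s) paste0(.PARAMS, "_", s, "_T", task),
           character(length(.PARAMS)))
  }, matrix("", length(.PARAMS), length(.SENSORS))))
}

#' Parse feature-grid column names
#'
#' @param keys Character vector of `<param>_<sensor>_T<task>` names.
#' @return data.frame with columns `parameter`, `sensor`, `task`,
#'   `param_group`, `imu`.
#' @export
parse_feature_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.*)_(A1|A2|G1|G2|M1|M2)_T([123])$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable feature keys: ", paste(keys[bad], collapse = ", "))
  parameter <- vapply(m, `[`, "", 2L)
  sensor <- vapply(m, `[`, "", 3L)
  task <- as.integer(vapply(m, `[`, "", 4L))
  data.frame(key = keys, parameter = parameter, sensor = sensor, task = task,
             param_group = unname(.PARAM_GROUPS[parameter]),
             imu = ifelse(substr(sensor, 2, 2) == "1", "IMU1", "IMU2"),
             stringsAsFactors = FALSE)
}

#' Extract the per-trial feature matrix of a cohort
#'
#' Preprocesses every (participant, task, trial, sensor) recording with
#' [preprocess_trial()] and computes the 18 parameters, assembling one row per
#' (participant, trial) with the 324 canonical columns.
#'
#' @param cohort An `imu_cohort` from [simulate_cohort_signals()].
#' @param cfg A [param_config()].
#' @return data.frame with `participant_id`, `age`, `group`, `trial` and the
#'   324 feature columns.
#' @export
extract_feature_matrix <- function(cohort, cfg = param_config()) {
  stopifnot(inherits(cohort, "imu_cohort"))
  spec <- cohort$spec
  cols <- feature_grid()
  rows <- list()
  for (p in cohort$participants) {
    for (tr in seq_len(spec$n_trials)) {
      v <- numeric(0)
      for (task in 1:3) {
        for (s in .SENSORS) {
          res <- preprocess_trial(p$signals[[task]][[tr]][[s]], spec$fs)
          f <- extract_features(res, spec$fs, cfg)
          names(f) <- paste0(.PARAMS, "_", s, "_T", task)
          v <- c(v, f)
        }
      }
      rows[[length(rows) + 1L]] <- c(list(participant_id = p$id, age = p$age,
                                          group = p$group, trial = tr),
                                     as.list(v[cols]))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE)
  }))
  rownames(out) <- NULL
  out
}
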