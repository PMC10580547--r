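# Synthetic cohort generator. Every downstream stage is testable without the
# (non-public) study recordings: the generator states an aging "world" --
# 8 decade groups, tremor-band oscillations whose amplitude and noise ratio
# drift with age, redundant feature pairs, occasional extreme outliers -- and
# exports a ground-truth registry so recovery can be scored.

.GROUP_SIZES <- c(13L, 12L, 13L, 15L, 11L, 14L, 13L, 8L)
.GROUP_AGE_MEANS <- c(24.53, 35.17, 45.15, 54.87, 64.45, 74.71, 84.53, 93.62)
.GROUP_AGE_SDS <- c(3.09, 3.16, 3.02, 3.02, 2.87, 2.84, 2.87, 2.67)
.SENSORS <- c("A1", "A2", "G1", "G2", "M1", "M2")

#' Cohort specification
#'
#' Defaults reproduce the study design: 8 age groups of sizes
#' 13, 12, 13, 15, 11, 14, 13, 8 (99 participants), decade-band ages with the
#' published means/sds, 50 Hz sampling, three 5-second trials of each of three
#' tasks (rest, pinch, pronation/supination).
#'
#' @param group_sizes Eight positive integers.
#' @param group_age_means,group_age_sds Age distribution per group, years.
#' @param seed Integer seed controlling all randomness of the generator.
#' @param fs Sampling frequency, Hz.
#' @param trial_duration Trial length, seconds (>= 1).
#' @param n_trials Trials per task.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = .GROUP_SIZES,
                        group_age_means = .GROUP_AGE_MEANS,
                        group_age_sds = .GROUP_AGE_SDS,
                        seed = 1L, fs = 50, trial_duration = 5, n_trials = 3L) {
  if (any(group_sizes <= 0)) stop("group sizes must be positive")
  if (trial_duration < 1) stop("trial_duration must be at least 1 s")
  stopifnot(length(group_sizes) == length(group_age_means),
            length(group_sizes) == length(group_age_sds))
  structure(list(group_sizes = as.integer(group_sizes),
                 group_age_means = group_age_means,
                 group_age_sds = group_age_sds,
                 seed = as.integer(seed), fs = fs,
                 trial_duration = trial_duration,
                 n_trials = as.integer(n_trials)),
            class = "cohort_spec")
}

#' Aging effect model for the synthetic cohort
#'
#' Controls how strongly the generated data carry an age signal. Defaults are
#' the canonical world used throughout the package: a third of features carry
#' a linear age trend (mirroring the fraction of features the axis search
#' retains), a per-year drift of 0.03 noise-SD units, unit feature noise, and
#' 2 percent extreme-outlier contamination.
#'
#' @param affected_fraction Proportion of features (or signal strength) with an
#'   age trend, in (0, 1].
#' @param slope_scale Per-year drift of affected quantities.
#' @param duplicate_pairs Number of injected near-duplicate feature columns
#'   (pairwise correlation above 0.9).
#' @param contamination_rate Probability a value is replaced by an extreme
#'   outlier, in \[0, 0.1\].
#' @param noise_sd Baseline noise standard deviation.
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(affected_fraction = 1 / 3, slope_scale = 0.03,
                         duplicate_pairs = 12L, contamination_rate = 0.02,
                         noise_sd = 1) {
  if (affected_fraction <= 0 || affected_fraction > 1) {
    stop("affected_fraction must lie in (0, 1]")
  }
  if (contamination_rate < 0 || contamination_rate > 0.1) {
    stop("contamination_rate must lie in [0, 0.1]")
  }
  structure(list(affected_fraction = affected_fraction,
                 slope_scale = slope_scale,
                 duplicate_pairs = as.integer(duplicate_pairs),
                 contamination_rate = contamination_rate,
                 noise_sd = noise_sd),
            class = "effect_model")
}

# ages drawn Gaussian per group, truncated to non-overlapping decade bands
# (group g spans [20 + 10 (g-1), 20 + 10 g])
.draw_ages <- function(spec) {
  unlist(lapply(seq_along(spec$group_sizes), function(g) {
    lo <- 20 + 10 * (g - 1)
    hi <- 20 + 10 * g
    out <- numeric(0)
    while (length(out) < spec$group_sizes[g]) {
      a <- stats::rnorm(spec$group_sizes[g], spec$group_age_means[g],
                        spec$group_age_sds[g])
      out <- c(out, a[a >= lo & a < hi])
    }
    out[seq_len(spec$group_sizes[g])]
  }))
}

#' Simulate raw multi-sensor cohort recordings
#'
#' Signal model: a band-limited oscillation at a participant-specific tremor
#' frequency (about 5 Hz) plus Gaussian noise. Both the oscillation amplitude
#' and the noise-to-signal ratio drift linearly with age, so every parameter
#' family (amplitude, frequency, entropy, statistics) responds. Magnetometer
#' streams are low-amplitude slow drift plus noise with a quarter-strength age
#' effect, reflecting their weak discriminative role.
#'
#' @param spec A [cohort_spec()].
#' @param effect An [effect_model()].
#' @return An object of class `imu_cohort`: a list with `participants` (each
#'   carrying `id`, `age`, `group` and `signals[[task]][[trial]][[sensor]]`,
#'   an N x 3 axis matrix), the `spec`, and a ground-truth `registry`
#'   (per-participant oscillation frequency and amplitude scale).
#' @export
simulate_cohort_signals <- function(spec = cohort_spec(),
                                    effect = effect_model()) {
  set.seed(spec$seed)
  ages <- .draw_ages(spec)
  groups <- rep(seq_along(spec$group_sizes), spec$group_sizes)
  n <- length(ages)
  nsamp <- round(spec$fs * spec$trial_duration)
  tt <- (seq_len(nsamp) - 1) / spec$fs
  f0 <- stats::rnorm(n, 5, 0.5)
  # per-task base amplitude: pinch (task 2) is the most demanding task
  task_amp <- c(1, 1.4, 1.2)
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    drift <- 1 + effect$slope_scale * (ages[i] - 20)
    amp_i <- drift                               # oscillation grows with age
    nsr_i <- effect$noise_sd * (0.3 + 0.5 * effect$slope_scale * (ages[i] - 20))
    signals <- vector("list", 3L)
    for (task in 1:3) {
      trials <- vector("list", spec$n_trials)
      for (tr in seq_len(spec$n_trials)) {
        sens <- lapply(.SENSORS, function(s) {
          type <- substr(s, 1, 1)
          phase <- stats::runif(3, 0, 2 * pi)
          if (type == "M") {
            # slow drift, weak age effect
            a <- 0.1 * (1 + 0.25 * effect$slope_scale * (ages[i] - 20))
            base <- sapply(phase, function(ph) a * sin(2 * pi * 0.3 * tt + ph))
            noise <- matrix(stats::rnorm(nsamp * 3, 0, 0.05), nsamp, 3)
          } else {
            gain <- if (type == "G") 0.8 else 1
            a <- gain * amp_i * task_amp[task]
            base <- sapply(phase, function(ph) a * sin(2 * pi * f0[i] * tt + ph))
            noise <- matrix(stats::rnorm(nsamp * 3, 0, a * nsr_i), nsamp, 3)
          }
          m <- base + noise
          colnames(m) <- c("x", "y", "z")
          m
        })
        names(sens) <- .SENSORS
        trials[[tr]] <- sens
      }
      signals[[task]] <- trials
    }
    participants[[i]] <- list(id = sprintf("P%03d", i), age = ages[i],
                              group = groups[i], signals = signals)
  }
  structure(list(participants = participants, spec = spec, effect = effect,
                 registry = list(f0 = f0, amplitude_scale =
                                   1 + effect$slope_scale * (ages - 20)),
                 ages = ages, groups = groups),
            class = "imu_cohort")
}

#' Simulate a participant-level feature matrix directly
#'
#' Feature-level shortcut for exercising the reduction and axis-search stages
#' without signal extraction. Affected columns follow
#' `mu_j + gamma_j * age + noise`; the last `duplicate_pairs` columns are noisy
#' near-copies of earlier columns (correlation above 0.9); contamination
#' replaces values with extremes far beyond the interquartile fences. The
#' ground-truth registry records affected columns, duplicate pairs, and
#' injected outlier positions.
#'
#' @param spec A [cohort_spec()] (only ages/groups/seed are used).
#' @param effect An [effect_model()].
#' @param n_features Number of feature columns (>= 2).
#' @return A `feature_set` (see [feature_set()]) with attribute `registry`.
#' @export
simulate_feature_matrix <- function(spec = cohort_spec(),
                                    effect = effect_model(),
                                    n_features = 155L) {
  if (n_features < 2) stop("n_features must be at least 2")
  if (effect$duplicate_pairs >= n_features) {
    stop("duplicate_pairs must be smaller than n_features")
  }
  set.seed(spec$seed)
  ages <- .draw_ages(spec)
  groups <- rep(seq_along(spec$group_sizes), spec$group_sizes)
  n <- length(ages)
  p_base <- n_features - effect$duplicate_pairs
  n_aff <- max(1L, round(effect$affected_fraction * p_base))
  affected <- sort(sample.int(p_base, n_aff))
  gamma <- numeric(p_base)
  gamma[affected] <- effect$slope_scale *
    sample(c(-1, 1), n_aff, replace = TRUE) * stats::runif(n_aff, 0.5, 1.5)
  mu <- stats::runif(p_base, -1, 1)
  x <- matrix(stats::rnorm(n * p_base, 0, effect$noise_sd), n, p_base)
  x <- sweep(x, 2, mu, "+") + outer(ages, gamma)
  # contamination on the base columns: values far outside the fences
  outliers <- matrix(FALSE, n, p_base)
  if (effect$contamination_rate > 0) {
    hit <- matrix(stats::runif(n * p_base) < effect$contamination_rate,
                  n, p_base)
    for (j in which(colSums(hit) > 0)) {
      i <- which(hit[, j])
      sdj <- stats::sd(x[, j])
      x[i, j] <- mean(x[, j]) +
        sample(c(-1, 1), length(i), replace = TRUE) *
          stats::runif(length(i), 8, 15) * sdj
      outliers[i, j] <- TRUE
    }
  }
  # near-duplicate columns: redundant readouts of an existing column, so a
  # contaminated trial corrupts both members of the pair coherently
  dup_src <- integer(0)
  if (effect$duplicate_pairs > 0) {
    dup_src <- sample.int(p_base, effect$duplicate_pairs,
                          replace = effect$duplicate_pairs > p_base)
    dups <- sapply(dup_src, function(j) {
      clean_sd <- stats::sd(x[!outliers[, j], j])
      x[, j] + stats::rnorm(n, 0, 0.2 * clean_sd)
    })
    x <- cbind(x, dups)
    outliers <- cbind(outliers, outliers[, dup_src, drop = FALSE])
  }
  colnames(x) <- sprintf("V%03d", seq_len(ncol(x)))
  fs <- feature_set(x, ages = ages, groups = groups,
                    ids = sprintf("P%03d", seq_len(n)))
  attr(fs, "registry") <- list(
    affected = affected, gamma = gamma,
    duplicate_pairs = if (length(dup_src) > 0)
      cbind(source = dup_src, copy = p_base + seq_along(dup_src)) else NULL,
    outliers = which(outliers, arr.ind = TRUE))
  fs
}

#' Feature set container
#'
#' Participants-by-features value matrix plus the cohort labels that travel
#' with it through reduction and axis search.
#'
#' @param x Numeric matrix, rows = participants, named columns = features.
#' @param ages Numeric vector of ages (years).
#' @param groups Integer group labels (1-8 in the standard design).
#' @param ids Participant identifiers.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(x, ages, groups, ids = rownames(x)) {
  stopifnot(is.matrix(x), nrow(x) == length(ages), nrow(x) == length(groups))
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%03d", seq_len(ncol(x)))
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(x)))
  structure(list(x = x, ages = ages, groups = as.integer(groups), ids = ids),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", nrow(x$x), " participants x ", ncol(x$x),
      " features, ", length(unique(x$groups)), " groups\n", sep = "")
  invisible(x)
}

#' Write a cohort or feature set to CSV files
#'
#' `write_cohort_csv` writes one CSV per participant-task-trial (columns
#' `time`, then `<sensor>_<axis>`) plus a manifest; `write_feature_csv` writes
#' a features CSV and a labels CSV.
#'
#' @param cohort An `imu_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest (or file paths).
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort$spec
  manifest <- data.frame(participant_id = sapply(cohort$participants, `[[`, "id"),
                         age = cohort$ages, group = cohort$groups)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (p in cohort$participants) {
    for (task in 1:3) {
      for (tr in seq_len(spec$n_trials)) {
        sens <- p$signals[[task]][[tr]]
        n <- nrow(sens[[1]])
        df <- data.frame(time = (seq_len(n) - 1) / spec$fs)
        for (s in names(sens)) {
          for (axn in colnames(sens[[s]])) {
            df[[paste0(s, "_", axn)]] <- sens[[s]][, axn]
          }
        }
        utils::write.csv(df, file.path(dir, sprintf("%s_T%d_trial%d.csv",
                                                    p$id, task, tr)),
                         row.names = FALSE)
      }
    }
  }
  invisible(manifest)
}

#' @rdname write_cohort_csv
#' @param fs A `feature_set`.
#' @param path Base path; `<path>_features.csv` and `<path>_labels.csv` are
#'   written.
#' @export
write_feature_csv <- function(fs, path) {
  fcsv <- paste0(path, "_features.csv")
  lcsv <- paste0(path, "_labels.csv")
  utils::write.csv(data.frame(participant_id = fs$ids, fs$x,
                              check.names = FALSE),
                   fcsv, row.names = FALSE)
  utils::write.csv(data.frame(participant_id = fs$ids, age = fs$ages,
                              group = fs$groups),
                   lcsv, row.names = FALSE)
  invisible(c(fcsv, lcsv))
}

#' Read a feature set from CSV files written by [write_feature_csv()]
#'
#' @param path Base path used when writing.
#' @return A `feature_set`.
#' @export
read_feature_csv <- function(path) {
  fdf <- utils::read.csv(paste0(path, "_features.csv"), check.names = FALSE)
  ldf <- utils::read.csv(paste0(path, "_labels.csv"))
  x <- as.matrix(fdf[, setdiff(names(fdf), "participant_id"), drop = FALSE])
  feature_set(x, ages = ldf$age, groups = ldf$group, ids = ldf$participant_id)
}
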