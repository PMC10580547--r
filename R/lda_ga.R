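# The core method: min-max + 0.1 normalization, hyperspherical representation,
# cosine-product axis projection ("LDA-value"), pairwise separability fitness
# E_z, real-coded genetic algorithm over the rotation angles, relevance
# elimination, and evaluation of the published 46-offset axis.

#' Genetic-algorithm configuration
#'
#' Production defaults follow the published run: 50,000 epochs, population of
#' 50 axes, 8 classes, mutation probability 0.1, crossover probability 0.8,
#' relevance threshold 1 percent. Use fewer epochs (e.g. 2000) for tests and
#' exploratory runs.
#'
#' @param epochs Number of GA generations.
#' @param s Population size (number of candidate axes).
#' @param xi Number of classes (groups).
#' @param p_mutation Per-gene mutation probability (`mutation = "gene"`), or
#'   per-individual probability of redrawing one random gene
#'   (`mutation = "individual"`).
#' @param p_crossover Probability a selected parent pair is replaced by its two
#'   best children.
#' @param seed Integer seed for the GA's randomness.
#' @param relevance_threshold Minimum relative change of the separability
#'   estimator for a feature to be kept (default 0.01 = 1 percent).
#' @param ez_epsilon Variance floor guarding the separability denominator.
#' @param mutation `"gene"` or `"individual"`.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(epochs = 50000L, s = 50L, xi = 8L, p_mutation = 0.1,
                      p_crossover = 0.8, seed = 1L,
                      relevance_threshold = 0.01, ez_epsilon = 1e-12,
                      mutation = c("gene", "individual")) {
  if (s < 2) stop("population size must be at least 2")
  structure(list(epochs = as.integer(epochs), s = as.integer(s),
                 xi = as.integer(xi), p_mutation = p_mutation,
                 p_crossover = p_crossover, seed = as.integer(seed),
                 relevance_threshold = relevance_threshold,
                 ez_epsilon = ez_epsilon, mutation = match.arg(mutation)),
            class = "ga_config")
}

#' Min-max normalization with a 0.1 offset
#'
#' Each column is mapped to \[0, 1\] by its range, then shifted by 0.1 so every
#' entry is strictly positive: the hyperspherical radius is then positive and
#' every angle well defined. Constant columns map to all-0.1 (warning).
#'
#' @param fs A [feature_set()] (or bare numeric matrix).
#' @return Object of the same kind with values in \[0.1, 1.1\].
#' @examples
#' normalize_columns(matrix(c(2, 4, 6), ncol = 1))  # 0.1, 0.6, 1.1
#' @export
normalize_columns <- function(fs) {
  x <- if (inherits(fs, "feature_set")) fs$x else as.matrix(fs)
  rng <- apply(x, 2, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    warning("constant column(s) normalized to all 0.1: ",
            paste(colnames(x)[span == 0], collapse = ", "))
  }
  y <- sweep(x, 2, rng[1, ], "-")
  y <- sweep(y, 2, ifelse(span == 0, 1, span), "/") + 0.1
  if (inherits(fs, "feature_set")) {
    out <- feature_set(y, fs$ages, fs$groups, fs$ids)
    attr(out, "normalized") <- TRUE
    out
  } else {
    y
  }
}

#' Hyperspherical representation of positive vectors
#'
#' Each row `c` of the matrix becomes a radius `p = ||c||` and `n - 1` angles
#' `theta_k = atan(c[k + 1] / ||c[1:k]||)`. For strictly positive input every
#' angle lies in (0, pi/2) and the reconstruction identity
#' `p * prod(cos(theta)) = c[1]` holds.
#'
#' @param x Numeric matrix (rows = observations) or a single positive vector.
#' @return List with `p` (radius per row) and `theta` (rows x (n-1) angle
#'   matrix).
#' @examples
#' to_hyperspherical(c(3, 4))  # p = 5, theta = atan(4/3)
#' @export
to_hyperspherical <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(x <= 0)) stop("hyperspherical representation requires positive entries")
  n <- ncol(x)
  if (n < 2) stop("need at least 2 coordinates")
  cums <- t(apply(x^2, 1, cumsum))
  if (nrow(x) == 1) cums <- matrix(cums, nrow = 1)
  p <- sqrt(cums[, n])
  theta <- atan(x[, -1, drop = FALSE] / sqrt(cums[, -n, drop = FALSE]))
  list(p = p, theta = theta)
}

#' Project hyperspherical data onto a rotated axis
#'
#' The scalar projection `p * prod_k cos(theta_k + axis_k)`. With a zero axis
#' this returns the first normalized coordinate.
#'
#' @param p Radius (scalar or vector).
#' @param theta Angle vector, or matrix with one row per observation.
#' @param axis Rotation-angle vector of the same length as each `theta` row.
#' @return Numeric vector of projections.
#' @export
project_lda_value <- function(p, theta, axis) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (length(axis) != ncol(theta)) {
    stop("axis length (", length(axis), ") must match angle count (",
         ncol(theta), ")")
  }
  as.vector(.project_population_cpp(theta, p, matrix(axis, nrow = 1)))
}

#' Pairwise group-separability estimator
#'
#' Sum over all unordered class pairs of the absolute standardized mean
#' difference `|mean_i - mean_j| / sqrt(var_i + var_j)` with population
#' variances; the GA's fitness. The denominator is floored at `eps` so
#' degenerate zero-variance pairs stay finite.
#'
#' @param values Numeric projection per participant.
#' @param groups Integer group labels.
#' @param eps Variance floor.
#' @return Scalar separability.
#' @examples
#' separability_ez(c(-1, 1, 2, 4), c(1, 1, 2, 2))  # 3 / sqrt(2)
#' @export
separability_ez <- function(values, groups, eps = 1e-12) {
  groups <- as.integer(factor(groups))
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  .ez_batch_cpp(matrix(values, ncol = 1), groups, max(groups), eps)[1]
}

#' Initial GA population
#'
#' `s` candidate axes with every rotation angle drawn uniformly on \[0, 2*pi).
#'
#' @param cfg A [ga_config()].
#' @param n_angles Number of rotation angles per axis.
#' @return `s x n_angles` numeric matrix.
#' @export
init_population <- function(cfg, n_angles) {
  if (n_angles < 1) stop("need at least one angle")
  matrix(stats::runif(cfg$s * n_angles, 0, 2 * pi), cfg$s, n_angles)
}

#' One GA generation
#'
#' Roulette-wheel selection proportional to fitness (uniform fallback when all
#' fitness is zero) forms the mating matrix, traversed in consecutive pairs
#' (an odd last individual passes through). With probability `p_crossover` a
#' pair is replaced by the two fittest of its three arithmetic children
#' `1.5 p1 - 0.5 p2`, `0.5 p1 + 0.5 p2`, `-0.5 p1 + 1.5 p2` (wrapped to
#' \[0, 2*pi)). Genes then mutate to fresh uniform angles, and the best axis of
#' the incoming generation survives unmodified in the last slot (elitism).
#'
#' @param population `s x k` matrix of axes.
#' @param fitness Fitness (separability) of each row.
#' @param cfg A [ga_config()].
#' @param fitness_fn Function mapping an axis matrix to a fitness vector, used
#'   to rank children.
#' @return The next-generation `s x k` matrix.
#' @export
evolve_generation <- function(population, fitness, cfg, fitness_fn) {
  s <- nrow(population)
  if (s < 2) stop("population size must be at least 2")
  two_pi <- 2 * pi
  prob <- if (sum(fitness) > 0) fitness / sum(fitness) else rep(1 / s, s)
  elite <- population[which.max(fitness), ]
  K <- population[sample.int(s, s, replace = TRUE, prob = prob), , drop = FALSE]
  newpop <- K
  pair_starts <- seq(1, s - 1, by = 2)
  cross <- stats::runif(length(pair_starts)) < cfg$p_crossover
  if (any(cross)) {
    kids <- list()
    for (i in pair_starts[cross]) {
      p1 <- K[i, ]
      p2 <- K[i + 1, ]
      kids[[length(kids) + 1L]] <- rbind(1.5 * p1 - 0.5 * p2,
                                         0.5 * p1 + 0.5 * p2,
                                         -0.5 * p1 + 1.5 * p2) %% two_pi
    }
    child_fit <- fitness_fn(do.call(rbind, kids))
    for (ci in seq_along(kids)) {
      f3 <- child_fit[(3 * ci - 2):(3 * ci)]
      best2 <- order(f3, decreasing = TRUE)[1:2]
      i <- pair_starts[cross][ci]
      newpop[c(i, i + 1), ] <- kids[[ci]][best2, ]
    }
  }
  if (cfg$mutation == "gene") {
    mut <- stats::runif(length(newpop)) < cfg$p_mutation
    newpop[mut] <- stats::runif(sum(mut), 0, two_pi)
  } else {
    hit <- which(stats::runif(s) < cfg$p_mutation)
    for (i in hit) {
      j <- sample.int(ncol(newpop), 1)
      newpop[i, j] <- stats::runif(1, 0, two_pi)
    }
  }
  newpop[s, ] <- elite
  newpop
}

#' Run the genetic axis search
#'
#' Projects every participant onto every candidate axis each generation,
#' scores axes with [separability_ez()], and evolves the population with
#' [evolve_generation()]. Deterministic given `cfg$seed`.
#'
#' @param C A normalized [feature_set()] (entries in \[0.1, 1.1\], see
#'   [normalize_columns()]).
#' @param cfg A [ga_config()].
#' @return An object of class `lda_result`: `best_axis`, per-participant
#'   `lda_values`, `ez_best`, the best-so-far `ez_trace`, and `internals`
#'   (final projection matrix `A`, fitness vector `ez_vec`, and the
#'   hyperspherical representation).
#' @export
run_ga <- function(C, cfg = ga_config()) {
  stopifnot(inherits(C, "feature_set"))
  if (ncol(C$x) < 2) stop("need at least 2 features")
  groups <- as.integer(factor(C$groups))
  ngroups <- max(groups)
  hs <- to_hyperspherical(C$x)
  k <- ncol(hs$theta)
  fitness_fn <- function(pop) {
    .ez_batch_cpp(.project_population_cpp(hs$theta, hs$p, pop),
                  groups, ngroups, cfg$ez_epsilon)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- init_population(cfg, k)
  fit <- fitness_fn(pop)
  best_i <- which.max(fit)
  best_axis <- pop[best_i, ]
  best_ez <- fit[best_i]
  trace <- numeric(cfg$epochs)
  for (g in seq_len(cfg$epochs)) {
    pop <- evolve_generation(pop, fit, cfg, fitness_fn)
    fit <- fitness_fn(pop)
    gi <- which.max(fit)
    if (fit[gi] > best_ez) {
      best_ez <- fit[gi]
      best_axis <- pop[gi, ]
    }
    trace[g] <- best_ez
  }
  lda <- project_lda_value(hs$p, hs$theta, best_axis)
  structure(list(best_axis = best_axis, lda_values = lda, ez_best = best_ez,
                 ez_trace = trace, groups = C$groups, ages = C$ages,
                 ids = C$ids, feature_names = colnames(C$x),
                 internals = list(A = .project_population_cpp(hs$theta, hs$p, pop),
                                  ez_vec = fit, hyperspherical = hs)),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  cat("<lda_result> ", length(x$lda_values), " participants, ",
      length(x$best_axis) + 1L, " features, E_z = ",
      format(x$ez_best, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Relevance filtering of features
#'
#' The relevance of a feature is the relative change of the separability
#' estimator when that feature is held at its column mean (removing its
#' variation without changing the dimensionality of the axis):
#' `|E_z(full) - E_z(feature k frozen)| / E_z(full)`. Features below the
#' threshold (default 1 percent) are eliminated and the hyperspherical
#' representation is recomputed on the survivors.
#'
#' @param C Normalized [feature_set()] the axis was fitted on.
#' @param best_axis Rotation-angle vector from [run_ga()].
#' @param cfg A [ga_config()] (threshold and variance floor).
#' @return List with `relevance` (per feature), logical `mask`, and `reduced`
#'   (the surviving-columns `feature_set`). If everything falls below the
#'   threshold the single most relevant feature pair is kept with a warning.
#' @export
relevance_filter <- function(C, best_axis, cfg = ga_config()) {
  stopifnot(inherits(C, "feature_set"))
  groups <- as.integer(factor(C$groups))
  ngroups <- max(groups)
  hs <- to_hyperspherical(C$x)
  ez_of <- function(x) {
    h <- to_hyperspherical(x)
    v <- project_lda_value(h$p, h$theta, best_axis)
    .ez_batch_cpp(matrix(v, ncol = 1), groups, ngroups, cfg$ez_epsilon)[1]
  }
  ez_full <- ez_of(C$x)
  p <- ncol(C$x)
  relevance <- vapply(seq_len(p), function(j) {
    xm <- C$x
    xm[, j] <- mean(xm[, j])
    abs(ez_full - ez_of(xm)) / ez_full
  }, numeric(1))
  names(relevance) <- colnames(C$x)
  mask <- relevance >= cfg$relevance_threshold
  if (sum(mask) < 2) {
    warning("fewer than 2 features pass the relevance threshold; ",
            "keeping the 2 most relevant")
    mask[order(relevance, decreasing = TRUE)[1:2]] <- TRUE
  }
  list(relevance = relevance, mask = mask,
       reduced = feature_set(C$x[, mask, drop = FALSE], C$ages, C$groups,
                             C$ids),
       ez_full = ez_full)
}

#' Full LDA-value estimation chain
#'
#' Normalize, represent in hyperspherical coordinates, run the genetic axis
#' search, eliminate irrelevant features (below 1 percent separability
#' contribution), re-run the search on the survivors, and report the final
#' per-participant LDA-values. The separability estimator is invariant to a
#' reflection of the axis, so the final axis is oriented to make group-mean
#' LDA-values increase with group index (first rotation angle shifted by pi
#' otherwise).
#'
#' @param fs A participant-level [feature_set()] (after reduction).
#' @param cfg A [ga_config()]; the second search derives its seed from
#'   `cfg$seed + 1` so the two stages can be reproduced in isolation.
#' @return An `lda_result` with additional fields `relevant_mask` (over the
#'   columns of `fs`), `relevance`, `ez_trace_initial` (first-stage trace),
#'   and `pearson_age` (correlation of the final values with age).
#' @export
estimate_lda_value <- function(fs, cfg = ga_config()) {
  stopifnot(inherits(fs, "feature_set"))
  C <- normalize_columns(fs)
  stage1 <- run_ga(C, cfg)
  rf <- relevance_filter(C, stage1$best_axis, cfg)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  final <- run_ga(rf$reduced, cfg2)
  # orientation: make group means increase with group index
  gm <- tapply(final$lda_values, final$groups, mean)
  ord <- order(as.numeric(names(gm)))
  if (stats::cor(as.numeric(names(gm))[ord], gm[ord],
                 method = "spearman") < 0) {
    final$best_axis[1] <- (final$best_axis[1] + pi) %% (2 * pi)
    final$lda_values <- -final$lda_values
  }
  final$relevant_mask <- rf$mask
  final$relevance <- rf$relevance
  final$ez_trace_initial <- stage1$ez_trace
  final$pearson_age <- stats::cor(final$lda_values, fs$ages)
  final
}

#' The published 46-offset rotation axis
#'
#' The printed aging-axis equation carries 46 numeric rotation offsets, indexed
#' by the 46 lettered relevant features (letters a-z plus A-U, the letter R
#' being reserved for the radius). The letters' task and parameter are
#' recoverable from the printed table; the sensor assignment is not preserved
#' by the table layout and is therefore omitted. These constants are shipped
#' for evaluation only -- they arise from the original non-public cohort and
#' are not re-derived.
#'
#' @return List with `offsets` (length 46), `labels` (the letters), and
#'   `features` (data.frame letter/task/parameter).
#' @export
published_axis <- function() {
  offsets <- c(2.33, 2.85, 2.21, 2.08, 3.03, 2.50, 2.70, 0.31, 2.62, 2.70,
               2.78, 2.98, 3.03, 3.06, 2.96, 0.18, 3.02, 3.09, 3.20, 8.73,
               -0.16, -6.55, 0.10, 2.89, 2.98, 2.60, 2.90, 2.91, 0.05, 3.41,
               2.55, 2.96, 3.14, 0.18, -3.33, -0.33, 0.34, 0.05, 0.14, 3.02,
               -0.21, 2.82, 2.93, 3.06, 3.07, 0.02)
  labels <- c(letters, setdiff(LETTERS, "R")[1:20])
  param_by_letter <- c(
    a = "MAV", f = "MAV", b = "MAVFD", g = "MAVFD", k = "MAVFD", x = "MAVFD",
    c = "Peak", l = "Peak", y = "Peak", d = "ZC", s = "ZC",
    e = "FMean", h = "FMean", m = "FMean", i = "FPeak", o = "FPeak",
    t = "FPeak", p = "F50", q = "F80",
    n = "Power3.5_7.5", u = "Power3.5_7.5", z = "Power3.5_7.5",
    r = "ApEn", v = "ApEn", A = "ApEn", w = "VAR", j = "SKEWNESS",
    B = "ZC", E = "ZC", I = "ZC", F = "FMean", C = "FPeak", K = "FPeak",
    G = "F50", J = "F50", L = "F50", H = "ApEn", D = "SKEWNESS",
    M = "SKEWNESS",
    O = "ZC", S = "ZC", N = "FPeak", P = "ApEn", T = "ApEn",
    Q = "SKEWNESS", U = "KURTOSIS")
  # task 1 runs through the lowercase letters and "A"; task 2 uses B-M;
  # task 3 the remaining N-U (R excluded)
  task_by_letter <- ifelse(labels %in% c(letters, "A"), 1L,
                           ifelse(labels %in% c("B", "C", "D", "E", "F", "G",
                                                "H", "I", "J", "K", "L", "M"),
                                  2L, 3L))
  list(offsets = offsets, labels = labels,
       features = data.frame(letter = labels, task = task_by_letter,
                             parameter = unname(param_by_letter[labels]),
                             stringsAsFactors = FALSE))
}

#' Evaluate the published axis
#'
#' `R * prod_k cos(theta_k + offset_k)` with the 46 published offsets. Note the
#' published equation indexes 46 angles although 46 features would yield 45
#' under the hyperspherical construction; the evaluator follows the printed
#' 46-term form and requires a 46-length angle vector.
#'
#' @param theta Numeric vector of 46 angles (or matrix with 46 columns).
#' @param R Radius (scalar or per-row vector).
#' @param axis A [published_axis()] (or compatible list with `offsets`).
#' @return Numeric projection(s).
#' @export
evaluate_published_axis <- function(theta, R, axis = published_axis()) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != length(axis$offsets)) {
    stop("theta must supply ", length(axis$offsets), " angles")
  }
  as.vector(R * apply(cos(sweep(theta, 2, axis$offsets, "+")), 1, prod))
}
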