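# Nonparametric screens and summaries: per-group normality, pooled
# young-vs-elderly feature tests, pairwise 8-group tests on the LDA-value,
# age correlation, and the tally views (rules a-g).

#' Per-feature, per-group normality screen
#'
#' Shapiro-Wilk p-value for every (feature, group) cell. Constant samples are
#' reported as `NA` with a warning. The overall flag `all_normal` is `TRUE`
#' only when every p-value is at least `alpha` -- in the standard workflow its
#' failure motivates rank-based tests downstream.
#'
#' @param fs A [feature_set()].
#' @param alpha Significance level (default 0.05).
#' @return List with matrix `p` (features x groups) and logical `all_normal`.
#' @export
normality_screen <- function(fs, alpha = 0.05) {
  stopifnot(inherits(fs, "feature_set"))
  gs <- sort(unique(fs$groups))
  if (any(table(fs$groups) < 3)) stop("every group needs at least 3 members")
  p <- matrix(NA_real_, ncol(fs$x), length(gs),
              dimnames = list(colnames(fs$x), paste0("G", gs)))
  warned <- FALSE
  for (j in seq_len(ncol(fs$x))) {
    for (gi in seq_along(gs)) {
      v <- fs$x[fs$groups == gs[gi], j]
      if (stats::sd(v) == 0) {
        warned <- TRUE
        next
      }
      p[j, gi] <- stats::shapiro.test(v)$p.value
    }
  }
  if (warned) warning("constant (feature, group) samples: normality p = NA")
  list(p = p, all_normal = all(p >= alpha, na.rm = FALSE))
}

#' Young-vs-elderly feature screen
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature comparing the
#' pooled young groups (1-4, under 60 by the WHO convention) against the
#' pooled elderly groups (5-8). No multiplicity correction by default,
#' mirroring per-feature screening tables; set `correct = "bonferroni"` (or
#' any [stats::p.adjust()] method) to correct.
#'
#' @param fs A [feature_set()].
#' @param young_groups Group indices pooled as "young" (default 1:4).
#' @param alpha Significance level (default 0.05).
#' @param correct Multiplicity correction method, default `"none"`.
#' @return data.frame with `feature`, `p_value`, `significant`.
#' @export
young_elderly_test <- function(fs, young_groups = 1:4, alpha = 0.05,
                               correct = "none") {
  stopifnot(inherits(fs, "feature_set"))
  young <- fs$groups %in% young_groups
  if (!any(young) || all(young)) stop("both pooled groups must be non-empty")
  p <- vapply(seq_len(ncol(fs$x)), function(j) {
    a <- fs$x[young, j]
    b <- fs$x[!young, j]
    if (length(unique(c(a, b))) == 1) {
      warning("all-tied feature ", colnames(fs$x)[j], ": p = 1")
      return(1)
    }
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, numeric(1))
  p <- stats::p.adjust(p, method = correct)
  data.frame(feature = colnames(fs$x), p_value = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Pairwise group tests on the LDA-value
#'
#' Omnibus Kruskal-Wallis over all groups, then Bonferroni-corrected pairwise
#' two-sided Mann-Whitney tests (28 pairs for 8 groups). Dunn's z-test is
#' available as the post hoc alternative.
#'
#' @param values Numeric per-participant values (e.g. LDA-values).
#' @param groups Integer group labels, each group with >= 2 members.
#' @param alpha Significance level.
#' @param posthoc `"wilcoxon"` (default) or `"dunn"`.
#' @return List with `kruskal_p`, symmetric matrix `p` of corrected pairwise
#'   p-values (`NA` diagonal), matrix `significant`, and `n_pairs`.
#' @export
pairwise_group_test <- function(values, groups, alpha = 0.05,
                                posthoc = c("wilcoxon", "dunn")) {
  posthoc <- match.arg(posthoc)
  gs <- sort(unique(groups))
  ng <- length(gs)
  if (ng < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  kp <- stats::kruskal.test(values, factor(groups))$p.value
  n_pairs <- ng * (ng - 1) / 2
  p <- matrix(NA_real_, ng, ng, dimnames = list(paste0("G", gs), paste0("G", gs)))
  rk <- rank(values)
  n <- length(values)
  ties <- table(rk)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  for (i in seq_len(ng - 1)) {
    for (j in (i + 1):ng) {
      a <- values[groups == gs[i]]
      b <- values[groups == gs[j]]
      praw <- if (posthoc == "wilcoxon") {
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
      } else {
        # Dunn: z of mean-rank difference with tie-corrected variance
        ri <- mean(rk[groups == gs[i]])
        rj <- mean(rk[groups == gs[j]])
        se <- sqrt(n * (n + 1) / 12 * tie_corr *
                     (1 / length(a) + 1 / length(b)))
        2 * stats::pnorm(-abs((ri - rj) / se))
      }
      p[i, j] <- p[j, i] <- min(1, praw * n_pairs)
    }
  }
  list(kruskal_p = kp, p = p, significant = p < alpha, n_pairs = n_pairs)
}

#' Pearson correlation between LDA-values and age
#'
#' @param values Numeric per-participant values.
#' @param ages Ages in years.
#' @return List with `r`, `p_value`, `n`.
#' @export
age_correlation <- function(values, ages) {
  if (length(values) < 3) stop("need at least 3 participants")
  if (stats::sd(values) == 0 || stats::sd(ages) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- stats::cor.test(values, ages)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(values))
}

#' Tally a significance (or relevance) table over the feature grid
#'
#' Implements the seven summary views: (a) counts per parameter, (b) counts
#' per parameter group (amplitude, frequency, statistic, entropy),
#' (c) parameter-group proportions of the total significant count, (d) counts
#' per task, (e) counts per sensor, (f) counts per sensor type (A1+A2, G1+G2,
#' M1+M2), (g) counts per IMU (A1+G1+M1 vs A2+G2+M2).
#'
#' @param table data.frame with columns `feature` (canonical
#'   `<param>_<sensor>_T<task>` names) and logical `significant` (e.g. from
#'   [young_elderly_test()]).
#' @return List of named count vectors `per_feature`, `per_param_group`,
#'   `per_param_group_proportion`, `per_task`, `per_sensor`,
#'   `per_sensor_type`, `per_imu`, plus `total`.
#' @export
tally_significant <- function(table) {
  if (nrow(table) == 0) stop("empty significance table")
  info <- parse_feature_key(table$feature)
  sig <- table$significant
  total <- sum(sig)
  cnt <- function(keys, levels) {
    v <- vapply(levels, function(l) sum(sig & keys == l), numeric(1))
    names(v) <- as.character(levels)
    v
  }
  per_param_group <- cnt(info$param_group,
                         c("amplitude", "frequency", "entropy", "statistic"))
  per_sensor <- cnt(info$sensor, .SENSORS)
  list(per_feature = cnt(info$parameter, .PARAMS),
       per_param_group = per_param_group,
       per_param_group_proportion = if (total > 0) per_param_group / total
                                    else per_param_group,
       per_task = cnt(info$task, 1:3),
       per_sensor = per_sensor,
       per_sensor_type = c(accelerometer = unname(per_sensor["A1"] + per_sensor["A2"]),
                           gyroscope = unname(per_sensor["G1"] + per_sensor["G2"]),
                           magnetometer = unname(per_sensor["M1"] + per_sensor["M2"])),
       per_imu = c(IMU1 = unname(per_sensor["A1"] + per_sensor["G1"] + per_sensor["M1"]),
                   IMU2 = unname(per_sensor["A2"] + per_sensor["G2"] + per_sensor["M2"])),
       total = total)
}
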