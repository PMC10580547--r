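# Reduction: interquartile-fence outlier handling at trial level, trial
# averaging, and greedy correlation pruning. Output is the complete
# participants-by-features matrix entering the axis search.

#' Interquartile outlier fences
#'
#' `lower = Q1 - 1.5 * IQR`, `upper = Q3 + 1.5 * IQR`, with quartiles under the
#' configured convention (linear interpolation by default).
#'
#' @param values Numeric vector of length >= 4.
#' @param quartile_type Quantile convention (see [stats::quantile()]).
#' @return Numeric `c(lower, upper)`.
#' @examples
#' iqr_fences(1:8)  # c(-2.5, 11.5)
#' @export
iqr_fences <- function(values, quartile_type = 7L) {
  if (length(values) < 4) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = quartile_type,
                       names = FALSE)
  iqr <- q[2] - q[1]
  c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
}

#' Flag and handle outliers in a per-trial feature table
#'
#' Fences are computed per feature within each age group, so genuine age
#' effects are not flagged as anomalies. Values beyond the fences are either
#' winsorized to the nearest fence (default; keeps the matrix complete) or set
#' to `NA` and excluded from trial averaging (`mode = "drop"`).
#'
#' @param trial_df Per-trial feature data.frame from [extract_feature_matrix()]
#'   (or any data.frame with `participant_id`, `group`, `trial` plus feature
#'   columns). A participant-level [feature_set()] is also accepted (and
#'   returned), for pipelines that operate on averaged or directly simulated
#'   matrices; there `mode = "drop"` falls back to winsorizing since a
#'   participant-level value has no sibling trials to average over.
#' @param mode `"winsorize"` (default) or `"drop"`.
#' @param quartile_type Quantile convention for the fences.
#' @return The data.frame with outliers handled, plus attribute `flags`: a
#'   data.frame of (participant_id, group, trial, feature, value) triples that
#'   were outside the fences (`trial` is `NA` at participant level).
#' @export
handle_outliers <- function(trial_df, mode = c("winsorize", "drop"),
                            quartile_type = 7L) {
  mode <- match.arg(mode)
  if (inherits(trial_df, "feature_set")) {
    fs <- trial_df
    df <- data.frame(participant_id = fs$ids, age = fs$ages,
                     group = fs$groups, trial = NA_integer_, fs$x,
                     check.names = FALSE)
    df <- handle_outliers(df, "winsorize", quartile_type)
    out <- feature_set(as.matrix(df[, colnames(fs$x), drop = FALSE]),
                       fs$ages, fs$groups, fs$ids)
    attr(out, "registry") <- attr(fs, "registry")
    attr(out, "flags") <- attr(df, "flags")
    return(out)
  }
  meta <- intersect(c("participant_id", "age", "group", "trial"),
                    names(trial_df))
  feats <- setdiff(names(trial_df), meta)
  flags <- list()
  for (g in unique(trial_df$group)) {
    idx <- which(trial_df$group == g)
    if (length(idx) < 4) {
      warning("group ", g, " has fewer than 4 trial rows; fences unstable")
    }
    for (f in feats) {
      v <- trial_df[[f]][idx]
      if (length(v) < 4) next
      fen <- iqr_fences(v, quartile_type)
      out <- v < fen[1] | v > fen[2]
      if (any(out)) {
        flags[[length(flags) + 1L]] <- data.frame(
          participant_id = trial_df$participant_id[idx][out],
          group = g, trial = trial_df$trial[idx][out], feature = f,
          value = v[out], stringsAsFactors = FALSE)
        repl <- if (mode == "winsorize") pmin(pmax(v[out], fen[1]), fen[2])
                else NA_real_
        trial_df[[f]][idx[out]] <- repl
      }
    }
  }
  attr(trial_df, "flags") <- if (length(flags) > 0) {
    do.call(rbind, flags)
  } else {
    data.frame(participant_id = character(0), group = integer(0),
               trial = integer(0), feature = character(0), value = numeric(0))
  }
  trial_df
}

#' Average surviving trials into a participant-level feature set
#'
#' Arithmetic mean of the (up to three) trial values per participant and
#' feature; `NA` trials (dropped outliers) are excluded. A participant-feature
#' cell with no surviving trial is imputed with the group median (warning).
#'
#' @param trial_df Per-trial feature data.frame (after [handle_outliers()]).
#' @return A [feature_set()].
#' @export
average_trials <- function(trial_df) {
  meta <- intersect(c("participant_id", "age", "group", "trial"),
                    names(trial_df))
  feats <- setdiff(names(trial_df), meta)
  ids <- unique(trial_df$participant_id)
  n <- length(ids)
  x <- matrix(NA_real_, n, length(feats), dimnames = list(ids, feats))
  ages <- numeric(n)
  groups <- integer(n)
  for (i in seq_len(n)) {
    rows <- trial_df$participant_id == ids[i]
    ages[i] <- trial_df$age[rows][1]
    groups[i] <- trial_df$group[rows][1]
    x[i, ] <- colMeans(trial_df[rows, feats, drop = FALSE], na.rm = TRUE)
  }
  if (anyNA(x)) {
    warning("participant-feature cells with zero surviving trials; ",
            "group-median imputation applied")
    for (j in which(colSums(is.na(x)) > 0)) {
      for (i in which(is.na(x[, j]))) {
        x[i, j] <- stats::median(x[groups == groups[i], j], na.rm = TRUE)
      }
    }
  }
  feature_set(x, ages = ages, groups = groups, ids = ids)
}

#' Prune highly correlated features
#'
#' Constant columns are removed first (flagged). Then a greedy scan in
#' canonical column order: a candidate column is removed when its absolute
#' Pearson correlation with any already-kept column exceeds the threshold
#' (keep-first tie-breaking; anti-correlated features are equally redundant,
#' hence the absolute value). No surviving pair exceeds the threshold.
#'
#' @param fs A [feature_set()].
#' @param threshold Correlation threshold in (0, 1); default 0.9.
#' @return The pruned `feature_set`, with attribute `report`: a list with
#'   `kept`, `pruned` (data.frame of feature, partner, r), and
#'   `constant_removed`.
#' @export
prune_correlated <- function(fs, threshold = 0.9) {
  stopifnot(inherits(fs, "feature_set"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  x <- fs$x
  sds <- apply(x, 2, stats::sd)
  constant <- colnames(x)[sds == 0]
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < 2) stop("need at least 2 non-constant columns")
  cm <- abs(stats::cor(x))
  kept <- integer(0)
  pruned <- list()
  for (j in seq_len(ncol(x))) {
    if (length(kept) > 0) {
      r <- cm[kept, j]
      hit <- which(r > threshold)
      if (length(hit) > 0) {
        partner <- kept[hit[which.max(r[hit])]]
        pruned[[length(pruned) + 1L]] <- data.frame(
          feature = colnames(x)[j], partner = colnames(x)[partner],
          r = cm[partner, j], stringsAsFactors = FALSE)
        next
      }
    }
    kept <- c(kept, j)
  }
  out <- feature_set(x[, kept, drop = FALSE], fs$ages, fs$groups, fs$ids)
  attr(out, "report") <- list(
    kept = colnames(x)[kept],
    pruned = if (length(pruned) > 0) do.call(rbind, pruned) else
      data.frame(feature = character(0), partner = character(0),
                 r = numeric(0)),
    constant_removed = constant)
  out
}
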