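make_fs <- function(x, groups, ages = NULL) {
  if (is.null(ages)) ages <- groups * 10 + 15
  feature_set(x, ages = ages, groups = groups)
}

test_that("normality screen behaves under null and heavy-tailed alternatives", {
  set.seed(1)
  reject_null <- 0
  reject_alt <- 0
  for (rep in 1:100) {
    g <- rnorm(50)
    if (stats::shapiro.test(g)$p.value < 0.05) reject_null <- reject_null + 1
    if (stats::shapiro.test(g^3)$p.value < 0.05) reject_alt <- reject_alt + 1
  }
  expect_lte(reject_null, 10)   # null: kept in at least 90% of repeats
  expect_gte(reject_alt, 90)    # cubed normals: rejected in at least 90%
  # package wrapper: per (feature, group) matrix, reproducible
  set.seed(2)
  x <- matrix(rnorm(120), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  fs <- make_fs(x, rep(1:2, each = 20))
  ns1 <- normality_screen(fs)
  ns2 <- normality_screen(fs)
  expect_identical(ns1$p, ns2$p)
  expect_equal(dim(ns1$p), c(3, 2))
  expect_true(all(ns1$p >= 0 & ns1$p <= 1))
})

test_that("young-elderly screen gives the exact rank-sum p on disjoint samples", {
  x <- matrix(c(1:5, 6:10), ncol = 1, dimnames = list(NULL, "f"))
  fs <- make_fs(x, groups = rep(c(1L, 5L), each = 5),
                ages = c(rep(30, 5), rep(70, 5)))
  tab <- young_elderly_test(fs)
  expect_equal(tab$p_value, 2 / choose(10, 5), tolerance = 1e-10)
  expect_true(tab$significant)
  # identical pooled groups: p = 1 (all-tied warning path)
  x2 <- matrix(rep(3, 10), ncol = 1, dimnames = list(NULL, "f"))
  fs2 <- make_fs(x2, groups = rep(c(1L, 5L), each = 5))
  expect_warning(tab2 <- young_elderly_test(fs2), "all-tied")
  expect_equal(tab2$p_value, 1)
  # invariance under monotone transforms (rank-based test)
  set.seed(3)
  x3 <- matrix(rlnorm(40), ncol = 1, dimnames = list(NULL, "f"))
  fs3 <- make_fs(x3, groups = rep(c(2L, 7L), each = 20))
  fs3log <- make_fs(log(x3), groups = fs3$groups)
  expect_equal(young_elderly_test(fs3)$p_value,
               young_elderly_test(fs3log)$p_value, tolerance = 1e-12)
})

test_that("screen recovers the generator's affected features at large effect", {
  eff <- effect_model(affected_fraction = 0.3, slope_scale = 0.08,
                      duplicate_pairs = 0, contamination_rate = 0)
  fs <- simulate_feature_matrix(cohort_spec(seed = 5), eff, n_features = 30)
  reg <- attr(fs, "registry")
  tab <- young_elderly_test(fs)
  affected_names <- colnames(fs$x)[reg$affected]
  expect_true(all(tab$significant[tab$feature %in% affected_names]))
})

test_that("pairwise group tests: Bonferroni factor, symmetry, null behavior", {
  set.seed(4)
  v <- rnorm(80)
  g <- rep(1:8, each = 10)
  pg <- pairwise_group_test(v + 0 * g, g)
  expect_equal(pg$n_pairs, 28)
  expect_false(any(pg$significant, na.rm = TRUE))   # identical groups
  expect_true(isSymmetric(pg$p))
  expect_true(all(is.na(diag(pg$p))))
  # strong gradation: independent recomputation (uncorrected wilcox * 28)
  v2 <- g + rnorm(80, 0, 0.2)
  pg2 <- pairwise_group_test(v2, g)
  for (i in 1:7) {
    for (j in (i + 1):8) {
      praw <- suppressWarnings(
        stats::wilcox.test(v2[g == i], v2[g == j])$p.value)
      expect_equal(pg2$p[i, j], min(1, praw * 28), tolerance = 1e-12)
      expect_gte(pg2$p[i, j], praw)  # correction never lowers a p-value
    }
  }
  # non-adjacent pairs all separate under strong gradation
  nonadj <- abs(outer(1:8, 1:8, "-")) >= 2
  expect_true(all(pg2$significant[nonadj & upper.tri(nonadj)]))
  expect_lt(pg2$kruskal_p, 1e-6)
  expect_error(pairwise_group_test(v, rep(1, 80)), "2 groups")
})

test_that("age correlation: exact limits and null behavior", {
  ages <- c(25, 40, 55, 70, 85)
  expect_equal(age_correlation(2 * ages + 1, ages)$r, 1.0)
  expect_equal(age_correlation(-ages, ages)$r, -1.0)
  expect_error(age_correlation(rep(2, 5), ages), "constant")
  set.seed(8)
  big <- 0
  for (rep in 1:200) {
    if (abs(stats::cor(rnorm(99), rnorm(99))) >= 0.3) big <- big + 1
  }
  expect_lte(big, 10)  # |r| < 0.3 in at least 95% of null repeats
})

test_that("tallies match a naive recount over the grid and keep sums consistent", {
  grid <- feature_grid()
  # single significant entry: MAV on A1 in task 2
  tab1 <- data.frame(feature = grid,
                     significant = grid == "MAV_A1_T2")
  t1 <- tally_significant(tab1)
  expect_equal(unname(t1$per_task), c(0, 1, 0))
  expect_equal(unname(t1$per_imu), c(1, 0))
  expect_equal(unname(t1$per_sensor_type), c(1, 0, 0))
  expect_equal(unname(t1$per_feature["MAV"]), 1)
  # everything significant: grid arithmetic
  tall <- tally_significant(data.frame(feature = grid, significant = TRUE))
  expect_equal(unname(tall$per_task), c(108, 108, 108))
  expect_equal(unname(tall$per_param_group),
               c(5, 6, 2, 5) * 18)  # amplitude, frequency, entropy, statistic
  expect_equal(sum(tall$per_param_group_proportion), 1)
  # random mask: independent loop recount
  set.seed(9)
  mask <- runif(324) < 0.3
  tr <- tally_significant(data.frame(feature = grid, significant = mask))
  info <- parse_feature_key(grid)
  for (task in 1:3) {
    expect_equal(unname(tr$per_task[task]),
                 sum(mask & info$task == task))
  }
  for (s in unique(info$sensor)) {
    expect_equal(unname(tr$per_sensor[s]), sum(mask & info$sensor == s))
  }
  # sum consistency across views
  expect_equal(sum(tr$per_task), tr$total)
  expect_equal(sum(tr$per_sensor), tr$total)
  expect_equal(sum(tr$per_feature), tr$total)
  expect_equal(sum(tr$per_imu), tr$total)
  expect_equal(unname(tr$per_sensor_type),
               unname(c(tr$per_sensor["A1"] + tr$per_sensor["A2"],
                        tr$per_sensor["G1"] + tr$per_sensor["G2"],
                        tr$per_sensor["M1"] + tr$per_sensor["M2"])))
  expect_error(tally_significant(data.frame(feature = character(0),
                                            significant = logical(0))),
               "empty")
})
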