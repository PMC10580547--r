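test_that("min-max + offset normalization hits its endpoints exactly", {
  expect_equal(as.vector(normalize_columns(matrix(c(2, 4, 6), ncol = 1))),
               c(0.1, 0.6, 1.1))
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  y <- normalize_columns(x)
  expect_equal(unname(apply(y, 2, min)), rep(0.1, 3))
  expect_equal(unname(apply(y, 2, max)), rep(1.1, 3))
  expect_true(all(y >= 0.1 & y <= 1.1))
  expect_warning(z <- normalize_columns(matrix(c(7, 7, 7), ncol = 1)),
                 "constant")
  expect_equal(as.vector(z), rep(0.1, 3))
})

test_that("hyperspherical representation and its reconstruction identity", {
  h <- to_hyperspherical(c(3, 4))
  expect_equal(h$p, 5)
  expect_equal(as.vector(h$theta), atan(4 / 3), tolerance = 1e-9)
  h3 <- to_hyperspherical(c(1, 1, 1))
  expect_equal(h3$p, sqrt(3), tolerance = 1e-9)
  expect_equal(as.vector(h3$theta), c(pi / 4, atan(1 / sqrt(2))),
               tolerance = 1e-9)
  set.seed(23)
  for (rep in 1:10) {
    v <- runif(8, 0.1, 1.1)
    h <- to_hyperspherical(v)
    expect_equal(h$p * prod(cos(h$theta)), v[1], tolerance = 1e-9)
    expect_true(all(h$theta > 0 & h$theta < pi / 2))
  }
  expect_error(to_hyperspherical(c(0, 1)), "positive")
})

test_that("axis projection: identity, alignment, orthogonality", {
  h <- to_hyperspherical(c(3, 4))
  expect_equal(project_lda_value(h$p, h$theta, 0), 3, tolerance = 1e-12)
  expect_equal(project_lda_value(h$p, h$theta, -as.vector(h$theta)), 5,
               tolerance = 1e-12)
  expect_equal(project_lda_value(h$p, h$theta, pi / 2 - as.vector(h$theta)),
               0, tolerance = 1e-12)
  expect_error(project_lda_value(h$p, h$theta, c(0, 0)), "must match")
  # matrix input: theta-hat = 0 recovers the first coordinate for every row
  set.seed(4)
  x <- matrix(runif(50, 0.1, 1.1), 10, 5)
  h2 <- to_hyperspherical(x)
  expect_equal(project_lda_value(h2$p, h2$theta, rep(0, 4)), x[, 1],
               tolerance = 1e-9)
})

test_that("separability estimator matches hand and decomposition oracles", {
  expect_equal(separability_ez(c(-1, 1, 2, 4), c(1, 1, 2, 2)), 3 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(separability_ez(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3)), 0)
  set.seed(6)
  v <- rnorm(30)
  g <- rep(1:3, each = 10)
  ez <- separability_ez(v, g)
  expect_equal(ez, ez_oracle(v, g), tolerance = 1e-12)
  # pairwise decomposition: 3-group value equals the sum over the three pairs
  pair_sum <- separability_ez(v[g != 3], g[g != 3]) +
    separability_ez(v[g != 2], g[g != 2]) +
    separability_ez(v[g != 1], g[g != 1])
  expect_equal(ez, pair_sum, tolerance = 1e-12)
  # invariances: shift-invariant, |a|-equivariant
  expect_equal(separability_ez(v + 7, g), ez, tolerance = 1e-9)
  expect_equal(separability_ez(-2 * v, g), ez, tolerance = 1e-9)
  expect_error(separability_ez(v, rep(1, 30)), "2 groups")
  expect_error(separability_ez(c(1, 2, 3), c(1, 1, 2)), "2 members")
})

test_that("initial population is uniform on [0, 2 pi) and seeded", {
  cfg <- ga_config(s = 50, seed = 3)
  set.seed(cfg$seed)
  pop <- init_population(cfg, 7)
  expect_equal(dim(pop), c(50, 7))
  expect_true(all(pop >= 0 & pop < 2 * pi))
  set.seed(cfg$seed)
  expect_identical(init_population(cfg, 7), pop)
})

test_that("arithmetic crossover children follow the printed recombination", {
  p1 <- c(0, 0)
  p2 <- c(2, 2)
  kids <- rbind(1.5 * p1 - 0.5 * p2, 0.5 * p1 + 0.5 * p2,
                -0.5 * p1 + 1.5 * p2)
  expect_equal(kids, rbind(c(-1, -1), c(1, 1), c(3, 3)))
  # wrapped into [0, 2 pi) inside the generation step
  cfg <- ga_config(s = 4, p_mutation = 0, p_crossover = 1, seed = 1)
  pop <- rbind(p1, p2, p1, p2)
  fit <- c(1, 2, 3, 4)
  set.seed(1)
  nxt <- evolve_generation(pop, fit, cfg, function(m) rowSums(m))
  expect_true(all(nxt >= 0 & nxt < 2 * pi))
})

test_that("pure selection keeps offspring within the current population", {
  cfg <- ga_config(s = 6, p_mutation = 0, p_crossover = 0, seed = 2)
  set.seed(2)
  pop <- matrix(runif(18, 0, 2 * pi), 6, 3)
  fit <- runif(6)
  nxt <- evolve_generation(pop, fit, cfg, function(m) rep(1, nrow(m)))
  in_pop <- apply(nxt, 1, function(r) {
    any(apply(pop, 1, function(p) all(abs(p - r) < 1e-12)))
  })
  expect_true(all(in_pop))
  # elitism: the fittest axis survives unmodified
  expect_equal(nxt[6, ], pop[which.max(fit), ])
})

test_that("GA trace is monotone, deterministic, and matches grid search on 2 features", {
  set.seed(44)
  n <- 48
  groups <- rep(1:4, each = 12)
  x <- cbind(rnorm(n, 1 + 0.3 * groups, 0.2), runif(n, 0.5, 1.5))
  colnames(x) <- c("f1", "f2")
  C <- normalize_columns(feature_set(x, ages = groups * 10 + 15, groups = groups))
  cfg <- ga_config(epochs = 150, s = 30, xi = 4, seed = 5)
  res <- run_ga(C, cfg)
  expect_true(all(diff(res$ez_trace) >= 0))
  res2 <- run_ga(C, cfg)
  expect_identical(res$best_axis, res2$best_axis)
  expect_identical(res$lda_values, res2$lda_values)
  # exhaustive 0.1-degree grid over the single angle
  h <- to_hyperspherical(C$x)
  grid <- seq(0, 2 * pi, length.out = 3600)
  ez_grid <- vapply(grid, function(a) {
    separability_ez(project_lda_value(h$p, h$theta, a), groups)
  }, numeric(1))
  expect_gte(res$ez_best, 0.99 * max(ez_grid))
})

test_that("permuted labels collapse the separability and the age correlation", {
  fs <- simulate_feature_matrix(tiny_spec(seed = 10, sizes = rep(12, 8)),
                                effect_model(slope_scale = 0.12,
                                             duplicate_pairs = 0,
                                             contamination_rate = 0),
                                n_features = 12)
  C <- normalize_columns(fs)
  cfg <- ga_config(epochs = 300, s = 30, seed = 6)
  structured <- run_ga(C, cfg)
  set.seed(77)
  Cperm <- feature_set(C$x, C$ages, sample(C$groups), C$ids)
  null <- run_ga(Cperm, cfg)
  expect_lt(null$ez_best, 0.25 * structured$ez_best)
})

test_that("relevance filtering keeps the separating feature and drops pure noise", {
  set.seed(12)
  n <- 64
  groups <- rep(1:4, each = 16)
  x <- cbind(sep = groups + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 10), n, 10))
  colnames(x)[-1] <- sprintf("noise%02d", 1:10)
  fs <- feature_set(x, ages = groups * 12 + 12, groups = groups)
  C <- normalize_columns(fs)
  r1 <- run_ga(C, ga_config(epochs = 400, s = 30, xi = 4, seed = 9))
  rf <- relevance_filter(C, r1$best_axis, ga_config())
  expect_true(rf$mask[["sep"]])
  expect_lt(sum(rf$mask), 11)  # most pure-noise columns are eliminated
  # zero-noise two-feature problem: everything relevant
  x2 <- cbind(a = groups, b = 5 - groups)
  C2 <- normalize_columns(feature_set(x2, groups * 10, groups))
  r2 <- run_ga(C2, ga_config(epochs = 200, s = 20, xi = 4, seed = 2))
  rf2 <- relevance_filter(C2, r2$best_axis, ga_config())
  expect_true(all(rf2$mask))
})

test_that("full estimation chain separates constructed groups and is seeded", {
  # two groups, large effect, tiny noise: distributions must not overlap
  set.seed(30)
  n <- 40
  groups <- rep(1:2, each = 20)
  ages <- c(runif(20, 25, 35), runif(20, 75, 85))
  x <- cbind(a = 2 * groups + rnorm(n, 0, 0.05),
             b = -groups + rnorm(n, 0, 0.05),
             c = rnorm(n))
  fs <- feature_set(x, ages, groups)
  cfg <- ga_config(epochs = 300, s = 30, xi = 2, seed = 3)
  res <- estimate_lda_value(fs, cfg)
  expect_lt(max(res$lda_values[groups == 1]) + 1e-12,
            min(res$lda_values[groups == 2]))
  res2 <- estimate_lda_value(fs, cfg)
  expect_identical(res$lda_values, res2$lda_values)
  # orientation convention: group means increase with group index
  expect_gt(mean(res$lda_values[groups == 2]),
            mean(res$lda_values[groups == 1]))
})

test_that("published 46-offset axis evaluates as the printed cosine product", {
  ax <- published_axis()
  expect_length(ax$offsets, 46)
  expect_equal(ax$offsets[1], 2.33)
  expect_equal(ax$offsets[46], 0.02)
  expect_equal(sum(ax$features$task == 1), 27)
  expect_equal(sum(ax$features$task == 2), 12)
  expect_equal(sum(ax$features$task == 3), 7)
  # cancelling angles return R; zero radius returns 0
  expect_equal(evaluate_published_axis(-ax$offsets, R = 3.7), 3.7,
               tolerance = 1e-12)
  expect_equal(evaluate_published_axis(rnorm(46), R = 0), 0)
  # independent product-loop oracle
  set.seed(15)
  th <- rnorm(46)
  manual <- 2.5
  for (k in 1:46) manual <- manual * cos(th[k] + ax$offsets[k])
  expect_equal(evaluate_published_axis(th, R = 2.5), manual,
               tolerance = 1e-12)
  expect_error(evaluate_published_axis(rnorm(45), R = 1), "46 angles")
})

test_that("population angles stay wrapped across many generations", {
  set.seed(50)
  pop <- matrix(runif(60, 0, 2 * pi), 20, 3)
  cfg <- ga_config(s = 20, seed = 8)
  fn <- function(m) apply(m, 1, function(r) sum(cos(r)) + 3)
  for (g in 1:100) {
    pop <- evolve_generation(pop, fn(pop), cfg, fn)
    expect_true(all(pop >= 0 & pop < 2 * pi))
  }
})
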