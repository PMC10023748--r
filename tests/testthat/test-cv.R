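test_that("fold plans are balanced, seeded, and bounded by |C|", {
  conds <- tibble::tibble(id = paste0("c", 1:6))
  f1 <- make_cv_folds(conds, K = 3, iterations = 10, seed = 5)
  f2 <- make_cv_folds(conds, K = 3, iterations = 10, seed = 5)
  expect_identical(f1, f2)                       # determinism
  expect_length(f1, 10)
  for (fold in f1) expect_equal(as.integer(table(fold)), rep(2L, 3))
  expect_error(make_cv_folds(conds[1:2, ], K = 3), "exceeds")
})

test_that("cv_score reproduces hand-evaluated cases", {
  # one iteration, two lambda: scaled omega (0, 1) x scaled logDelta
  # (log10(10/10), log10(100/10)) / log10(100/10) = (0, 1) -> s = (0, 1)
  s <- cv_score(matrix(c(0.2, 0.4), 2, 1), matrix(c(10, 100), 2, 1))
  expect_equal(s, c(0, 1))
  # degenerate scaling: all lambda identical -> 0
  expect_equal(cv_score(matrix(0.3, 3, 1), matrix(5, 3, 1)), rep(0, 3))
  # three lambda hand case: omega scaled (0, .5, 1), logDelta scaled (1, .5, 0)
  s3 <- cv_score(matrix(c(0.1, 0.2, 0.3), 3, 1),
                 matrix(c(100, 10, 1), 3, 1))
  expect_equal(s3, c(0, 0.25, 0))
  # scores are averages of products of unit-scaled factors: always in [0,1]
  set.seed(8)
  sr <- cv_score(matrix(runif(28), 14), matrix(10^runif(28, -3, 3), 14))
  expect_true(all(sr >= 0 & sr <= 1))
  expect_message(cv_score(matrix(c(0.1, 0.2), 2, 1),
                          matrix(c(0, 10), 2, 1)), "floor")
})

test_that("lambda selection finds the first curvature sign change from the top", {
  grid <- 10^(-8:-1)
  # convex rise turning concave near the top of the grid
  s <- c(0, 0.01, 0.04, 0.09, 0.16, 0.30, 0.44, 0.50)
  d2 <- c(NA, diff(diff(s)), NA)        # brute-force difference table
  expect_true(all(d2[2:5] > 0))
  expect_equal(d2[6], 0)
  expect_lt(d2[7], 0)
  # scanning downward from lambda_max: negative at 7, zero at 6, positive
  # at 5 -> the first sign change is detected at grid point 5
  expect_equal(select_lambda(grid, s), grid[5])
  # strictly linear score: zero second gradient -> argmin fallback
  expect_message(l <- select_lambda(grid, seq(1, 0.3, length.out = 8)),
                 "argmin")
  expect_equal(l, grid[8])
  expect_error(select_lambda(grid[1:3], s[1:3]), "at least 4")
})

test_that("Jaccard distances: identical, disjoint, partial, empty", {
  expect_equal(fold_overlap(list(c("a", "b"), c("a", "b"))), 0)
  expect_equal(fold_overlap(list(c("a"), c("b"))), 1)
  # one shared member of three total: 1 - 1/3
  expect_equal(fold_overlap(list(c("a", "b"), c("b", "c"))), 2 / 3)
  expect_equal(fold_overlap(list(character(0), character(0))), 0)
})

test_that("cross-validation runs end to end and selects a grid member", {
  inst <- make_synthetic_instance(n_linear = 3, n_parallel = 1,
                                  n_conditions = 6, n_deflate = 2,
                                  noise_cv = 0.15, seed = 41)
  grid <- 10^seq(-10, -1, by = 3)        # 4 points keep the test fast
  cv <- presto_crossval(inst$model, inst$conditions, lambda_grid = grid,
                        K = 3, iterations = 2, seed = 9)
  expect_true(cv$lambda_opt %in% grid)
  expect_true(all(cv$scores$score >= 0 & cv$scores$score <= 1))
  expect_identical(nrow(cv$measures), length(grid) * 2L)
  expect_gte(cv$fold_jaccard, 0)
  # 3-fold x 2 iterations -> 6 corrected sets per lambda
  expect_length(cv$corrected_sets[[1]], 6)
})

test_that("subsampling concordance: full collection gives distance 0, r = 1", {
  inst <- make_synthetic_instance(n_linear = 4, n_parallel = 1,
                                  n_conditions = 4, n_deflate = 3, seed = 43)
  rb <- robustness_subsample(inst$model, inst$conditions, lambda = 1e-8,
                             sizes = c(3, 4), draws = 2, seed = 3)
  full <- rb[rb$size == 4, ]
  expect_true(all(full$jaccard == 0))
  expect_true(all(abs(full$pearson - 1) < 1e-9))
  expect_true(all(rb$feasible))
  # determinism under the same seed
  rb2 <- robustness_subsample(inst$model, inst$conditions, lambda = 1e-8,
                              sizes = c(3, 4), draws = 2, seed = 3)
  expect_equal(rb$jaccard, rb2$jaccard)
})
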