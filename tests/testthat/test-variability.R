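# Variability analysis and sampling, checked against hand-solvable
# polytopes.

make_fitted_instance <- function(seed = 7, n_conditions = 4) {
  inst <- make_synthetic_instance(n_linear = 4, n_parallel = 2,
                                  n_conditions = n_conditions,
                                  n_deflate = 3, seed = seed)
  prob <- build_presto_lp(inst$model, inst$conditions, lambda = 1e-7)
  list(inst = inst, prob = prob, res = solve_presto(prob))
}

test_that("the fitted optimum lies inside every variability interval", {
  f <- make_fitted_instance()
  vr <- delta_variability(f$prob, f$res)
  iv <- vr$intervals
  expect_true(all(iv$delta_min <= iv$delta_opt + 1e-6))
  expect_true(all(iv$delta_opt <= iv$delta_max + 1e-6))
  # intervals respect the fold-change / absolute caps
  caps <- pmin((f$prob$epsilon - 1) * f$prob$kmin,
               f$prob$kmax - f$prob$kmin)
  expect_true(all(iv$delta_max <= caps + 1e-6))
  expect_true(all(iv$delta_min >= -1e-9))
})

test_that("uniquely determined corrections have zero-width intervals", {
  # single chain enzyme whose capacity binds: delta pinned by mu and Delta
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  cond <- manual_condition("c1", c(e1 = 1e-4), mu = 0.72)
  prob <- build_presto_lp(m, cond, lambda = 1e-7)
  res <- solve_presto(prob)
  vr <- delta_variability(prob, res, delta_tol = 1e-9)
  expect_equal(vr$intervals$delta_min, vr$intervals$delta_max,
               tolerance = 1e-6)
  expect_equal(vr$intervals$delta_opt, 1, tolerance = 1e-5)
})

test_that("two parallel isozymes share only their delta sum", {
  # both branches identical: only delta_1 + delta_2 is pinned; each
  # interval spans [0, required sum] and the endpoints are complementary
  toy <- parallel_network(c(pa = 1, pb = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  E <- c(pa = 1e-4, pb = 1e-4)
  mu <- 1.44   # joint capacity 0.72 -> required extra capacity = sum delta = 2
  cond <- manual_condition("c1", E, mu = mu)
  prob <- build_presto_lp(m, cond, lambda = 1e-7)
  res <- solve_presto(prob)
  expect_equal(sum(res$delta$delta), 2, tolerance = 1e-5)
  vr <- delta_variability(prob, res, delta_tol = 1e-9)
  iv <- vr$intervals
  expect_equal(iv$delta_min, c(0, 0), tolerance = 1e-5)
  expect_equal(iv$delta_max, c(2, 2), tolerance = 1e-4)
  expect_equal(iv$delta_min + rev(iv$delta_max), c(2, 2), tolerance = 1e-4)
})

test_that("error-band bounds are exactly 0.99 and 1.01 of the optimum", {
  f <- make_fitted_instance(seed = 15, n_conditions = 3)
  # force a nonzero optimal omega: raise one growth target above reach
  fx <- prestor:::variability_constraints(f$prob, f$res, 0.01, 1e-3)
  w <- f$res$errors$omega_lp
  expect_equal(fx$lb[f$prob$idx_w], pmax(0, 0.99 * w), tolerance = 1e-12)
  expect_equal(fx$ub[f$prob$idx_w], pmin(f$prob$theta, 1.01 * w),
               tolerance = 1e-12)
})

test_that("tightening the error tolerance never widens an interval", {
  f <- make_fitted_instance(seed = 19, n_conditions = 3)
  wide <- delta_variability(f$prob, f$res, omega_tol = 0.01)
  tight <- delta_variability(f$prob, f$res, omega_tol = 0.001)
  expect_true(all(tight$intervals$delta_min >=
                    wide$intervals$delta_min - 1e-6))
  expect_true(all(tight$intervals$delta_max <=
                    wide$intervals$delta_max + 1e-6))
})

test_that("projection returns interior points unchanged and ties go to the
           lexicographically least vertex", {
  # polytope {d1 + d2 = 2, d >= 0} via two identical parallel branches
  toy <- parallel_network(c(pa = 1, pb = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  cond <- manual_condition("c1", c(pa = 1e-4, pb = 1e-4), mu = 1.44)
  prob <- build_presto_lp(m, cond, lambda = 1e-7)
  res <- solve_presto(prob)
  vr <- delta_variability(prob, res, delta_tol = 1e-12)
  # draws inside [0,2]^2 project onto the segment; a feasible draw (on the
  # segment) is returned unchanged
  ss <- sample_corrections(prob, vr, n = 40, seed = 11, tie_break = "lex")
  expect_identical(ss$n_failed, 0L)
  expect_true(ss$all_verified)
  sums <- rowSums(ss$samples)
  expect_true(all(abs(sums - 2) < 1e-5))
  # on the segment d1 + d2 = 2 the minimal L1 distance to a draw (a, b) in
  # [0,2]^2 is |a + b - 2| and the lexicographically least optimal vertex
  # has d1 = max(0, 2 - b) when a + b > 2 and d1 = a when a + b < 2
  a <- ss$targets[, 1]; b <- ss$targets[, 2]
  expect_equal(ss$distance, abs(a + b - 2), tolerance = 1e-5)
  d1_expect <- ifelse(a + b > 2, pmax(0, 2 - b), a)
  expect_equal(unname(ss$samples[, 1]), unname(d1_expect), tolerance = 1e-4)
})

test_that("precision summaries match direct order statistics", {
  s <- matrix(c(1, 3, 1, 3, 2, 2), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  ps <- precision_summary(s)
  expect_equal(ps$mean, c(2, 2, 2))
  expect_equal(ps$spread, c(1, 1, 0))     # mean |x - mean|; constant -> 0
  set.seed(2)
  m <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  ps2 <- precision_summary(m)
  expect_equal(ps2$p25, unname(apply(m, 2, quantile, 0.25, names = FALSE)))
  expect_equal(ps2$p75, unname(apply(m, 2, quantile, 0.75, names = FALSE)))
  # baseline shift moves means but not spreads
  ps3 <- precision_summary(m, kcat_min = c(a = 1, b = 2, c = 3))
  expect_equal(ps3$mean, ps2$mean + 1:3)
  expect_equal(ps3$spread, ps2$spread)
})
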