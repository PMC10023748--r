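# Core correction program, checked against analytic and brute-force
# oracles on chain/parallel fixtures with closed-form maximal growth.

test_that("single-constraint chain: delta = mu/(3600 E) - kcat, omega = 0", {
  # capacity 3600 * 1 * 1e-4 = 0.36 h^-1; measured growth 0.72 needs
  # delta = 0.72/0.36 * 1 - 1 = 1 s^-1 exactly
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  cond <- manual_condition("c1", c(e1 = 1e-4), mu = 0.72)
  res <- presto_correct(m, cond, lambda = 1e-7)
  expect_identical(res$status, "optimal")
  expect_equal(res$delta$delta, 1, tolerance = 1e-6)
  expect_lt(res$errors$omega, 1e-7)
  expect_equal(res$Delta, sum(res$delta$delta))   # Delta = sum exactly
})

test_that("zero correction is optimal when growth is already attained", {
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  cond <- manual_condition("c1", c(e1 = 1e-4), mu = 0.2)  # < capacity 0.36
  res <- presto_correct(m, cond, lambda = 1e-7)
  expect_lt(res$delta$delta, 1e-9)
  expect_lt(res$errors$omega, 1e-7)
})

test_that("a shared enzyme takes the larger of two per-condition needs", {
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  conds <- dplyr::bind_rows(
    manual_condition("c1", c(e1 = 1e-4), mu = 0.72),   # needs delta = 1
    manual_condition("c2", c(e1 = 1e-4), mu = 1.44))   # needs delta = 3
  res <- presto_correct(m, conds, lambda = 1e-9)
  # brute-force grid over delta with per-condition feasibility (oracle)
  grid <- seq(0, 4, by = 1e-3)
  obj <- vapply(grid, function(d) {
    g <- vapply(conds$growth, function(mu)
      chain_growth(c(e1 = 1), c(e1 = 1e-4), U = 1000, delta = d), 0)
    mean(pmax(0, (conds$growth - g) / conds$growth)) + 1e-9 * d
  }, 0)
  expect_equal(res$delta$delta, grid[which.min(obj)], tolerance = 1e-3)
  expect_equal(res$delta$delta, 3, tolerance = 1e-5)
})

test_that("delta bounds follow the fold-change and absolute caps", {
  toy <- chain_network(c(e1 = 1, e2 = 5e7))
  m <- build_pc_model(toy$network, toy$enzymes)
  cond <- manual_condition("c1", c(e1 = 1e-4, e2 = 1e-4), mu = 0.2)
  prob <- build_presto_lp(m, cond, lambda = 1e-7)
  ub <- prob$ub[prob$idx_d]
  names(ub) <- prob$M
  expect_equal(ub[["e1"]], (1e5 - 1) * 1)        # epsilon cap
  expect_equal(ub[["e2"]], 5.75e7 - 5e7)         # absolute cap
})

test_that("objective reduces to omega + lambda * delta for singletons", {
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  cond <- manual_condition("c1", c(e1 = 1e-4), mu = 0.72)
  prob <- build_presto_lp(m, cond, lambda = 0.25)
  expect_equal(prob$obj[prob$idx_w], 1)
  expect_equal(prob$obj[prob$idx_d], 0.25)
})

test_that("relative error conventions", {
  expect_equal(relative_error(0.4, 0.4), 0)
  expect_equal(relative_error(0.4, 0.2), 0.5)
  expect_equal(relative_error(0.4, 1.2), 2)     # overprediction can exceed 1
  expect_equal(relative_error(0.4, 0.2, denominator = "predicted"), 1)
  expect_error(relative_error(0.4, -0.1, denominator = "predicted"),
               "undefined")
  expect_error(relative_error(0, 0.4), "> 0")
})

test_that("infeasible instances name the offending condition block", {
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  # theta = 0.6 and a growth rate no correction can reach (uptake-capped)
  conds <- dplyr::bind_rows(
    manual_condition("ok", c(e1 = 1e-4), mu = 0.3, U = 1000),
    manual_condition("hopeless", c(e1 = 1e-4), mu = 50, U = 2))
  res <- presto_correct(m, conds, lambda = 1e-7)
  expect_identical(res$status, "infeasible")
  expect_identical(res$offending, "hopeless")
})

test_that("solutions pass the independent constraint checker", {
  inst <- make_synthetic_instance(n_linear = 3, n_parallel = 2,
                                  n_conditions = 4, n_deflate = 2, seed = 31)
  prob <- build_presto_lp(inst$model, inst$conditions, lambda = 1e-7)
  res <- solve_presto(prob)
  expect_true(res$verified)
  chk <- check_lp_solution(res$x, prob$mat, prob$dir, prob$rhs,
                           prob$lb, prob$ub, tol = 1e-6)
  expect_true(chk$ok)
})

test_that("idempotence: a fully fitted model yields delta = 0 at any lambda", {
  inst <- make_synthetic_instance(n_linear = 3, n_parallel = 1,
                                  n_conditions = 3, n_deflate = 2, seed = 33)
  res <- presto_correct(inst$model, inst$conditions, lambda = 1e-8)
  expect_lt(max(res$errors$omega), 1e-6)
  corrected <- apply_kcat_corrections(
    inst$model, stats::setNames(res$delta$delta, res$delta$enzyme))
  for (lam in c(1e-10, 1e-7, 1e-3, 1e-1)) {
    again <- presto_correct(corrected, inst$conditions, lambda = lam)
    expect_lt(max(again$delta$delta), 1e-9)
  }
})

test_that("LP optimum matches the dense grid oracle (2 enzymes, parallel)", {
  set.seed(77)
  toy <- parallel_network(c(pa = 0.5, pb = 0.8))
  m <- build_pc_model(toy$network, toy$enzymes)
  E <- c(pa = 2e-4, pb = 1e-4)
  # both branches needed: mu above the uncorrected joint capacity
  cap0 <- parallel_growth(c(pa = 0.5, pb = 0.8), E, U = 1000)
  mu <- cap0 * 1.4
  cond <- manual_condition("c1", E, mu = mu)
  lambda <- 1e-4
  res <- presto_correct(m, cond, lambda = lambda)
  dmax <- (mu - cap0) / (3600 * min(E)) * 1.1  # covers either-branch fix
  g1 <- seq(0, dmax, by = 1e-3)
  deltas <- as.matrix(expand.grid(pa = g1, pb = g1))
  oracle <- grid_search_objective(deltas, function(d) {
    cbind(pmin(1000, 3600 * ((0.5 + d[, 1]) * E["pa"] +
                               (0.8 + d[, 2]) * E["pb"])))
  }, mu = mu, lambda = lambda, theta = 0.6)
  expect_equal(res$objective, oracle$objective, tolerance = 1e-3)
})
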