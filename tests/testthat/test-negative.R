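# The negative-correction second stage on fixtures built to over-predict
# pool-only growth while the abundance-constrained scenario stays binding.

overpredicting_instance <- function(seed = 11, n_conditions = 3,
                                    headroom = 2, n_parallel = 1) {
  toy <- make_toy_network(3, n_parallel, seed = seed)
  m <- build_pc_model(toy$network, toy$enzymes)
  conds <- simulate_conditions(m, n_conditions, seed = seed + 1,
                               headroom = headroom)
  prob <- build_presto_lp(m, conds, lambda = 1e-7)
  list(model = m, conds = conds, prob = prob, res = solve_presto(prob))
}

test_that("binding capacities leave no room for negative corrections", {
  # chain-only fixture at headroom 1: every capacity is exactly binding in
  # the abundance-constrained scenario, so preservation pins delta_neg = 0
  f <- overpredicting_instance(seed = 13, headroom = 1, n_parallel = 0)
  neg <- negative_correction_step(f$prob, f$res)
  expect_true(all(neg$delta$delta_neg == 0))
  expect_false(isTRUE(neg$apparent_rates))
})

test_that("pool-only overprediction is reduced, stage-one errors preserved", {
  f <- overpredicting_instance(seed = 11, headroom = 2)
  before <- evaluate_conditions(list(m = apply_kcat_corrections(
    f$model, stats::setNames(f$res$delta$delta, f$res$delta$enzyme))),
    f$conds)
  neg <- negative_correction_step(f$prob, f$res)
  expect_true(neg$apparent_rates)
  expect_true(any(neg$delta$delta_neg < 0))
  expect_true(all(neg$errors_pool$omega_after <=
                    neg$errors_pool$omega_before + 1e-9))
  expect_lt(mean(neg$errors_pool$omega_after),
            mean(neg$errors_pool$omega_before))
  # abundance-constrained errors unchanged within tolerance
  merged <- stats::setNames(neg$delta$delta + neg$delta$delta_neg,
                            neg$delta$enzyme)
  after <- evaluate_conditions(list(m = apply_kcat_corrections(
    f$model, merged, allow_negative = TRUE)), f$conds)
  iii_b <- before[before$scenario == "pool_uptake_abundance", ]
  iii_a <- after[after$scenario == "pool_uptake_abundance", ]
  expect_equal(iii_a$omega, iii_b$omega, tolerance = 1e-6)
  # corrected kcats remain strictly positive
  expect_true(all(neg$delta$kcat_new > 0))
})

test_that("the single-enzyme halving case is solved exactly", {
  # one enzyme, abundance twice the requirement: pool-only growth is
  # double the measurement, and halving the kcat removes the gap entirely
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  E <- 2e-4                                 # twice the need for mu = 0.36
  mu <- 0.36
  mw <- m$enzymes$mw
  # measured uptake pins the abundance-constrained scenario at mu, so the
  # enzyme capacity (0.72) has exactly twofold slack there
  cond <- manual_condition("c1", c(e1 = E), mu = mu, U = mu)
  # pool cap sized so pool-only growth = 2 * mu exactly:
  # g_pool = 3600 * kcat * cap / mw ; want 0.72 -> cap = 0.72 mw / 3600
  cond$ptot <- 0.72 * mw / 3600 / (0.5 * 0.5)
  prob <- build_presto_lp(m, cond, lambda = 1e-7)
  res <- solve_presto(prob)
  expect_lt(res$errors$omega, 1e-6)         # scenario fits without delta
  neg <- negative_correction_step(prob, res)
  expect_true(neg$apparent_rates)
  expect_equal(neg$delta$delta_neg, -0.5, tolerance = 1e-3)
  expect_lt(max(abs(neg$errors_pool$omega_after)), 1e-3)
})
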