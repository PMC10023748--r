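# The control-coefficient correction heuristic, checked against analytic
# pool-limited chain FBA: with pool cap P and molecular weights mw_i, the
# maximal chain flux is v = min(U, 3600 P / sum_i mw_i / kcat_i).

pool_chain <- function(kcats, mw = NULL, ptot = 0.036, mu = 1, U = 1000) {
  if (is.null(mw)) mw <- stats::setNames(rep(50, length(kcats)),
                                         names(kcats))
  toy <- chain_network(kcats, mw)
  m <- build_pc_model(toy$network, toy$enzymes)
  cond <- manual_condition(
    "c1", stats::setNames(rep(NA_real_, length(kcats)), names(kcats)),
    mu = mu, U = U, ptot = ptot, f = 1, sigma = 1)
  list(model = m, cond = cond)
}

pool_growth_analytic <- function(kcats, mw = 50, P = 0.036, U = 1000)
  min(U, 3600 * P / sum(mw / kcats))

test_that("control coefficients are analytic on the bottleneck, ~0 off it", {
  px <- pool_chain(c(e1 = 1, e2 = 1e5))
  cc <- control_coefficients(px$model, px$cond)
  v0 <- pool_growth_analytic(c(1, 1e5))
  v1 <- pool_growth_analytic(c(1000, 1e5))
  expect_equal(cc[["e1"]], (v1 - v0) / v0, tolerance = 1e-6)
  v2 <- pool_growth_analytic(c(1, 1e8))   # e2 boosted 1000-fold
  expect_equal(cc[["e2"]], (v2 - v0) / v0, tolerance = 1e-4)
  expect_lt(abs(cc[["e2"]]), 1e-4)        # far below the 0.001 threshold
  # absolute-change variant
  cc_abs <- control_coefficients(px$model, px$cond, mode = "absolute")
  expect_equal(cc_abs[["e1"]], v1 - v0, tolerance = 1e-6)
})

test_that("the heuristic relieves sequential bottlenecks in rank order", {
  px <- pool_chain(c(e1 = 1, e2 = 2, e3 = 1e5), mu = 6)
  db <- c(e1 = 100, e2 = 100, e3 = 100)
  tr <- gecko_correct_condition(px$model, px$cond, kcat_db = db)
  expect_identical(tr$trace$enzyme, c("e1", "e2"))
  expect_identical(tr$stop_reason, "growth_within_tolerance")
  expect_gte(tr$growth, 0.9 * 6)
  expect_equal(tr$trace$kcat_new, c(100, 100))
  # growth is non-decreasing along the trace (recomputed analytically)
  g0 <- pool_growth_analytic(c(1, 2, 1e5))
  g1 <- pool_growth_analytic(c(100, 2, 1e5))
  g2 <- pool_growth_analytic(c(100, 100, 1e5))
  expect_true(g0 <= g1 && g1 <= g2)
  expect_equal(tr$growth, g2, tolerance = 1e-6)
  # terminates within |M| iterations by construction
  expect_lte(nrow(tr$trace), nrow(px$model$enzymes))
})

test_that("stop conditions: already within tolerance / below threshold", {
  # within 10% from the start: empty trace
  px <- pool_chain(c(e1 = 100, e2 = 100), mu = 1)
  tr <- gecko_correct_condition(px$model, px$cond,
                                kcat_db = c(e1 = 200, e2 = 200))
  expect_identical(nrow(tr$trace), 0L)
  expect_identical(tr$stop_reason, "growth_within_tolerance")

  # uptake-limited (default bound 1000): no coefficient above threshold
  px2 <- pool_chain(c(e1 = 1e4, e2 = 1e4), mu = 5000, ptot = 10)
  tr2 <- gecko_correct_condition(px2$model, px2$cond,
                                 kcat_db = c(e1 = 2e4, e2 = 2e4))
  expect_identical(nrow(tr2$trace), 0L)
  expect_identical(tr2$stop_reason, "no_coefficient_above_threshold")
})

test_that("database replacement never decreases a kcat", {
  px <- pool_chain(c(e1 = 1, e2 = 1e5), mu = 50)
  tr <- gecko_correct_condition(px$model, px$cond,
                                kcat_db = c(e1 = 0.5, e2 = 0.5))
  if (nrow(tr$trace) > 0)
    expect_true(all(tr$trace$kcat_new >= tr$trace$kcat_old))
  kc <- tr$model$kcats
  expect_true(all(kc$kcat >= px$model$kcats$kcat[match(
    paste(kc$enzyme, kc$rxn),
    paste(px$model$kcats$enzyme, px$model$kcats$rxn))]))
})

test_that("union/max aggregation takes per-reaction maxima", {
  toy <- chain_network(c(e1 = 2, e2 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  m2 <- m; m2$kcats$kcat <- c(5, 1); m2 <- prestor:::refresh_kcat_min(m2)
  m3 <- m; m3$kcats$kcat <- c(3, 4); m3 <- prestor:::refresh_kcat_min(m3)
  um <- aggregate_union_max(list(m, m2, m3))
  expect_equal(um$kcats$kcat, c(5, 4))    # max of {2,5,3} and {1,1,4}
  expect_equal(aggregate_union_max(list(m))$kcats$kcat, m$kcats$kcat)
  bad <- m
  bad$kcats <- bad$kcats[-1, ]
  expect_error(aggregate_union_max(list(m, bad)), "structure")
})
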