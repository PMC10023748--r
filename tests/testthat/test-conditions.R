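test_that("condition loading defines M and applies the Ptot fill policy", {
  ab <- data.frame(enzyme = c("e1", "e2"),
                   c1 = c(1e-5, 2e-5), c2 = c(3e-5, NA),
                   c3 = c(2e-5, 1e-5), c4 = c(4e-5, 2e-5),
                   check.names = FALSE)
  meta <- data.frame(condition = paste0("c", 1:4),
                     growth = c(0.1, 0.2, 0.3, 0.4),
                     ptot = c(0.5, 0.67, NA, 0.6),
                     f = 0.5, sigma = 0.5, gam = 50)
  abp <- withr::local_tempfile(fileext = ".tsv")
  mep <- withr::local_tempfile(fileext = ".tsv")
  write.table(ab, abp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, mep, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(conds <- load_conditions(abp, mep), "maximum measured")
  expect_identical(measured_in_all(conds), "e1")   # e2 missing in c2
  expect_equal(conds$ptot[3], 0.67)                # max across measured
  expect_error(load_conditions(abp, mep, ptot_fill = "error"), "Ptot")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("enzyme", empty)
  expect_error(load_conditions(empty, mep), "empty|malformed")
})

test_that("replicates aggregate as max abundance / mean rates", {
  ab <- tibble::tibble(condition = "c1", replicate = c(1, 1, 2, 2),
                       enzyme = c("e1", "e2", "e1", "e2"),
                       abundance = c(1e-5, 2e-5, 3e-5, 1e-5))
  gr <- tibble::tibble(condition = c("c1", "c1"), replicate = 1:2,
                       growth = c(0.1, 0.3))
  up <- tibble::tibble(condition = c("c1", "c1"), replicate = 1:2,
                       reaction = "upt", rate = c(2, 4))
  agg <- aggregate_replicates(ab, gr, up)
  expect_equal(agg$abundance$abundance[agg$abundance$enzyme == "e1"], 3e-5)
  expect_equal(agg$growth$growth, 0.2)
  expect_equal(agg$uptake$rate, 3)

  # single replicate is the identity
  one <- aggregate_replicates(ab[ab$replicate == 1, ], gr[1, ])
  expect_equal(one$abundance$abundance,
               ab$abundance[ab$replicate == 1])
  # inconsistent protein sets: union, logged
  ab2 <- ab[-4, ]
  expect_message(aggregate_replicates(ab2, gr), "union")
})

test_that("scenario models apply pool cap, uptake bounds and abundances", {
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  cond <- manual_condition("c1", c(e1 = 1e-4), mu = 0.72, U = 5,
                           ptot = 0.5, f = 0.5, sigma = 0.5)
  cm1 <- make_condition_model(m, cond, scenario_spec("pool_only"))
  expect_equal(cm1$pool_cap, 0.125)                # Ptot * f * sigma
  expect_equal(cm1$bounds$ub[cm1$bounds$id == "upt"], 1000)
  expect_null(cm1$usage_ub)

  cm2 <- make_condition_model(m, cond, scenario_spec("pool_plus_uptake"))
  expect_equal(cm2$bounds$ub[cm2$bounds$id == "upt"], 5)

  cm3 <- make_condition_model(m, cond,
                              scenario_spec("pool_uptake_abundance"))
  expect_equal(cm3$usage_ub, c(e1 = 1e-4))

  # nutrient measured but absent from the model exchanges
  bad <- cond
  bad$uptake <- list(c(ghost = 1))
  expect_error(make_condition_model(m, bad, scenario_spec("ii")), "ghost")

  # abundance mass above the pool cap warns about inconsistency
  rich <- manual_condition("c2", c(e1 = 1), mu = 0.72, ptot = 0.001)
  expect_warning(make_condition_model(m, rich, scenario_spec("iii")),
                 "exceeds the pool cap")
})

test_that("feasible sets nest across scenarios (growth non-increasing)", {
  inst <- make_synthetic_instance(n_linear = 3, n_parallel = 1,
                                  n_conditions = 3, n_deflate = 0, seed = 21)
  ev <- evaluate_conditions(list(m = inst$model_true), inst$conditions)
  wide <- tidyr::pivot_wider(ev[c("condition", "scenario", "v_bio")],
                             names_from = "scenario", values_from = "v_bio")
  expect_true(all(wide$pool_uptake_abundance <=
                    wide$pool_plus_uptake + 1e-8))
  expect_true(all(wide$pool_plus_uptake <= wide$pool_only + 1e-8))
})
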