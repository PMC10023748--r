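test_that("kcat_min is the minimum over each enzyme's reactions", {
  toy <- chain_network(c(e1 = 5, e2 = 3))
  enz <- toy$enzymes
  # give e1 a second, slower reaction: also catalyses r2
  enz <- enzyme_table(dplyr::bind_rows(
    enz, tibble::tibble(enzyme = "e1", reaction = "r2", kcat = 2,
                        mw = enz$mw[enz$enzyme == "e1"][1],
                        measured_in_all = TRUE)))
  net2 <- toy$network
  net2$rxns$gpr[net2$rxns$id == "r2"] <- "e1 or e2"
  m <- build_pc_model(net2, enz)
  brute <- vapply(split(m$kcats$kcat, m$kcats$enzyme), min, 0)
  expect_equal(stats::setNames(m$enzymes$kcat_min, m$enzymes$enzyme),
               brute[m$enzymes$enzyme])
  expect_equal(m$enzymes$kcat_min[m$enzymes$enzyme == "e1"], 2)
})

test_that("usage coupling uses -1/(3600 kcat) internally", {
  toy <- chain_network(c(e1 = 1))
  m <- build_pc_model(toy$network, toy$enzymes)
  lp <- prestor:::fba_lp(m)
  row <- which(apply(lp$mat, 1, function(r) r[match("usage__e1", lp$vars)] == -1))
  expect_length(row, 1)
  expect_equal(lp$mat[row, match("r1", lp$vars)], 1 / 3600)
})

test_that("splitting preserves optimal net flux on random objectives", {
  set.seed(42)
  for (rep in 1:5) {
    # random network with reversible reactions
    nm <- 4; nr <- 6
    S <- matrix(0, nm, nr,
                dimnames = list(paste0("m", 1:nm), paste0("r", 1:nr)))
    for (r in 1:nr) S[sample(nm, 2), r] <- c(1, -1)
    S[, 1] <- 0; S[1, 1] <- 1              # exchange in
    S[, nr] <- 0; S[nm, nr] <- -1          # biomass drain
    lb <- c(0, runif(nr - 2, -5, 0), 0)
    ub <- runif(nr, 2, 8)
    net <- metabolic_network(S, lb, ub, paste0("r", nr))
    m <- build_pc_model(net, enzyme_table(tibble::tibble(
      enzyme = "eX", reaction = "r2", kcat = 1e6, mw = 50,
      measured_in_all = TRUE)))
    obj <- rnorm(nr)
    # original LP over net fluxes
    ref <- solve_lp(obj, as.matrix(net$stoich), rep("==", nm), rep(0, nm),
                    lb, ub, maximize = TRUE)
    # split LP, objective mapped via dir * orig column
    objs <- obj[match(m$rxns$orig, net$rxns$id)] * m$rxns$dir
    spl <- solve_lp(objs, as.matrix(m$stoich), rep("==", nm),
                    rep(0, nm), m$rxns$lb, m$rxns$ub, maximize = TRUE)
    expect_identical(ref$status, spl$status)
    if (ref$status == "optimal")
      expect_equal(spl$objval, ref$objval, tolerance = 1e-8)
  }
})

test_that("corrections apply uniformly per enzyme and respect the caps", {
  toy <- chain_network(c(e1 = 2, e2 = 5))
  m <- build_pc_model(toy$network, toy$enzymes)
  m0 <- apply_kcat_corrections(m, c(e1 = 0, e2 = 0))
  expect_equal(m0$kcats$kcat, m$kcats$kcat)

  m1 <- apply_kcat_corrections(m, c(e1 = 3))
  expect_equal(m1$kcats$kcat[m1$kcats$enzyme == "e1"], 5)
  expect_equal(m1$enzymes$kcat_min[m1$enzymes$enzyme == "e1"], 5)

  eps <- 1e5
  at_bound <- (eps - 1) * 2
  expect_no_error(apply_kcat_corrections(m, c(e1 = at_bound), kmax = Inf))
  one_ulp_up <- at_bound * (1 + .Machine$double.eps)
  expect_error(apply_kcat_corrections(m, c(e1 = one_ulp_up), kmax = Inf),
               "fold change")
  expect_error(apply_kcat_corrections(m, c(e1 = 6e7)), "cap|fold")
  expect_error(apply_kcat_corrections(m, c(e1 = -1)), "negative")
  expect_error(apply_kcat_corrections(m, c(e1 = -3), allow_negative = TRUE),
               "<= 0")
})

test_that("external kcats replace isozyme copies but never complexes", {
  toy <- make_toy_network(3, 2, seed = 5)   # r2 complex, p1 isozymes
  m <- build_pc_model(toy$network, toy$enzymes)
  tab <- tibble::tibble(reaction = c("p1", "r2", "ghost"),
                        kcat = c(7, 9, 1))
  expect_warning(m2 <- substitute_external_kcats(m, tab), "ghost")
  p1 <- m2$kcats[m2$kcats$orig_rxn == "p1", ]
  expect_true(all(p1$kcat == 7))            # both isozyme copies
  r2 <- m2$kcats[m2$kcats$orig_rxn == "r2", ]
  expect_equal(r2$kcat, m$kcats$kcat[m$kcats$orig_rxn == "r2"])  # complex
  expect_equal(substitute_external_kcats(m, tab[0, ])$kcats$kcat,
               m$kcats$kcat)
})

test_that("kcat tables round-trip and reproduce kcat_min", {
  toy <- make_toy_network(3, 2, seed = 6)
  m <- build_pc_model(toy$network, toy$enzymes)
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_kcat_table(m, path)
  expect_identical(nrow(tab),
                   nrow(unique(m$kcats[c("enzyme", "orig_rxn")])))
  back <- read_kcat_table(path)
  expect_equal(sort(back$kcat_s), sort(tab$kcat_s), tolerance = 1e-12)
  kmin <- vapply(split(back$kcat_s, back$enzyme), min, 0)
  expect_equal(unname(kmin[m$enzymes$enzyme]),
               m$enzymes$kcat_min, tolerance = 1e-12)
})

test_that("a GPR-free network keeps its flux feasible set", {
  toy <- chain_network(c(e1 = 1))
  net <- toy$network
  net$rxns$gpr <- ""
  m <- build_pc_model(net, toy$enzymes[0, ])
  res <- fba(m, bounds = tibble::tibble(id = "upt", lb = 0, ub = 7))
  expect_equal(res$objective, 7, tolerance = 1e-9)  # no kinetic limits
})
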