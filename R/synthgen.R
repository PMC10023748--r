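# Synthetic toy models and condition data with known ground-truth kcat
# deflations.
#
# The generator emulates the inputs the correction method consumes: a small
# metabolic network (substrate uptake -> linear chain -> optional parallel
# branches -> biomass) with per-reaction enzymes including one two-subunit
# complex and one isozyme pair, plus per-condition "measurements" obtained
# by solving the true-kcat model and exporting its optimal growth and
# enzyme usage (times a headroom factor and optional multiplicative
# lognormal noise) as the measured abundances. Deflating chosen kcats then
# yields instances where the correct correction delta is known exactly.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a toy metabolic network with per-reaction enzymes
#'
#' Topology: one substrate exchange, a linear chain of `n_linear`
#' enzyme-catalysed conversions (the second chain step, when present, is
#' catalysed by a two-subunit complex), optionally `n_parallel` parallel
#' routes between the chain product and the biomass precursor (the first
#' route carries two isozymes), and a biomass drain. Turnover numbers are
#' log-uniform on [0.1, 100] s^-1 and molecular weights uniform on
#' [20, 200] g/mmol.
#'
#' @param n_linear number of chain reactions (>= 1).
#' @param n_parallel number of parallel routes (>= 0).
#' @param seed RNG seed (local; does not disturb the global RNG).
#' @return list with `network` (a `metabolic_network`) and `enzymes`
#'   (an [enzyme_table()], all flagged `measured_in_all`).
#' @export
make_toy_network <- function(n_linear = 3, n_parallel = 2, seed = 1) {
  stopifnot(n_linear >= 1, n_parallel >= 0)
  with_local_seed(seed, {
    mets <- paste0("m", seq_len(n_linear + 1 + (n_parallel > 0)))
    nm <- length(mets)
    rxn <- list()
    add <- function(id, stoich, lb, ub, gpr) {
      rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich,
                                       lb = lb, ub = ub, gpr = gpr)
    }
    add("upt", c(m1 = 1), 0, 1000, "")
    enz <- list()
    reg <- function(enzyme, reaction) {
      enz[[length(enz) + 1L]] <<- tibble::tibble(enzyme = enzyme,
                                                 reaction = reaction)
    }
    for (i in seq_len(n_linear)) {
      id <- paste0("r", i)
      st <- stats::setNames(c(-1, 1), mets[c(i, i + 1)])
      if (i == 2 && n_linear >= 2) {
        gpr <- paste0("cx", i, "a and cx", i, "b")
        reg(paste0("cx", i, "a"), id); reg(paste0("cx", i, "b"), id)
      } else {
        gpr <- paste0("e", i)
        reg(paste0("e", i), id)
      }
      add(id, st, 0, 1000, gpr)
    }
    if (n_parallel > 0) {
      for (p in seq_len(n_parallel)) {
        id <- paste0("p", p)
        st <- stats::setNames(c(-1, 1), mets[c(n_linear + 1, nm)])
        if (p == 1) {
          gpr <- paste0("pz", p, "a or pz", p, "b")
          reg(paste0("pz", p, "a"), id); reg(paste0("pz", p, "b"), id)
        } else {
          gpr <- paste0("ep", p)
          reg(paste0("ep", p), id)
        }
        add(id, st, 0, 1000, gpr)
      }
    }
    add("biomass", stats::setNames(-1, mets[nm]), 0, 1000, "")

    S <- matrix(0, nm, length(rxn),
                dimnames = list(mets, vapply(rxn, `[[`, "", "id")))
    for (r in rxn) S[names(r$stoich), r$id] <- r$stoich
    net <- metabolic_network(S,
                             lb = vapply(rxn, `[[`, 0, "lb"),
                             ub = vapply(rxn, `[[`, 0, "ub"),
                             biomass = "biomass",
                             gpr = vapply(rxn, `[[`, "", "gpr"))
    pairs <- dplyr::bind_rows(enz)
    enzymes <- unique(pairs$enzyme)
    mw <- stats::setNames(stats::runif(length(enzymes), 20, 200), enzymes)
    pairs$kcat <- 10^stats::runif(nrow(pairs), -1, 2)
    pairs$mw <- mw[pairs$enzyme]
    pairs$measured_in_all <- TRUE
    list(network = net, enzymes = enzyme_table(pairs))
  })
}

#' Simulate condition-specific measurements from a true-kcat model
#'
#' Per condition: draw a substrate uptake bound, maximise growth of the
#' true-kcat model, record the optimum as the measured growth rate, and
#' export the optimal enzyme usage -- multiplied by the headroom factor and
#' multiplicative lognormal noise (coefficient of variation `noise_cv`),
#' floored so every abundance still supports the optimal flux -- as the
#' measured abundances. Enzymes idle at the optimum receive a small
#' baseline abundance. Pool parameters (`Ptot`, `f`, `sigma`) are set so
#' the pool constraint holds with slack `pool_slack` at the optimum.
#'
#' @param model a `pc_model` built from the *true* enzyme table.
#' @param n_conditions number of conditions to simulate.
#' @param noise_cv coefficient of variation of the multiplicative
#'   lognormal abundance noise (0 = noise-free).
#' @param seed RNG seed (local).
#' @param headroom multiplicative abundance headroom (>= 1; with 1 and no
#'   noise the abundance bounds are exactly binding).
#' @param uptake_range range from which substrate uptake bounds are drawn
#'   (mmol/gDW/h).
#' @param pool_slack pool cap as a multiple of the enzyme mass actually
#'   used at the optimum (> 1 keeps abundance bounds, not the pool,
#'   binding).
#' @param idle_abundance baseline abundance for enzymes unused at the
#'   optimum, as a fraction of the smallest used abundance.
#' @return a validated condition tibble.
#' @export
simulate_conditions <- function(model, n_conditions, noise_cv = 0, seed = 1,
                                headroom = 1.2, uptake_range = c(1, 10),
                                pool_slack = 1.5, idle_abundance = 0.05) {
  stopifnot(inherits(model, "pc_model"), n_conditions >= 1, headroom >= 1)
  upt <- exchange_reactions(model$network)[1]
  upt_copy <- model$rxns$id[model$rxns$orig == upt][1]
  mwv <- stats::setNames(model$enzymes$mw, model$enzymes$enzyme)
  with_local_seed(seed, {
    rows <- vector("list", n_conditions)
    for (j in seq_len(n_conditions)) {
      ok <- FALSE
      for (try in 1:20) {
        U <- stats::runif(1, uptake_range[1], uptake_range[2])
        res <- fba(model, bounds = tibble::tibble(id = upt_copy,
                                                  lb = 0, ub = U))
        if (res$status == "optimal" && res$objective > 1e-8) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a feasible condition (try ", j, ")")
      usage <- res$usage
      names(usage) <- sub("^usage__", "", names(usage))
      used <- usage[usage > 1e-12]
      base <- if (length(used)) idle_abundance * min(used) else 1e-6
      sdlog <- sqrt(log(1 + noise_cv^2))
      noise <- if (noise_cv > 0)
        stats::rlnorm(length(usage), -sdlog^2 / 2, sdlog) else
          rep(1, length(usage))
      factor <- pmax(headroom * noise, 1.0)   # keep mu attainable
      E <- pmax(usage, base) * factor
      f <- 0.5; sigma <- 0.5
      pool_used <- sum(mwv[names(E)] * E)
      ptot <- pool_used * pool_slack / (f * sigma)
      rows[[j]] <- tibble::tibble(
        id = sprintf("cond%02d", j), growth = res$objective,
        ptot = ptot, f = f, sigma = sigma,
        gam = stats::runif(1, 20, 80),
        abundance = list(E),
        uptake = list(stats::setNames(U, upt)),
        medium = list(upt))
    }
    validate_conditions(dplyr::bind_rows(rows))
  })
}

#' Deflate turnover numbers and record the ground truth
#'
#' Divides every reaction-specific kcat of each target enzyme by its
#' factor (> 1), emulating the systematic underestimation of in vivo
#' turnover numbers by in vitro measurements. The ground-truth correction
#' is `kcat_min(true) - kcat_min(deflated)` per enzyme.
#'
#' @param enzymes an [enzyme_table()] with the true kcats.
#' @param factors named numeric vector (enzyme -> deflation factor > 1);
#'   empty input returns the table unchanged.
#' @return list with `enzymes` (deflated table) and `truth` (tibble:
#'   `enzyme`, `kcat_true`, `kcat_deflated`, `delta_true`).
#' @export
deflate_kcats <- function(enzymes, factors) {
  enzymes <- enzyme_table(enzymes)
  if (length(factors) == 0)
    return(list(enzymes = enzymes,
                truth = tibble::tibble(enzyme = character(0),
                                       kcat_true = numeric(0),
                                       kcat_deflated = numeric(0),
                                       delta_true = numeric(0))))
  stopifnot(!is.null(names(factors)), all(factors > 1))
  unknown <- setdiff(names(factors), enzymes$enzyme)
  if (length(unknown))
    stop("deflation targets not in the enzyme table: ",
         paste(unknown, collapse = ", "))
  kmin_true <- enzymes |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(kcat_true = min(.data$kcat))
  out <- enzymes
  idx <- out$enzyme %in% names(factors)
  out$kcat[idx] <- out$kcat[idx] / factors[out$enzyme[idx]]
  truth <- kmin_true |>
    dplyr::filter(.data$enzyme %in% names(factors)) |>
    dplyr::mutate(
      kcat_deflated = .data$kcat_true / unname(factors[.data$enzyme]),
      delta_true = .data$kcat_true - .data$kcat_deflated)
  list(enzymes = enzyme_table(out), truth = truth)
}

#' Generate a complete synthetic benchmark instance
#'
#' Builds the toy network, simulates conditions from the true kcats, then
#' deflates the kcats of `n_deflate` chain enzymes (single-enzyme chain
#' steps, which are identifiable: their capacity constraint binds in every
#' simulated condition) by factors drawn log-uniformly from
#' `deflation_range`.
#'
#' @param n_linear,n_parallel toy network size (see [make_toy_network()]).
#' @param n_conditions number of simulated conditions.
#' @param n_deflate number of deflated enzymes (chain enzymes first).
#' @param deflation_range range of deflation factors (log-uniform draw).
#' @param noise_cv,headroom,seed passed to [simulate_conditions()] /
#'   [make_toy_network()].
#' @return list with `network`, `enzymes_true`, `enzymes` (deflated),
#'   `truth`, `conditions`, `model` (pc_model on the deflated kcats) and
#'   `model_true`.
#' @export
make_synthetic_instance <- function(n_linear = 4, n_parallel = 2,
                                    n_conditions = 6, n_deflate = 3,
                                    deflation_range = c(2, 8),
                                    noise_cv = 0, headroom = 1, seed = 1) {
  toy <- make_toy_network(n_linear, n_parallel, seed = seed)
  model_true <- build_pc_model(toy$network, toy$enzymes)
  conditions <- simulate_conditions(model_true, n_conditions,
                                    noise_cv = noise_cv, seed = seed + 1,
                                    headroom = headroom)
  chain <- paste0("e", seq_len(n_linear))
  chain <- intersect(chain, toy$enzymes$enzyme)
  if (n_deflate > length(chain))
    stop("not enough single-enzyme chain steps to deflate (",
         length(chain), " available)")
  targets <- chain[seq_len(n_deflate)]
  factors <- with_local_seed(seed + 2,
    stats::setNames(10^stats::runif(length(targets),
                                    log10(deflation_range[1]),
                                    log10(deflation_range[2])), targets))
  defl <- deflate_kcats(toy$enzymes, factors)
  list(network = toy$network, enzymes_true = toy$enzymes,
       enzymes = defl$enzymes, truth = defl$truth, conditions = conditions,
       model = build_pc_model(toy$network, defl$enzymes),
       model_true = model_true)
}
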