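# Condition-specific experimental data: loading, replicate aggregation,
# and assembly of condition-constrained models for the three validation
# scenarios.
#
# A condition set is a tibble with one row per experimental condition and
# columns:
#   id        condition identifier
#   growth    measured specific growth rate mu_exp (h^-1)
#   ptot      total protein content (g/gDW)
#   f         enzyme mass fraction of the proteome (0, 1]
#   sigma     average enzyme saturation (0, 1]
#   gam       growth-associated maintenance (mmol/gDW/h; consumed as an
#             input coefficient, not fitted)
#   abundance list column: named numeric, enzyme abundances (mmol/gDW)
#   uptake    list column: named numeric, measured nutrient exchange
#             rates (mmol/gDW/h), keyed by exchange reaction identifier
#   medium    list column: character, exchange reactions of nutrients
#             present in the culture medium

#' Validate a condition tibble
#' @param conditions a condition tibble (see file header for columns).
#' @return the tibble, checked.
#' @export
validate_conditions <- function(conditions) {
  need <- c("id", "growth", "ptot", "f", "sigma", "gam",
            "abundance", "uptake", "medium")
  miss <- setdiff(need, names(conditions))
  if (length(miss))
    stop("condition table is missing columns: ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(conditions$growth)) || any(conditions$growth <= 0))
    stop("every condition needs a measured growth rate > 0")
  if (any(!is.finite(conditions$ptot)) || any(conditions$ptot <= 0))
    stop("every condition needs a total protein content > 0")
  if (any(conditions$f <= 0 | conditions$f > 1) ||
      any(conditions$sigma <= 0 | conditions$sigma > 1))
    stop("f and sigma must lie in (0, 1]")
  ab <- unlist(conditions$abundance)
  if (length(ab) && any(ab < 0, na.rm = TRUE))
    stop("negative enzyme abundances")
  tibble::as_tibble(conditions)
}

#' Enzymes measured in every condition (the set M)
#'
#' @param conditions a condition tibble.
#' @return character vector of enzyme identifiers with a non-missing
#'   abundance in every condition.
#' @export
measured_in_all <- function(conditions) {
  sets <- lapply(conditions$abundance,
                 function(a) names(a)[!is.na(a)])
  if (length(sets) == 0) return(character(0))
  sort(Reduce(intersect, sets))
}

#' Load condition data from TSV files
#'
#' @param abundance_path TSV abundance matrix: first column `enzyme`,
#'   remaining columns one per condition (mmol/gDW; empty = missing).
#' @param meta_path TSV condition metadata with columns `condition`,
#'   `growth`, `ptot`, `f`, `sigma`, `gam`. A missing `ptot` is filled
#'   according to `ptot_fill`.
#' @param uptake_path optional long TSV (`condition`, `reaction`, `rate`)
#'   of measured nutrient exchange rates.
#' @param medium optional character vector (or named list per condition)
#'   of exchange reactions present in the culture medium.
#' @param ptot_fill policy for missing total protein content; `"max"`
#'   (default) substitutes the maximum Ptot measured across the remaining
#'   conditions (logged), `"error"` fails.
#' @return a validated condition tibble; enzymes measured in every
#'   condition define the correctable set (see [measured_in_all()]).
#' @export
load_conditions <- function(abundance_path, meta_path, uptake_path = NULL,
                            medium = NULL, ptot_fill = c("max", "error")) {
  ptot_fill <- match.arg(ptot_fill)
  ab <- utils::read.delim(abundance_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(ab) == 0 || ncol(ab) < 2)
    stop("empty or malformed abundance matrix: ", abundance_path)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (nrow(meta) == 0) stop("empty condition metadata: ", meta_path)
  conds <- meta$condition
  missing_cols <- setdiff(conds, names(ab)[-1])
  if (length(missing_cols))
    stop("abundance matrix lacks condition columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(is.na(meta$growth)))
    stop("missing growth rate for condition(s): ",
         paste(meta$condition[is.na(meta$growth)], collapse = ", "))
  if (any(is.na(meta$ptot))) {
    if (ptot_fill == "error")
      stop("missing Ptot for condition(s): ",
           paste(meta$condition[is.na(meta$ptot)], collapse = ", "))
    fill <- max(meta$ptot, na.rm = TRUE)
    message("filling missing Ptot for ",
            paste(meta$condition[is.na(meta$ptot)], collapse = ", "),
            " with the maximum measured value (", fill, " g/gDW)")
    meta$ptot[is.na(meta$ptot)] <- fill
  }
  upt <- if (!is.null(uptake_path))
    utils::read.delim(uptake_path, stringsAsFactors = FALSE) else NULL

  med_for <- function(cond) {
    if (is.null(medium)) return(character(0))
    if (is.list(medium)) as.character(medium[[cond]])
    else as.character(medium)
  }
  abundance <- lapply(conds, function(cn) {
    v <- ab[[cn]]
    stats::setNames(as.numeric(v), ab[[1]])
  })
  uptake <- lapply(conds, function(cn) {
    if (is.null(upt)) return(stats::setNames(numeric(0), character(0)))
    u <- upt[upt$condition == cn, ]
    stats::setNames(u$rate, u$reaction)
  })
  validate_conditions(tibble::tibble(
    id = conds, growth = meta$growth, ptot = meta$ptot, f = meta$f,
    sigma = meta$sigma, gam = meta$gam,
    abundance = abundance, uptake = uptake,
    medium = lapply(conds, med_for)))
}

#' Aggregate replicate measurements into per-condition values
#'
#' Protein abundances are aggregated as the per-protein maximum over all
#' replicates of a condition; growth and nutrient exchange rates as the
#' per-condition mean. Replicates with inconsistent protein sets are
#' combined over the union, treating a protein absent from a replicate as
#' missing there (logged).
#'
#' @param abundance tibble (`condition`, `replicate`, `enzyme`,
#'   `abundance`).
#' @param growth tibble (`condition`, `replicate`, `growth`).
#' @param uptake optional tibble (`condition`, `replicate`, `reaction`,
#'   `rate`).
#' @return list with per-condition tibbles `abundance` (max), `growth`
#'   (mean) and `uptake` (mean).
#' @export
aggregate_replicates <- function(abundance, growth, uptake = NULL) {
  ab <- tibble::as_tibble(abundance)
  sets <- ab |>
    dplyr::distinct(.data$condition, .data$replicate, .data$enzyme) |>
    dplyr::count(.data$condition, .data$enzyme, name = "n_rep")
  nrep <- ab |>
    dplyr::distinct(.data$condition, .data$replicate) |>
    dplyr::count(.data$condition, name = "total")
  incons <- dplyr::left_join(sets, nrep, by = "condition") |>
    dplyr::filter(.data$n_rep < .data$total)
  if (nrow(incons))
    message("inconsistent protein sets across replicates for ",
            dplyr::n_distinct(incons$condition),
            " condition(s); using the union with missing-as-absent")
  out_ab <- ab |>
    dplyr::group_by(.data$condition, .data$enzyme) |>
    dplyr::summarise(abundance = max(.data$abundance, na.rm = TRUE),
                     .groups = "drop")
  out_gr <- tibble::as_tibble(growth) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(growth = mean(.data$growth), .groups = "drop")
  out_up <- if (!is.null(uptake))
    tibble::as_tibble(uptake) |>
      dplyr::group_by(.data$condition, .data$reaction) |>
      dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
  else NULL
  list(abundance = out_ab, growth = out_gr, uptake = out_up)
}

#' Scenario specification for condition-constrained models
#'
#' @param scenario one of `"pool_only"` (i), `"pool_plus_uptake"` (ii),
#'   `"pool_uptake_abundance"` (iii); the numerals `"i"`, `"ii"`, `"iii"`
#'   are accepted.
#' @param default_uptake default nutrient uptake bound (mmol/gDW/h) used
#'   for medium nutrients without a measurement; default 1000.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("pool_only", "pool_plus_uptake",
                                       "pool_uptake_abundance",
                                       "i", "ii", "iii"),
                          default_uptake = 1000) {
  scenario <- match.arg(scenario)
  scenario <- c(i = "pool_only", ii = "pool_plus_uptake",
                iii = "pool_uptake_abundance")[scenario] %||% scenario
  scenario <- unname(scenario)
  if (!is.finite(default_uptake) || default_uptake <= 0)
    stop("default uptake bound must be > 0")
  structure(list(scenario = scenario, default_uptake = default_uptake),
            class = "scenario_spec")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Build a condition-constrained model
#'
#' Applies the protein-pool cap `Ptot * f * sigma` (over all enzymes,
#' measured and unmeasured), the scenario's nutrient uptake bounds, and --
#' for scenario (iii) -- per-enzyme usage bounds `e_i <= E_i` for every
#' measured enzyme.
#'
#' Uptake policy: for every exchange reaction in the condition's medium
#' the *import* direction is bounded by the measured rate (scenarios ii
#' and iii) or the default (scenario i, or when unmeasured); import
#' through exchanges not in the medium is closed. An empty medium leaves
#' the network's own exchange bounds in place, capped at the default.
#'
#' @param model a `pc_model`.
#' @param cond one row of a condition tibble.
#' @param scenario a [scenario_spec()].
#' @return a `condition_model`: list with `model`, `pool_cap`, `bounds`,
#'   `usage_ub`, `condition`, `scenario`.
#' @export
make_condition_model <- function(model, cond, scenario = scenario_spec()) {
  stopifnot(inherits(model, "pc_model"), inherits(scenario, "scenario_spec"))
  if (is.data.frame(cond)) {
    stopifnot(nrow(cond) == 1)
    cond <- as.list(cond)
    cond$abundance <- cond$abundance[[1]]
    cond$uptake <- cond$uptake[[1]]
    cond$medium <- cond$medium[[1]]
  }
  pool_cap <- cond$ptot * cond$f * cond$sigma

  exch <- exchange_reactions(model$network)
  measured_upt <- cond$uptake
  unknown_upt <- setdiff(names(measured_upt), exch)
  if (length(unknown_upt))
    stop("measured nutrients without a matching exchange reaction: ",
         paste(unknown_upt, collapse = ", "))
  medium <- cond$medium
  use_measured <- scenario$scenario != "pool_only"

  bl <- list()
  for (r in exch) {
    copies <- model$rxns[model$rxns$orig == r, ]
    # import copy: the direction that produces the exchanged metabolite
    met <- rownames(model$stoich)[which(model$stoich[, copies$id[1]] != 0)]
    for (k in seq_len(nrow(copies))) {
      sgn <- model$stoich[met, copies$id[k]]
      if (sgn <= 0) next                      # export direction: untouched
      in_medium <- length(medium) == 0 || r %in% medium
      cap <- if (!in_medium) 0
      else if (use_measured && r %in% names(measured_upt) &&
               !is.na(measured_upt[[r]])) abs(measured_upt[[r]])
      else scenario$default_uptake
      bl[[length(bl) + 1L]] <- tibble::tibble(
        id = copies$id[k], lb = copies$lb[k],
        ub = min(copies$ub[k], cap))
    }
  }
  bounds <- if (length(bl)) dplyr::bind_rows(bl) else NULL

  usage_ub <- NULL
  if (scenario$scenario == "pool_uptake_abundance") {
    ab <- cond$abundance
    ab <- ab[!is.na(ab)]
    ab <- ab[names(ab) %in% model$enzymes$enzyme]
    if (length(ab)) {
      usage_ub <- ab
      mwv <- stats::setNames(model$enzymes$mw, model$enzymes$enzyme)
      mass <- sum(mwv[names(ab)] * ab)
      if (mass > pool_cap)
        warning("measured enzyme mass (", signif(mass, 4),
                " g/gDW) exceeds the pool cap (", signif(pool_cap, 4),
                " g/gDW); data inconsistency for condition ", cond$id)
    }
  }

  structure(list(model = model, pool_cap = pool_cap, bounds = bounds,
                 usage_ub = usage_ub, condition = cond$id,
                 scenario = scenario$scenario),
            class = "condition_model")
}

#' Predict maximal growth for a condition-constrained model
#'
#' Flux balance analysis maximising the biomass reaction; infeasible
#' models yield `NA` (reported, never zero-filled), an unbounded
#' objective is flagged (a missing pool cap).
#'
#' @param cmodel a `condition_model` from [make_condition_model()].
#' @param tol solver feasibility tolerance.
#' @return list with `status` and `objective` (`v_bio`, h^-1).
#' @export
predict_growth <- function(cmodel, tol = 1e-9) {
  stopifnot(inherits(cmodel, "condition_model"))
  res <- fba(cmodel$model, pool_cap = cmodel$pool_cap,
             usage_ub = cmodel$usage_ub, bounds = cmodel$bounds, tol = tol)
  if (res$status == "unbounded")
    warning("unbounded growth objective (missing pool cap?) for condition ",
            cmodel$condition)
  res
}
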