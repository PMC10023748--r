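# Growth-prediction validation across constraint scenarios.

#' Tabulate growth predictions and relative errors per condition/scenario
#'
#' For one or several (corrected) models, predicts maximal growth for every
#' condition under the requested constraint scenarios and tabulates the
#' relative error against the measured growth rate. Infeasible models are
#' reported with `feasible = FALSE` and `NA` predictions, never
#' zero-filled.
#'
#' @param models a `pc_model` or a named list of them (e.g. uncorrected
#'   vs corrected vs baseline) for side-by-side comparison.
#' @param conditions a condition tibble.
#' @param scenarios character vector among `"pool_only"`,
#'   `"pool_plus_uptake"`, `"pool_uptake_abundance"` (or `"i"`, `"ii"`,
#'   `"iii"`); default all three.
#' @param default_uptake default uptake bound (mmol/gDW/h).
#' @param tol solver tolerance.
#' @return tibble (model, condition, scenario, mu, v_bio, omega,
#'   feasible).
#' @export
evaluate_conditions <- function(models, conditions,
                                scenarios = c("pool_only",
                                              "pool_plus_uptake",
                                              "pool_uptake_abundance"),
                                default_uptake = 1000, tol = 1e-9) {
  if (inherits(models, "pc_model")) models <- list(model = models)
  stopifnot(length(names(models)) == length(models))
  conditions <- validate_conditions(conditions)
  rows <- list()
  for (mn in names(models)) {
    for (sc in scenarios) {
      spec <- scenario_spec(sc, default_uptake = default_uptake)
      for (q in seq_len(nrow(conditions))) {
        cm <- make_condition_model(models[[mn]], conditions[q, ], spec)
        g <- predict_growth(cm, tol = tol)
        ok <- g$status == "optimal"
        rows[[length(rows) + 1L]] <- tibble::tibble(
          model = mn, condition = conditions$id[q], scenario = spec$scenario,
          mu = conditions$growth[q],
          v_bio = if (ok) g$objective else NA_real_,
          omega = if (ok) relative_error(conditions$growth[q], g$objective)
                  else NA_real_,
          feasible = ok)
      }
    }
  }
  dplyr::bind_rows(rows)
}
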