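# The objective-control-coefficient correction heuristic (the GECKO
# baseline) and its condition-wise aggregation.
#
# For one condition, the heuristic repeatedly (1) scores every enzyme by
# the relative growth gain from a 1000-fold increase of its turnover
# numbers in the pool-only model, (2) replaces the top-ranked enzyme's
# kcats by the maximum value reported for that enzyme across organisms
# (never decreasing them), and (3) stops once predicted growth is within
# 10% of the measurement or no control coefficient exceeds 0.001.

#' Objective control coefficients
#'
#' For each enzyme, the effect of a `factor`-fold increase of all its
#' turnover numbers on pool-only predicted growth:
#' `(v_bio(kcat x factor) - v_bio(base)) / v_bio(base)` (relative mode,
#' default) or the absolute difference.
#'
#' @param model a `pc_model`.
#' @param cond one condition row (pool cap and uptake bounds are taken
#'   from it; abundances are not used).
#' @param factor perturbation factor (default 1000).
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param default_uptake default uptake bound (mmol/gDW/h).
#' @param tol solver tolerance.
#' @return named numeric vector of coefficients (one per enzyme).
#' @export
control_coefficients <- function(model, cond, factor = 1000,
                                 mode = c("relative", "absolute"),
                                 default_uptake = 1000, tol = 1e-9) {
  mode <- match.arg(mode)
  scen <- scenario_spec("pool_only", default_uptake = default_uptake)
  cm <- make_condition_model(model, cond, scen)
  base <- predict_growth(cm, tol = tol)
  if (base$status != "optimal")
    stop("base pool-only FBA infeasible for condition ", cm$condition)
  v0 <- base$objective
  enzymes <- model$enzymes$enzyme
  vapply(enzymes, function(e) {
    pert <- model
    idx <- pert$kcats$enzyme == e
    pert$kcats$kcat[idx] <- pert$kcats$kcat[idx] * factor
    pert <- refresh_kcat_min(pert)
    cmp <- cm; cmp$model <- pert
    g <- predict_growth(cmp, tol = tol)
    if (g$status != "optimal") return(NA_real_)
    if (mode == "relative") (g$objective - v0) / v0 else g$objective - v0
  }, 0)
}

#' Condition-wise kcat correction by control coefficients
#'
#' @param model a `pc_model`.
#' @param cond one condition row.
#' @param kcat_db named numeric vector: per enzyme, the maximum turnover
#'   number across organisms (s^-1) used as the replacement value.
#' @param growth_tol the heuristic stops once predicted growth is at most
#'   this fraction below the measured rate (default 0.1).
#' @param coef_threshold minimum control coefficient to act on (default
#'   0.001).
#' @param factor perturbation factor for scoring (default 1000).
#' @param default_uptake,tol see [control_coefficients()].
#' @return a `heuristic_trace`: `trace` tibble (iteration, enzyme,
#'   coefficient, kcat_old, kcat_new), `stop_reason` (one of
#'   `growth_within_tolerance`, `no_coefficient_above_threshold`,
#'   `max_iterations`), `growth` (final predicted), `mu` (measured), and
#'   `model` (the corrected `pc_model`).
#' @export
gecko_correct_condition <- function(model, cond, kcat_db, growth_tol = 0.1,
                                    coef_threshold = 0.001, factor = 1000,
                                    default_uptake = 1000, tol = 1e-9) {
  if (is.data.frame(cond)) mu <- cond$growth[[1]] else mu <- cond$growth
  scen <- scenario_spec("pool_only", default_uptake = default_uptake)
  corrected <- character(0)
  rows <- list()
  stop_reason <- "max_iterations"
  max_iter <- nrow(model$enzymes)
  g <- NA_real_
  for (it in seq_len(max_iter + 1L)) {
    cm <- make_condition_model(model, cond, scen)
    res <- predict_growth(cm, tol = tol)
    if (res$status != "optimal")
      stop("pool-only FBA infeasible during the heuristic")
    g <- res$objective
    if (g >= (1 - growth_tol) * mu) { stop_reason <- "growth_within_tolerance"; break }
    if (it > max_iter) break
    cc <- control_coefficients(model, cond, factor = factor,
                               default_uptake = default_uptake, tol = tol)
    cc <- cc[setdiff(names(cc), corrected)]
    cc <- cc[!is.na(cc) & cc > coef_threshold]
    if (length(cc) == 0) { stop_reason <- "no_coefficient_above_threshold"; break }
    ord <- order(-cc, names(cc))          # ties by enzyme identifier
    pick <- names(cc)[ord[1]]
    old <- model$enzymes$kcat_min[model$enzymes$enzyme == pick]
    db <- kcat_db[[pick]]
    if (is.null(db) || is.na(db))
      stop("no database maximum for enzyme '", pick, "'")
    idx <- model$kcats$enzyme == pick
    model$kcats$kcat[idx] <- pmax(model$kcats$kcat[idx], db)  # never decrease
    model <- refresh_kcat_min(model)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      iteration = length(rows) + 1L, enzyme = pick,
      coefficient = unname(cc[ord[1]]), kcat_old = old,
      kcat_new = model$enzymes$kcat_min[model$enzymes$enzyme == pick])
    corrected <- c(corrected, pick)
  }
  structure(list(
    trace = if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(iteration = integer(0), enzyme = character(0),
                     coefficient = numeric(0), kcat_old = numeric(0),
                     kcat_new = numeric(0)),
    stop_reason = stop_reason, growth = g, mu = mu, model = model
  ), class = "heuristic_trace")
}

#' @export
print.heuristic_trace <- function(x, ...) {
  cat("<heuristic_trace> ", nrow(x$trace), " corrections; stop: ",
      x$stop_reason, "; predicted growth ", signif(x$growth, 4),
      " vs measured ", signif(x$mu, 4), " h^-1\n", sep = "")
  invisible(x)
}

#' Aggregate condition-specific corrected models (union/max)
#'
#' Combines models corrected per condition into a single model by taking,
#' for each (enzyme, reaction) pair, the maximum turnover number across
#' the inputs.
#'
#' @param models list of `pc_model`s sharing the same structure.
#' @return a single aggregated `pc_model`.
#' @export
aggregate_union_max <- function(models) {
  stopifnot(length(models) >= 1)
  base <- models[[1]]
  key <- paste(base$kcats$enzyme, base$kcats$rxn)
  for (m in models[-1]) {
    k2 <- paste(m$kcats$enzyme, m$kcats$rxn)
    if (!identical(sort(key), sort(k2)))
      stop("models do not share the same enzyme-reaction structure")
    base$kcats$kcat <- pmax(base$kcats$kcat,
                            m$kcats$kcat[match(key, k2)])
  }
  refresh_kcat_min(base)
}
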