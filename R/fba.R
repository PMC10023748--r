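# Flux balance analysis on protein-constrained models.
#
# The LP has one flux variable per split reaction and one usage variable
# e_i (mmol/gDW) per enzyme. Enzyme mass-balance rows tie usage to flux via
# sum_j coef_ij / (3600 * kcat_ij) * v_j - e_i = 0, and an optional
# protein-pool row bounds sum_i MW_i * e_i by Ptot * f * sigma.

#' Flux balance analysis
#'
#' Maximises (by default) the flux through `objective` subject to steady
#' state, flux bounds, enzyme usage coupling, optional per-enzyme usage
#' bounds, and an optional protein-pool cap.
#'
#' @param model a `pc_model`.
#' @param pool_cap protein-pool cap in g/gDW (`Inf` = no pool row).
#' @param usage_ub optional named vector of usage upper bounds
#'   (mmol/gDW) for a subset of enzymes.
#' @param bounds optional data frame (`id`, `lb`, `ub`) overriding split
#'   reaction bounds.
#' @param objective split reaction identifier (default: biomass).
#' @param maximize direction (default `TRUE`).
#' @param tol solver feasibility tolerance (default `1e-9`).
#' @return list with `status`, `objective` (`NA` when infeasible,
#'   flagged unbounded when the pool cap and bounds leave the objective
#'   unlimited), `fluxes` (named, split reactions), `usage` (named,
#'   enzymes).
#' @export
fba <- function(model, pool_cap = Inf, usage_ub = NULL, bounds = NULL,
                objective = model$biomass, maximize = TRUE, tol = 1e-9) {
  lp <- fba_lp(model, pool_cap, usage_ub, bounds)
  obj <- rep(0, length(lp$lb))
  oi <- match(objective, lp$vars)
  if (is.na(oi)) stop("unknown objective reaction: ", objective)
  obj[oi] <- 1
  sol <- solve_lp(obj, lp$mat, lp$dir, lp$rhs, lp$lb, lp$ub,
                  maximize = maximize, tol = tol)
  nv <- nrow(model$rxns)
  if (sol$status != "optimal")
    return(list(status = sol$status, objective = NA_real_,
                fluxes = NULL, usage = NULL))
  list(status = "optimal", objective = sol$objval,
       fluxes = stats::setNames(sol$x[seq_len(nv)], lp$vars[seq_len(nv)]),
       usage = stats::setNames(sol$x[-seq_len(nv)], lp$vars[-seq_len(nv)]),
       dual = sol$dual, lp = lp)
}

# Assemble the FBA constraint blocks shared by fba() and the correction
# programs. Variable order: split-reaction fluxes, then enzyme usages.
fba_lp <- function(model, pool_cap = Inf, usage_ub = NULL, bounds = NULL) {
  nv <- nrow(model$rxns)
  enz <- model$enzymes$enzyme
  ne <- length(enz)
  vars <- c(model$rxns$id, paste0("usage__", enz, recycle0 = TRUE))

  lb <- c(model$rxns$lb, rep(0, ne))
  ub <- c(model$rxns$ub, rep(Inf, ne))
  if (!is.null(bounds)) {
    idx <- match(bounds$id, model$rxns$id)
    if (anyNA(idx)) stop("bounds refer to unknown split reactions: ",
                         paste(bounds$id[is.na(idx)], collapse = ", "))
    lb[idx] <- bounds$lb
    ub[idx] <- bounds$ub
  }
  if (!is.null(usage_ub)) {
    ui <- match(names(usage_ub), enz)
    if (anyNA(ui)) stop("usage bounds for unknown enzymes: ",
                        paste(names(usage_ub)[is.na(ui)], collapse = ", "))
    ub[nv + ui] <- pmin(ub[nv + ui], usage_ub)
  }

  n <- nv + ne
  A <- matrix(0, nrow(model$stoich) + ne + (is.finite(pool_cap)), n)
  A[seq_len(nrow(model$stoich)), seq_len(nv)] <- model$stoich
  dir <- rep("==", nrow(model$stoich))
  rhs <- rep(0, nrow(model$stoich))
  # enzyme usage coupling (h^-1 internally: 3600 * kcat[s^-1])
  for (i in seq_len(ne)) {
    ki <- model$kcats[model$kcats$enzyme == enz[i], ]
    row <- nrow(model$stoich) + i
    A[row, match(ki$rxn, model$rxns$id)] <- ki$coef / (3600 * ki$kcat)
    A[row, nv + i] <- -1
  }
  dir <- c(dir, rep("==", ne))
  rhs <- c(rhs, rep(0, ne))
  if (is.finite(pool_cap)) {
    A[nrow(A), nv + seq_len(ne)] <- model$enzymes$mw
    dir <- c(dir, "<=")
    rhs <- c(rhs, pool_cap)
  }
  list(mat = A, dir = dir, rhs = rhs, lb = lb, ub = ub, vars = vars,
       n_flux = nv, enzymes = enz)
}
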