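# The multi-condition turnover-number correction program (PRESTO).
#
# One linear program couples all training conditions: each condition j
# contributes a steady-state flux block v^j (over the split reactions,
# with that condition's nutrient uptake bounds) and a relative-error
# variable omega_j; the conditions share one correction variable delta_i
# (s^-1) per enzyme i in the measured-in-all set M. For every i in M and
# condition j the enzyme's total catalysed flux is capped by its abundance:
#
#   sum_{r: i in GPR(r)} coef_ir * v_r^j <= 3600 (kcat_i^min + delta_i) E_i^j
#
# and the objective trades the mean relative growth error against the mean
# correction:  min (1/|C|) sum_j omega_j + (lambda/|M|) sum_i delta_i.
#
# The printed error-coupling constraints (v_bio * omega >= +/-(mu - v_bio))
# are bilinear in two decision variables; the program instead uses the
# linear surrogate  mu_exp * omega_j >= |mu_exp - v_bio^j|  (constant
# denominator), which coincides with the printed definition to first order
# at the relevant optimum v_bio ~ mu_exp. Both error conventions are
# reported post hoc.

#' Assemble the multi-condition correction program
#'
#' @param model a `pc_model`.
#' @param conditions a validated condition tibble; the correctable set M is
#'   the intersection of [measured_in_all()] with the model's enzymes.
#' @param lambda non-negative weight on the total correction.
#' @param theta upper bound on each relative error variable (default 0.6).
#' @param epsilon maximum allowed fold change of `kcat_min`
#'   (`delta_i <= (epsilon - 1) kcat_i^min`); default 1e5.
#' @param kmax absolute cap on corrected kcats (s^-1); default 5.75e7.
#' @param default_uptake default bound for unmeasured medium nutrients
#'   (mmol/gDW/h); default 1000.
#' @param scale_rows row-normalise the abundance-scaled capacity rows by
#'   their largest coefficient before solving (default `TRUE`).
#' @return a `presto_problem` with the LP blocks and index maps.
#' @export
build_presto_lp <- function(model, conditions, lambda, theta = 0.6,
                            epsilon = 1e5, kmax = 5.75e7,
                            default_uptake = 1000, scale_rows = TRUE) {
  stopifnot(inherits(model, "pc_model"))
  conditions <- validate_conditions(conditions)
  if (lambda < 0) stop("lambda must be non-negative")
  M <- intersect(measured_in_all(conditions), model$enzymes$enzyme)
  if (length(M) == 0)
    stop("no enzyme is measured in every condition (set M is empty)")

  nv <- nrow(model$rxns)
  nC <- nrow(conditions)
  nM <- length(M)
  idx_v <- function(j) (j - 1L) * nv + seq_len(nv)
  idx_d <- nC * nv + seq_len(nM)
  idx_w <- nC * nv + nM + seq_len(nC)
  ntot <- nC * nv + nM + nC

  kmin <- stats::setNames(model$enzymes$kcat_min, model$enzymes$enzyme)[M]
  emap <- enzyme_reaction_map(model)[M]
  bio <- match(model$biomass, model$rxns$id)
  scen <- scenario_spec("pool_plus_uptake", default_uptake = default_uptake)

  E <- matrix(NA_real_, nM, nC, dimnames = list(M, conditions$id))
  lb <- numeric(ntot); ub <- numeric(ntot)
  rows <- vector("list", nC)
  mu <- conditions$growth
  cap_rows <- integer(0)

  for (j in seq_len(nC)) {
    cm <- make_condition_model(model, conditions[j, ], scen)
    l <- model$rxns$lb; u <- model$rxns$ub
    if (!is.null(cm$bounds)) {
      bi <- match(cm$bounds$id, model$rxns$id)
      l[bi] <- cm$bounds$lb; u[bi] <- cm$bounds$ub
    }
    lb[idx_v(j)] <- l; ub[idx_v(j)] <- u
    E[, j] <- conditions$abundance[[j]][M]

    blk <- matrix(0, nrow(model$stoich) + nM + 2L, ntot)
    blk[seq_len(nrow(model$stoich)), idx_v(j)] <- model$stoich
    dirj <- rep("==", nrow(model$stoich))
    rhsj <- rep(0, nrow(model$stoich))
    for (i in seq_len(nM)) {
      er <- emap[[M[i]]]
      row <- nrow(model$stoich) + i
      blk[row, idx_v(j)[match(er$rxn, model$rxns$id)]] <- er$coef
      blk[row, idx_d[i]] <- -3600 * E[i, j]
      rhsij <- 3600 * kmin[i] * E[i, j]
      if (scale_rows) {
        sc <- max(abs(blk[row, ]), 1e-300)
        blk[row, ] <- blk[row, ] / sc
        rhsij <- rhsij / sc
      }
      dirj <- c(dirj, "<=")
      rhsj <- c(rhsj, rhsij)
    }
    # mu * omega_j >= +/- (mu - v_bio)
    r1 <- nrow(model$stoich) + nM + 1L
    blk[r1, idx_w[j]] <- -mu[j]; blk[r1, idx_v(j)[bio]] <- -1
    blk[r1 + 1L, idx_w[j]] <- -mu[j]; blk[r1 + 1L, idx_v(j)[bio]] <- 1
    dirj <- c(dirj, "<=", "<=")
    rhsj <- c(rhsj, -mu[j], mu[j])
    rows[[j]] <- list(mat = blk, dir = dirj, rhs = rhsj)
    cap_rows <- c(cap_rows, (j - 1L) * (nrow(model$stoich) + nM + 2L) +
                    nrow(model$stoich) + seq_len(nM))
  }

  lb[idx_d] <- 0
  ub[idx_d] <- pmin((epsilon - 1) * kmin, kmax - kmin)
  lb[idx_w] <- 0
  ub[idx_w] <- theta

  obj <- numeric(ntot)
  obj[idx_w] <- 1 / nC
  obj[idx_d] <- lambda / nM

  structure(list(
    mat = do.call(rbind, lapply(rows, `[[`, "mat")),
    dir = unlist(lapply(rows, `[[`, "dir")),
    rhs = unlist(lapply(rows, `[[`, "rhs")),
    lb = lb, ub = ub, obj = obj,
    idx_v = lapply(seq_len(nC), idx_v), idx_d = idx_d, idx_w = idx_w,
    bio = bio, M = M, kmin = kmin, E = E, mu = mu,
    cap_rows = cap_rows,
    lambda = lambda, theta = theta, epsilon = epsilon, kmax = kmax,
    model = model, conditions = conditions,
    condition_ids = conditions$id
  ), class = "presto_problem")
}

#' @export
print.presto_problem <- function(x, ...) {
  cat("<presto_problem> ", length(x$condition_ids), " conditions, |M| = ",
      length(x$M), ", lambda = ", format(x$lambda), "; LP: ",
      nrow(x$mat), " rows x ", ncol(x$mat), " columns\n", sep = "")
  invisible(x)
}

#' Solve the correction program
#'
#' Solves the LP, then (by default) re-optimises the total correction at
#' the fixed optimal objective value: among alternative optima the
#' solution with minimal `sum(delta)` is returned, a deterministic
#' tie-break that keeps the regularisation path monotone even when
#' `lambda / |M|` falls below the pricing tolerance. Every returned
#' solution is re-verified against all constraints by an independent
#' checker; on infeasibility each condition is probed separately to name
#' the offending block.
#'
#' @param problem a `presto_problem`.
#' @param tol solver feasibility tolerance (default 1e-9).
#' @param refine run the minimal-total-correction tie-break (default
#'   `TRUE`).
#' @return a `correction_result`: tibble-based summaries `delta` (per
#'   enzyme: `kcat_min`, `delta`, `kcat_new`), `errors` (per condition:
#'   `v_bio`, `omega` = |mu - v|/mu, `omega_pred_denom` = |mu - v|/v),
#'   scalars `Delta`, `lambda`, `objective`, `status`, plus the raw
#'   solution vector.
#' @export
solve_presto <- function(problem, tol = 1e-9, refine = TRUE) {
  stopifnot(inherits(problem, "presto_problem"))
  p <- problem
  sol <- solve_lp(p$obj, p$mat, p$dir, p$rhs, p$lb, p$ub, tol = tol)
  if (sol$status != "optimal") {
    offending <- presto_probe_conditions(p, tol)
    return(structure(list(status = sol$status, offending = offending,
                          lambda = p$lambda),
                     class = "correction_result"))
  }
  if (refine) {
    # fix the attained objective, minimise the total correction
    margin <- 1e-9 * (1 + abs(sol$objval))
    mat2 <- rbind(p$mat, p$obj)
    obj2 <- numeric(length(p$obj)); obj2[p$idx_d] <- 1
    sol2 <- solve_lp(obj2, mat2, c(p$dir, "<="), c(p$rhs, sol$objval + margin),
                     p$lb, p$ub, tol = tol)
    if (sol2$status == "optimal") sol <- list(status = "optimal", x = sol2$x,
                                              objval = sum(p$obj * sol2$x),
                                              dual = NULL)
  }
  chk <- check_lp_solution(sol$x, p$mat, p$dir, p$rhs, p$lb, p$ub, tol = 1e-6)
  if (!chk$ok)
    warning("solution failed independent constraint verification ",
            "(max violation ", format(chk$max_violation), ")")
  delta <- stats::setNames(pmax(sol$x[p$idx_d], 0), p$M)  # clip solver noise
  v_bio <- vapply(seq_along(p$condition_ids),
                  function(j) sol$x[p$idx_v[[j]][p$bio]], 0)
  structure(list(
    status = "optimal",
    delta = tibble::tibble(enzyme = p$M, kcat_min = unname(p$kmin),
                           delta = unname(delta),
                           kcat_new = unname(p$kmin + delta)),
    errors = tibble::tibble(
      condition = p$condition_ids, mu = p$mu, v_bio = v_bio,
      omega = relative_error(p$mu, v_bio),
      omega_pred_denom = relative_error(p$mu, v_bio,
                                        denominator = "predicted"),
      omega_lp = sol$x[p$idx_w]),
    Delta = sum(delta), lambda = p$lambda, objective = sol$objval,
    verified = chk$ok, x = sol$x
  ), class = "correction_result")
}

presto_probe_conditions <- function(p, tol) {
  bad <- character(0)
  for (j in seq_along(p$condition_ids)) {
    sub <- build_presto_lp(p$model, p$conditions[j, , drop = FALSE],
                           lambda = p$lambda, theta = p$theta,
                           epsilon = p$epsilon, kmax = p$kmax)
    s <- solve_lp(sub$obj, sub$mat, sub$dir, sub$rhs, sub$lb, sub$ub,
                  tol = tol)
    if (s$status != "optimal") bad <- c(bad, p$condition_ids[j])
  }
  bad
}

#' @export
print.correction_result <- function(x, ...) {
  if (x$status != "optimal") {
    cat("<correction_result> solver status: ", x$status, "\n", sep = "")
    if (length(x$offending))
      cat("  offending condition blocks: ",
          paste(x$offending, collapse = ", "), "\n", sep = "")
    return(invisible(x))
  }
  cat("<correction_result> lambda = ", format(x$lambda),
      ", corrected enzymes: ", sum(x$delta$delta > 1e-6), "/",
      nrow(x$delta), ", total correction = ", signif(x$Delta, 6),
      " s^-1, mean relative error = ", signif(mean(x$errors$omega), 4),
      "\n", sep = "")
  invisible(x)
}

#' One-shot correction on a model + condition set
#'
#' Convenience wrapper: [build_presto_lp()] then [solve_presto()].
#'
#' @inheritParams build_presto_lp
#' @inheritParams solve_presto
#' @param ... passed to [build_presto_lp()].
#' @return a `correction_result`.
#' @export
presto_correct <- function(model, conditions, lambda, ..., tol = 1e-9) {
  solve_presto(build_presto_lp(model, conditions, lambda, ...), tol = tol)
}

#' Relative growth-rate error
#'
#' Reporting definition: `|mu - v_bio| / mu` (measured denominator). The
#' predicted-growth denominator `|mu - v_bio| / v_bio` is available for
#' diagnostics; it is undefined for `v_bio <= 0`.
#'
#' @param mu measured specific growth rate(s), > 0 (h^-1).
#' @param v_bio predicted specific growth rate(s) (h^-1).
#' @param denominator `"measured"` (default) or `"predicted"`.
#' @return numeric vector of relative errors.
#' @export
relative_error <- function(mu, v_bio,
                           denominator = c("measured", "predicted")) {
  denominator <- match.arg(denominator)
  if (any(mu <= 0)) stop("measured growth rates must be > 0")
  if (denominator == "measured") return(abs(mu - v_bio) / mu)
  if (any(v_bio <= 0, na.rm = TRUE))
    stop("predicted-growth denominator undefined for v_bio <= 0")
  abs(mu - v_bio) / v_bio
}
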