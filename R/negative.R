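# Optional second stage: negative corrections (apparent catalytic rates).
#
# Positive corrections cannot reduce growth that the pool-only scenario
# already *over*-predicts. This stage searches for non-positive per-enzyme
# corrections delta_neg <= 0 on the measured set M that minimise the mean
# pool-only relative growth error while leaving the abundance-constrained
# errors of the first stage unchanged. Because the pool-only optimum is
# itself the value of an LP, its dependence on the kcats is only piecewise
# linear; the search therefore solves a short sequence of linearised
# programs (growth responses estimated by downward secants, an exact
# linear achievability block preserving the first-stage optima, and a
# line search on the true FBA error), and the preservation requirement is
# re-verified by FBA afterwards. Reduced kcats are apparent catalytic
# rates for the considered conditions, not condition-independent turnover
# numbers.

#' Negative-correction second stage
#'
#' @param problem the `presto_problem` of the first stage.
#' @param result the optimal first-stage `correction_result`.
#' @param default_uptake uptake bound for the pool-only scenario
#'   (mmol/gDW/h).
#' @param max_iter linearisation iterations (default 6).
#' @param preserve_tol maximum allowed change of an abundance-constrained
#'   relative error (default 1e-6).
#' @param tol solver tolerance.
#' @return a `correction_result` whose `delta` table gains `delta_neg`
#'   and whose `kcat_new` includes both stages; `apparent_rates = TRUE`
#'   flags reduced values. Extra fields: `errors_pool` (per condition:
#'   pool-only error before/after), `diagnostic`. If the pool-only
#'   scenario never over-predicts, or no preserving improvement exists,
#'   the corrections are returned unchanged with a diagnostic.
#' @export
negative_correction_step <- function(problem, result, default_uptake = 1000,
                                     max_iter = 6, preserve_tol = 1e-6,
                                     tol = 1e-9) {
  stopifnot(inherits(problem, "presto_problem"),
            inherits(result, "correction_result"),
            result$status == "optimal")
  p <- problem
  conditions <- p$conditions
  nC <- nrow(conditions); M <- p$M; nM <- length(M)
  dpos <- stats::setNames(result$delta$delta, M)
  model_pos <- apply_kcat_corrections(p$model, dpos, epsilon = p$epsilon,
                                      kmax = p$kmax)
  kappa <- stats::setNames(model_pos$enzymes$kcat_min,
                           model_pos$enzymes$enzyme)[M]
  scen_i <- scenario_spec("pool_only", default_uptake = default_uptake)

  pool_growth <- function(mod) vapply(seq_len(nC), function(j) {
    g <- predict_growth(make_condition_model(mod, conditions[j, ], scen_i),
                        tol = tol)
    if (g$status == "optimal") g$objective else NA_real_
  }, 0)
  mean_err <- function(g) mean(abs(g - p$mu) / p$mu)

  unchanged <- function(msg) {
    out <- result
    out$delta$delta_neg <- rep(0, nM)
    out$apparent_rates <- FALSE
    out$diagnostic <- msg
    out
  }

  g0 <- pool_growth(model_pos)
  if (anyNA(g0)) return(unchanged("pool-only FBA infeasible"))
  if (all(g0 <= p$mu * (1 + 1e-9)))
    return(unchanged("no pool-only overprediction; delta_neg = 0"))

  # iii-scenario reference errors (preservation target)
  ref_iii <- evaluate_conditions(list(m = model_pos), conditions,
                                 scenarios = "pool_uptake_abundance",
                                 default_uptake = default_uptake, tol = tol)

  dneg <- stats::setNames(rep(0, nM), M)
  err_cur <- mean_err(g0); g_cur <- g0
  for (it in seq_len(max_iter)) {
    mod_cur <- apply_kcat_corrections(model_pos, dneg, allow_negative = TRUE,
                                      epsilon = p$epsilon, kmax = p$kmax)
    kap_cur <- kappa + dneg
    # downward secant slopes of pool-only growth wrt each kcat
    slopes <- matrix(0, nM, nC, dimnames = list(M, NULL))
    for (i in seq_len(nM)) {
      step <- kap_cur[i] / 2
      trial <- dneg; trial[i] <- trial[i] - step
      mod_t <- apply_kcat_corrections(model_pos, trial,
                                      allow_negative = TRUE,
                                      epsilon = p$epsilon, kmax = p$kmax)
      gt <- pool_growth(mod_t)
      slopes[i, ] <- (g_cur - gt) / step
    }
    cand <- negative_step_lp(p, dneg, g_cur, slopes, kappa,
                             result$errors$v_bio, tol = tol)
    if (is.null(cand)) break
    # line search on the true pool-only error
    improved <- FALSE
    for (ls in 0:3) {
      trial <- dneg + (cand - dneg) / 2^ls
      mod_t <- apply_kcat_corrections(model_pos, trial,
                                      allow_negative = TRUE,
                                      epsilon = p$epsilon, kmax = p$kmax)
      gt <- pool_growth(mod_t)
      if (!anyNA(gt) && mean_err(gt) < err_cur - 1e-12) {
        dneg <- trial; g_cur <- gt; err_cur <- mean_err(gt)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }

  dneg[dneg > -1e-9] <- 0              # drop negligible corrections
  if (max(abs(dneg)) < 1e-12 || err_cur > mean_err(g0) - 1e-9)
    return(unchanged("no preserving improvement found; delta_neg = 0"))

  # post-hoc preservation: scale back until iii-errors are unchanged
  for (half in 0:30) {
    mod_f <- apply_kcat_corrections(model_pos, dneg, allow_negative = TRUE,
                                    epsilon = p$epsilon, kmax = p$kmax)
    new_iii <- evaluate_conditions(list(m = mod_f), conditions,
                                   scenarios = "pool_uptake_abundance",
                                   default_uptake = default_uptake,
                                   tol = tol)
    dev <- max(abs(new_iii$omega - ref_iii$omega), na.rm = TRUE)
    if (all(new_iii$feasible == ref_iii$feasible) && dev <= preserve_tol)
      break
    dneg <- dneg / 2
    if (max(abs(dneg)) < 1e-12)
      return(unchanged("preservation constraint infeasible; delta_neg = 0"))
  }
  gf <- pool_growth(mod_f)
  if (mean_err(gf) > mean_err(g0) - 1e-9)
    return(unchanged("no preserving improvement found; delta_neg = 0"))

  out <- result
  out$delta$delta_neg <- unname(dneg)
  out$delta$kcat_new <- unname(kappa + dneg)
  out$apparent_rates <- TRUE
  out$errors_pool <- tibble::tibble(
    condition = p$condition_ids, mu = p$mu,
    v_bio_before = g0, omega_before = abs(g0 - p$mu) / p$mu,
    v_bio_after = gf, omega_after = abs(gf - p$mu) / p$mu)
  out$diagnostic <- sprintf(
    "%d negative corrections; mean pool-only error %.4g -> %.4g",
    sum(dneg < -1e-9), mean_err(g0), mean_err(gf))
  out
}

# Linearised subproblem: choose delta_neg (within a trust region) to
# minimise the predicted mean pool-only error, subject to exact
# achievability of the first-stage growth under the abundance-capacity
# constraints (which are linear in delta_neg).
negative_step_lp <- function(p, dneg, g_cur, slopes, kappa, vbio_target,
                             tol = 1e-9) {
  nC <- length(p$mu); nM <- length(p$M)
  nv <- nrow(p$model$rxns)
  # variables: d (nM, total negative correction), w (nC), v3 blocks (nC*nv)
  nd <- nM; nw <- nC
  ntot <- nd + nw + nC * nv
  idx_d <- seq_len(nd); idx_w <- nd + seq_len(nw)
  idx_v <- function(j) nd + nw + (j - 1L) * nv + seq_len(nv)
  kap_cur <- kappa + dneg

  lb <- numeric(ntot); ub <- numeric(ntot)
  lb[idx_d] <- pmax(-(kappa) * (1 - 1e-6), dneg - 0.45 * kap_cur)
  ub[idx_d] <- 0
  lb[idx_w] <- 0; ub[idx_w] <- Inf
  rows <- list(); dirs <- character(0); rhs <- numeric(0)
  add <- function(r, d, b) {
    rows[[length(rows) + 1L]] <<- r; dirs <<- c(dirs, d); rhs <<- c(rhs, b)
  }
  # error linearisation: mu*w >= +/-(g_cur + s'(d - dneg) - mu)
  for (j in seq_len(nC)) {
    base <- g_cur[j] - sum(slopes[, j] * dneg)
    r1 <- numeric(ntot); r1[idx_w[j]] <- -p$mu[j]
    r1[idx_d] <- -slopes[, j]
    add(r1, "<=", -(p$mu[j] - base))
    r2 <- numeric(ntot); r2[idx_w[j]] <- -p$mu[j]
    r2[idx_d] <- slopes[, j]
    add(r2, "<=", p$mu[j] - base)
  }
  # achievability blocks: steady state + capacity with kappa + d
  emap <- enzyme_reaction_map(p$model)[p$M]
  bio <- p$bio
  for (j in seq_len(nC)) {
    iv <- idx_v(j)
    lb[iv] <- p$lb[p$idx_v[[j]]]
    ub[iv] <- p$ub[p$idx_v[[j]]]
    Sblk <- matrix(0, nrow(p$model$stoich), ntot)
    Sblk[, iv] <- p$model$stoich
    for (r in seq_len(nrow(Sblk))) add(Sblk[r, ], "==", 0)
    for (i in seq_len(nM)) {
      er <- emap[[p$M[i]]]
      row <- numeric(ntot)
      row[iv[match(er$rxn, p$model$rxns$id)]] <- er$coef
      row[idx_d[i]] <- -3600 * p$E[i, j]
      add(row, "<=", 3600 * kappa[i] * p$E[i, j])
    }
    vb <- numeric(ntot); vb[iv[bio]] <- 1
    add(vb, ">=", vbio_target[j] * (1 - 1e-9) - 1e-12)
  }
  mat <- do.call(rbind, rows)
  obj <- numeric(ntot)
  obj[idx_w] <- 1 / nC
  obj[idx_d] <- -1e-8     # prefer the least negative correction among ties
  sol <- solve_lp(obj, mat, dirs, rhs, lb, ub, tol = tol)
  if (sol$status != "optimal") return(NULL)
  stats::setNames(sol$x[idx_d], p$M)
}
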