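# Post-optimal variability of the corrections and sampling of alternative
# optima.
#
# With the per-condition relative errors fixed within +/-1% of their
# optimal values and the total correction fixed within +/-1e-3 (internal
# kcat units, s^-1), each correction delta_i is minimised and maximised
# over the remaining solution space. Alternative optimal corrections are
# then sampled by drawing uniform points inside the per-enzyme intervals
# and projecting them onto the fixed-optimum polytope by minimising the L1
# distance.

#' Variability intervals for the corrections
#'
#' @param problem the `presto_problem` that produced `result`.
#' @param result an optimal `correction_result`.
#' @param omega_tol relative tolerance for fixing each condition's error
#'   variable (default 0.01, i.e. `0.99 w_opt <= w <= 1.01 w_opt`).
#' @param delta_tol absolute tolerance for fixing the total correction
#'   (default 1e-3, internal kcat units).
#' @param tol solver feasibility tolerance.
#' @return a `variability_result`: tibble `intervals` (enzyme, delta_opt,
#'   delta_min, delta_max), the tolerances used, and the augmented
#'   constraint blocks reused by [sample_corrections()].
#' @export
delta_variability <- function(problem, result, omega_tol = 0.01,
                              delta_tol = 1e-3, tol = 1e-9) {
  stopifnot(inherits(problem, "presto_problem"),
            inherits(result, "correction_result"),
            result$status == "optimal")
  fixed <- variability_constraints(problem, result, omega_tol, delta_tol)
  nM <- length(problem$M)
  run <- function(fx) {
    dmin <- numeric(nM); dmax <- numeric(nM)
    for (i in seq_len(nM)) {
      obj <- numeric(ncol(fx$mat)); obj[problem$idx_d[i]] <- 1
      lo <- solve_lp(obj, fx$mat, fx$dir, fx$rhs, fx$lb, fx$ub, tol = tol)
      hi <- solve_lp(obj, fx$mat, fx$dir, fx$rhs, fx$lb, fx$ub,
                     maximize = TRUE, tol = tol)
      if (lo$status != "optimal" || hi$status != "optimal")
        return(NULL)
      dmin[i] <- lo$objval; dmax[i] <- hi$objval
    }
    list(dmin = dmin, dmax = dmax)
  }
  iv <- run(fixed)
  if (is.null(iv)) {
    warning("fixed-optimum polytope numerically empty; widening the ",
            "tolerances once (omega x2, Delta x10)")
    omega_tol <- omega_tol * 2; delta_tol <- delta_tol * 10
    fixed <- variability_constraints(problem, result, omega_tol, delta_tol)
    iv <- run(fixed)
    if (is.null(iv))
      stop("variability analysis infeasible even after widening")
  }
  structure(list(
    intervals = tibble::tibble(
      enzyme = problem$M,
      delta_opt = result$delta$delta,
      delta_min = pmax(iv$dmin, 0),
      delta_max = iv$dmax),
    omega_opt = result$errors$omega_lp,
    Delta_opt = result$Delta,
    omega_tol = omega_tol, delta_tol = delta_tol,
    fixed = fixed
  ), class = "variability_result")
}

# Constraint system of the fixed-optimum polytope: all PRESTO constraints
# plus the error band (as bounds on the omega variables) and the total-
# correction band (two extra rows).
variability_constraints <- function(problem, result, omega_tol, delta_tol) {
  p <- problem
  lb <- p$lb; ub <- p$ub
  w_opt <- result$errors$omega_lp
  lb[p$idx_w] <- pmax(0, (1 - omega_tol) * w_opt)
  ub[p$idx_w] <- pmin(p$theta, (1 + omega_tol) * w_opt)
  drow <- numeric(ncol(p$mat)); drow[p$idx_d] <- 1
  mat <- rbind(p$mat, drow, drow)
  dir <- c(p$dir, "<=", ">=")
  rhs <- c(p$rhs, result$Delta + delta_tol,
           max(0, result$Delta - delta_tol))
  list(mat = mat, dir = dir, rhs = rhs, lb = lb, ub = ub)
}

#' @export
print.variability_result <- function(x, ...) {
  wid <- x$intervals$delta_max - x$intervals$delta_min
  cat("<variability_result> ", nrow(x$intervals), " enzymes; median ",
      "interval width ", signif(stats::median(wid), 4), " s^-1 (omega ",
      "tolerance +/-", 100 * x$omega_tol, "%, Delta tolerance +/-",
      format(x$delta_tol), ")\n", sep = "")
  invisible(x)
}

#' Sample alternative optimal corrections
#'
#' Draws `n` candidate correction vectors uniformly within the per-enzyme
#' variability intervals and projects each onto the fixed-optimum polytope
#' by minimising the L1 distance `sum_i |delta_i - candidate_i|` (split
#' into auxiliary positive/negative parts). A candidate already inside the
#' polytope projects to itself. With `tie_break = "lex"` the projection is
#' refined to the lexicographically smallest optimal vertex (the L1
#' distance is fixed, then delta_1, delta_2, ... are minimised in turn).
#'
#' @param problem the `presto_problem`.
#' @param variability a `variability_result`.
#' @param n number of samples (the reference analysis uses 10,000).
#' @param seed RNG seed (local).
#' @param tie_break `"none"` (deterministic simplex vertex) or `"lex"`.
#' @param tol solver feasibility tolerance.
#' @return a `sample_set`: `samples` matrix (n x enzymes, s^-1),
#'   `distance` (attained L1 distance per draw), `n_failed`, `seed`, and
#'   `all_verified` (every accepted row re-checked against the polytope at
#'   tolerance 1e-6).
#' @export
sample_corrections <- function(problem, variability, n = 10000, seed = 1,
                               tie_break = c("none", "lex"), tol = 1e-9) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(variability, "variability_result"))
  p <- problem
  fx <- variability$fixed
  nM <- length(p$M)
  ntot <- ncol(fx$mat)
  # augmented system: x, then split distances pl (+) and mi (-)
  aug <- cbind(fx$mat, matrix(0, nrow(fx$mat), 2 * nM))
  link <- matrix(0, nM, ntot + 2 * nM)
  link[cbind(seq_len(nM), p$idx_d)] <- 1
  link[cbind(seq_len(nM), ntot + seq_len(nM))] <- -1
  link[cbind(seq_len(nM), ntot + nM + seq_len(nM))] <- 1
  mat <- rbind(aug, link)
  dir <- c(fx$dir, rep("==", nM))
  lb <- c(fx$lb, rep(0, 2 * nM))
  ub <- c(fx$ub, rep(Inf, 2 * nM))
  obj <- c(numeric(ntot), rep(1, 2 * nM))

  dmin <- variability$intervals$delta_min
  dmax <- variability$intervals$delta_max
  targets <- matrix(NA_real_, n, nM, dimnames = list(NULL, p$M))
  samples <- matrix(NA_real_, n, nM, dimnames = list(NULL, p$M))
  distance <- rep(NA_real_, n)
  failed <- 0L
  ok_all <- TRUE
  with_local_seed(seed, {
    for (s in seq_len(n)) {
      target <- dmin + stats::runif(nM) * (dmax - dmin)
      targets[s, ] <- target
      rhs <- c(fx$rhs, target)
      sol <- solve_lp(obj, mat, dir, rhs, lb, ub, tol = tol)
      if (sol$status != "optimal") { failed <- failed + 1L; next }
      if (tie_break == "lex") {
        margin <- 1e-9 * (1 + abs(sol$objval))
        mat_l <- rbind(mat, obj); dir_l <- c(dir, "<=")
        rhs_l <- c(rhs, sol$objval + margin)
        lb_l <- lb; ub_l <- ub
        for (i in seq_len(nM)) {
          o <- numeric(ncol(mat_l)); o[p$idx_d[i]] <- 1
          si <- solve_lp(o, mat_l, dir_l, rhs_l, lb_l, ub_l, tol = tol)
          if (si$status != "optimal") break
          sol <- si
          lb_l[p$idx_d[i]] <- si$objval - 1e-10
          ub_l[p$idx_d[i]] <- si$objval + 1e-10
        }
      }
      dvec <- sol$x[p$idx_d]
      chk <- check_lp_solution(sol$x[seq_len(ntot)], fx$mat, fx$dir, fx$rhs,
                               fx$lb, fx$ub, tol = 1e-6)
      if (!chk$ok) ok_all <- FALSE
      samples[s, ] <- dvec
      distance[s] <- sum(abs(dvec - target))
    }
  })
  structure(list(samples = samples, targets = targets, distance = distance,
                 n_failed = failed, seed = seed, all_verified = ok_all),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", nrow(x$samples), " draws x ", ncol(x$samples),
      " enzymes; ", x$n_failed, " failed projections; verified: ",
      x$all_verified, "\n", sep = "")
  invisible(x)
}

#' Per-enzyme spread of sampled corrections
#'
#' Summarises the sampled corrected kcats per enzyme: mean, 25th/75th
#' percentiles, and the mean Euclidean distance of the samples to their
#' mean (the precision measure used to compare against per-EC-class kcat
#' spread).
#'
#' @param samples a `sample_set` (or a numeric matrix of sampled deltas,
#'   columns = enzymes).
#' @param kcat_min optional named baseline kcats (s^-1); when given the
#'   summary is on `kcat_min + delta` instead of delta.
#' @return tibble (enzyme, mean, p25, p75, spread) plus attribute
#'   `mean_spread` (average spread over enzymes).
#' @export
precision_summary <- function(samples, kcat_min = NULL) {
  m <- if (inherits(samples, "sample_set")) samples$samples else
    as.matrix(samples)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) stop("need at least two samples")
  if (!is.null(kcat_min))
    m <- sweep(m, 2, kcat_min[colnames(m)], "+")
  out <- tibble::tibble(
    enzyme = colnames(m),
    mean = unname(colMeans(m)),
    p25 = unname(apply(m, 2, stats::quantile, 0.25, names = FALSE)),
    p75 = unname(apply(m, 2, stats::quantile, 0.75, names = FALSE)),
    spread = unname(apply(m, 2, function(v) mean(abs(v - mean(v))))))
  attr(out, "mean_spread") <- mean(out$spread)
  out
}
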