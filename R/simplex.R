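# Dense bounded-variable primal simplex.
#
# All constrained optimisation in this package (flux balance analysis, the
# turnover-number correction program, variability analysis, sample
# projection) reduces to linear programs of moderate size (tens to a few
# hundred variables). The solver below implements the textbook two-phase
# primal simplex with variable bounds handled implicitly (nonbasic variables
# rest at a finite bound; bound flips do not change the basis), Dantzig
# pricing with a Bland fallback on stalls, and periodic refactorisation of
# the basis inverse to bound numerical drift.

#' Solve a linear program
#'
#' Minimises (or maximises) \code{obj \%*\% x} subject to
#' \code{mat \%*\% x (dir) rhs} and \code{lb <= x <= ub}. Every variable must
#' have a finite lower bound; upper bounds may be infinite. Rows are
#' equilibrated (scaled by their largest absolute coefficient) before
#' solving, which leaves the solution unchanged.
#'
#' @param obj numeric objective coefficients.
#' @param mat constraint matrix (dense or sparse; coerced to dense).
#' @param dir character vector of \code{"<="}, \code{">="}, \code{"=="},
#'   one per row.
#' @param rhs right-hand sides.
#' @param lb,ub variable bounds; \code{lb} must be finite.
#' @param maximize if \code{TRUE}, maximise the objective.
#' @param tol feasibility/optimality tolerance on the scaled problem
#'   (default \code{1e-9}).
#' @param max_iter iteration cap (default scales with problem size).
#'
#' @return A list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"maxiter"}), \code{x}
#'   (primal solution), \code{objval}, and \code{dual} (row duals of the
#'   scaled-back problem, sign convention: Lagrangian
#'   \code{obj - t(mat) \%*\% dual}).
#' @export
solve_lp <- function(obj, mat, dir, rhs, lb, ub,
                     maximize = FALSE, tol = 1e-9, max_iter = NULL) {
  mat <- as.matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)))
    stop("solve_lp() requires finite lower bounds on all variables")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_, dual = rep(NA_real_, m)))
  if (!all(dir %in% c("<=", ">=", "==")))
    stop("dir entries must be one of '<=', '>=', '=='")

  c0 <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # row equilibration
  rsc <- apply(abs(mat), 1, max)
  rsc[rsc < .Machine$double.eps] <- 1
  A <- mat / rsc
  b <- as.numeric(rhs) / rsc

  # slacks: "<=" row i gains +s_i, ">=" gains -s_i, s_i >= 0
  ineq <- which(dir != "==")
  ns <- length(ineq)
  if (ns > 0) {
    S <- matrix(0, m, ns)
    S[cbind(ineq, seq_len(ns))] <- ifelse(dir[ineq] == "<=", 1, -1)
    A <- cbind(A, S)
    c0 <- c(c0, rep(0, ns))
    lb <- c(lb, rep(0, ns))
    ub <- c(ub, rep(Inf, ns))
  }
  nt <- n + ns

  # artificial start: nonbasics at lower bound, one artificial per row
  xN <- lb[seq_len(nt)]
  r <- b - drop(A %*% xN)
  sg <- ifelse(r >= 0, 1, -1)
  A <- cbind(A, diag(sg, m))
  lb <- c(lb, rep(0, m))
  ub <- c(ub, rep(Inf, m))
  art <- nt + seq_len(m)

  if (is.null(max_iter)) max_iter <- max(2000L, 60L * (m + nt))

  st <- new.env(parent = emptyenv())
  st$basis <- art
  st$stat <- rep(1L, nt + m)        # 1 = at lb, 2 = at ub, 0 = basic
  st$stat[art] <- 0L
  st$x <- c(xN, abs(r))
  st$Binv <- diag(1, m)

  phase_cost <- rep(0, nt + m); phase_cost[art] <- 1
  res1 <- simplex_phase(A, b, phase_cost, lb, ub, st, tol, max_iter,
                        phase1 = TRUE)
  if (res1 == "maxiter")
    return(list(status = "maxiter", x = rep(NA_real_, n),
                objval = NA_real_, dual = rep(NA_real_, m)))
  if (sum(st$x[art]) > 1e-7 * (1 + max(abs(b))))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_, dual = rep(NA_real_, m)))

  # freeze artificials at zero for phase 2
  lb[art] <- 0; ub[art] <- 0
  st$x[art] <- 0
  cost2 <- c(c0, rep(0, m))
  res2 <- simplex_phase(A, b, cost2, lb, ub, st, tol, max_iter,
                        phase1 = FALSE)
  if (res2 == "maxiter")
    return(list(status = "maxiter", x = rep(NA_real_, n),
                objval = NA_real_, dual = rep(NA_real_, m)))
  if (res2 == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objval = if (maximize) Inf else -Inf, dual = rep(NA_real_, m)))

  x <- st$x[seq_len(n)]
  objval <- sum(obj * x)
  y <- drop(crossprod(st$Binv, cost2[st$basis])) / rsc
  if (maximize) y <- -y
  list(status = "optimal", x = x, objval = objval, dual = y)
}

# One simplex phase operating on the environment `st` in place.
# Returns "optimal", "unbounded", or "maxiter".
simplex_phase <- function(A, b, cost, lb, ub, st, tol, max_iter, phase1) {
  m <- nrow(A); nt <- ncol(A)
  refactor <- function() {
    B <- A[, st$basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) Binv <- MASS::ginv(B)
    st$Binv <- Binv
    nb <- setdiff(seq_len(nt), st$basis)
    st$x[st$basis] <- drop(st$Binv %*%
                             (b - A[, nb, drop = FALSE] %*% st$x[nb]))
  }
  refactor()
  stall <- 0L
  bland <- FALSE
  for (it in seq_len(max_iter)) {
    if (it %% 60L == 0L) refactor()
    y <- drop(crossprod(st$Binv, cost[st$basis]))
    d <- cost - drop(y %*% A)           # reduced costs, basics ~ 0
    d[st$basis] <- 0
    elig_lo <- which(st$stat == 1L & d < -tol & ub > lb)
    elig_hi <- which(st$stat == 2L & d > tol & ub > lb)
    cand <- c(elig_lo, elig_hi)
    if (length(cand) == 0L) return("optimal")
    if (bland || stall > 40L) {
      e <- min(cand)
    } else {
      e <- cand[which.max(abs(d[cand]))]
    }
    up <- st$stat[e] == 1L              # entering variable increases?
    w <- drop(st$Binv %*% A[, e])       # xB changes by -w*t (if up)
    dxB <- if (up) -w else w
    # ratio test
    t_own <- ub[e] - lb[e]
    t_best <- t_own; leave <- 0L; leave_to <- NA_integer_
    xB <- st$x[st$basis]
    piv_tol <- 1e-10
    for (i in seq_len(m)) {
      di <- dxB[i]
      if (di > piv_tol) {
        ti <- (ub[st$basis[i]] - xB[i]) / di
        if (ti < t_best - 1e-12 || (ti < t_best + 1e-12 && leave == 0L)) {
          if (ti < t_best) { t_best <- ti; leave <- i; leave_to <- 2L }
        }
      } else if (di < -piv_tol) {
        ti <- (lb[st$basis[i]] - xB[i]) / di
        if (ti < t_best) { t_best <- ti; leave <- i; leave_to <- 1L }
      }
    }
    if (!is.finite(t_best)) return("unbounded")
    t_best <- max(t_best, 0)
    if (t_best < 1e-11) stall <- stall + 1L else stall <- 0L
    if (stall > 80L) bland <- TRUE
    # apply step
    st$x[st$basis] <- xB + dxB * t_best
    st$x[e] <- st$x[e] + (if (up) t_best else -t_best)
    if (leave == 0L) {
      # bound flip, basis unchanged
      st$stat[e] <- if (up) 2L else 1L
      next
    }
    lv <- st$basis[leave]
    st$stat[lv] <- leave_to
    st$x[lv] <- if (leave_to == 1L) lb[lv] else ub[lv]
    st$basis[leave] <- e
    st$stat[e] <- 0L
    # product-form update of Binv
    piv <- if (up) -dxB[leave] else dxB[leave]   # = w[leave]
    if (abs(piv) < 1e-9) { refactor(); next }
    Brow <- st$Binv[leave, ] / piv
    st$Binv <- st$Binv - outer(w, Brow)
    st$Binv[leave, ] <- Brow
  }
  "maxiter"
}

#' Verify a candidate LP solution against its constraints
#'
#' Independent constraint checker: recomputes every row residual and bound
#' violation without reference to the solver path.
#'
#' @param x candidate solution.
#' @inheritParams solve_lp
#' @param tol violation tolerance (absolute, on the original row scale,
#'   relative to \code{1 + |rhs|}).
#' @return A list with \code{ok} (logical) and \code{max_violation}.
#' @export
check_lp_solution <- function(x, mat, dir, rhs, lb, ub, tol = 1e-6) {
  lhs <- drop(as.matrix(mat) %*% x)
  sc <- 1 + abs(rhs)
  viol <- numeric(length(rhs))
  le <- dir == "<="; ge <- dir == ">="; eq <- dir == "=="
  viol[le] <- (lhs[le] - rhs[le]) / sc[le]
  viol[ge] <- (rhs[ge] - lhs[ge]) / sc[ge]
  viol[eq] <- abs(lhs[eq] - rhs[eq]) / sc[eq]
  bviol <- pmax(lb - x, x - ub, 0) / (1 + abs(x))
  mv <- max(c(viol, bviol, 0))
  list(ok = mv <= tol, max_violation = mv)
}
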