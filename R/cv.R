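# Cross-validated selection of the regularisation weight lambda, plus the
# condition-subsampling robustness analysis.
#
# Repeated K-fold cross-validation over a log-spaced lambda grid: each
# iteration partitions the conditions into K folds, fits corrections on
# K - 1 folds, and validates on the held-out fold by predicting growth
# with the corrected kcats under the pool-plus-measured-uptake scenario
# (no abundance constraints), which counteracts overprediction in the
# proteomics-free scenario. The per-lambda score is the average product of
# min-max-scaled validation error and log-scaled total correction across
# iterations; the chosen lambda sits at the first sign change of the
# second numerical gradient of the score, scanning from the largest
# lambda.

#' Build a repeated K-fold cross-validation plan
#'
#' @param conditions a condition tibble (or anything with `nrow`).
#' @param K number of folds (default 3).
#' @param iterations number of repetitions (default 10).
#' @param seed RNG seed (local).
#' @return list of integer vectors (one per iteration) assigning each
#'   condition to a fold `1..K`; folds are balanced within one condition.
#' @export
make_cv_folds <- function(conditions, K = 3, iterations = 10, seed = 1) {
  n <- nrow(conditions)
  if (K > n) stop("K (", K, ") exceeds the number of conditions (", n, ")")
  with_local_seed(seed, {
    lapply(seq_len(iterations), function(i) {
      sample(rep_len(seq_len(K), n))
    })
  })
}

presto_set_lambda <- function(problem, lambda) {
  problem$obj[problem$idx_d] <- lambda / length(problem$M)
  problem$lambda <- lambda
  problem
}

#' Repeated cross-validation over a lambda grid
#'
#' @param model a `pc_model` (uncorrected kcats).
#' @param conditions a condition tibble.
#' @param lambda_grid log-spaced grid; default one point per decade from
#'   1e-14 to 1e-1 (14 values).
#' @param K,iterations,seed cross-validation plan (see [make_cv_folds()]).
#' @param corrected_tol minimum delta (s^-1) for an enzyme to count as
#'   corrected.
#' @param ... passed to [build_presto_lp()] (theta, epsilon, kmax,
#'   default_uptake).
#' @return a `cv_report`: `measures` tibble (lambda, iteration, omega =
#'   mean validation error, Delta = mean training total correction),
#'   `scores` tibble (lambda, score), `lambda_opt`, `folds`,
#'   `corrected_sets` (per lambda: list over iteration x fold of corrected
#'   enzyme sets), `fold_jaccard` (mean pairwise Jaccard distance of the
#'   corrected sets at `lambda_opt`).
#' @export
presto_crossval <- function(model, conditions, lambda_grid = 10^(-14:-1),
                            K = 3, iterations = 10, seed = 1,
                            corrected_tol = 1e-6, ...) {
  conditions <- validate_conditions(conditions)
  folds <- make_cv_folds(conditions, K, iterations, seed)
  nL <- length(lambda_grid)
  omega <- matrix(NA_real_, nL, iterations)
  Delta <- matrix(NA_real_, nL, iterations)
  sets <- lapply(seq_len(nL), function(i) list())

  for (tau in seq_len(iterations)) {
    val_err <- replicate(nL, list())      # per lambda: pooled fold errors
    fold_delta <- matrix(NA_real_, nL, K)
    for (k in seq_len(K)) {
      tr <- conditions[folds[[tau]] != k, ]
      va <- conditions[folds[[tau]] == k, ]
      prob <- build_presto_lp(model, tr, lambda = lambda_grid[1], ...)
      for (li in seq_len(nL)) {
        res <- solve_presto(presto_set_lambda(prob, lambda_grid[li]))
        if (res$status != "optimal") next
        fold_delta[li, k] <- res$Delta
        sets[[li]][[length(sets[[li]]) + 1L]] <-
          res$delta$enzyme[res$delta$delta > corrected_tol]
        dvec <- stats::setNames(res$delta$delta, res$delta$enzyme)
        corrected <- apply_kcat_corrections(model, dvec)
        ve <- vapply(seq_len(nrow(va)), function(q) {
          cm <- make_condition_model(corrected, va[q, ],
                                     scenario_spec("pool_plus_uptake"))
          g <- predict_growth(cm)
          if (g$status != "optimal") return(NA_real_)
          relative_error(va$growth[q], g$objective)
        }, 0)
        val_err[[li]] <- c(val_err[[li]], list(ve))
      }
    }
    for (li in seq_len(nL)) {
      omega[li, tau] <- mean(unlist(val_err[[li]]), na.rm = TRUE)
      Delta[li, tau] <- mean(fold_delta[li, ], na.rm = TRUE)
    }
  }

  scores <- cv_score(omega, Delta)
  lambda_opt <- select_lambda(lambda_grid, scores)
  li_opt <- match(lambda_opt, lambda_grid)
  structure(list(
    measures = tibble::tibble(
      lambda = rep(lambda_grid, iterations),
      iteration = rep(seq_len(iterations), each = nL),
      omega = as.vector(omega), Delta = as.vector(Delta)),
    scores = tibble::tibble(lambda = lambda_grid, score = scores),
    lambda_opt = lambda_opt,
    folds = folds,
    corrected_sets = sets,
    fold_jaccard = fold_overlap(sets[[li_opt]]),
    K = K, iterations = iterations, seed = seed
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$K, "-fold x ", x$iterations,
      " iterations over ", nrow(x$scores), " lambda values; lambda* = ",
      format(x$lambda_opt), " (mean fold Jaccard distance ",
      signif(x$fold_jaccard, 3), ")\n", sep = "")
  invisible(x)
}

#' Cross-validation score per lambda
#'
#' For each iteration, min-max-scales the validation error over the lambda
#' grid and log10-scales the total correction between its per-iteration
#' extremes, then averages the product of the two factors over iterations:
#' `s = mean_tau[ scale(omega) * log10(Delta/Delta_min) /
#' log10(Delta_max/Delta_min) ]`. A degenerate scaling (max = min)
#' contributes 0 for that factor; `Delta = 0` is floored at 1e-12 before
#' log-scaling (logged).
#'
#' @param omega matrix lambda x iteration of validation mean relative
#'   errors.
#' @param Delta matrix lambda x iteration of total corrections.
#' @return numeric score per lambda, each in `[0, 1]`.
#' @export
cv_score <- function(omega, Delta) {
  omega <- as.matrix(omega); Delta <- as.matrix(Delta)
  stopifnot(identical(dim(omega), dim(Delta)))
  if (any(Delta <= 0, na.rm = TRUE)) {
    message("flooring non-positive total corrections at 1e-12 before ",
            "log-scaling")
    Delta[Delta <= 0] <- 1e-12
  }
  sapply_cols <- function(f) vapply(seq_len(ncol(omega)), f, numeric(nrow(omega)))
  terms <- sapply_cols(function(tau) {
    w <- omega[, tau]; d <- Delta[, tau]
    ws <- if (diff(range(w, na.rm = TRUE)) < 1e-15) rep(0, length(w))
    else (w - min(w, na.rm = TRUE)) / diff(range(w, na.rm = TRUE))
    ds <- if (diff(range(log10(d), na.rm = TRUE)) < 1e-15) rep(0, length(d))
    else log10(d / min(d, na.rm = TRUE)) / diff(range(log10(d), na.rm = TRUE))
    ws * ds
  })
  rowMeans(matrix(terms, nrow = nrow(omega)), na.rm = TRUE)
}

#' Select lambda from the score profile
#'
#' Second-order numerical differences of the score over the (uniform in
#' log10-lambda) grid index, one-sided at the endpoints; scanning from the
#' largest lambda downward, the chosen lambda is the grid point at the
#' first sign change of this second gradient. Without any sign change the
#' score's argmin is returned (logged).
#'
#' @param grid ascending lambda grid (>= 4 points).
#' @param score score per grid point (see [cv_score()]).
#' @return the selected lambda (a grid member).
#' @export
select_lambda <- function(grid, score) {
  n <- length(grid)
  if (n < 4) stop("lambda grid needs at least 4 points")
  stopifnot(length(score) == n, !is.unsorted(grid))
  d2 <- numeric(n)
  d2[2:(n - 1)] <- score[3:n] - 2 * score[2:(n - 1)] + score[1:(n - 2)]
  d2[1] <- score[3] - 2 * score[2] + score[1]
  d2[n] <- score[n] - 2 * score[n - 1] + score[n - 2]
  d2[abs(d2) < 1e-9 * max(abs(score), 1e-12)] <- 0
  sgn <- sign(d2)
  last <- sgn[n]
  for (k in seq(n - 1, 1)) {
    if (sgn[k] != 0 && last != 0 && sgn[k] != last) return(grid[k])
    if (sgn[k] != 0) last <- sgn[k]
  }
  message("no sign change in the second score gradient; ",
          "falling back to the score argmin")
  grid[which.min(score)]
}

#' Mean pairwise Jaccard distance between corrected-enzyme sets
#'
#' @param sets list of character vectors (>= 2). Two empty sets have
#'   distance 0.
#' @return mean over unordered pairs of `1 - |intersection| / |union|`.
#' @export
fold_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  pairs <- utils::combn(length(sets), 2)
  mean(apply(pairs, 2, function(p) {
    jaccard_distance(sets[[p[1]]], sets[[p[2]]])
  }))
}

jaccard_distance <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(0)
  1 - length(intersect(a, b)) / length(u)
}

#' Robustness of corrections to the number of conditions
#'
#' Re-runs the correction on randomly sampled subcollections of conditions
#' and quantifies concordance with the all-conditions run: Jaccard
#' distance between corrected-enzyme sets, and the Pearson correlation of
#' log10-transformed corrected kcats over the enzymes corrected in both
#' runs (reported as `NA` when fewer than 3 enzymes are shared -- never
#' as 0).
#'
#' @param model a `pc_model`.
#' @param conditions condition tibble.
#' @param lambda weighting factor for all runs (typically the selected
#'   lambda).
#' @param sizes subcollection sizes; sizes exceeding the number of
#'   conditions are dropped.
#' @param draws random subcollections per size (default 10).
#' @param seed RNG seed (local).
#' @param corrected_tol minimum delta counting as corrected.
#' @param ... passed to [build_presto_lp()].
#' @return tibble (size, draw, jaccard, pearson, n_common, feasible).
#' @export
robustness_subsample <- function(model, conditions, lambda,
                                 sizes = c(3, 5, 10, 15), draws = 10,
                                 seed = 1, corrected_tol = 1e-6, ...) {
  conditions <- validate_conditions(conditions)
  sizes <- sizes[sizes <= nrow(conditions)]
  if (length(sizes) == 0) stop("all subcollection sizes exceed |C|")
  ref <- presto_correct(model, conditions, lambda, ...)
  if (ref$status != "optimal") stop("reference run infeasible")
  ref_set <- ref$delta$enzyme[ref$delta$delta > corrected_tol]
  ref_k <- stats::setNames(ref$delta$kcat_new, ref$delta$enzyme)
  grid <- expand.grid(size = sizes, draw = seq_len(draws))
  rows <- with_local_seed(seed, {
    lapply(seq_len(nrow(grid)), function(g) {
      sz <- grid$size[g]
      sub <- conditions[sample(nrow(conditions), sz), ]
      res <- tryCatch(presto_correct(model, sub, lambda, ...),
                      error = function(e) list(status = "error"))
      if (res$status != "optimal")
        return(tibble::tibble(size = sz, draw = grid$draw[g],
                              jaccard = NA_real_, pearson = NA_real_,
                              n_common = NA_integer_, feasible = FALSE))
      st <- res$delta$enzyme[res$delta$delta > corrected_tol]
      common <- intersect(st, ref_set)
      kv <- stats::setNames(res$delta$kcat_new, res$delta$enzyme)
      pear <- if (length(common) >= 3)
        stats::cor(log10(ref_k[common]), log10(kv[common])) else NA_real_
      tibble::tibble(size = sz, draw = grid$draw[g],
                     jaccard = jaccard_distance(st, ref_set),
                     pearson = pear, n_common = length(common),
                     feasible = TRUE)
    })
  })
  dplyr::bind_rows(rows)
}
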