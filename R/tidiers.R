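# Broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correction result
#'
#' One row per enzyme in the measured set M: baseline kcat, fitted
#' correction (and negative correction when the second stage ran), and
#' corrected kcat, all in s^-1.
#'
#' @param x a `correction_result`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.correction_result <- function(x, ...) {
  if (x$status != "optimal")
    return(tibble::tibble(enzyme = character(0), kcat_min = numeric(0),
                          delta = numeric(0), kcat_new = numeric(0)))
  x$delta
}

#' Summarise a correction result in one row
#'
#' @param x a `correction_result`.
#' @param corrected_tol minimum delta counting as corrected (s^-1).
#' @param ... unused.
#' @return one-row tibble: lambda, mean/max relative error, total
#'   correction, number of corrected enzymes, objective, status.
#' @export
glance.correction_result <- function(x, corrected_tol = 1e-6, ...) {
  if (x$status != "optimal")
    return(tibble::tibble(lambda = x$lambda, status = x$status))
  tibble::tibble(
    lambda = x$lambda,
    mean_omega = mean(x$errors$omega),
    max_omega = max(x$errors$omega),
    Delta = x$Delta,
    n_corrected = sum(x$delta$delta > corrected_tol),
    objective = x$objective,
    status = x$status)
}

#' Tidy a cross-validation report
#' @param x a `cv_report`.
#' @param ... unused.
#' @return the per-(lambda, iteration) measures tibble.
#' @export
tidy.cv_report <- function(x, ...) x$measures

#' Summarise a cross-validation report in one row
#' @param x a `cv_report`.
#' @param ... unused.
#' @return one-row tibble: selected lambda, its mean validation error and
#'   mean total correction, fold Jaccard distance.
#' @export
glance.cv_report <- function(x, ...) {
  at <- x$measures[x$measures$lambda == x$lambda_opt, ]
  tibble::tibble(lambda_opt = x$lambda_opt,
                 mean_omega = mean(at$omega, na.rm = TRUE),
                 mean_Delta = mean(at$Delta, na.rm = TRUE),
                 fold_jaccard = x$fold_jaccard,
                 K = x$K, iterations = x$iterations)
}

#' Tidy a variability result
#' @param x a `variability_result`.
#' @param ... unused.
#' @return the per-enzyme interval tibble.
#' @export
tidy.variability_result <- function(x, ...) x$intervals
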