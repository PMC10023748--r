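# Enzyme tables: identifiers, molecular weights, per-(enzyme, reaction)
# turnover numbers (s^-1), and the measured-in-all-conditions flag that
# defines the correctable set M.

#' Construct/validate an enzyme table
#'
#' @param x a data frame with columns `enzyme`, `reaction`,
#'   `kcat` (s^-1, one row per enzyme-reaction pair), `mw`
#'   (g/mmol, constant within an enzyme) and optionally
#'   `measured_in_all` (logical; default `FALSE`).
#' @return a validated tibble with class `enzyme_table`.
#' @export
enzyme_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("enzyme", "reaction", "kcat", "mw")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("enzyme table is missing columns: ", paste(miss, collapse = ", "))
  if (!"measured_in_all" %in% names(x)) x$measured_in_all <- FALSE
  if (any(!is.finite(x$kcat)) || any(x$kcat <= 0))
    stop("all turnover numbers must be finite and > 0 (s^-1)")
  if (any(!is.finite(x$mw)) || any(x$mw <= 0))
    stop("all molecular weights must be finite and > 0 (g/mmol)")
  if (anyDuplicated(x[c("enzyme", "reaction")]))
    stop("duplicate (enzyme, reaction) rows in enzyme table")
  bad <- x |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(nmw = dplyr::n_distinct(.data$mw),
                     nm = dplyr::n_distinct(.data$measured_in_all)) |>
    dplyr::filter(.data$nmw > 1 | .data$nm > 1)
  if (nrow(bad))
    stop("inconsistent mw or measured_in_all within enzyme(s): ",
         paste(bad$enzyme, collapse = ", "))
  class(x) <- c("enzyme_table", class(x))
  x
}

#' Read an enzyme table from TSV
#'
#' Expected columns: `enzyme`, `reaction`, `kcat_s`, `mw_g_per_mmol`,
#' `measured_in_all`.
#'
#' @param path TSV file path.
#' @return an `enzyme_table` tibble.
#' @export
read_enzyme_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ren <- c(kcat_s = "kcat", mw_g_per_mmol = "mw")
  for (nm in names(ren))
    if (nm %in% names(d)) names(d)[names(d) == nm] <- ren[[nm]]
  if ("measured_in_all" %in% names(d))
    d$measured_in_all <- as.logical(d$measured_in_all)
  enzyme_table(d)
}

#' Write an enzyme table to TSV
#' @param x an `enzyme_table`.
#' @param path destination TSV path.
#' @return `path`, invisibly.
#' @export
write_enzyme_table <- function(x, path) {
  out <- data.frame(enzyme = x$enzyme, reaction = x$reaction,
                    kcat_s = x$kcat, mw_g_per_mmol = x$mw,
                    measured_in_all = x$measured_in_all)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
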