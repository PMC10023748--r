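# Protein-constrained model construction (GECKO-style augmentation).
#
# A pc_model is the metabolic network after (1) splitting every reversible
# reaction into irreversible forward/backward copies and (2) splitting
# OR-type GPR rules into one reaction copy per isozyme alternative, so that
# each remaining reaction copy is catalysed by a single enzyme or a single
# complex (AND set of subunits). Enzyme usage variables e_i (mmol/gDW) are
# coupled to flux through enzyme mass-balance rows with coefficients
# -1/(3600 * kcat_ij) on the flux columns (kcat stored in s^-1, constraint
# matrices in h^-1 so fluxes remain mmol/gDW/h), and a protein-pool row
# limits the total enzyme mass sum(e_i * MW_i).

#' Build a protein-constrained model
#'
#' @param network a `metabolic_network`.
#' @param enzymes an [enzyme_table()] with kcats keyed by the network's
#'   original reaction identifiers.
#' @param complex_stoich optional data frame (`enzyme`, `reaction`, `coef`)
#'   giving subunit copy numbers per catalytic event for complex members;
#'   defaults to 1 per subunit.
#' @return A `pc_model` object with elements `stoich` (split matrix),
#'   `rxns` (split reaction tibble with `orig`, `dir`, `enzymes` list
#'   column), `enzymes` (per-enzyme `mw`, `kcat_min`, `measured_in_all`),
#'   `kcats` (per enzyme x split-reaction turnover numbers, s^-1), and
#'   `biomass` (split identifier).
#' @export
build_pc_model <- function(network, enzymes, complex_stoich = NULL) {
  network <- validate_network(network)
  enzymes <- enzyme_table(enzymes)

  genes <- sort(unique(unlist(lapply(network$gpr_trees, gpr_genes))))
  missing_enz <- setdiff(genes, unique(enzymes$enzyme))
  if (length(missing_enz))
    stop("GPR rules reference enzymes absent from the enzyme table: ",
         paste(missing_enz, collapse = ", "))

  # 1. directional split
  split <- split_reversible(network)

  # 2. isozyme split; enzyme association per copy
  rows <- list()
  for (k in seq_len(nrow(split$rxns))) {
    r <- split$rxns[k, ]
    alts <- gpr_isozymes(network$gpr_trees[[r$orig]])
    if (length(alts) <= 1L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = r$id, orig = r$orig, dir = r$dir, lb = r$lb, ub = r$ub,
        enzymes = list(if (length(alts)) alts[[1]] else character(0)))
    } else {
      for (a in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = paste0(r$id, "_iz", a), orig = r$orig, dir = r$dir,
          lb = r$lb, ub = r$ub, enzymes = list(alts[[a]]))
      }
    }
  }
  rxns <- dplyr::bind_rows(rows)
  # isozyme copies share the parent's bounds (GECKO arm convention); a
  # nonzero lower bound on a split parent would force flux through every
  # arm, so it is kept only on the first copy.
  dup <- duplicated(paste(rxns$orig, rxns$dir)) & rxns$lb > 0
  rxns$lb[dup] <- 0

  S <- split$stoich_cols[, match(paste(rxns$orig, rxns$dir),
                                 colnames(split$stoich_cols)), drop = FALSE]
  colnames(S) <- rxns$id

  # 3. kcat assignment per (enzyme, split copy)
  kl <- list()
  for (k in seq_len(nrow(rxns))) {
    for (e in rxns$enzymes[[k]]) {
      hit <- which(enzymes$enzyme == e & enzymes$reaction == rxns$orig[k])
      if (length(hit) == 0)
        stop("no turnover number for enzyme '", e, "' on reaction '",
             rxns$orig[k], "'")
      co <- 1
      if (!is.null(complex_stoich)) {
        ch <- which(complex_stoich$enzyme == e &
                      complex_stoich$reaction == rxns$orig[k])
        if (length(ch)) co <- complex_stoich$coef[ch[[1]]]
      }
      kl[[length(kl) + 1L]] <- tibble::tibble(
        enzyme = e, rxn = rxns$id[k], orig_rxn = rxns$orig[k],
        kcat = enzymes$kcat[hit[[1]]], coef = co)
    }
  }
  kcats <- if (length(kl)) dplyr::bind_rows(kl) else
    tibble::tibble(enzyme = character(0), rxn = character(0),
                   orig_rxn = character(0), kcat = numeric(0),
                   coef = numeric(0))

  enz <- enzymes |>
    dplyr::distinct(.data$enzyme, .data$mw, .data$measured_in_all) |>
    dplyr::filter(.data$enzyme %in% kcats$enzyme)

  biomass_split <- rxns$id[rxns$orig == network$biomass & rxns$dir > 0][1]
  if (is.na(biomass_split))
    stop("biomass reaction lost during splitting (is it irreversible?)")

  m <- structure(list(
    stoich = S, rxns = rxns, enzymes = enz, kcats = kcats,
    biomass = biomass_split, network = network
  ), class = "pc_model")
  refresh_kcat_min(m)
}

split_reversible <- function(network) {
  out <- list(); cols <- list()
  for (k in seq_len(nrow(network$rxns))) {
    r <- network$rxns[k, ]
    s <- network$stoich[, r$id]
    if (r$lb < 0 && r$ub > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = paste0(r$id, "_fwd"), orig = r$id, dir = 1,
        lb = 0, ub = r$ub)
      cols[[paste(r$id, 1)]] <- s
      out[[length(out) + 1L]] <- tibble::tibble(
        id = paste0(r$id, "_rev"), orig = r$id, dir = -1,
        lb = 0, ub = -r$lb)
      cols[[paste(r$id, -1)]] <- -s
    } else if (r$ub <= 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = paste0(r$id, "_rev"), orig = r$id, dir = -1,
        lb = max(0, -r$ub), ub = -r$lb)
      cols[[paste(r$id, -1)]] <- -s
    } else {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = r$id, orig = r$id, dir = 1, lb = max(0, r$lb), ub = r$ub)
      cols[[paste(r$id, 1)]] <- s
    }
  }
  rxns <- dplyr::bind_rows(out)
  M <- do.call(cbind, cols)
  colnames(M) <- names(cols)
  list(rxns = rxns, stoich_cols = M)
}

refresh_kcat_min <- function(model) {
  km <- if (nrow(model$kcats) == 0)
    tibble::tibble(enzyme = character(0), kcat_min = numeric(0))
  else model$kcats |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::summarise(kcat_min = min(.data$kcat))
  model$enzymes <- model$enzymes |>
    dplyr::select(-dplyr::any_of("kcat_min")) |>
    dplyr::left_join(km, by = "enzyme")
  model
}

#' @export
print.pc_model <- function(x, ...) {
  cat("<pc_model> ", nrow(x$stoich), " metabolites x ", nrow(x$rxns),
      " split reactions; ", nrow(x$enzymes), " enzymes (",
      sum(x$enzymes$measured_in_all), " measured in all conditions)\n",
      sep = "")
  invisible(x)
}

#' Apply additive kcat corrections to a model
#'
#' Every reaction-specific turnover number of a corrected enzyme becomes
#' `kcat_min + delta` (a single value per enzyme), and `kcat_min` is
#' updated accordingly.
#'
#' @param model a `pc_model`.
#' @param delta named numeric vector of corrections (s^-1), indexed by
#'   enzyme identifier. Must be non-negative unless
#'   `allow_negative = TRUE`.
#' @param allow_negative permit negative corrections (apparent catalytic
#'   rates); the corrected kcat must remain > 0.
#' @param epsilon maximum allowed fold change of `kcat_min`
#'   (`delta <= (epsilon - 1) * kcat_min`); default `1e5`.
#' @param kmax absolute cap on the corrected kcat (s^-1); default
#'   `5.75e7`.
#' @return the corrected `pc_model`.
#' @export
apply_kcat_corrections <- function(model, delta, allow_negative = FALSE,
                                   epsilon = 1e5, kmax = 5.75e7) {
  stopifnot(inherits(model, "pc_model"))
  if (length(delta) == 0) return(model)
  if (is.null(names(delta)) || any(!nzchar(names(delta))))
    stop("delta must be a named vector indexed by enzyme identifiers")
  unknown <- setdiff(names(delta), model$enzymes$enzyme)
  if (length(unknown))
    stop("corrections for unknown enzymes: ", paste(unknown, collapse = ", "))
  if (!allow_negative && any(delta < 0))
    stop("negative corrections require allow_negative = TRUE")
  km <- stats::setNames(model$enzymes$kcat_min, model$enzymes$enzyme)
  kmin <- km[names(delta)]
  newk <- kmin + delta
  if (any(newk <= 0))
    stop("correction drives kcat of ",
         paste(names(delta)[newk <= 0], collapse = ", "), " to <= 0")
  over_eps <- delta > (epsilon - 1) * kmin
  if (any(over_eps))
    stop("correction exceeds the allowed ", format(epsilon),
         "-fold change for: ",
         paste(names(delta)[over_eps], collapse = ", "))
  if (any(newk > kmax))
    stop("corrected kcat exceeds the absolute cap (", format(kmax),
         " s^-1) for: ", paste(names(delta)[newk > kmax], collapse = ", "))
  idx <- model$kcats$enzyme %in% names(delta)
  model$kcats$kcat[idx] <- newk[model$kcats$enzyme[idx]]
  refresh_kcat_min(model)
}

#' Substitute externally estimated kcats by reaction
#'
#' Replaces the turnover numbers of single-enzyme reactions (including
#' each isozyme copy of a split OR rule) with per-reaction values from an
#' external source such as pFBA-derived in vivo estimates. Reactions
#' catalysed by enzyme complexes are left untouched; unknown reaction
#' identifiers are skipped with a warning.
#'
#' @param model a `pc_model`.
#' @param table data frame with columns `reaction` (original, pre-split
#'   identifiers) and `kcat` (s^-1).
#' @return the modified `pc_model`.
#' @export
substitute_external_kcats <- function(model, table) {
  stopifnot(inherits(model, "pc_model"))
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0) return(model)
  stopifnot(all(c("reaction", "kcat") %in% names(table)))
  unknown <- setdiff(table$reaction, model$rxns$orig)
  if (length(unknown))
    warning("unknown reaction identifiers skipped: ",
            paste(unknown, collapse = ", "))
  nsub <- stats::setNames(vapply(model$rxns$enzymes, length, 0L),
                          model$rxns$id)
  for (i in seq_len(nrow(table))) {
    copies <- model$rxns$id[model$rxns$orig == table$reaction[i]]
    copies <- copies[nsub[copies] == 1L]   # complexes not corrected
    idx <- model$kcats$rxn %in% copies
    model$kcats$kcat[idx] <- table$kcat[i]
  }
  refresh_kcat_min(model)
}

#' Export the model's turnover numbers as a table
#'
#' One row per (enzyme, original reaction) pair, kcat in s^-1.
#'
#' @param model a `pc_model`.
#' @param path optional TSV destination; when `NULL` the tibble is
#'   returned without writing.
#' @return a tibble with columns `enzyme`, `reaction`, `kcat_s`.
#' @export
write_kcat_table <- function(model, path = NULL) {
  out <- model$kcats |>
    dplyr::distinct(.data$enzyme, reaction = .data$orig_rxn,
                    kcat_s = .data$kcat)
  if (!is.null(path))
    utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Read a kcat table written by [write_kcat_table()]
#' @param path TSV path.
#' @return tibble with columns `enzyme`, `reaction`, `kcat_s`.
#' @export
read_kcat_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

# Split-reaction columns catalysed by each enzyme (capacity row support),
# with complex-stoichiometry coefficients.
enzyme_reaction_map <- function(model) {
  split(model$kcats[c("rxn", "kcat", "coef")], model$kcats$enzyme)
}
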