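# Metabolic network container and I/O.
#
# A metabolic_network holds the stoichiometric matrix over *internal*
# metabolites (rows) and reactions (columns), per-reaction flux bounds in
# mmol/gDW/h, one biomass reaction, and a GPR rule per reaction. Exchange
# reactions are recognised structurally as columns with a single nonzero
# stoichiometric entry. Two on-disk formats are supported: a JSON dialect
# (native) and a subset of SBML Level 3 with the fbc extension (see
# R/sbml.R).

#' Construct a metabolic network
#'
#' @param stoich numeric matrix, metabolites x reactions, with row and
#'   column names (metabolite and reaction identifiers). Rows are internal
#'   metabolites only; boundary metabolites are represented implicitly by
#'   exchange reactions with a single nonzero entry.
#' @param lb,ub flux bounds (mmol/gDW/h), one per reaction.
#' @param biomass identifier of the biomass reaction.
#' @param gpr character vector of GPR rules, one per reaction
#'   (`""`/`NA` = none, i.e. kinetics-free).
#' @return A `metabolic_network` object.
#' @export
metabolic_network <- function(stoich, lb, ub, biomass, gpr = NULL) {
  stoich <- as.matrix(stoich)
  nr <- ncol(stoich)
  if (is.null(colnames(stoich)) || is.null(rownames(stoich)))
    stop("stoich must have metabolite row names and reaction column names")
  if (is.null(gpr)) gpr <- rep("", nr)
  gpr[is.na(gpr)] <- ""
  net <- structure(list(
    stoich = stoich,
    rxns = tibble::tibble(
      id = colnames(stoich),
      lb = as.numeric(lb),
      ub = as.numeric(ub),
      gpr = as.character(gpr)
    ),
    mets = tibble::tibble(id = rownames(stoich)),
    biomass = biomass
  ), class = "metabolic_network")
  validate_network(net)
}

#' Validate a metabolic network
#'
#' Checks identifier uniqueness, the presence of exactly one biomass
#' reaction, that no reaction column is all-zero, that every exchange
#' reaction has a single nonzero entry (structural, always true), and that
#' all GPR rules parse.
#'
#' @param net a `metabolic_network`.
#' @return `net`, invisibly modified with parsed GPR trees cached in
#'   `net$gpr_trees`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  ids <- net$rxns$id
  if (anyDuplicated(ids))
    stop("duplicate reaction identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(net$mets$id))
    stop("duplicate metabolite identifiers")
  if (!net$biomass %in% ids)
    stop("biomass reaction '", net$biomass, "' not found in the network")
  zero_cols <- colSums(net$stoich != 0) == 0
  if (any(zero_cols))
    stop("all-zero reaction columns: ",
         paste(ids[zero_cols], collapse = ", "))
  if (any(net$rxns$lb > net$rxns$ub))
    stop("reaction lower bound exceeds upper bound")
  net$gpr_trees <- lapply(net$rxns$gpr, parse_gpr)
  names(net$gpr_trees) <- ids
  net
}

#' Exchange reaction identifiers of a network
#'
#' Exchange reactions are the columns of the stoichiometric matrix with a
#' single nonzero entry (a source or drain across the system boundary).
#' The biomass reaction is excluded even if it drains a single metabolite.
#'
#' @param net a `metabolic_network`.
#' @return character vector of reaction identifiers.
#' @export
exchange_reactions <- function(net) {
  single <- colSums(net$stoich != 0) == 1
  setdiff(net$rxns$id[single], net$biomass)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$stoich), " metabolites x ",
      ncol(x$stoich), " reactions; biomass: ", x$biomass, "; ",
      length(exchange_reactions(x)), " exchange reactions\n", sep = "")
  invisible(x)
}

#' Read a metabolic network from disk
#'
#' @param path file path.
#' @param format `"json"` (the package's native dialect) or `"sbml"`
#'   (SBML Level 3 + fbc subset). Guessed from the file extension when
#'   omitted.
#' @return A validated `metabolic_network`.
#' @export
load_network <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "sbml") return(read_sbml_network(path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$reactions) || length(j$reactions) == 0)
    stop("no reactions in network file: ", path)
  mets <- vapply(j$metabolites, function(m) m$id, "")
  rid <- vapply(j$reactions, function(r) r$id, "")
  if (anyDuplicated(rid))
    stop("duplicate reaction identifiers in ", path)
  S <- matrix(0, length(mets), length(rid), dimnames = list(mets, rid))
  for (r in j$reactions) {
    for (mid in names(r$stoich)) {
      if (!mid %in% mets) stop("unknown metabolite '", mid, "' in ", r$id)
      S[mid, r$id] <- as.numeric(r$stoich[[mid]])
    }
  }
  if (is.null(j$biomass)) stop("missing biomass reaction in ", path)
  metabolic_network(
    S,
    lb = vapply(j$reactions, function(r) as.numeric(r$lb), 0),
    ub = vapply(j$reactions, function(r) as.numeric(r$ub), 0),
    biomass = j$biomass,
    gpr = vapply(j$reactions, function(r) {
      if (is.null(r$gpr)) "" else as.character(r$gpr)
    }, "")
  )
}

#' Write a metabolic network to disk
#'
#' Lossless counterpart of [load_network()].
#'
#' @param net a `metabolic_network`.
#' @param path destination file.
#' @param format `"json"` or `"sbml"`; guessed from the extension when
#'   `"auto"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  if (format == "sbml") return(write_sbml_network(net, path))
  rx <- lapply(seq_len(nrow(net$rxns)), function(i) {
    id <- net$rxns$id[i]
    s <- net$stoich[, id]
    s <- s[s != 0]
    list(id = id, lb = net$rxns$lb[i], ub = net$rxns$ub[i],
         gpr = net$rxns$gpr[i], stoich = as.list(s))
  })
  jsonlite::write_json(
    list(metabolites = lapply(net$mets$id, function(m) list(id = m)),
         reactions = rx, biomass = net$biomass),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
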