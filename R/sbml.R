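# SBML Level 3 (+ fbc version 2) reading and writing.
#
# Covers the subset of SBML used for constraint-based models: species,
# reactions with stoichiometry, flux bounds as shared parameters, gene
# product associations (nested fbc:and / fbc:or), and the active maximise
# objective marking the biomass reaction. Identifiers are written with the
# conventional R_/M_/G_ prefixes and stripped again on reading, so
# write/read round-trips are exact. No installed R package parses SBML, so
# the mapping onto XML is done here with xml2.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_sid <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", id))

write_sbml_network <- function(net, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")

  sp <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in net$mets$id)
    xml2::xml_add_child(sp, "species", id = sbml_sid("M_", m), name = m,
                        compartment = "c", hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  pars <- xml2::xml_add_child(model, "listOfParameters")
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  for (i in seq_len(nrow(net$rxns))) {
    rid <- sbml_sid("R_", net$rxns$id[i])
    xml2::xml_add_child(pars, "parameter", id = paste0("lb_", rid),
                        value = fmt(net$rxns$lb[i]), constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0("ub_", rid),
                        value = fmt(net$rxns$ub[i]), constant = "true")
  }

  genes <- sort(unique(unlist(lapply(net$rxns$gpr,
                                     function(g) gpr_genes(parse_gpr(g))))))
  if (length(genes)) {
    gl <- xml2::xml_add_child(model, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(gl, "fbc:geneProduct",
                          "fbc:id" = sbml_sid("G_", g), "fbc:label" = g)
  }

  rl <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(net$rxns))) {
    id <- net$rxns$id[i]
    rid <- sbml_sid("R_", id)
    rnode <- xml2::xml_add_child(
      rl, "reaction", id = rid, name = id,
      reversible = tolower(as.character(net$rxns$lb[i] < 0)), fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", rid),
      "fbc:upperFluxBound" = paste0("ub_", rid))
    s <- net$stoich[, id]
    rea <- names(s)[s < 0]; pro <- names(s)[s > 0]
    if (length(rea)) {
      ln <- xml2::xml_add_child(rnode, "listOfReactants")
      for (m in rea)
        xml2::xml_add_child(ln, "speciesReference",
                            species = sbml_sid("M_", m),
                            stoichiometry = fmt(-s[[m]]), constant = "true")
    }
    if (length(pro)) {
      ln <- xml2::xml_add_child(rnode, "listOfProducts")
      for (m in pro)
        xml2::xml_add_child(ln, "speciesReference",
                            species = sbml_sid("M_", m),
                            stoichiometry = fmt(s[[m]]), constant = "true")
    }
    tree <- parse_gpr(net$rxns$gpr[i])
    if (!is.null(tree)) {
      assoc <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      sbml_add_gpa(assoc, tree)
    }
  }

  ol <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  on <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fl <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fl, "fbc:fluxObjective",
                      "fbc:reaction" = sbml_sid("R_", net$biomass),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_add_gpa <- function(parent, tree) {
  if (tree$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = sbml_sid("G_", tree$gene))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
    for (a in tree$args) sbml_add_gpa(node, a)
  }
  invisible(parent)
}

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

sbml_local <- function(node, name) {
  xml2::xml_find_all(node, paste0("./*[local-name()='", name, "']"))
}

sbml_attr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(c(name, paste0("fbc:", name)), names(at))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NA_character_ else unname(at[[hit[[1]]]])
}

read_sbml_network <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unparsable SBML file: ", path,
                                           " (", conditionMessage(e), ")"))
  find <- function(xp) xml2::xml_find_all(doc, xp)
  sp <- find("//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- strip_prefix(vapply(sp, function(n) sbml_attr(n, "id"), ""), "M_")
  keep <- !vapply(sp, function(n)
    identical(sbml_attr(n, "boundaryCondition"), "true"), TRUE)
  mets <- mets[keep]

  pars <- find("//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- vapply(pars, function(n) as.numeric(sbml_attr(n, "value")), 0)
  names(pval) <- vapply(pars, function(n) sbml_attr(n, "id"), "")

  rn <- find("//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rn) == 0) stop("no reactions in SBML file: ", path)
  rid_raw <- vapply(rn, function(n) sbml_attr(n, "id"), "")
  rid <- strip_prefix(rid_raw, "R_")
  if (anyDuplicated(rid)) stop("duplicate reaction identifiers in ", path)
  S <- matrix(0, length(mets), length(rid), dimnames = list(mets, rid))
  lb <- numeric(length(rid)); ub <- numeric(length(rid))
  gpr <- character(length(rid))
  for (k in seq_along(rn)) {
    node <- rn[[k]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in sbml_local(node, side)) {
        for (ref in sbml_local(sr, "speciesReference")) {
          m <- strip_prefix(sbml_attr(ref, "species"), "M_")
          if (m %in% mets)
            S[m, rid[k]] <- S[m, rid[k]] +
              sgn * as.numeric(sbml_attr(ref, "stoichiometry"))
        }
      }
    }
    lbid <- sbml_attr(node, "lowerFluxBound")
    ubid <- sbml_attr(node, "upperFluxBound")
    lb[k] <- if (!is.na(lbid) && lbid %in% names(pval)) pval[[lbid]] else -Inf
    ub[k] <- if (!is.na(ubid) && ubid %in% names(pval)) pval[[ubid]] else Inf
    gpa <- sbml_local(node, "geneProductAssociation")
    gpr[k] <- if (length(gpa)) {
      kids <- xml2::xml_children(gpa[[1]])
      if (length(kids)) deparse_gpr(sbml_read_gpa(kids[[1]])) else ""
    } else ""
  }

  fo <- find("//*[local-name()='fluxObjective']")
  if (length(fo) == 0) stop("missing biomass (flux objective) in ", path)
  biomass <- strip_prefix(sbml_attr(fo[[1]], "reaction"), "R_")
  metabolic_network(S, lb = lb, ub = ub, biomass = biomass, gpr = gpr)
}

sbml_read_gpa <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef")
    return(list(op = "gene",
                gene = strip_prefix(sbml_attr(node, "geneProduct"), "G_")))
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(op = nm, args = lapply(kids, sbml_read_gpa)))
  }
  stop("unsupported gene association element: ", nm)
}
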