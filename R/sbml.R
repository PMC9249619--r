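# SBML Level 3 + FBC v2 input/output.
#
# Scope: the constructs constraint-based models actually use -- species with
# compartment/formula/charge, reactions with stoichiometry, flux bounds via
# FBC parameters, gene-product associations, and the active FBC objective.
# Kinetic laws, rules and events are out of scope. The conventional "M_",
# "R_", "G_" id prefixes are stripped on read and re-added on write, so ids
# match the community JSON dialect.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

#' Read a model from SBML Level 3 with the FBC package
#'
#' @param path SBML file (plain or gzip-compressed).
#' @return a `cbm_model`. Bounds come from the FBC bound parameters, GPR
#'   trees from the FBC gene-product associations (deparsed to rule text
#'   using gene labels), and the objective from the active FBC objective.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML XML in '", path,
                                           "': ", conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("no <model> element in '", path, "'")

  # bound parameters: id -> value
  par_nodes <- xml2::xml_find_all(model_node, "./s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  # gene products: fbc:id -> label (fall back to id sans G_)
  gp_nodes <- xml2::xml_find_all(model_node, "./fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_id <- xml2::xml_attr(gp_nodes, "fbc:id", ns)
  if (all(is.na(gp_id))) gp_id <- xml2::xml_attr(gp_nodes, "id")
  gp_label <- xml2::xml_attr(gp_nodes, "fbc:label", ns)
  gp_label[is.na(gp_label)] <- sub("^G_", "", gp_id[is.na(gp_label)])
  gene_label <- stats::setNames(gp_label, gp_id)

  sp_nodes <- xml2::xml_find_all(model_node, "./s:listOfSpecies/s:species", ns)
  sp_sid <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  keep <- is.na(boundary) | boundary != "true"
  mets <- data.frame(
    id = sub("^M_", "", sp_sid[keep]),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")[keep]),
                  sub("^M_", "", sp_sid[keep]),
                  xml2::xml_attr(sp_nodes, "name")[keep]),
    compartment = xml2::xml_attr(sp_nodes, "compartment")[keep],
    formula = xml2::xml_attr(sp_nodes, "fbc:chemicalFormula", ns)[keep],
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "fbc:charge", ns)[keep])),
    stringsAsFactors = FALSE)
  known_species <- sp_sid

  rxn_nodes <- xml2::xml_find_all(model_node, "./s:listOfReactions/s:reaction", ns)
  if (length(rxn_nodes) == 0L) stop("no reactions in '", path, "'")

  rxns <- vector("list", length(rxn_nodes))
  missing_bounds <- character()
  for (k in seq_along(rxn_nodes)) {
    nd <- rxn_nodes[[k]]
    rid_raw <- xml2::xml_attr(nd, "id")
    rid <- sub("^R_", "", rid_raw)
    lb_ref <- xml2::xml_attr(nd, "fbc:lowerFluxBound", ns)
    ub_ref <- xml2::xml_attr(nd, "fbc:upperFluxBound", ns)
    if (is.na(lb_ref) || is.na(ub_ref)) { missing_bounds <- c(missing_bounds, rid); next }
    lb <- unname(par_val[lb_ref]); ub <- unname(par_val[ub_ref])
    refs <- xml2::xml_find_all(nd, "./s:listOfReactants/s:speciesReference", ns)
    prods <- xml2::xml_find_all(nd, "./s:listOfProducts/s:speciesReference", ns)
    sid <- c(xml2::xml_attr(refs, "species"), xml2::xml_attr(prods, "species"))
    coef <- c(-as.numeric(xml2::xml_attr(refs, "stoichiometry")),
              as.numeric(xml2::xml_attr(prods, "stoichiometry")))
    bad <- setdiff(sid, known_species)
    if (length(bad) > 0L) {
      stop("reaction '", rid, "' references undefined species: ",
           paste(bad, collapse = ", "))
    }
    st <- tapply(coef, sub("^M_", "", sid), sum)   # merge duplicate refs
    st <- stats::setNames(as.numeric(st), names(st))
    gpa <- xml2::xml_find_first(nd, "./fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      tree <- sbml_gpr_tree(xml2::xml_child(gpa), gene_label)
      gpr_deparse(tree)
    }
    rxns[[k]] <- reaction(id = rid,
                          name = xml2::xml_attr(nd, "name") %||na% rid,
                          stoichiometry = st, lower_bound = lb,
                          upper_bound = ub, gpr = gpr)
  }
  if (length(missing_bounds) > 0L) {
    stop("reactions without FBC flux bounds: ",
         paste(missing_bounds, collapse = ", "))
  }

  # active objective
  obj_list <- xml2::xml_find_first(model_node, "./fbc:listOfObjectives", ns)
  if (inherits(obj_list, "xml_missing")) stop("no FBC objective in '", path, "'")
  active <- xml2::xml_attr(obj_list, "fbc:activeObjective", ns)
  objs <- xml2::xml_find_all(obj_list, "./fbc:objective", ns)
  oid <- xml2::xml_attr(objs, "fbc:id", ns)
  pick <- if (!is.na(active) && active %in% oid) which(oid == active)[1] else 1L
  fo <- xml2::xml_find_first(objs[[pick]],
                             "./fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective_id <- sub("^R_", "", xml2::xml_attr(fo, "fbc:reaction", ns))

  cbm_model(id = xml2::xml_attr(model_node, "id") %||na%
              tools::file_path_sans_ext(basename(path)),
            metabolites = mets, reactions = rxns, objective_id = objective_id)
}

`%||na%` <- function(a, b) if (is.na(a)) b else a

# recursive FBC association -> GPR tree
sbml_gpr_tree <- function(node, gene_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lbl <- gene_label[ref]
    return(list(op = "gene", gene = unname(if (is.na(lbl)) sub("^G_", "", ref) else lbl)))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(op = nm, args = lapply(seq_along(kids),
                                       function(i) sbml_gpr_tree(kids[[i]], gene_label))))
  }
  stop("unexpected node <", nm, "> in gene association")
}

#' Write a model as SBML Level 3 with FBC v2
#'
#' Emits the subset of SBML the reader consumes; `read_sbml(write_sbml(m))`
#' preserves stoichiometry, bounds and GPR truth tables.
#'
#' @param model a `cbm_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(model$id), '" fbc:strict="true">'))

  comps <- unique(model$metabolites$compartment)
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
             "    </listOfCompartments>")

  m <- model$metabolites
  sp <- sprintf(paste0('      <species id="M_%s" name="%s" compartment="%s"',
                       ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
                       ' constant="false"%s%s/>'),
                esc(m$id), esc(m$name), esc(m$compartment),
                ifelse(is.na(m$formula), "",
                       sprintf(' fbc:chemicalFormula="%s"', esc(m$formula))),
                ifelse(is.na(m$charge), "",
                       sprintf(' fbc:charge="%d"', m$charge)))
  lines <- c(lines, "    <listOfSpecies>", sp, "    </listOfSpecies>")

  bounds <- reaction_bounds(model)
  vals <- sort(unique(c(bounds$lower, bounds$upper)))
  par_id <- stats::setNames(paste0("fb_", seq_along(vals)), num(vals))
  lines <- c(lines, "    <listOfParameters>",
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     par_id, names(par_id)),
             "    </listOfParameters>")

  genes <- model$genes
  if (length(genes) > 0L) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
                       esc(gsub("[^A-Za-z0-9_]", "_", genes)), esc(genes)),
               "    </fbc:listOfGeneProducts>")
  }

  assoc_xml <- function(tree, indent) {
    pad <- strrep(" ", indent)
    if (tree$op == "gene") {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', pad,
                     esc(gsub("[^A-Za-z0-9_]", "_", tree$gene))))
    }
    c(sprintf("%s<fbc:%s>", pad, tree$op),
      unlist(lapply(tree$args, assoc_xml, indent = indent + 2L)),
      sprintf("%s</fbc:%s>", pad, tree$op))
  }

  lines <- c(lines, "    <listOfReactions>")
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(r$id), esc(r$name), tolower(r$lower_bound < 0),
      par_id[num(r$lower_bound)], par_id[num(r$upper_bound)]))
    st <- r$stoichiometry
    rea <- st[st < 0]; pro <- st[st > 0]
    if (length(rea) > 0L) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf(paste0('          <speciesReference species="M_%s"',
                                ' stoichiometry="%s" constant="true"/>'),
                         esc(names(rea)), num(-unname(rea))),
                 "        </listOfReactants>")
    }
    if (length(pro) > 0L) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf(paste0('          <speciesReference species="M_%s"',
                                ' stoichiometry="%s" constant="true"/>'),
                         esc(names(pro)), num(unname(pro))),
                 "        </listOfProducts>")
    }
    tree <- gpr_parse(r$gpr)
    if (!is.null(tree)) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 assoc_xml(tree, 10L), "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>",
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             "        <fbc:listOfFluxObjectives>",
             sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
                     esc(model$objective_id)),
             "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>",
             "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
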