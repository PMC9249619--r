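#' A heterologous pathway definition
#'
#' Bundles the new metabolites and reactions a graft adds to a host model,
#' plus the id of the product exchange. Reaction stoichiometries may
#' reference host metabolites; [graft_pathway()] checks they resolve.
#'
#' @param metabolites data.frame of [metabolite()] rows (the new species).
#' @param reactions list of [reaction()] objects (the new reactions).
#' @param product_exchange_id id of the product exchange among `reactions`.
#' @param notes named character vector: provenance text per reaction id.
#' @return a `pathway_definition`.
#' @export
pathway_definition <- function(metabolites, reactions, product_exchange_id,
                               notes = character()) {
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (!product_exchange_id %in% ids) {
    stop("product exchange '", product_exchange_id, "' not among pathway reactions")
  }
  structure(list(metabolites = metabolites, reactions = reactions,
                 product_exchange_id = product_exchange_id, notes = notes),
            class = "pathway_definition")
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat("<pathway_definition> ", length(x$reactions), " reactions, ",
      nrow(x$metabolites), " new metabolites, product exchange: ",
      x$product_exchange_id, "\n", sep = "")
  invisible(x)
}

#' The built-in papBAC pathway: chorismate to para-aminophenylalanine
#'
#' The consolidated four-step block expressed from the papBAC gene cluster
#' plus export machinery, in BiGG host ids:
#' \describe{
#'   \item{PAPA}{chorismate + L-glutamine -> 4-amino-4-deoxychorismate +
#'     L-glutamate (aminodeoxychorismate synthase, PapA).}
#'   \item{PAPB}{4-amino-4-deoxychorismate -> 4-amino-4-deoxyprephenate
#'     (mutase, PapB).}
#'   \item{PAPC}{4-amino-4-deoxyprephenate + NAD+ -> 4-aminophenylpyruvate
#'     + CO2 + NADH + H+ (dehydrogenase, PapC; NAD-dependent by analogy to
#'     the host prephenate dehydrogenase).}
#'   \item{PAFTA}{4-aminophenylpyruvate + L-glutamate <-> pAF +
#'     2-oxoglutarate (transamination; in vivo by promiscuous host
#'     aminotransferases, added here as an explicit reaction).}
#'   \item{PAFt, EX_paf_e}{diffusive export and exchange of pAF.}
#' }
#' All reactions are balanced for C, N, H, O and charge against the shipped
#' formulas. Glutamine and chorismate are the pathway's host precursors.
#'
#' @param transaminase_gpr GPR text for the transamination step; empty by
#'   default (native host enzymes, no dedicated heterologous gene).
#' @return a `pathway_definition`.
#' @export
builtin_papbac_pathway <- function(transaminase_gpr = "") {
  mets <- rbind(
    metabolite("4adcho_c", "4-amino-4-deoxychorismate", "c", "C10H10NO5", -1L),
    metabolite("4a4dpre_c", "4-amino-4-deoxyprephenate", "c", "C10H10NO5", -1L),
    metabolite("4aphpyr_c", "4-aminophenylpyruvate", "c", "C9H8NO3", -1L),
    metabolite("paf_c", "para-aminophenylalanine", "c", "C9H12N2O2", 0L),
    metabolite("paf_e", "para-aminophenylalanine", "e", "C9H12N2O2", 0L))
  rxns <- list(
    reaction("PAPA", c(chor_c = -1, gln__L_c = -1, `4adcho_c` = 1, glu__L_c = 1),
             0, 1000, gpr = "papA", name = "aminodeoxychorismate synthase (PapA)"),
    reaction("PAPB", c(`4adcho_c` = -1, `4a4dpre_c` = 1),
             0, 1000, gpr = "papB", name = "aminodeoxychorismate mutase (PapB)"),
    reaction("PAPC", c(`4a4dpre_c` = -1, nad_c = -1, `4aphpyr_c` = 1,
                       co2_c = 1, nadh_c = 1, h_c = 1),
             0, 1000, gpr = "papC",
             name = "aminodeoxyprephenate dehydrogenase (PapC)"),
    reaction("PAFTA", c(`4aphpyr_c` = -1, glu__L_c = -1, paf_c = 1, akg_c = 1),
             -1000, 1000, gpr = transaminase_gpr,
             name = "4-aminophenylpyruvate transaminase"),
    reaction("PAFt", c(paf_c = -1, paf_e = 1), -1000, 1000,
             name = "pAF transport (diffusion)"),
    reaction("EX_paf_e", c(paf_e = -1), 0, 1000, name = "pAF exchange"))
  notes <- c(
    PAPA = "PapA; stoichiometry as the host aminodeoxychorismate synthase (MetaCyc/KEGG consolidation)",
    PAPB = "PapB; isomerization, no cofactor",
    PAPC = "PapC; NAD-dependent oxidative decarboxylation, by analogy to prephenate dehydrogenase",
    PAFTA = "native host aminotransferases; explicit reaction, glutamate donor",
    PAFt = "passive export",
    EX_paf_e = "product exchange")
  pathway_definition(mets, rxns, "EX_paf_e", notes)
}

#' Graft a heterologous pathway into a host model
#'
#' New metabolites whose id already exists in the host are taken to be the
#' host species (shared currency metabolites); new reactions must not
#' collide with host reaction ids. Host metabolites referenced by pathway
#' stoichiometries must exist. With all grafted reactions closed the
#' augmented model's growth optimum equals the host's exactly (graft
#' neutrality).
#'
#' @param host a `cbm_model`.
#' @param pathway a `pathway_definition`.
#' @param id_map optional named character vector mapping pathway metabolite
#'   ids to host ids (for hosts outside the BiGG namespace).
#' @return the augmented `cbm_model`; the product exchange id is recorded
#'   and retrievable with [product_exchange()].
#' @export
graft_pathway <- function(host, pathway, id_map = NULL) {
  rxn_ids <- vapply(pathway$reactions, `[[`, character(1), "id")
  clash <- intersect(rxn_ids, reaction_ids(host))
  if (length(clash) > 0L) {
    stop("duplicate pathway ids already present in host: ",
         paste(clash, collapse = ", "))
  }
  remap <- function(ids) {
    if (is.null(id_map)) return(ids)
    hit <- ids %in% names(id_map)
    ids[hit] <- id_map[ids[hit]]
    ids
  }
  new_mets <- pathway$metabolites
  new_mets$id <- remap(new_mets$id)
  new_mets <- new_mets[!new_mets$id %in% host$metabolites$id, , drop = FALSE]
  all_mets <- rbind(host$metabolites, new_mets)
  rxns <- lapply(pathway$reactions, function(r) {
    names(r$stoichiometry) <- remap(names(r$stoichiometry))
    r
  })
  missing <- setdiff(unique(unlist(lapply(rxns, function(r) names(r$stoichiometry)))),
                     all_mets$id)
  if (length(missing) > 0L) {
    stop("pathway references host metabolites that do not exist: ",
         paste(missing, collapse = ", "))
  }
  out <- cbm_model(host$id, all_mets, c(host$reactions, rxns),
                   host$objective_id, check = FALSE)
  attr(out, "product_exchange_id") <- pathway$product_exchange_id
  attr(out, "pathway_reaction_ids") <- rxn_ids
  out
}

#' Reaction ids added by the last graft
#' @param model a grafted `cbm_model`.
#' @return character vector (or `NULL` if the model was not grafted).
#' @export
pathway_reactions <- function(model) attr(model, "pathway_reaction_ids")

#' Close the grafted pathway (wild-type reference state)
#' @param model a grafted `cbm_model`.
#' @return copy with all grafted reaction bounds set to zero.
#' @export
close_pathway <- function(model) {
  ids <- pathway_reactions(model)
  if (is.null(ids)) stop("model carries no pathway annotation")
  for (rid in ids) model <- set_bounds(model, rid, 0, 0)
  model
}

# --- pathway file format ------------------------------------------------

#' Parse a reaction equation string
#'
#' Syntax: `"a + 2 b -> c"` (irreversible) or `"a <-> b"` (reversible
#' marker only; bounds still come from the reaction record). Coefficients
#' are optional rationals ("0.5" or "1/2") preceding a metabolite id.
#'
#' @param eq equation text.
#' @return named numeric stoichiometry vector (negative = consumed).
#' @export
parse_equation <- function(eq) {
  arrow <- regexpr("<->|<=>|->|=>", eq, perl = TRUE)
  if (arrow < 0) stop("equation needs an arrow: ", eq)
  sides <- c(substr(eq, 1L, arrow - 1L),
             substr(eq, arrow + attr(arrow, "match.length"), nchar(eq)))
  if (grepl("<->|<=>|->|=>", sides[2], perl = TRUE)) {
    stop("equation needs exactly one arrow: ", eq)
  }
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; id <- parts[1]
      } else if (length(parts) == 2L) {
        coef <- if (grepl("/", parts[1], fixed = TRUE)) {
          nd <- as.numeric(strsplit(parts[1], "/", fixed = TRUE)[[1]])
          nd[1] / nd[2]
        } else suppressWarnings(as.numeric(parts[1]))
        id <- parts[2]
        if (is.na(coef)) stop("bad coefficient in term '", tm, "' of: ", eq)
      } else stop("cannot parse term '", tm, "' in: ", eq)
      out[id] <- (if (is.na(out[id])) 0 else out[id]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (is.na(st[id])) 0 else st[id]) + rhs[id]
  st[st != 0]
}

#' Read a pathway definition from YAML
#'
#' Layout:
#' \preformatted{
#' product_exchange: EX_x_e
#' metabolites:
#'   - {id: x_c, formula: C1, compartment: c, charge: 0}
#' reactions:
#'   - {id: RX, equation: "a_c -> x_c", lower: 0, upper: 1000, gpr: "gene1"}
#' }
#'
#' @param path YAML file.
#' @return a `pathway_definition`.
#' @export
read_pathway_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  mets <- do.call(rbind, lapply(y$metabolites, function(m) {
    metabolite(m$id, m$name %||% m$id, m$compartment %||% "c",
               m$formula %||% NA_character_, m$charge %||% NA_integer_)
  }))
  rxns <- lapply(y$reactions, function(r) {
    reaction(r$id, parse_equation(r$equation),
             lower_bound = r$lower %||% 0, upper_bound = r$upper %||% 1000,
             gpr = r$gpr %||% "", name = r$name %||% r$id)
  })
  notes <- vapply(y$reactions, function(r) r$note %||% "", character(1))
  names(notes) <- vapply(y$reactions, `[[`, character(1), "id")
  pathway_definition(mets, rxns, y$product_exchange, notes)
}

#' Check elemental balance of pathway reactions
#'
#' Sums each element (and charge) over a reaction's stoichiometry given the
#' formulas known to the model; exchanges and demands (single-metabolite
#' boundary reactions) are skipped.
#'
#' @param model a `cbm_model` whose metabolites carry formulas.
#' @param reaction_ids reactions to check.
#' @param elements which elements to balance.
#' @return data.frame (`reaction_id`, `element`, `imbalance`) of nonzero
#'   imbalances; zero rows means balanced.
#' @export
check_balance <- function(model, reaction_ids,
                          elements = c("C", "N", "H", "O")) {
  formula_counts <- function(f) {
    if (is.na(f)) return(NULL)
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    el <- sub("[0-9]*$", "", parts)
    ct <- as.numeric(sub("^[A-Za-z]+", "", parts))
    ct[is.na(ct)] <- 1
    stats::setNames(ct, el)
  }
  fmap <- lapply(stats::setNames(model$metabolites$formula,
                                 model$metabolites$id), formula_counts)
  out <- data.frame(reaction_id = character(), element = character(),
                    imbalance = numeric(), stringsAsFactors = FALSE)
  for (rid in reaction_ids) {
    r <- model$reactions[[rid]]
    if (length(r$stoichiometry) == 1L) next
    for (el in elements) {
      tot <- 0
      known <- TRUE
      for (mid in names(r$stoichiometry)) {
        fc <- fmap[[mid]]
        if (is.null(fc)) { known <- FALSE; break }
        tot <- tot + r$stoichiometry[[mid]] * (if (el %in% names(fc)) fc[[el]] else 0)
      }
      if (known && abs(tot) > 1e-9) {
        out <- rbind(out, data.frame(reaction_id = rid, element = el,
                                     imbalance = tot, stringsAsFactors = FALSE))
      }
    }
  }
  out
}
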