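#' Construct a metabolite table entry
#'
#' @param id unique short identifier (e.g. `"chor_c"`).
#' @param name free-text name.
#' @param compartment compartment code (e.g. `"c"`, `"e"`); must be non-empty.
#' @param formula optional elemental formula (e.g. `"C10H8O6"`).
#' @param charge optional integer charge.
#' @return one-row data.frame.
#' @export
metabolite <- function(id, name = id, compartment, formula = NA_character_,
                       charge = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (missing(compartment) || !nzchar(compartment)) {
    stop("metabolite '", id, "': compartment must be non-empty")
  }
  data.frame(id = id, name = name, compartment = compartment,
             formula = as.character(formula), charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' @param id unique short identifier.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed). At least one nonzero entry.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param gpr gene-protein-reaction rule text (empty = no gene association).
#' @param name free-text name.
#' @param subsystem optional subsystem label.
#' @return a `cbm_reaction` list.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     gpr = "", name = id, subsystem = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) == 0L) {
    stop("reaction '", id, "': stoichiometry needs at least one nonzero entry")
  }
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("reaction '", id, "': stoichiometry must be a named vector")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr, subsystem = subsystem),
            class = "cbm_reaction")
}

#' Assemble a constraint-based model
#'
#' A `cbm_model` is the package's stoichiometric container: a metabolite
#' table, a reaction list (bounds, stoichiometry, GPR), the gene inventory
#' (union of GPR leaves) and the id of the objective (biomass) reaction.
#'
#' @param id model identifier.
#' @param metabolites data.frame as produced by rbinding [metabolite()] rows.
#' @param reactions list of [reaction()] objects.
#' @param objective_id id of the objective reaction; must be present.
#' @param check validate invariants (unique ids, resolvable stoichiometry).
#' @return a `cbm_model`.
#' @export
cbm_model <- function(id, metabolites, reactions, objective_id, check = TRUE) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  mod <- structure(list(id = id, metabolites = metabolites,
                        reactions = reactions,
                        objective_id = objective_id),
                   class = "cbm_model")
  mod$genes <- sort(unique(unlist(lapply(reactions, function(r) {
    gpr_genes(gpr_parse_safe(r$gpr))
  }))))
  if (check) {
    rep <- validate_model(mod)
    if (nrow(rep) > 0L) {
      stop("invalid model '", id, "':\n  ",
           paste(rep$message, collapse = "\n  "))
    }
    if (!objective_id %in% names(reactions)) {
      stop("objective reaction '", objective_id, "' not in model")
    }
  }
  mod
}

# tolerant parse used where a broken rule must become a report line, not an
# abort (validate_model); returns NULL and records nothing on failure.
gpr_parse_safe <- function(rule) {
  tryCatch(gpr_parse(rule), error = function(e) NULL)
}

#' @export
print.cbm_model <- function(x, ...) {
  cat("<cbm_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  reactions:   ", length(x$reactions), "\n",
      "  genes:       ", length(x$genes), "\n",
      "  objective:   ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `cbm_model`.
#' @return character vector.
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Per-reaction bounds as a data.frame
#' @param model a `cbm_model`.
#' @return data.frame with reaction_id, lower, upper.
#' @export
reaction_bounds <- function(model) {
  data.frame(reaction_id = reaction_ids(model),
             lower = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
             upper = vapply(model$reactions, `[[`, numeric(1), "upper_bound"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sparse stoichiometric matrix S (metabolites x reactions)
#' @param model a `cbm_model`.
#' @return a `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- reaction_ids(model)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  midx <- stats::setNames(seq_along(met_ids), met_ids)
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, unname(midx[names(st)]))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Exchange reactions of a model
#'
#' An exchange moves a single metabolite across the system boundary: exactly
#' one entry in its stoichiometry. Sign convention (BiGG): negative flux =
#' uptake, positive = secretion.
#'
#' @param model a `cbm_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  is_ex <- vapply(model$reactions, function(r) length(r$stoichiometry) == 1L,
                  logical(1))
  names(model$reactions)[is_ex]
}

#' Validate a model and report findings
#'
#' Report-only: lists duplicate ids, reversed bounds, stoichiometry keys
#' that do not resolve against the metabolite table, and unparseable GPR
#' rules. A valid model yields a zero-row report.
#'
#' @param model a `cbm_model` (structural fields are enough; no LP is run).
#' @return data.frame with columns `kind`, `id`, `message`.
#' @export
validate_model <- function(model) {
  kind <- character(); id <- character(); msg <- character()
  add <- function(k, i, m) {
    kind <<- c(kind, k); id <<- c(id, i); msg <<- c(msg, m)
  }
  mids <- model$metabolites$id
  dup <- mids[duplicated(mids)]
  for (d in unique(dup)) add("duplicate_metabolite", d, paste0("duplicate metabolite id '", d, "'"))
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  dup <- rids[duplicated(rids)]
  for (d in unique(dup)) add("duplicate_reaction", d, paste0("duplicate reaction id '", d, "'"))
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound) {
      add("reversed_bounds", r$id,
          paste0("reaction '", r$id, "': lower_bound ", r$lower_bound,
                 " > upper_bound ", r$upper_bound))
    }
    bad <- setdiff(names(r$stoichiometry), mids)
    if (length(bad) > 0L) {
      add("unresolved_metabolite", r$id,
          paste0("reaction '", r$id, "': unknown metabolite id(s) ",
                 paste(bad, collapse = ", ")))
    }
    ok <- tryCatch({ gpr_parse(r$gpr); TRUE }, error = function(e) FALSE)
    if (!ok) add("bad_gpr", r$id, paste0("reaction '", r$id, "': unparseable GPR '", r$gpr, "'"))
  }
  data.frame(kind = kind, id = id, message = msg, stringsAsFactors = FALSE)
}

#' Apply a growth medium to a model
#'
#' A medium is a named numeric vector: exchange reaction id -> maximum
#' uptake rate (>= 0). Listed exchanges get `lower_bound = -uptake`; every
#' other exchange has its uptake closed (`lower_bound = 0`). Secretion
#' (upper) bounds are untouched. Idempotent.
#'
#' @param model a `cbm_model`.
#' @param medium named numeric vector of uptake rates.
#' @return a modified copy of `model`.
#' @export
apply_medium <- function(model, medium) {
  ex <- exchange_reactions(model)
  if (length(medium) > 0L) {
    if (is.null(names(medium)) || any(!nzchar(names(medium)))) {
      stop("medium must be a named numeric vector")
    }
    if (any(medium < 0)) stop("medium uptake rates must be >= 0")
    bad <- setdiff(names(medium), ex)
    if (length(bad) > 0L) {
      stop("medium keys are not exchange reactions of the model: ",
           paste(bad, collapse = ", "))
    }
  }
  for (rid in ex) {
    model$reactions[[rid]]$lower_bound <-
      if (rid %in% names(medium)) -unname(medium[[rid]]) else 0
  }
  model
}

#' Set bounds on one reaction
#' @param model a `cbm_model`.
#' @param reaction_id reaction to modify.
#' @param lower,upper new bounds (either may be `NULL` to keep).
#' @return modified copy.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  if (!reaction_id %in% names(model$reactions)) {
    stop("unknown reaction '", reaction_id, "'")
  }
  if (!is.null(lower)) model$reactions[[reaction_id]]$lower_bound <- lower
  if (!is.null(upper)) model$reactions[[reaction_id]]$upper_bound <- upper
  r <- model$reactions[[reaction_id]]
  if (r$lower_bound > r$upper_bound) {
    stop("reaction '", reaction_id, "': bounds crossed (",
         r$lower_bound, " > ", r$upper_bound, ")")
  }
  model
}

#' Identify the product exchange attached by a pathway graft
#' @param model a `cbm_model`.
#' @return reaction id or `NULL`.
#' @export
product_exchange <- function(model) attr(model, "product_exchange_id")
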