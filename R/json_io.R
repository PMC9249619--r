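#' Read a model from the community JSON dialect
#'
#' The widely used genome-scale-model JSON layout: top-level arrays
#' `metabolites`, `reactions`, `genes`; each reaction carries `metabolites`
#' (id -> coefficient), `lower_bound`/`upper_bound`, `gene_reaction_rule`
#' and `objective_coefficient`. Unknown top-level keys produce a warning;
#' missing bounds are an error.
#'
#' @param path JSON file.
#' @return a `cbm_model`.
#' @export
read_json_model <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  known <- c("id", "metabolites", "reactions", "genes", "compartments",
             "version", "notes", "annotation")
  extra <- setdiff(names(js), known)
  if (length(extra) > 0L) {
    warning("unknown model JSON keys ignored: ", paste(extra, collapse = ", "))
  }
  if (is.null(js$reactions) || length(js$reactions) == 0L) {
    stop("no reactions in model JSON '", path, "'")
  }
  mets <- do.call(rbind, lapply(js$metabolites, function(m) {
    metabolite(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "c",
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_integer_)
  }))
  obj_id <- NULL
  rxns <- lapply(js$reactions, function(r) {
    if (is.null(r$lower_bound) || is.null(r$upper_bound)) {
      stop("reaction '", r$id, "': missing bounds in model JSON")
    }
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      obj_id <<- r$id
    }
    st <- vapply(r$metabolites, as.numeric, numeric(1))
    reaction(id = r$id, stoichiometry = st,
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             gpr = r$gene_reaction_rule %||% "", name = r$name %||% r$id,
             subsystem = r$subsystem %||% NA_character_)
  })
  if (is.null(obj_id)) {
    stop("model JSON '", path, "' declares no objective (objective_coefficient)")
  }
  cbm_model(id = js$id %||% tools::file_path_sans_ext(basename(path)),
            metabolites = mets, reactions = rxns, objective_id = obj_id)
}

#' Write a model in the community JSON dialect
#'
#' Lossless for id, name, stoichiometry, bounds, GPR text and objective:
#' `read_json_model(write_json_model(m))` reproduces `m` field by field.
#'
#' @param model a `cbm_model`.
#' @param path output file.
#' @param pretty pretty-print.
#' @return `path`, invisibly.
#' @export
write_json_model <- function(model, path, pretty = TRUE) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(r$stoichiometry),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gpr,
                objective_coefficient = if (r$id == model$objective_id) 1 else 0)
    if (!is.na(r$subsystem)) out$subsystem <- r$subsystem
    out
  })
  genes <- lapply(model$genes, function(g) list(id = g, name = g))
  js <- list(id = model$id, metabolites = mets,
             reactions = unname(rxns), genes = genes)
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = pretty,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
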