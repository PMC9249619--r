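#' Read an experimental flux-constraint table
#'
#' Tab-separated with header `reaction_id`, `lower`, `upper`: measured flux
#' intervals standing in for fluxomics data on a reference strain. Duplicate
#' reaction ids are merged by interval intersection (two measurements of the
#' same reaction constrain it jointly); an empty intersection is an error.
#'
#' @param path TSV file.
#' @return data.frame (`reaction_id`, `lower`, `upper`) of class
#'   `flux_data`.
#' @export
read_flux_data <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("flux data file '", path, "' is empty")
  need <- c("reaction_id", "lower", "upper")
  if (!all(need %in% names(df))) {
    stop("flux data needs columns: ", paste(need, collapse = ", "))
  }
  bad <- which(df$lower > df$upper)
  if (length(bad) > 0L) {
    stop("flux data row ", bad[1], " (", df$reaction_id[bad[1]],
         "): lower > upper")
  }
  out <- do.call(rbind, lapply(split(df, df$reaction_id), function(g) {
    lo <- max(g$lower); hi <- min(g$upper)
    if (lo > hi) {
      stop("flux data for '", g$reaction_id[1],
           "': empty intersection of measured intervals")
    }
    data.frame(reaction_id = g$reaction_id[1], lower = lo, upper = hi,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$reaction_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("flux_data", "data.frame")
  out
}

#' Resolve a flux dataset against a model
#'
#' Unresolvable reaction ids are reported (attribute `unresolved` and a
#' warning), never silently dropped.
#'
#' @param flux_data a `flux_data` table.
#' @param model a `cbm_model`.
#' @return the resolvable subset, with attribute `unresolved`.
#' @export
resolve_flux_data <- function(flux_data, model) {
  if (is.null(flux_data)) return(NULL)
  known <- flux_data$reaction_id %in% reaction_ids(model)
  if (any(!known)) {
    warning("flux data ids not in model: ",
            paste(flux_data$reaction_id[!known], collapse = ", "))
  }
  out <- flux_data[known, , drop = FALSE]
  attr(out, "unresolved") <- flux_data$reaction_id[!known]
  out
}

#' Read a medium preset from YAML
#'
#' Layout: a mapping `uptake: {EX_xxx_e: rate, ...}` (rates >= 0, in
#' mmol/gDW/h). The shipped preset `"m9_aerobic_glucose"` encodes aerobic
#' minimal M9 with glucose as carbon source in BiGG exchange ids.
#'
#' @param path YAML file, or a preset name shipped with the package.
#' @return named numeric vector usable with [apply_medium()].
#' @export
read_medium <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", paste0(path, ".yaml"),
                           package = "fluxforce")
    if (nzchar(shipped)) path <- shipped else stop("no such medium file or preset: ", path)
  }
  y <- yaml::read_yaml(path)
  upt <- y$uptake
  if (is.null(upt)) stop("medium YAML needs an 'uptake' mapping")
  med <- vapply(upt, as.numeric, numeric(1))
  if (any(med < 0)) stop("medium uptake rates must be >= 0")
  med
}
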