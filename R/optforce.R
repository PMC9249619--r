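# MUST/FORCE strain design core.
#
# The procedure: (1) characterize the attainable flux range of every
# reaction in the reference (wild-type) strain under experimental flux
# data; (2) characterize the overproducer's ranges under a growth floor
# and a required product level; (3) superimpose the two range maps to
# classify reactions whose flux MUST increase (MUST-U), decrease (MUST-L)
# or vanish (MUST-X) in any overproducing state; (4) turn MUST entries
# into candidate bound interventions, minus exclusions; (5) search subsets
# of candidates for minimal FORCE sets, scoring each by the worst-case
# (adversarial) minimum product formation.

#' Design thresholds for overproducer characterization
#'
#' @param growth_fraction required biomass production as a fraction of the
#'   maximum (default 0.2: at least 20\% of maximal growth).
#' @param product_fraction required product level as a fraction of the
#'   theoretical maximum (default 0.8: 80\% of theoretical maximum).
#' @param epsilon classification margin for MUST sets, in flux units
#'   (default 1e-3; distinct from the LP tolerance).
#' @return a `design_thresholds` list.
#' @export
design_thresholds <- function(growth_fraction = 0.2, product_fraction = 0.8,
                              epsilon = 1e-3) {
  stopifnot(growth_fraction > 0, growth_fraction <= 1,
            product_fraction > 0, product_fraction <= 1, epsilon > 0)
  structure(list(growth_fraction = growth_fraction,
                 product_fraction = product_fraction, epsilon = epsilon),
            class = "design_thresholds")
}

#' Wild-type flux ranges under experimental flux data
#'
#' FVA over the reference strain with measured flux intervals imposed and,
#' optionally, a floor on growth (a stand-in for the near-optimal growth
#' of an evolved reference when few fluxes were measured).
#'
#' @param model_wt reference-strain model (heterologous pathway absent or
#'   closed).
#' @param flux_data a [read_flux_data()] table, or `NULL` for plain FVA.
#' @param growth_fraction optional growth floor as a fraction of the
#'   maximum growth attainable under the flux data; `NULL` for none.
#' @param reaction_ids reactions to range (default: all).
#' @param solver backend name or `NULL`.
#' @return data.frame (`reaction_id`, `min`, `max`).
#' @export
wildtype_ranges <- function(model_wt, flux_data = NULL, growth_fraction = NULL,
                            reaction_ids = NULL, solver = NULL) {
  ec <- NULL
  if (!is.null(flux_data)) {
    fd <- resolve_flux_data(flux_data, model_wt)
    if (length(attr(fd, "unresolved")) > 0L) {
      stop("flux data reference reactions absent from the model: ",
           paste(attr(fd, "unresolved"), collapse = ", "))
    }
    ec <- data.frame(reaction_id = fd$reaction_id, lower = fd$lower,
                     upper = fd$upper, stringsAsFactors = FALSE)
  }
  if (!is.null(growth_fraction)) {
    gmax <- fba(model_wt, direction = "max", extra_constraints = ec,
                solver = solver, want_fluxes = FALSE)
    if (gmax$status != "optimal") {
      stop("wild-type model infeasible under the flux data; ",
           fva_diagnose(lp_problem(model_wt), ec, solver))
    }
    ec <- rbind(ec, data.frame(reaction_id = model_wt$objective_id,
                               lower = growth_fraction * gmax$objective_value,
                               upper = Inf, stringsAsFactors = FALSE))
  }
  fva(model_wt, reaction_ids = reaction_ids, extra_constraints = ec,
      solver = solver)
}

#' Overproducer flux ranges under design thresholds
#'
#' FVA over the grafted model with growth at or above
#' `growth_fraction * max growth` and product at or above
#' `product_fraction * theoretical max product`. If the two thresholds are
#' jointly infeasible the error reports the maximal feasible product
#' fraction at the given growth fraction.
#'
#' @param model_ov grafted overproducer model.
#' @param thresholds a [design_thresholds()].
#' @param product_exchange_id product exchange; defaults to the graft
#'   annotation.
#' @param reaction_ids reactions to range (default: all).
#' @param solver backend name or `NULL`.
#' @return data.frame (`reaction_id`, `min`, `max`); attributes
#'   `mu_max` and `theoretical_max_product` carry the reference optima.
#' @export
overproducer_ranges <- function(model_ov, thresholds = design_thresholds(),
                                product_exchange_id = product_exchange(model_ov),
                                reaction_ids = NULL, solver = NULL) {
  if (is.null(product_exchange_id)) stop("no product exchange given or annotated")
  pr <- lp_problem(model_ov)
  jp <- match(product_exchange_id, pr$rxn_ids)
  jb <- match(model_ov$objective_id, pr$rxn_ids)
  ref <- lp_solve_batch(pr, list(list(c_idx = jp, c_val = 1, sense = "max"),
                                 list(c_idx = jb, c_val = 1, sense = "max")),
                        solver)
  if (ref[[1]]$status != "optimal" || ref[[2]]$status != "optimal") {
    stop("overproducer model infeasible before thresholds")
  }
  theo <- ref[[1]]$objective; mu_max <- ref[[2]]$objective
  ec <- data.frame(
    reaction_id = c(model_ov$objective_id, product_exchange_id),
    lower = c(thresholds$growth_fraction * mu_max,
              thresholds$product_fraction * theo),
    upper = c(Inf, Inf), stringsAsFactors = FALSE)
  feas <- lp_solve_batch(pr, list(c(list(c_idx = jp, c_val = 1, sense = "max"),
                                    constraints_to_overrides(pr, ec[1, ]))),
                         solver)[[1]]
  if (feas$status != "optimal" ||
      feas$objective < thresholds$product_fraction * theo - 1e-9) {
    max_frac <- if (feas$status == "optimal") feas$objective / theo else 0
    stop("thresholds jointly infeasible: at growth_fraction ",
         thresholds$growth_fraction, " the maximal feasible product_fraction is ",
         format(max_frac, digits = 6))
  }
  out <- fva(model_ov, reaction_ids = reaction_ids, extra_constraints = ec,
             solver = solver)
  attr(out, "mu_max") <- mu_max
  attr(out, "theoretical_max_product") <- theo
  out
}

#' Classify MUST sets by superimposing flux range maps
#'
#' For each reaction present in both maps (with wild-type range
#' `[wmin, wmax]` and overproducer range `[omin, omax]`):
#' \itemize{
#'   \item MUST-U when `omin > wmax + eps`: flux must increase; required
#'     level `omin`.
#'   \item MUST-L when `omax < wmin - eps`: flux must decrease; required
#'     level `omax`.
#'   \item MUST-X when the overproducer range lies inside `[-eps, eps]`
#'     but the wild-type range does not: flux must vanish.
#' }
#' Reactions present in only one map are excluded and reported via the
#' `skipped` attribute.
#'
#' @param wt_ranges,ov_ranges data.frames from [wildtype_ranges()] /
#'   [overproducer_ranges()].
#' @param epsilon classification margin (flux units).
#' @return a `must_sets` list: `must_u`, `must_l` (data.frames with
#'   `reaction_id`, `level`), `must_x` (character vector), and `provenance`
#'   (the merged range map).
#' @export
classify_must_sets <- function(wt_ranges, ov_ranges, epsilon = 1e-3) {
  common <- intersect(wt_ranges$reaction_id, ov_ranges$reaction_id)
  skipped <- union(setdiff(wt_ranges$reaction_id, common),
                   setdiff(ov_ranges$reaction_id, common))
  if (length(skipped) > 0L) {
    message("classify_must_sets: ", length(skipped),
            " reaction(s) present in only one range map were skipped")
  }
  wt <- wt_ranges[match(common, wt_ranges$reaction_id), ]
  ov <- ov_ranges[match(common, ov_ranges$reaction_id), ]
  u <- ov$min > wt$max + epsilon
  l <- ov$max < wt$min - epsilon
  x <- (ov$min >= -epsilon & ov$max <= epsilon) &
       !(wt$min >= -epsilon & wt$max <= epsilon)
  # precedence: a MUST-X entry is a stronger statement than MUST-L
  l <- l & !x
  u <- u & !x
  prov <- data.frame(reaction_id = common,
                     wt_min = wt$min, wt_max = wt$max,
                     ov_min = ov$min, ov_max = ov$max,
                     stringsAsFactors = FALSE)
  out <- list(
    must_u = data.frame(reaction_id = common[u], level = ov$min[u],
                        stringsAsFactors = FALSE),
    must_l = data.frame(reaction_id = common[l], level = ov$max[l],
                        stringsAsFactors = FALSE),
    must_x = common[x],
    provenance = prov)
  attr(out, "skipped") <- skipped
  structure(out, class = "must_sets")
}

#' @export
print.must_sets <- function(x, ...) {
  cat("<must_sets> U:", nrow(x$must_u), " L:", nrow(x$must_l),
      " X:", length(x$must_x), "\n")
  invisible(x)
}

#' Export MUST sets (with their provenance ranges) as TSV
#' @param must a `must_sets`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_must_tsv <- function(must, path) {
  prov <- must$provenance
  cls <- rep("", nrow(prov))
  cls[prov$reaction_id %in% must$must_u$reaction_id] <- "MUST_U"
  cls[prov$reaction_id %in% must$must_l$reaction_id] <- "MUST_L"
  cls[prov$reaction_id %in% must$must_x] <- "MUST_X"
  lvl <- rep(NA_real_, nrow(prov))
  lvl[match(must$must_u$reaction_id, prov$reaction_id)] <- must$must_u$level
  lvl[match(must$must_l$reaction_id, prov$reaction_id)] <- must$must_l$level
  out <- cbind(prov, classification = cls, level = lvl)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build candidate interventions from MUST sets
#'
#' One intervention per MUST entry: MUST-U becomes an up-regulation to its
#' required level, MUST-L a down-regulation, MUST-X a knockout. Exclusion
#' rules then remove:
#' \enumerate{
#'   \item reactions with no gene association (not addressable genetically);
#'   \item knockouts of reactions whose GPR involves an essential gene;
#'   \item reactions listed in `exclude_reactions` (e.g. the grafted
#'     pathway itself, to force interventions into native metabolism).
#' }
#'
#' @param must a `must_sets`.
#' @param model the model the candidates apply to.
#' @param essential optional data.frame from [single_gene_deletions()];
#'   when given, rule 2 is enforced.
#' @param exclude_reactions reaction ids excluded from any manipulation.
#' @return an `intervention_set`.
#' @export
candidate_interventions <- function(must, model, essential = NULL,
                                    exclude_reactions = character()) {
  cand <- rbind(
    if (nrow(must$must_u) > 0L)
      data.frame(reaction_id = must$must_u$reaction_id, kind = "up",
                 level = must$must_u$level, stringsAsFactors = FALSE),
    if (nrow(must$must_l) > 0L)
      data.frame(reaction_id = must$must_l$reaction_id, kind = "down",
                 level = must$must_l$level, stringsAsFactors = FALSE),
    if (length(must$must_x) > 0L)
      data.frame(reaction_id = must$must_x, kind = "ko", level = NA_real_,
                 stringsAsFactors = FALSE))
  if (is.null(cand) || nrow(cand) == 0L) {
    return(interventions(character(0), character(0)))
  }
  keep <- rep(TRUE, nrow(cand))
  ess_genes <- if (!is.null(essential)) essential$gene[essential$essential] else character()
  for (i in seq_len(nrow(cand))) {
    r <- model$reactions[[cand$reaction_id[i]]]
    if (is.null(r)) { keep[i] <- FALSE; next }
    genes <- gpr_genes(gpr_parse_safe(r$gpr))
    if (length(genes) == 0L) { keep[i] <- FALSE; next }           # rule 1
    if (cand$kind[i] == "ko" && any(genes %in% ess_genes)) {      # rule 2
      keep[i] <- FALSE; next
    }
    if (cand$reaction_id[i] %in% exclude_reactions) keep[i] <- FALSE  # rule 3
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$reaction_id), , drop = FALSE]
  rownames(cand) <- NULL
  class(cand) <- c("intervention_set", "data.frame")
  cand
}

#' Search for minimal FORCE intervention sets
#'
#' Enumerates subsets of the candidate interventions by increasing size
#' (up to `k_max`), scoring each by the worst-case minimum product: the LP
#' minimum of product flux under the applied interventions and the growth
#' floor. A subset "achieves the target" when its worst-case minimum
#' reaches `product_fraction * theoretical max`; supersets of achieving
#' subsets are pruned (worst-case minima are monotone under inclusion).
#' Returned are the minimal positive subsets -- those with a positive
#' worst-case minimum, no proper subset of which is positive -- ranked by
#' size ascending, worst-case minimum descending, then lexicographic
#' member string.
#'
#' @param model_ov grafted overproducer model.
#' @param candidates an `intervention_set` from [candidate_interventions()].
#' @param k_max largest subset size to consider.
#' @param thresholds a [design_thresholds()].
#' @param growth_floor impose the growth floor in the worst-case LPs.
#' @param product_exchange_id product exchange; defaults to annotation.
#' @param solver backend name or `NULL`.
#' @return data.frame of class `force_results` (`members`, `size`,
#'   `worst_case_min_product`, `percent_of_max`, `max_product`, `feasible`,
#'   `achieves_target`, `minimal`), one row per evaluated subset; the
#'   selected minimal sets first. Attribute `n_evaluated` counts inner LPs.
#' @export
find_force_sets <- function(model_ov, candidates, k_max = 4L,
                            thresholds = design_thresholds(),
                            growth_floor = TRUE,
                            product_exchange_id = product_exchange(model_ov),
                            solver = NULL) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    out <- data.frame(members = character(), size = integer(),
                      worst_case_min_product = numeric(),
                      percent_of_max = numeric(), max_product = numeric(),
                      feasible = logical(), achieves_target = logical(),
                      minimal = logical(), stringsAsFactors = FALSE)
    class(out) <- c("force_results", "data.frame")
    return(out)
  }
  n <- nrow(candidates)
  if (k_max > n) {
    warning("k_max = ", k_max, " exceeds the ", n,
            " candidates; evaluating up to size ", n)
    k_max <- n
  }
  ctx <- scan_context(model_ov, thresholds, growth_floor,
                      product_exchange_id, solver)
  target <- thresholds$product_fraction * ctx$theo

  achieved <- list()   # index sets that reached the target (for pruning)
  positive <- list()   # index sets with positive worst-case minimum
  rows <- list()
  for (k in seq_len(k_max)) {
    combs <- utils::combn(n, k, simplify = FALSE)
    pruned <- vapply(combs, function(idx) {
      any(vapply(achieved, function(a) all(a %in% idx), logical(1)))
    }, logical(1))
    combs <- combs[!pruned]
    if (length(combs) == 0L) next
    jobs <- lapply(combs, function(idx) {
      sub <- candidates[idx, , drop = FALSE]
      c(list(c_idx = ctx$jp, c_val = 1, sense = "min"),
        intervention_overrides(ctx, sub))
    })
    jobs_max <- lapply(combs, function(idx) {
      sub <- candidates[idx, , drop = FALSE]
      c(list(c_idx = ctx$jp, c_val = 1, sense = "max"),
        intervention_overrides(ctx, sub))
    })
    res <- lp_solve_batch(ctx$pr, c(jobs, jobs_max), solver)
    res_min <- res[seq_along(combs)]
    res_max <- res[length(combs) + seq_along(combs)]
    for (s in seq_along(combs)) {
      idx <- combs[[s]]
      sub <- candidates[idx, , drop = FALSE]
      ok <- res_min[[s]]$status == "optimal"
      wc <- if (ok) max(0, res_min[[s]]$objective) else NA_real_
      is_pos <- ok && wc > 1e-6
      covers_positive <- any(vapply(positive, function(p) all(p %in% idx),
                                    logical(1)))
      if (is_pos) positive <- c(positive, list(idx))
      if (ok && wc >= target - 1e-6) achieved <- c(achieved, list(idx))
      rows <- c(rows, list(data.frame(
        members = members_string(sub),
        size = k,
        worst_case_min_product = wc,
        percent_of_max = if (ok) 100 * wc / ctx$theo else NA_real_,
        max_product = if (res_max[[s]]$status == "optimal")
          res_max[[s]]$objective else NA_real_,
        feasible = ok,
        achieves_target = ok && wc >= target - 1e-6,
        minimal = is_pos && !covers_positive,
        stringsAsFactors = FALSE)))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(!out$minimal, out$size, -out$worst_case_min_product,
                   out$members, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_evaluated") <- nrow(out)
  attr(out, "theoretical_max_product") <- ctx$theo
  class(out) <- c("force_results", "data.frame")
  out
}

#' Export FORCE search results as TSV
#' @param force a `force_results`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_force_tsv <- function(force, path) {
  utils::write.table(force, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
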