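#' Construct an intervention table
#'
#' A flux intervention is one bound manipulation on one reaction:
#' \describe{
#'   \item{up}{force flux at or above `level` (lower bound raised).}
#'   \item{down}{cap flux at or below `level` (upper bound lowered).}
#'   \item{ko}{knockout: both bounds to zero (`level` ignored).}
#' }
#'
#' @param reaction_id character vector.
#' @param kind `"up"`, `"down"` or `"ko"` (recycled).
#' @param level numeric bound level (NA for ko).
#' @return data.frame of class `intervention_set`.
#' @export
interventions <- function(reaction_id, kind, level = NA_real_) {
  if (length(reaction_id) == 0L) {
    df <- data.frame(reaction_id = character(), kind = character(),
                     level = numeric(), stringsAsFactors = FALSE)
    class(df) <- c("intervention_set", "data.frame")
    return(df)
  }
  kind <- match.arg(kind, c("up", "down", "ko"), several.ok = TRUE)
  df <- data.frame(reaction_id = reaction_id, kind = kind, level = level,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$reaction_id)) {
    stop("two interventions target the same reaction: ",
         paste(df$reaction_id[duplicated(df$reaction_id)], collapse = ", "))
  }
  bad <- df$kind != "ko" & !is.finite(df$level)
  if (any(bad)) {
    stop("up/down interventions need a finite level: ",
         paste(df$reaction_id[bad], collapse = ", "))
  }
  class(df) <- c("intervention_set", "data.frame")
  df
}

#' Apply interventions to a model
#'
#' Bounds are edited per [interventions()] semantics; the pre-intervention
#' bounds of the touched reactions are retained in an undo record
#' (attribute `undo`), restorable with [undo_interventions()]. A resulting
#' crossed bound (e.g. an up-level above the reaction's upper bound) is an
#' error naming the intervention.
#'
#' @param model a `cbm_model`.
#' @param ints an `intervention_set` (possibly empty).
#' @return modified copy with an `undo` attribute.
#' @export
apply_interventions <- function(model, ints) {
  undo <- list()
  if (!is.null(ints) && nrow(ints) > 0L) {
    if (anyDuplicated(ints$reaction_id)) {
      stop("two interventions target the same reaction")
    }
    for (i in seq_len(nrow(ints))) {
      rid <- ints$reaction_id[i]
      r <- model$reactions[[rid]]
      if (is.null(r)) stop("intervention targets unknown reaction '", rid, "'")
      undo[[rid]] <- c(r$lower_bound, r$upper_bound)
      new_lb <- r$lower_bound; new_ub <- r$upper_bound
      switch(ints$kind[i],
             up = { new_lb <- ints$level[i] },
             down = { new_ub <- ints$level[i] },
             ko = { new_lb <- 0; new_ub <- 0 })
      if (new_lb > new_ub) {
        stop("intervention ", ints$kind[i], " ", rid, " @ ", ints$level[i],
             " contradicts bounds [", r$lower_bound, ", ", r$upper_bound, "]")
      }
      model$reactions[[rid]]$lower_bound <- new_lb
      model$reactions[[rid]]$upper_bound <- new_ub
    }
  }
  attr(model, ".lp_problem") <- NULL   # cached LP is stale
  attr(model, "undo") <- undo
  model
}

#' Undo a previous [apply_interventions()]
#' @param model model carrying an `undo` attribute.
#' @return copy with original bounds restored.
#' @export
undo_interventions <- function(model) {
  undo <- attr(model, "undo")
  if (is.null(undo)) stop("model carries no undo record")
  for (rid in names(undo)) {
    model$reactions[[rid]]$lower_bound <- undo[[rid]][1]
    model$reactions[[rid]]$upper_bound <- undo[[rid]][2]
  }
  attr(model, "undo") <- NULL
  attr(model, ".lp_problem") <- NULL
  model
}

# growth floor used by the worst-case LPs: a fixed reference (fraction of
# the *pre-intervention* maximum growth), so values are comparable across
# intervention sets.
growth_floor_constraint <- function(model, thresholds, mu_max) {
  data.frame(reaction_id = model$objective_id,
             lower = thresholds$growth_fraction * mu_max, upper = Inf,
             stringsAsFactors = FALSE)
}

#' Worst-case minimum product under interventions
#'
#' The "network fights back" value: the LP minimum of the product exchange
#' flux with the interventions applied and (optionally) a growth floor at
#' `growth_fraction` of the un-intervened maximum growth. Also reported as
#' percent of the un-intervened theoretical maximum product.
#'
#' @param model a grafted `cbm_model`.
#' @param ints an `intervention_set`.
#' @param thresholds a [design_thresholds()].
#' @param growth_floor impose the growth floor (default TRUE).
#' @param product_exchange_id product exchange; defaults to the graft
#'   annotation.
#' @param solver backend name or `NULL`.
#' @return list (`flux`, `percent_of_max`, `feasible`).
#' @export
min_product <- function(model, ints, thresholds = design_thresholds(),
                        growth_floor = TRUE,
                        product_exchange_id = product_exchange(model),
                        solver = NULL) {
  product_extremum(model, ints, thresholds, growth_floor,
                   product_exchange_id, solver, sense = "min")
}

#' Maximum product under interventions
#'
#' Upper companion of [min_product()]: the LP maximum of product flux under
#' the interventions and growth floor.
#' @inheritParams min_product
#' @return list (`flux`, `percent_of_max`, `feasible`).
#' @export
max_product <- function(model, ints, thresholds = design_thresholds(),
                        growth_floor = TRUE,
                        product_exchange_id = product_exchange(model),
                        solver = NULL) {
  product_extremum(model, ints, thresholds, growth_floor,
                   product_exchange_id, solver, sense = "max")
}

product_extremum <- function(model, ints, thresholds, growth_floor,
                             product_exchange_id, solver, sense) {
  if (is.null(product_exchange_id)) stop("no product exchange given or annotated")
  pr <- lp_problem(model)
  jp <- match(product_exchange_id, pr$rxn_ids)
  jb <- match(model$objective_id, pr$rxn_ids)
  theo <- lp_solve_batch(pr, list(list(c_idx = jp, c_val = 1, sense = "max")),
                         solver)[[1]]
  mu <- lp_solve_batch(pr, list(list(c_idx = jb, c_val = 1, sense = "max")),
                       solver)[[1]]
  if (theo$status != "optimal" || mu$status != "optimal") {
    stop("reference model not optimal (product: ", theo$status,
         ", growth: ", mu$status, ")")
  }
  mint <- apply_interventions(model, ints)
  ec <- if (growth_floor) {
    growth_floor_constraint(model, thresholds, mu$objective)
  } else NULL
  res <- fba(mint, product_exchange_id, direction = sense,
             extra_constraints = ec, solver = solver, want_fluxes = FALSE)
  if (res$status != "optimal") {
    return(list(flux = NA_real_, percent_of_max = NA_real_, feasible = FALSE,
                status = res$status))
  }
  v <- res$objective_value
  list(flux = v, percent_of_max = 100 * v / theo$objective, feasible = TRUE,
       status = "optimal")
}

#' Map a reaction intervention to minimal gene interventions
#'
#' Uses the reaction's GPR:
#' \itemize{
#'   \item ko / down: the minimal gene sets whose removal falsifies the
#'     rule (an OR of isozymes needs every branch hit; an AND complex needs
#'     any one subunit).
#'   \item up: the gene sets of each minimal satisfying assignment (any one
#'     sufficient AND clause).
#' }
#' Alternatives are ordered by set size, then lexicographically.
#'
#' @param model a `cbm_model`.
#' @param intervention one-row `intervention_set`.
#' @return list of `gene_intervention`s: each a list with `genes`, `kind`,
#'   `reaction_id`, `level`.
#' @export
reaction_to_gene_interventions <- function(model, intervention) {
  rid <- intervention$reaction_id[1]
  r <- model$reactions[[rid]]
  if (is.null(r)) stop("unknown reaction '", rid, "'")
  tree <- gpr_parse(r$gpr)
  if (is.null(tree)) stop("no gene association for reaction '", rid, "'")
  kind <- intervention$kind[1]
  sets <- if (kind == "up") {
    gpr_minimal_satisfying_sets(tree)
  } else {
    gpr_minimal_falsifying_sets(tree)
  }
  lapply(sets, function(gs) {
    structure(list(genes = gs, kind = kind, reaction_id = rid,
                   level = intervention$level[1]),
              class = "gene_intervention")
  })
}

#' @export
print.gene_intervention <- function(x, ...) {
  cat("<gene_intervention> ", x$kind, " {", paste(x$genes, collapse = ", "),
      "} <- ", x$reaction_id, "\n", sep = "")
  invisible(x)
}

#' Combinatorial epistasis scan over reaction interventions
#'
#' Evaluates every subset of the given interventions up to `max_size`
#' (including the empty set): worst-case minimum and maximum product per
#' subset, plus a flag for the minimal subsets achieving a positive
#' minimum. Enumeration order is by size then lexicographic member string,
#' so output is deterministic.
#'
#' @param model a grafted `cbm_model`.
#' @param ints an `intervention_set` (the full set to scan).
#' @param max_size largest subset size (defaults to all).
#' @param thresholds a [design_thresholds()].
#' @param growth_floor impose the growth floor in the inner LPs.
#' @param product_exchange_id product exchange; defaults to annotation.
#' @param solver backend name or `NULL`.
#' @param subset_guard abort if more than this many subsets would enumerate.
#' @return data.frame (`members`, `size`, `min_product`,
#'   `percent_of_max`, `max_product`, `feasible`, `minimal_positive`).
#' @export
combination_scan <- function(model, ints, max_size = nrow(ints),
                             thresholds = design_thresholds(),
                             growth_floor = TRUE,
                             product_exchange_id = product_exchange(model),
                             solver = NULL, subset_guard = 2^20) {
  n <- if (is.null(ints)) 0L else nrow(ints)
  n_subsets <- sum(choose(n, 0:min(max_size, n)))
  if (n_subsets > subset_guard) {
    stop(n_subsets, " subsets exceed the guard (", subset_guard,
         "); prune the candidate list first")
  }
  subsets <- list(integer(0))
  for (k in seq_len(min(max_size, n))) {
    subsets <- c(subsets, utils::combn(n, k, simplify = FALSE))
  }
  ctx <- scan_context(model, thresholds, growth_floor, product_exchange_id,
                      solver)
  rows <- vector("list", length(subsets))
  jobs <- list()
  for (s in seq_along(subsets)) {
    sub <- ints[subsets[[s]], , drop = FALSE]
    ov <- intervention_overrides(ctx, sub)
    jobs <- c(jobs, list(c(list(c_idx = ctx$jp, c_val = 1, sense = "min"), ov),
                         c(list(c_idx = ctx$jp, c_val = 1, sense = "max"), ov)))
  }
  res <- lp_solve_batch(ctx$pr, jobs, solver)
  for (s in seq_along(subsets)) {
    sub <- ints[subsets[[s]], , drop = FALSE]
    mn <- res[[2 * s - 1]]; mx <- res[[2 * s]]
    ok <- mn$status == "optimal"
    rows[[s]] <- data.frame(
      members = members_string(sub),
      size = nrow(sub),
      min_product = if (ok) mn$objective else NA_real_,
      percent_of_max = if (ok) 100 * mn$objective / ctx$theo else NA_real_,
      max_product = if (mx$status == "optimal") mx$objective else NA_real_,
      feasible = ok, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$size, out$members), , drop = FALSE]
  rownames(out) <- NULL
  pos <- !is.na(out$min_product) & out$min_product > 1e-6 & out$feasible
  member_sets <- strsplit(out$members, ",", fixed = TRUE)
  out$minimal_positive <- vapply(seq_len(nrow(out)), function(i) {
    if (!pos[i]) return(FALSE)
    !any(vapply(which(pos), function(j) {
      j != i && length(member_sets[[j]]) < length(member_sets[[i]]) &&
        all(member_sets[[j]] %in% member_sets[[i]])
    }, logical(1)))
  }, logical(1))
  out
}

#' Epistasis scan over gene-level interventions
#'
#' The gene-level counterpart of [combination_scan()]: enumeration is over
#' individual genes (the union of the supplied gene interventions); a
#' source reaction's bound manipulation is active in a subset exactly when
#' the subset covers that gene intervention's full gene set. This mirrors
#' inferring gene interventions from GPR rules: downregulating a reaction
#' carried by two isozymes requires both genes.
#'
#' @param model a grafted `cbm_model`.
#' @param gene_ints list of `gene_intervention`s (one per source reaction;
#'   e.g. the first alternative from [reaction_to_gene_interventions()]).
#' @param max_size largest gene-subset size (defaults to all genes).
#' @inheritParams combination_scan
#' @return data.frame (`genes`, `n_genes`, `active_reactions`,
#'   `min_product`, `percent_of_max`, `feasible`).
#' @export
gene_combination_scan <- function(model, gene_ints, max_size = NULL,
                                  thresholds = design_thresholds(),
                                  growth_floor = TRUE,
                                  product_exchange_id = product_exchange(model),
                                  solver = NULL) {
  all_genes <- sort(unique(unlist(lapply(gene_ints, `[[`, "genes"))))
  if (is.null(max_size)) max_size <- length(all_genes)
  subsets <- list(integer(0))
  for (k in seq_len(min(max_size, length(all_genes)))) {
    subsets <- c(subsets, utils::combn(length(all_genes), k, simplify = FALSE))
  }
  ctx <- scan_context(model, thresholds, growth_floor, product_exchange_id,
                      solver)
  active_of <- lapply(subsets, function(idx) {
    gs <- all_genes[idx]
    Filter(function(gi) all(gi$genes %in% gs), gene_ints)
  })
  jobs <- lapply(active_of, function(active) {
    ints <- gene_ints_to_interventions(active)
    c(list(c_idx = ctx$jp, c_val = 1, sense = "min"),
      intervention_overrides(ctx, ints))
  })
  res <- lp_solve_batch(ctx$pr, jobs, solver)
  rows <- lapply(seq_along(subsets), function(s) {
    gs <- all_genes[subsets[[s]]]
    mn <- res[[s]]
    ok <- mn$status == "optimal"
    data.frame(genes = paste(gs, collapse = ","), n_genes = length(gs),
               active_reactions = paste(vapply(active_of[[s]], `[[`,
                                               character(1), "reaction_id"),
                                        collapse = ","),
               min_product = if (ok) mn$objective else NA_real_,
               percent_of_max = if (ok) 100 * mn$objective / ctx$theo else NA_real_,
               feasible = ok, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$n_genes, out$genes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- shared internals for the subset scans ------------------------------

# canonical "kind:reaction,kind:reaction" label; "" for the empty set
members_string <- function(ints) {
  if (is.null(ints) || nrow(ints) == 0L) return("")
  paste(sort(paste0(ints$kind, ":", ints$reaction_id)), collapse = ",")
}

gene_ints_to_interventions <- function(gene_ints) {
  if (length(gene_ints) == 0L) return(interventions(character(0), character(0)))
  interventions(vapply(gene_ints, `[[`, character(1), "reaction_id"),
                vapply(gene_ints, `[[`, character(1), "kind"),
                vapply(gene_ints, `[[`, numeric(1), "level"))
}

# reference quantities + LP problem reused across every subset of a scan
scan_context <- function(model, thresholds, growth_floor,
                         product_exchange_id, solver) {
  if (is.null(product_exchange_id)) stop("no product exchange given or annotated")
  pr <- lp_problem(model)
  jp <- match(product_exchange_id, pr$rxn_ids)
  jb <- match(model$objective_id, pr$rxn_ids)
  if (is.na(jp)) stop("unknown product exchange '", product_exchange_id, "'")
  ref <- lp_solve_batch(pr, list(list(c_idx = jp, c_val = 1, sense = "max"),
                                 list(c_idx = jb, c_val = 1, sense = "max")),
                        solver)
  if (ref[[1]]$status != "optimal" || ref[[2]]$status != "optimal") {
    stop("reference model not optimal")
  }
  floor_lb <- if (growth_floor) thresholds$growth_fraction * ref[[2]]$objective else NULL
  list(pr = pr, jp = jp, jb = jb, theo = ref[[1]]$objective,
       mu_max = ref[[2]]$objective, floor_lb = floor_lb)
}

# bound overrides implementing an intervention set (plus the growth floor)
# on top of a scan context; mirrors apply_interventions() semantics, with
# bound contradictions surfacing as LP infeasibility rather than errors.
intervention_overrides <- function(ctx, ints) {
  lb_idx <- integer(); lb_val <- numeric()
  ub_idx <- integer(); ub_val <- numeric()
  if (!is.null(ints) && nrow(ints) > 0L) {
    idx <- match(ints$reaction_id, ctx$pr$rxn_ids)
    if (anyNA(idx)) {
      stop("intervention targets unknown reaction: ",
           paste(ints$reaction_id[is.na(idx)], collapse = ", "))
    }
    for (i in seq_along(idx)) {
      switch(ints$kind[i],
             up = { lb_idx <- c(lb_idx, idx[i]); lb_val <- c(lb_val, ints$level[i]) },
             down = { ub_idx <- c(ub_idx, idx[i]); ub_val <- c(ub_val, ints$level[i]) },
             ko = {
               lb_idx <- c(lb_idx, idx[i]); lb_val <- c(lb_val, 0)
               ub_idx <- c(ub_idx, idx[i]); ub_val <- c(ub_val, 0)
             })
    }
  }
  if (!is.null(ctx$floor_lb)) {
    lb_idx <- c(lb_idx, ctx$jb); lb_val <- c(lb_val, ctx$floor_lb)
  }
  list(lb_idx = lb_idx, lb_val = lb_val, ub_idx = ub_idx, ub_val = ub_val)
}
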