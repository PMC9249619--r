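#' Flux balance analysis
#'
#' Optimizes a single reaction flux subject to steady-state mass balance
#' (`S v = 0`) and flux bounds. Extra constraints are interval restrictions
#' on named reactions, intersected with the model bounds.
#'
#' @param model a `cbm_model`.
#' @param objective_id reaction to optimize (default: the model objective).
#' @param direction `"max"` or `"min"`.
#' @param extra_constraints optional data.frame (`reaction_id`, `lower`,
#'   `upper`).
#' @param solver backend name (see [lp_backends()]) or `NULL` for auto.
#' @param want_fluxes return the full flux vector.
#' @return a `cbm_solution`: list with `status` (`optimal` / `infeasible` /
#'   `unbounded`), `objective_value`, and `fluxes` (named; entries with
#'   magnitude below 1e-6 are reported as zero).
#' @export
fba <- function(model, objective_id = model$objective_id,
                direction = c("max", "min"), extra_constraints = NULL,
                solver = NULL, want_fluxes = TRUE) {
  direction <- match.arg(direction)
  pr <- lp_problem(model)
  j <- match(objective_id, pr$rxn_ids)
  if (is.na(j)) stop("objective reaction '", objective_id, "' not in model")
  ov <- constraints_to_overrides(pr, extra_constraints)
  job <- c(list(c_idx = j, c_val = 1, sense = direction,
                want_fluxes = want_fluxes), ov)
  res <- lp_solve_batch(pr, list(job), solver)[[1]]
  fluxes <- NULL
  if (!is.null(res$fluxes)) {
    fluxes <- stats::setNames(ifelse(abs(res$fluxes) < 1e-6, 0, res$fluxes),
                              pr$rxn_ids)
  }
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal") res$objective else NA_real_,
                 fluxes = fluxes),
            class = "cbm_solution")
}

#' @export
print.cbm_solution <- function(x, ...) {
  cat("<cbm_solution> status:", x$status,
      " objective:", format(x$objective_value), "\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux under mass balance, bounds, and
#' optional extra constraints. An infeasible constraint system is an error
#' that names the extra constraints whose individual relaxation restores
#' feasibility (constraint-relaxation probing).
#'
#' @inheritParams fba
#' @param reaction_ids reactions to range (default: all).
#' @return data.frame (`reaction_id`, `min`, `max`).
#' @export
fva <- function(model, reaction_ids = NULL, extra_constraints = NULL,
                solver = NULL) {
  pr <- lp_problem(model)
  if (is.null(reaction_ids)) reaction_ids <- pr$rxn_ids
  idx <- match(reaction_ids, pr$rxn_ids)
  if (anyNA(idx)) {
    stop("unknown reactions in fva(): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "))
  }
  ov <- constraints_to_overrides(pr, extra_constraints)
  jobs <- list()
  for (j in idx) {
    jobs <- c(jobs,
              list(c(list(c_idx = j, c_val = 1, sense = "min"), ov),
                   c(list(c_idx = j, c_val = 1, sense = "max"), ov)))
  }
  res <- lp_solve_batch(pr, jobs, solver)
  st <- vapply(res, `[[`, character(1), "status")
  if (any(st == "infeasible")) {
    stop("FVA constraint system infeasible; ",
         fva_diagnose(pr, extra_constraints, solver))
  }
  mins <- vapply(res[seq(1, length(res), 2)], `[[`, numeric(1), "objective")
  maxs <- vapply(res[seq(2, length(res), 2)], `[[`, numeric(1), "objective")
  data.frame(reaction_id = reaction_ids, min = mins, max = maxs,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Which extra constraints are binding? Drop each one in turn and test
# feasibility; report those whose removal restores a feasible system.
fva_diagnose <- function(problem, extra_constraints, solver) {
  if (is.null(extra_constraints) || nrow(extra_constraints) == 0L) {
    return("the model itself admits no steady-state flux distribution")
  }
  feas_job <- function(ec) {
    ov <- constraints_to_overrides(problem, ec)
    c(list(c_idx = 1L, c_val = 0, sense = "max", want_fluxes = FALSE), ov)
  }
  jobs <- lapply(seq_len(nrow(extra_constraints)), function(i) {
    feas_job(extra_constraints[-i, , drop = FALSE])
  })
  res <- lp_solve_batch(problem, jobs, solver)
  fixed <- vapply(res, function(r) r$status == "optimal", logical(1))
  if (any(fixed)) {
    paste0("conflicting constraint record(s): ",
           paste(extra_constraints$reaction_id[fixed], collapse = ", "))
  } else {
    "no single extra constraint explains the conflict (joint infeasibility)"
  }
}

#' Export FVA ranges as TSV
#' @param ranges data.frame from [fva()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fva_tsv <- function(ranges, path) {
  utils::write.table(ranges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Single-gene deletion scan
#'
#' For each gene, every reaction whose GPR evaluates to FALSE with that gene
#' absent is closed, and growth is re-maximized. A gene is essential when
#' the knockout growth falls below `threshold_fraction` of the wild-type
#' maximum.
#'
#' @param model a `cbm_model`.
#' @param threshold_fraction essentiality cutoff as a fraction of wild-type
#'   maximum growth (default 0.05).
#' @param genes subset of genes to scan (default: all model genes).
#' @param solver backend name or `NULL`.
#' @return data.frame (`gene`, `growth`, `essential`).
#' @export
single_gene_deletions <- function(model, threshold_fraction = 0.05,
                                  genes = model$genes, solver = NULL) {
  pr <- lp_problem(model)
  jobj <- match(model$objective_id, pr$rxn_ids)
  trees <- lapply(model$reactions, function(r) gpr_parse(r$gpr))
  gene_of <- lapply(trees, gpr_genes)
  wt <- lp_solve_batch(pr, list(list(c_idx = jobj, c_val = 1, sense = "max")),
                       solver)[[1]]
  if (wt$status != "optimal") stop("wild-type model does not grow (status ", wt$status, ")")
  wt_growth <- wt$objective

  jobs <- vector("list", length(genes))
  affected <- vector("list", length(genes))
  for (k in seq_along(genes)) {
    g <- genes[[k]]
    touches <- which(vapply(gene_of, function(gs) g %in% gs, logical(1)))
    off <- touches[vapply(touches, function(j) {
      !gpr_eval(trees[[j]], stats::setNames(FALSE, g))
    }, logical(1))]
    affected[[k]] <- off
    jobs[[k]] <- list(c_idx = jobj, c_val = 1, sense = "max",
                      lb_idx = off, lb_val = rep(0, length(off)),
                      ub_idx = off, ub_val = rep(0, length(off)))
  }
  res <- lp_solve_batch(pr, jobs, solver)
  growth <- vapply(res, function(r) {
    if (r$status == "optimal") r$objective else 0
  }, numeric(1))
  data.frame(gene = unlist(genes), growth = growth,
             essential = growth < threshold_fraction * wt_growth,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Theoretical maximum product yield
#'
#' Maximizes the product exchange flux with no growth requirement, then (at
#' the fixed optimum) minimizes substrate uptake so the reported ratio is
#' well defined even when the optimal flux vector is degenerate.
#'
#' @param model a `cbm_model`.
#' @param product_exchange_id product exchange reaction id.
#' @param substrate_exchange_id substrate exchange reaction id (uptake is
#'   its negative flux).
#' @param solver backend name or `NULL`.
#' @return list with `yield` (mol product per mol substrate), `product_flux`
#'   and `substrate_uptake`.
#' @export
theoretical_max_yield <- function(model, product_exchange_id,
                                  substrate_exchange_id, solver = NULL) {
  pr <- lp_problem(model)
  jp <- match(product_exchange_id, pr$rxn_ids)
  js <- match(substrate_exchange_id, pr$rxn_ids)
  if (is.na(jp)) stop("unknown product exchange '", product_exchange_id, "'")
  if (is.na(js)) stop("unknown substrate exchange '", substrate_exchange_id, "'")
  if (!is.finite(pr$lb[js]) || pr$lb[js] == 0) {
    stop("substrate uptake bound must be finite and nonzero")
  }
  r1 <- lp_solve_batch(pr, list(list(c_idx = jp, c_val = 1, sense = "max")),
                       solver)[[1]]
  if (r1$status != "optimal") {
    stop("product maximization not optimal (status ", r1$status, ")")
  }
  vmax <- r1$objective
  # stage 2: fix product at optimum, minimize uptake magnitude (maximize
  # the signed exchange flux, which is negative under uptake)
  r2 <- lp_solve_batch(pr, list(list(c_idx = js, c_val = 1, sense = "max",
                                     lb_idx = jp, lb_val = vmax,
                                     ub_idx = jp, ub_val = pr$ub[jp])),
                       solver)[[1]]
  uptake <- if (r2$status == "optimal") -r2$objective else -pr$lb[js]
  if (uptake < 1e-9) {
    stop("yield undefined: no substrate uptake at the product optimum")
  }
  list(yield = vmax / uptake, product_flux = vmax, substrate_uptake = uptake)
}
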