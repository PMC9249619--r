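#' Production envelope: product range versus growth
#'
#' Fixes biomass (as an equality) at `n_points` evenly spaced fractions of
#' its maximum, and at each grid point minimizes and maximizes the product
#' exchange flux. The upper boundary quantifies the production-growth
#' trade-off; it is concave in the biomass flux (parametric-LP property).
#'
#' @param model a `cbm_model` (typically grafted).
#' @param product_exchange_id product exchange reaction; defaults to the
#'   graft annotation.
#' @param n_points number of grid points (>= 2; endpoints always included).
#' @param solver backend name or `NULL`.
#' @return data.frame (`fraction`, `biomass_flux`, `product_min`,
#'   `product_max`, `feasible`). Infeasible grid points are flagged, not
#'   dropped.
#' @export
production_envelope <- function(model, product_exchange_id = product_exchange(model),
                                n_points = 21L, solver = NULL) {
  if (is.null(product_exchange_id)) stop("no product exchange given or annotated")
  if (n_points < 2L) stop("n_points must be >= 2")
  pr <- lp_problem(model)
  jb <- match(model$objective_id, pr$rxn_ids)
  jp <- match(product_exchange_id, pr$rxn_ids)
  if (is.na(jp)) stop("unknown product exchange '", product_exchange_id, "'")
  r0 <- lp_solve_batch(pr, list(list(c_idx = jb, c_val = 1, sense = "max")),
                       solver)[[1]]
  if (r0$status != "optimal") stop("model infeasible; no envelope (status ", r0$status, ")")
  mu_max <- r0$objective
  fr <- seq(0, 1, length.out = n_points)
  jobs <- list()
  for (f in fr) {
    b <- f * mu_max
    jobs <- c(jobs, list(
      list(c_idx = jp, c_val = 1, sense = "min",
           lb_idx = jb, lb_val = b, ub_idx = jb, ub_val = b),
      list(c_idx = jp, c_val = 1, sense = "max",
           lb_idx = jb, lb_val = b, ub_idx = jb, ub_val = b)))
  }
  res <- lp_solve_batch(pr, jobs, solver)
  lo <- res[seq(1, length(res), 2)]
  hi <- res[seq(2, length(res), 2)]
  ok <- vapply(lo, function(r) r$status == "optimal", logical(1)) &
        vapply(hi, function(r) r$status == "optimal", logical(1))
  data.frame(
    fraction = fr,
    biomass_flux = fr * mu_max,
    product_min = ifelse(ok, vapply(lo, `[[`, numeric(1), "objective"), NA_real_),
    product_max = ifelse(ok, vapply(hi, `[[`, numeric(1), "objective"), NA_real_),
    feasible = ok, row.names = NULL)
}

#' Export an envelope as TSV
#' @param env data.frame from [production_envelope()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_envelope_tsv <- function(env, path) {
  utils::write.table(env, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
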