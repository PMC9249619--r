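# LP backend contract.
#
# A backend is a function(problem, jobs) -> list of results, where
#   problem: list(S = dgCMatrix (m x n), lb, ub  -- numeric n-vectors)
#   job:     list(c_idx, c_val   -- sparse objective,
#                 sense = "max"/"min",
#                 lb_idx/lb_val, ub_idx/ub_val -- bound overrides,
#                 want_fluxes = TRUE/FALSE)
#   result:  list(status = "optimal"/"infeasible"/"unbounded"/"error",
#                 objective = numeric, fluxes = numeric n-vector or NULL)
# Two interchangeable backends ship: "simplex" (pure R, dense; the default
# for small and toy models) and "highs" (scipy/HiGHS through the python
# bridge; the default for genome-scale models). Select globally with
# options(fluxforce.solver = ...) or per call.

LP_INF <- 1e30

#' Available LP backends
#' @return character vector of backend names.
#' @export
lp_backends <- function() c("simplex", "highs")

resolve_solver <- function(solver, n) {
  if (is.null(solver)) solver <- getOption("fluxforce.solver", "auto")
  if (identical(solver, "auto")) solver <- if (n > 400L) "highs" else "simplex"
  match.arg(solver, lp_backends())
}

lp_solve_batch <- function(problem, jobs, solver = NULL) {
  solver <- resolve_solver(solver, ncol(problem$S))
  switch(solver,
         simplex = lp_backend_simplex(problem, jobs),
         highs = lp_backend_highs(problem, jobs))
}

lp_backend_simplex <- function(problem, jobs) {
  A <- as.matrix(problem$S)
  m <- nrow(A); n <- ncol(A)
  lapply(jobs, function(job) {
    lb <- problem$lb; ub <- problem$ub
    if (length(job$lb_idx)) lb[job$lb_idx] <- job$lb_val
    if (length(job$ub_idx)) ub[job$ub_idx] <- job$ub_val
    cc <- numeric(n); cc[job$c_idx] <- job$c_val
    res <- simplex_solve(A, rep(0, m), cc, lb, ub,
                         sense = job$sense %||% "max")
    list(status = res$status, objective = res$objective,
         fluxes = if (isTRUE(job$want_fluxes)) res$x else NULL)
  })
}

lp_backend_highs <- function(problem, jobs) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("the 'highs' backend needs a python interpreter with scipy on PATH")
  script <- system.file("python", "lp_batch.py", package = "fluxforce")
  if (!nzchar(script) && file.exists(file.path("inst", "python", "lp_batch.py"))) {
    script <- file.path("inst", "python", "lp_batch.py")  # source-tree runs
  }
  if (!nzchar(script)) stop("lp_batch.py helper not found")
  trip <- Matrix::summary(problem$S)  # i, j, x triplets
  payload <- list(
    m = nrow(problem$S), n = ncol(problem$S),
    Ai = trip$i, Aj = trip$j, Ax = trip$x,
    lb = pmax(problem$lb, -LP_INF), ub = pmin(problem$ub, LP_INF),
    inf = LP_INF,
    jobs = lapply(jobs, function(job) {
      list(c_idx = as.integer(job$c_idx), c_val = as.numeric(job$c_val),
           sense = job$sense %||% "max",
           lb_idx = as.integer(job$lb_idx %||% integer()),
           lb_val = as.numeric(job$lb_val %||% numeric()),
           ub_idx = as.integer(job$ub_idx %||% integer()),
           ub_val = as.numeric(job$ub_val %||% numeric()),
           want_fluxes = isTRUE(job$want_fluxes))
    }))
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(py, c(script, fin, fout), stdout = NULL, stderr = "")
  if (!identical(status, 0L) || !file.exists(fout)) {
    stop("LP bridge failed (python exit status ", status, ")")
  }
  res <- jsonlite::fromJSON(fout, simplifyVector = FALSE)
  lapply(res, function(r) {
    list(status = r$status, objective = r$objective %||% NA_real_,
         fluxes = if (!is.null(r$fluxes)) as.numeric(unlist(r$fluxes)) else NULL)
  })
}

# --- model-level LP assembly -------------------------------------------

# Cache the numeric problem (S, bounds) on the model so repeated FBA/FVA
# calls do not rebuild the sparse matrix.
lp_problem <- function(model) {
  pr <- attr(model, ".lp_problem")
  if (!is.null(pr)) return(pr)
  bd <- reaction_bounds(model)
  list(S = stoich_matrix(model), lb = bd$lower, ub = bd$upper,
       rxn_ids = bd$reaction_id)
}

#' Precompute the LP form of a model
#'
#' Optional optimization: attaches the sparse stoichiometric matrix to the
#' model so repeated analyses skip re-assembly.
#' @param model a `cbm_model`.
#' @return the model with a cached LP problem.
#' @export
precompute_lp <- function(model) {
  attr(model, ".lp_problem") <- NULL
  attr(model, ".lp_problem") <- lp_problem(model)
  model
}

constraints_to_overrides <- function(problem, extra_constraints) {
  if (is.null(extra_constraints) || nrow(extra_constraints) == 0L) {
    return(list(lb_idx = integer(), lb_val = numeric(),
                ub_idx = integer(), ub_val = numeric()))
  }
  idx <- match(extra_constraints$reaction_id, problem$rxn_ids)
  if (anyNA(idx)) {
    stop("extra constraints reference unknown reactions: ",
         paste(extra_constraints$reaction_id[is.na(idx)], collapse = ", "))
  }
  # an extra constraint narrows the model bounds, never widens them
  lbv <- pmax(extra_constraints$lower, problem$lb[idx])
  ubv <- pmin(extra_constraints$upper, problem$ub[idx])
  list(lb_idx = idx, lb_val = lbv, ub_idx = idx, ub_val = ubv)
}
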