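# Shared fixtures. The canonical toy is cheap to rebuild; the genome-scale
# model is parsed once per test run and cached here.

.fixture_cache <- new.env(parent = emptyenv())

canonical_toy <- function() toy_chor_model()

canonical_flux_data <- function() {
  fd <- attr(toy_chor_model(), "flux_data")
  class(fd) <- c("flux_data", "data.frame")
  fd
}

# Grafted iJO1366 on aerobic M9 glucose, or NULL when no local copy of the
# model exists (the locator needs no network; see find_ijo1366()).
grafted_ijo1366 <- function() {
  if (!is.null(.fixture_cache$ijo_grafted)) return(.fixture_cache$ijo_grafted)
  p <- find_ijo1366()
  if (is.null(p)) return(NULL)
  host <- read_sbml(p)
  model <- graft_pathway(host, builtin_papbac_pathway())
  medium <- read_medium(system.file("extdata", "m9_aerobic_glucose.yaml",
                                    package = "fluxforce"))
  model <- precompute_lp(apply_medium(model, medium))
  .fixture_cache$ijo_grafted <- model
  model
}

# small seeded toy battery reused by the property tests; the branch-count
# cap keeps every model inside the rational oracle's guard
toy_battery <- function(n, base_seed = 100L) {
  lapply(seq_len(n), function(k) {
    set.seed(base_seed + k)
    kb <- sample(1:3, 1)
    kf <- sample(0:(3 - kb), 1)
    spec <- toy_spec(
      n_bio_branches = kb, n_free_branches = kf,
      uptake = sample(c(4, 5, 8, 10, 12, 20), 1),
      product_yield = sample(c(1 / 2, 1, 2), 1),
      branch_yields = sample(c(1, 2), kb, replace = TRUE),
      seed = base_seed + k)
    generate_toy_model(spec)
  })
}

expect_backends_agree <- function(model, objective_id, direction = "max",
                                  extra_constraints = NULL, tol = 1e-6) {
  a <- fba(model, objective_id, direction, extra_constraints,
           solver = "simplex", want_fluxes = FALSE)
  b <- fba(model, objective_id, direction, extra_constraints,
           solver = "highs", want_fluxes = FALSE)
  expect_identical(a$status, b$status)
  if (a$status == "optimal") {
    denom <- max(1, abs(a$objective_value))
    expect_lt(abs(a$objective_value - b$objective_value) / denom, tol)
  }
  invisible(a)
}
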