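test_that("FBA reproduces the toy optima known in closed form", {
  m <- canonical_toy()
  expect_equal(fba(m, solver = "simplex")$objective_value, 5)
  expect_equal(fba(m, "EX_paf", solver = "simplex")$objective_value, 10)
  # a reaction pinned by extra constraints optimizes to its pin
  s <- fba(m, "R_ent", extra_constraints = data.frame(
    reaction_id = "R_ent", lower = 2, upper = 2), solver = "simplex")
  expect_equal(s$objective_value, 2)
  # all uptakes closed: no carbon, no growth
  m0 <- apply_medium(m, stats::setNames(numeric(0), character(0)))
  expect_equal(fba(m0, solver = "simplex")$objective_value, 0)
})

test_that("optimal flux vectors satisfy mass balance and bounds", {
  m <- canonical_toy()
  for (sv in c("simplex", "highs")) {
    s <- fba(m, solver = sv)
    expect_identical(s$status, "optimal")
    S <- stoich_matrix(m)
    expect_lt(max(abs(as.numeric(S %*% s$fluxes))), 1e-6)
    bd <- reaction_bounds(m)
    expect_true(all(s$fluxes >= bd$lower - 1e-6))
    expect_true(all(s$fluxes <= bd$upper + 1e-6))
  }
})

test_that("infeasible and unbounded problems are reported as such", {
  m <- canonical_toy()
  ec <- data.frame(reaction_id = "BIOMASS", lower = 6, upper = 100)
  for (sv in c("simplex", "highs")) {
    expect_identical(fba(m, extra_constraints = ec, solver = sv)$status,
                     "infeasible")
  }
  # a genuinely open direction must come back unbounded, not a big number
  mets <- rbind(metabolite("a_c", compartment = "c"))
  loop <- cbm_model("loop", mets, list(
    reaction("R1", c(a_c = 1), -Inf, Inf),
    reaction("R2", c(a_c = -1), -Inf, Inf)), "R1", check = TRUE)
  for (sv in c("simplex", "highs")) {
    expect_identical(fba(loop, "R1", solver = sv)$status, "unbounded")
  }
})

test_that("FVA brackets the toy ranges and every FBA optimum", {
  m <- canonical_toy()
  wt <- close_pathway(m)
  ec <- data.frame(reaction_id = "BIOMASS", lower = 4.5, upper = Inf)
  r <- fva(wt, c("R_trp", "R_ent"), extra_constraints = ec, solver = "simplex")
  expect_equal(r$min[r$reaction_id == "R_trp"], 4.5)
  expect_equal(r$max[r$reaction_id == "R_trp"], 5.5) # 10 - 4.5 via trp demand
  expect_equal(r$min[r$reaction_id == "R_ent"], 0)
  expect_equal(r$max[r$reaction_id == "R_ent"], 1)   # 10 - 2 * 4.5 spillover
  # blocked reaction has the degenerate range [0, 0]
  mb <- set_bounds(m, "R_ent", 0, 0)
  rb <- fva(mb, "R_ent", solver = "simplex")
  expect_equal(c(rb$min, rb$max), c(0, 0))
  # FVA containment: optimal FBA fluxes lie within ranges under the same
  # constraints
  s <- fba(wt, extra_constraints = ec, solver = "simplex")
  rall <- fva(wt, extra_constraints = ec, solver = "simplex")
  expect_true(all(s$fluxes >= rall$min - 1e-6 & s$fluxes <= rall$max + 1e-6))
})

test_that("infeasible FVA identifies the conflicting constraint record", {
  m <- canonical_toy()
  ec <- data.frame(reaction_id = c("EX_glc", "BIOMASS"),
                   lower = c(20, 0), upper = c(30, 1000))
  expect_error(fva(m, "R_trp", extra_constraints = ec, solver = "simplex"),
               "EX_glc")
})

test_that("both LP backends agree on fixture LPs (solver independence)", {
  m <- canonical_toy()
  expect_backends_agree(m, "BIOMASS")
  expect_backends_agree(m, "EX_paf")
  expect_backends_agree(m, "EX_paf", "min")
  expect_backends_agree(m, "R_ent", "max",
                        data.frame(reaction_id = "BIOMASS", lower = 4,
                                   upper = Inf))
  for (tm in toy_battery(4, base_seed = 300L)) {
    expect_backends_agree(tm, tm$objective_id)
    expect_backends_agree(tm, product_exchange(tm))
  }
})

test_that("LP optima equal the exact-rational oracle on seeded toys", {
  m <- canonical_toy()
  for (obj in c("BIOMASS", "EX_paf")) {
    o <- brute_force_oracle(m, obj, "max")
    expect_identical(o$status, "optimal")
    expect_lt(abs(fba(m, obj, solver = "simplex")$objective_value -
                    o$objective), 1e-9)
  }
  for (tm in toy_battery(5, base_seed = 420L)) {
    o <- brute_force_oracle(tm, tm$objective_id, "max")
    expect_lt(abs(fba(tm, solver = "simplex")$objective_value - o$objective),
              1e-9)
  }
  # oracle agrees on infeasibility too
  o <- brute_force_oracle(m, "BIOMASS", "max", data.frame(
    reaction_id = "BIOMASS", lower = 6, upper = 100))
  expect_identical(o$status, "infeasible")
  # and refuses models beyond its guard
  expect_error(brute_force_oracle(canonical_toy(), max_reactions = 5L),
               "guard")
})
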