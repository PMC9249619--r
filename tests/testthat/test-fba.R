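test_that("single-gene deletions honor GPR logic and the growth threshold", {
  m <- canonical_toy()
  del <- single_gene_deletions(m, solver = "simplex")
  g <- function(id) del[del$gene == id, ]
  # sole route to the hub: lethal
  expect_equal(g("aroT")$growth, 0)
  expect_true(g("aroT")$essential)
  # overflow branch unused at the growth optimum
  expect_equal(g("entA")$growth, 5)
  expect_false(g("entA")$essential)
  # OR-redundant isozyme: reaction stays catalyzed
  expect_equal(g("pheA")$growth, 5)
  expect_false(g("pheA")$essential)
  # AND complex: either subunit loss kills the branch
  expect_true(g("trpA1")$essential)
  expect_true(g("trpA2")$essential)
})

test_that("theoretical yield is exact on the toy and intensive in the uptake bound", {
  m <- canonical_toy()
  y <- theoretical_max_yield(m, "EX_paf", "EX_glc", solver = "simplex")
  expect_equal(y$yield, 1)           # 1:1 chain stoichiometry
  expect_equal(y$substrate_uptake, 10)

  # scale invariance: mol/mol does not depend on the uptake bound
  m2 <- set_bounds(m, "EX_glc", lower = -20)
  y2 <- theoretical_max_yield(m2, "EX_paf", "EX_glc", solver = "simplex")
  expect_equal(y2$yield, y$yield)
  for (tm in toy_battery(3, base_seed = 510L)) {
    ya <- theoretical_max_yield(tm, "EX_prod", "EX_sub", solver = "simplex")
    tm2 <- set_bounds(tm, "EX_sub",
                      lower = 2 * tm$reactions$EX_sub$lower_bound)
    yb <- theoretical_max_yield(tm2, "EX_prod", "EX_sub", solver = "simplex")
    expect_equal(ya$yield, yb$yield)
    spec <- attr(tm, "toy_spec")
    expect_equal(ya$yield, spec$product_yield)   # closed-form ground truth
  }

  # passthrough model: product exchange is a straight relabeling of the
  # substrate, so the yield is exactly one
  mets <- rbind(metabolite("s_e", compartment = "e"),
                metabolite("p_e", compartment = "e"))
  mp <- cbm_model("pass", mets, list(
    reaction("EX_s", c(s_e = -1), -10, 1000),
    reaction("T_sp", c(s_e = -1, p_e = 1), 0, 1000),
    reaction("EX_p", c(p_e = -1), 0, 1000)), "EX_p")
  yp <- theoretical_max_yield(mp, "EX_p", "EX_s", solver = "simplex")
  expect_equal(yp$yield, 1)

  # a model that cannot draw substrate has no defined yield
  mz <- set_bounds(canonical_toy(), "R_chor", 0, 0)
  expect_error(theoretical_max_yield(mz, "EX_paf", "EX_glc",
                                     solver = "simplex"),
               "yield undefined")
})
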