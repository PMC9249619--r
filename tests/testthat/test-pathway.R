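test_that("the built-in papBAC block has the documented structure", {
  pw <- builtin_papbac_pathway()
  expect_identical(length(pw$reactions), 6L)   # 3 enzymatic + transamination + transport + exchange
  ids <- vapply(pw$reactions, `[[`, character(1), "id")
  expect_setequal(ids, c("PAPA", "PAPB", "PAPC", "PAFTA", "PAFt", "EX_paf_e"))
  # PapA draws on the two host precursors: glutamine and chorismate
  st <- pw$reactions[[which(ids == "PAPA")]]$stoichiometry
  expect_lt(st[["gln__L_c"]], 0)
  expect_lt(st[["chor_c"]], 0)
  # the whole block is provenance-annotated
  expect_true(all(ids %in% names(pw$notes)))
})

test_that("papBAC is elementally balanced: one chorismate -> one pAF + CO2", {
  ij <- grafted_ijo1366()
  if (is.null(ij)) {
    # desk fallback: check balance against a minimal host metabolite table
    # carrying the BiGG formulas the pathway touches
    host_mets <- rbind(
      metabolite("chor_c", compartment = "c", formula = "C10H8O6", charge = -2L),
      metabolite("gln__L_c", compartment = "c", formula = "C5H10N2O3", charge = 0L),
      metabolite("glu__L_c", compartment = "c", formula = "C5H8NO4", charge = -1L),
      metabolite("nad_c", compartment = "c", formula = "C21H26N7O14P2", charge = -1L),
      metabolite("nadh_c", compartment = "c", formula = "C21H27N7O14P2", charge = -2L),
      metabolite("co2_c", compartment = "c", formula = "CO2", charge = 0L),
      metabolite("h_c", compartment = "c", formula = "H", charge = 1L),
      metabolite("akg_c", compartment = "c", formula = "C5H4O5", charge = -2L))
    pw <- builtin_papbac_pathway()
    host <- cbm_model("mini_host", host_mets, list(
      reaction("DM_chor", c(chor_c = -1), -1000, 1000)), "DM_chor")
    ij <- graft_pathway(host, pw)
  }
  bal <- check_balance(ij, c("PAPA", "PAPB", "PAPC", "PAFTA", "PAFt"),
                       elements = c("C", "N", "H", "O"))
  expect_identical(nrow(bal), 0L)
})

test_that("grafting is neutral when the branch is closed, and collision-safe", {
  host <- toy_chor_model(include_product_branch = FALSE)
  g <- graft_pathway(host, toy_product_pathway())
  expect_identical(product_exchange(g), "EX_paf")
  # closed graft reproduces the host optimum exactly
  mu_host <- fba(host, solver = "simplex")$objective_value
  expect_identical(fba(close_pathway(g), solver = "simplex")$objective_value,
                   mu_host)
  # open graft makes product
  expect_gt(fba(g, "EX_paf", solver = "simplex")$objective_value, 0)
  # grafting twice collides
  expect_error(graft_pathway(g, toy_product_pathway()), "duplicate")
  # unmapped host species are reported by id
  bad <- toy_product_pathway()
  names(bad$reactions[[1]]$stoichiometry)[1] <- "missing_c"
  expect_error(graft_pathway(host, bad), "missing_c")
})

test_that("equation parsing and the pathway YAML format round-trip a graft", {
  expect_equal(parse_equation("a + 2 b -> c"), c(a = -1, b = -2, c = 1))
  expect_equal(parse_equation("a <-> b"), c(a = -1, b = 1))
  expect_equal(parse_equation("1/2 a -> b"), c(a = -0.5, b = 1))
  expect_equal(parse_equation("a ->"), c(a = -1))
  expect_error(parse_equation("a b c"), "arrow")
  expect_error(parse_equation("a -> b -> c"), "one arrow")

  pw <- read_pathway_yaml(system.file("extdata", "pathway_toy.yaml",
                                      package = "fluxforce"))
  host <- toy_chor_model(include_product_branch = FALSE)
  g <- graft_pathway(host, pw)
  expect_equal(fba(g, "EX_paf", solver = "simplex")$objective_value, 10)
})
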