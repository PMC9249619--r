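test_that("toy generation is deterministic: same seed, byte-identical export", {
  sp <- toy_spec(n_bio_branches = 2, n_free_branches = 1, uptake = 10, seed = 7L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_json_model(generate_toy_model(sp), f1)
  write_json_model(generate_toy_model(toy_spec(2, 1, 10, seed = 7L)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ground-truth closure: closed form = oracle = LP on every spec", {
  specs <- list(
    toy_spec(1, 0, uptake = 6, seed = 21L),        # single sink, no overflow
    toy_spec(2, 1, uptake = 10, seed = 22L),
    toy_spec(1, 2, uptake = 8, product_yield = 1 / 2, seed = 23L),
    toy_spec(2, 1, uptake = 12, product_yield = 2, branch_yields = c(1, 2),
             seed = 24L))
  for (sp in specs) {
    m <- generate_toy_model(sp)
    gt <- sp$ground_truth
    expect_equal(fba(m, solver = "simplex")$objective_value, gt$max_growth)
    expect_equal(fba(m, "EX_prod", solver = "simplex")$objective_value,
                 gt$theoretical_max_product)
    o <- brute_force_oracle(m, "BIOMASS", "max")
    expect_lt(abs(o$objective - gt$max_growth), 1e-12)
    o2 <- brute_force_oracle(m, "EX_prod", "max")
    expect_lt(abs(o2$objective - gt$theoretical_max_product), 1e-12)
  }
  # a spec with one sink and unit yield has trivially yield one
  y <- theoretical_max_yield(generate_toy_model(toy_spec(1, 0, seed = 31L)),
                             "EX_prod", "EX_sub", solver = "simplex")
  expect_equal(y$yield, 1)
})

test_that("degenerate specs are rejected", {
  expect_error(toy_spec(0, 1), "biomass unsatisfiable")
  expect_error(toy_spec(2, 2), "at most 3")
  expect_error(toy_spec(1, 1, uptake = -1), "positive")
  expect_error(toy_spec(1, 1, uptake = 10, wt_uptake = 12), "strictly between")
})

test_that("the pipeline recovers the constructed FORCE set on seeded toys", {
  for (m in toy_battery(8, base_seed = 900L)) {
    gt <- attr(m, "toy_spec")$ground_truth
    pl <- toy_pipeline(m, solver = "simplex")
    expect_equal(as.data.frame(pl$candidates), gt$force_set,
                 ignore_attr = TRUE)
    mins <- pl$force[pl$force$minimal, ]
    expect_identical(nrow(mins), 1L)
    expect_equal(mins$worst_case_min_product, gt$worst_case_min_product)
    # gene-level cost matches the template arithmetic
    cost <- sum(vapply(seq_len(nrow(pl$candidates)), function(i) {
      length(reaction_to_gene_interventions(m, pl$candidates[i, ])[[1]]$genes)
    }, integer(1)))
    expect_identical(cost, as.integer(gt$gene_cost))
  }
})
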