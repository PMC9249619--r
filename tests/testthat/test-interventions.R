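test_that("interventions edit bounds per kind and undo exactly", {
  m <- canonical_toy()
  ints <- interventions(c("R_chor", "R_trp", "R_ent"),
                        c("up", "down", "ko"), c(10, 1, NA))
  m2 <- apply_interventions(m, ints)
  expect_equal(m2$reactions$R_chor$lower_bound, 10)
  expect_equal(m2$reactions$R_chor$upper_bound, 1000)
  expect_equal(m2$reactions$R_trp$upper_bound, 1)
  expect_equal(unname(c(m2$reactions$R_ent$lower_bound,
                        m2$reactions$R_ent$upper_bound)), c(0, 0))
  m3 <- undo_interventions(m2)
  expect_equal(reaction_bounds(m3), reaction_bounds(m))

  # contradictions are named
  expect_error(apply_interventions(
    m, interventions("R_chor", "up", 2000)), "contradicts")
  expect_error(interventions(c("R_trp", "R_trp"), "down", 1), "same reaction")
  expect_error(interventions("R_trp", "down", NA_real_), "finite level")
})

test_that("min/max product reproduce the toy worst-case values", {
  m <- canonical_toy()
  none <- interventions(character(0), character(0))
  expect_equal(min_product(m, none, solver = "simplex")$flux, 0)
  expect_equal(max_product(m, none, solver = "simplex")$flux, 8)  # envelope at the 20% floor
  full <- interventions(c("R_chor", "R_trp", "R_phe", "R_ent"),
                        c("up", "down", "down", "ko"), c(10, 1, 1, NA))
  mn <- min_product(m, full, solver = "simplex")
  expect_equal(mn$flux, 8)
  expect_equal(mn$percent_of_max, 80)
  expect_equal(max_product(m, full, solver = "simplex")$flux, 8)
  # knocking out the product branch zeroes the maximum
  ko <- interventions("R_pap", "ko")
  mx <- max_product(m, ko, thresholds = design_thresholds(0.1, 0.8),
                    solver = "simplex")
  expect_equal(mx$flux, 0)
  # the two reported values differ when the growth floor is lifted
  mn_nf <- min_product(m, full, growth_floor = FALSE, solver = "simplex")
  expect_lte(mn_nf$flux, mn$flux + 1e-9)
})

test_that("gene mapping produces minimal hitting and sufficiency sets", {
  m <- canonical_toy()
  gi_phe <- reaction_to_gene_interventions(
    m, interventions("R_phe", "down", 1))
  expect_identical(length(gi_phe), 1L)
  expect_identical(gi_phe[[1]]$genes, c("pheA", "tyrA"))  # both isozymes
  gi_trp <- reaction_to_gene_interventions(
    m, interventions("R_trp", "down", 1))
  expect_identical(lapply(gi_trp, `[[`, "genes"), list("trpA1", "trpA2"))
  gi_up <- reaction_to_gene_interventions(
    m, interventions("R_chor", "up", 10))
  expect_identical(gi_up[[1]]$genes, "aroT")
  expect_error(reaction_to_gene_interventions(
    m, interventions("DM_ent", "ko")), "no gene association")
})

test_that("simulating a ko hitting set drives the source reaction to zero", {
  m <- canonical_toy()
  for (rid in c("R_trp", "R_phe", "R_ent")) {
    alts <- reaction_to_gene_interventions(m, interventions(rid, "ko"))
    for (alt in alts) {
      act <- stats::setNames(rep(FALSE, length(alt$genes)), alt$genes)
      off <- vapply(m$reactions, function(r) {
        tr <- gpr_parse(r$gpr)
        !is.null(tr) && !gpr_eval(tr, act)
      }, logical(1))
      expect_true(off[[rid]])
      m2 <- m
      for (r2 in names(off)[off]) m2 <- set_bounds(m2, r2, 0, 0)
      rng <- fva(m2, rid, solver = "simplex")
      expect_equal(unlist(rng[, c("min", "max")], use.names = FALSE), c(0, 0))
    }
  }
})

test_that("the combination scan is consistent, monotone and epistatic", {
  m <- canonical_toy()
  full <- interventions(c("R_chor", "R_trp", "R_phe", "R_ent"),
                        c("up", "down", "down", "ko"), c(10, 1, 1, NA))
  scan <- combination_scan(m, full, solver = "simplex")
  expect_identical(nrow(scan), 16L)               # all subsets incl. empty
  # all-or-nothing epistasis: only the full quadruple forces production
  expect_identical(scan$members[scan$minimal_positive],
                   "down:R_phe,down:R_trp,ko:R_ent,up:R_chor")
  expect_true(all(scan$min_product[scan$size < 4] < 1e-6))
  # scan rows equal an independent min_product recomputation
  for (i in sample(nrow(scan), 5)) {
    ids <- setdiff(strsplit(scan$members[i], ",")[[1]], "")
    sub <- full[match(sub("^[a-z]+:", "", ids), full$reaction_id), , drop = FALSE]
    mp <- min_product(m, sub, solver = "simplex")
    expect_equal(scan$min_product[i], mp$flux)
  }
  # monotone rows: supersets never force less
  sets <- strsplit(scan$members, ",")
  for (i in seq_len(nrow(scan))) {
    for (j in seq_len(nrow(scan))) {
      if (i != j && all(sets[[i]] %in% sets[[j]]) &&
          scan$feasible[i] && scan$feasible[j]) {
        expect_gte(scan$min_product[j], scan$min_product[i] - 1e-8)
      }
    }
  }
  # empty intervention list: a single zero row
  scan0 <- combination_scan(m, interventions(character(0), character(0)),
                            solver = "simplex")
  expect_identical(nrow(scan0), 1L)
  expect_equal(scan0$min_product, 0)
  # the subset guard refuses explosions
  expect_error(combination_scan(m, full, subset_guard = 4), "guard")
})

test_that("the gene-level scan needs all five toy genes", {
  m <- canonical_toy()
  cand <- interventions(c("R_chor", "R_trp", "R_phe", "R_ent"),
                        c("up", "down", "down", "ko"), c(10, 1, 1, NA))
  gene_ints <- lapply(seq_len(nrow(cand)), function(i) {
    reaction_to_gene_interventions(m, cand[i, ])[[1]]
  })
  n_genes <- sum(lengths(lapply(gene_ints, `[[`, "genes")))
  expect_identical(n_genes, 5L)                   # aroT, trpA1, pheA+tyrA, entA
  scan <- gene_combination_scan(m, gene_ints, solver = "simplex")
  pos <- scan$min_product > 1e-6 & scan$feasible
  expect_identical(min(scan$n_genes[pos]), 5L)
  expect_true(all(scan$min_product[scan$n_genes < 5] < 1e-6))
  top <- scan[scan$n_genes == 5, ]
  expect_equal(top$min_product, 8)
})
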