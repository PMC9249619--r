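test_that("wild-type ranges honor flux data and the growth floor", {
  m <- canonical_toy()
  wt <- close_pathway(m)
  fd <- canonical_flux_data()                 # glucose uptake measured at 8
  wr <- wildtype_ranges(wt, fd, growth_fraction = 0.9, solver = "simplex")
  g <- function(id) unlist(wr[wr$reaction_id == id, c("min", "max")],
                           use.names = FALSE)
  expect_equal(g("R_chor"), c(8, 8))
  expect_equal(g("BIOMASS"), c(3.6, 4))       # floor 0.9 * (8 / 2)
  expect_equal(g("R_trp"), c(3.6, 4.4))
  expect_equal(g("R_ent"), c(0, 0.8))
  expect_equal(g("R_pap"), c(0, 0))           # pathway closed in the reference

  # empty flux data degrade to plain FVA
  wr0 <- wildtype_ranges(wt, NULL, solver = "simplex")
  expect_equal(unlist(wr0[wr0$reaction_id == "R_chor", c("min", "max")],
                      use.names = FALSE), c(0, 10))

  # conflicting measurement: infeasibility error names the record
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tlower\tupper", "EX_glc\t20\t30"), f)
  expect_error(wildtype_ranges(wt, read_flux_data(f), growth_fraction = 0.5,
                               solver = "simplex"),
               "EX_glc")
})

test_that("overproducer ranges pin the toy under the default thresholds", {
  m <- canonical_toy()
  ov <- overproducer_ranges(m, design_thresholds(0.2, 0.8), solver = "simplex")
  g <- function(id) unlist(ov[ov$reaction_id == id, c("min", "max")],
                           use.names = FALSE)
  # product >= 8 plus growth >= 1 saturates the uptake: everything pinned
  expect_equal(g("R_chor"), c(10, 10))
  expect_equal(g("R_trp"), c(1, 1))
  expect_equal(g("R_phe"), c(1, 1))
  expect_equal(g("R_ent"), c(0, 0))
  expect_equal(g("R_pap"), c(8, 8))
  expect_equal(attr(ov, "theoretical_max_product"), 10)

  # jointly unreachable thresholds report the attainable product fraction
  expect_error(overproducer_ranges(m, design_thresholds(1, 1),
                                   solver = "simplex"),
               "maximal feasible product_fraction")
})

test_that("superimposing ranges yields the expected MUST classification", {
  m <- canonical_toy()
  pl <- toy_pipeline(m, solver = "simplex")
  must <- pl$must
  expect_true("R_chor" %in% must$must_u$reaction_id)
  expect_equal(must$must_u$level[must$must_u$reaction_id == "R_chor"], 10)
  expect_true(all(c("R_trp", "R_phe") %in% must$must_l$reaction_id))
  expect_true("R_ent" %in% must$must_x)
  # provenance invariant: MUST-U overproducer minimum exceeds wild-type max
  prov <- must$provenance
  for (rid in must$must_u$reaction_id) {
    row <- prov[prov$reaction_id == rid, ]
    expect_gt(row$ov_min, row$wt_max)
  }
  # identical maps produce empty MUST sets
  eq <- classify_must_sets(pl$wt_ranges, pl$wt_ranges)
  expect_identical(nrow(eq$must_u), 0L)
  expect_identical(nrow(eq$must_l), 0L)
  expect_identical(length(eq$must_x), 0L)
  # a reaction present in only one map is skipped and reported
  short <- pl$ov_ranges[pl$ov_ranges$reaction_id != "R_ent", ]
  suppressMessages(ms <- classify_must_sets(pl$wt_ranges, short))
  expect_identical(attr(ms, "skipped"), "R_ent")
})

test_that("candidate construction applies the three exclusion rules", {
  m <- canonical_toy()
  pl <- toy_pipeline(m, solver = "simplex")
  cand <- pl$candidates
  # no-GPR reactions (transport, exchanges, demands, biomass) never appear
  expect_setequal(cand$reaction_id, c("R_chor", "R_trp", "R_phe", "R_ent"))
  expect_identical(cand$kind[cand$reaction_id == "R_chor"], "up")
  expect_identical(cand$kind[cand$reaction_id == "R_ent"], "ko")
  expect_equal(cand$level[cand$reaction_id == "R_trp"], 1)

  # rule 1: stripping a GPR removes the candidate entirely
  m2 <- m
  m2$reactions$R_chor$gpr <- ""
  cand2 <- candidate_interventions(pl$must, m2,
                                   exclude_reactions = pathway_reactions(m))
  expect_false("R_chor" %in% cand2$reaction_id)

  # rule 2: essential-gene knockouts are excluded
  ess <- data.frame(gene = "entA", growth = 0, essential = TRUE)
  cand3 <- candidate_interventions(pl$must, m, essential = ess,
                                   exclude_reactions = pathway_reactions(m))
  expect_false("R_ent" %in% cand3$reaction_id)

  # rule 3: without the pathway exclusion the papBAC-like upregulation
  # of the grafted branch is offered (the "pull" strategy)
  cand4 <- candidate_interventions(pl$must, m)
  expect_true("R_pap" %in% cand4$reaction_id)
  expect_identical(cand4$kind[cand4$reaction_id == "R_pap"], "up")
})

test_that("FORCE search finds the unique minimal quadruple on the canonical toy", {
  m <- canonical_toy()
  pl <- toy_pipeline(m, solver = "simplex")
  force <- pl$force
  mins <- force[force$minimal, ]
  expect_identical(nrow(mins), 1L)
  expect_identical(mins$members,
                   "down:R_phe,down:R_trp,ko:R_ent,up:R_chor")
  expect_equal(mins$worst_case_min_product, 8)
  expect_equal(mins$percent_of_max, 80)
  expect_true(mins$achieves_target)
  # every proper subset fails to force any production
  subs <- force[force$size < 4 & force$feasible, ]
  expect_true(all(subs$worst_case_min_product < 1e-6))

  # empty candidate list is a clean empty result
  empty <- find_force_sets(m, interventions(character(0), character(0)),
                           solver = "simplex")
  expect_identical(nrow(empty), 0L)

  # oversized k_max warns and clamps
  expect_warning(find_force_sets(m, pl$candidates, k_max = 10L,
                                 solver = "simplex"),
                 "exceeds")
})

test_that("pruned search equals the unpruned exhaustive scan", {
  m <- canonical_toy()
  pl <- toy_pipeline(m, solver = "simplex")
  force <- pl$force
  scan <- combination_scan(m, pl$candidates, solver = "simplex")
  scan <- scan[scan$size > 0, ]
  # the scan is unpruned; minimal positive subsets must coincide
  expect_setequal(force$members[force$minimal],
                  scan$members[scan$minimal_positive])
  # and every evaluated subset value agrees between the two code paths
  shared <- merge(force, scan, by = "members")
  expect_equal(shared$worst_case_min_product, shared$min_product)
})

test_that("worst-case minimum is monotone under intervention-set inclusion", {
  models <- c(list(canonical_toy()), toy_battery(3, base_seed = 710L))
  for (m in models) {
    pl <- toy_pipeline(m, solver = "simplex")
    cand <- pl$candidates
    set.seed(nrow(cand))
    for (rep in 1:4) {
      ks <- sample(nrow(cand), 2)
      small <- sort(sample(nrow(cand), min(ks)))
      big <- sort(unique(c(small, sample(nrow(cand), max(ks)))))
      lo <- min_product(m, cand[small, ], solver = "simplex")
      hi <- min_product(m, cand[big, ], solver = "simplex")
      if (lo$feasible && hi$feasible) {
        expect_gte(hi$flux, lo$flux - 1e-8)
      }
    }
  }
})

test_that("re-running with shifted thresholds keeps the intervention identities", {
  # perturbations along the saturating line (growth + product fractions
  # summing to one) keep the overproducer state pinned; the identified
  # reactions are unchanged even though the imposed levels move
  m <- canonical_toy()
  base <- toy_pipeline(m, design_thresholds(0.2, 0.8), solver = "simplex")
  for (g in c(0.15, 0.25)) {
    alt <- toy_pipeline(m, design_thresholds(g, 1 - g), solver = "simplex")
    expect_identical(alt$candidates$reaction_id, base$candidates$reaction_id)
    expect_identical(alt$candidates$kind, base$candidates$kind)
    expect_setequal(alt$force$members[alt$force$minimal],
                    base$force$members[base$force$minimal])
  }
})
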