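test_that("model validation reports structural defects and passes fixtures", {
  m <- canonical_toy()
  expect_identical(nrow(validate_model(m)), 0L)

  bad <- m
  bad$reactions$R_trp$lower_bound <- 5
  bad$reactions$R_trp$upper_bound <- 1
  rep <- validate_model(bad)
  expect_identical(rep$kind, "reversed_bounds")

  bad2 <- m
  bad2$reactions$R_phe$gpr <- "(a and"
  rep2 <- validate_model(bad2)
  expect_identical(rep2$kind, "bad_gpr")
  expect_identical(rep2$id, "R_phe")

  bad3 <- m
  names(bad3$reactions$R_ent$stoichiometry)[1] <- "ghost_c"
  expect_identical(validate_model(bad3)$kind, "unresolved_metabolite")
})

test_that("JSON round trip is lossless and cross-format equal to SBML", {
  m <- canonical_toy()
  fj <- withr::local_tempfile(fileext = ".json")
  fx <- withr::local_tempfile(fileext = ".xml")
  write_json_model(m, fj)
  write_sbml(m, fx)
  mj <- read_json_model(fj)
  mx <- read_sbml(fx)
  for (m2 in list(mj, mx)) {
    expect_identical(reaction_ids(m2), reaction_ids(m))
    expect_equal(reaction_bounds(m2), reaction_bounds(m))
    expect_identical(m2$objective_id, m$objective_id)
    expect_setequal(m2$genes, m$genes)
    for (rid in reaction_ids(m)) {
      a <- m2$reactions[[rid]]$stoichiometry
      b <- m$reactions[[rid]]$stoichiometry
      expect_equal(a[order(names(a))], b[order(names(b))], info = rid)
    }
  }
  # GPR truth tables survive both formats over all gene assignments
  genes <- m$genes
  set.seed(11)
  for (rep in 1:20) {
    act <- stats::setNames(sample(c(TRUE, FALSE), length(genes), TRUE), genes)
    for (rid in c("R_trp", "R_phe", "R_chor")) {
      v0 <- gpr_eval(gpr_parse(m$reactions[[rid]]$gpr), act)
      expect_identical(gpr_eval(gpr_parse(mj$reactions[[rid]]$gpr), act), v0)
      expect_identical(gpr_eval(gpr_parse(mx$reactions[[rid]]$gpr), act), v0)
    }
  }
})

test_that("shipped fixtures load clean in both formats", {
  mj <- read_json_model(system.file("extdata", "toy_chor.json",
                                    package = "fluxforce"))
  mx <- read_sbml(system.file("extdata", "toy_chor.xml",
                              package = "fluxforce"))
  expect_identical(nrow(validate_model(mj)), 0L)
  expect_identical(nrow(validate_model(mx)), 0L)
  expect_identical(length(mj$reactions), length(mx$reactions))
})

test_that("malformed model files produce named errors", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x", metabolites = list(), reactions = list()),
                       f, auto_unbox = TRUE)
  expect_error(read_json_model(f), "no reactions")

  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model>", f2)
  expect_error(read_sbml(f2), "malformed")

  # undefined species reference names the offending reaction
  m <- canonical_toy()
  f3 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f3)
  txt <- readLines(f3)
  txt <- sub('species="M_ent_c" stoichiometry="1"',
             'species="M_ghost_c" stoichiometry="1"', txt)
  writeLines(txt, f3)
  expect_error(read_sbml(f3), "R_ent.*undefined|undefined.*ghost")
})

test_that("apply_medium closes unlisted uptakes, keeps secretion, idempotent", {
  m <- canonical_toy()
  m2 <- apply_medium(m, c(EX_glc = 10))
  expect_equal(m2$reactions$EX_glc$lower_bound, -10)
  expect_equal(m2$reactions$EX_glc$upper_bound, 1000)
  expect_equal(m2$reactions$EX_paf$lower_bound, 0)
  expect_identical(apply_medium(m2, c(EX_glc = 10)), m2)

  # empty medium: all uptakes closed, growth collapses to zero
  m0 <- apply_medium(m, stats::setNames(numeric(0), character(0)))
  expect_equal(fba(m0, solver = "simplex")$objective_value, 0)

  expect_error(apply_medium(m, c(R_chor = 5)), "not exchange")
  expect_error(apply_medium(m, c(EX_glc = -1)), ">= 0")
})

test_that("flux data tables parse, merge duplicates, reject conflicts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tlower\tupper",
               "R_a\t1\t5", "R_b\t0\t2", "R_c\t-3\t3"), f)
  fd <- read_flux_data(f)
  expect_identical(nrow(fd), 3L)

  writeLines(c("reaction_id\tlower\tupper",
               "R_a\t1\t5", "R_a\t3\t9"), f)
  fd2 <- read_flux_data(f)
  expect_equal(unlist(fd2[1, c("lower", "upper")], use.names = FALSE), c(3, 5))

  writeLines(c("reaction_id\tlower\tupper",
               "R_a\t1\t2", "R_a\t4\t5"), f)
  expect_error(read_flux_data(f), "empty intersection")

  writeLines(c("reaction_id\tlower\tupper", "R_a\t7\t2"), f)
  expect_error(read_flux_data(f), "row 1")

  writeLines("reaction_id\tlower\tupper", f)
  expect_error(read_flux_data(f), "empty")

  # unresolvable ids reported, not dropped silently
  fd3 <- canonical_flux_data()
  fd3 <- rbind(fd3, data.frame(reaction_id = "NOPE", lower = 0, upper = 1))
  expect_warning(res <- resolve_flux_data(fd3, canonical_toy()), "NOPE")
  expect_identical(attr(res, "unresolved"), "NOPE")
})
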