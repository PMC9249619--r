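test_that("GPR parsing handles precedence, case and parentheses", {
  t1 <- gpr_parse("(b1263 and b1264) or b0123")
  expect_identical(t1$op, "or")
  expect_setequal(gpr_genes(t1), c("b1263", "b1264", "b0123"))

  # and binds tighter than or, case-insensitive keywords
  t2 <- gpr_parse("a AND b OR c")
  expect_identical(t2$op, "or")
  expect_identical(gpr_deparse(t2), "(a and b) or c")

  expect_null(gpr_parse(""))
  expect_null(gpr_parse("   "))
  expect_error(gpr_parse("(a and"), "paren|end")
  expect_error(gpr_parse("a and or b"), "unexpected")
  expect_error(gpr_parse("a b"), "trailing")
})

test_that("GPR evaluation implements isozyme/complex semantics", {
  tr <- gpr_parse("(g1 and g2) or g3")
  expect_true(gpr_eval(tr, c(g1 = TRUE, g2 = TRUE, g3 = FALSE)))
  expect_true(gpr_eval(tr, c(g1 = FALSE, g3 = TRUE)))
  expect_false(gpr_eval(tr, c(g1 = FALSE, g3 = FALSE)))
  # unmentioned genes default to present
  expect_true(gpr_eval(tr, c(g3 = FALSE)))
  # empty rule is always available
  expect_true(gpr_eval(NULL, c(g1 = FALSE)))
})

test_that("deparse round-trips the truth table on random rules", {
  genes <- paste0("g", 1:4)
  set.seed(7)
  rand_tree <- function(depth) {
    if (depth == 0 || stats::runif(1) < 0.35) {
      return(list(op = "gene", gene = sample(genes, 1)))
    }
    list(op = sample(c("and", "or"), 1),
         args = lapply(seq_len(sample(2:3, 1)), function(i) rand_tree(depth - 1)))
  }
  assignments <- expand.grid(rep(list(c(TRUE, FALSE)), length(genes)))
  names(assignments) <- genes
  for (rep in 1:25) {
    tr <- rand_tree(2)
    tr2 <- gpr_parse(gpr_deparse(tr))
    for (i in seq_len(nrow(assignments))) {
      act <- unlist(assignments[i, ])
      expect_identical(gpr_eval(tr, act), gpr_eval(tr2, act))
    }
  }
})

test_that("minimal falsifying and satisfying sets match the field arithmetic", {
  # isozymes: both genes must be removed -> one two-gene set
  expect_identical(gpr_minimal_falsifying_sets(gpr_parse("pheA or tyrA")),
                   list(c("pheA", "tyrA")))
  # complex: either subunit suffices
  expect_identical(gpr_minimal_falsifying_sets(gpr_parse("trpA1 and trpA2")),
                   list("trpA1", "trpA2"))
  # mixed: exhaustive truth-table falsification
  expect_identical(gpr_minimal_falsifying_sets(gpr_parse("(a and b) or c")),
                   list(c("a", "c"), c("b", "c")))
  # upregulation side: minimal sufficient gene sets
  expect_identical(gpr_minimal_satisfying_sets(gpr_parse("(a and b) or c")),
                   list("c", c("a", "b")))
  expect_error(gpr_minimal_falsifying_sets(NULL), "no gene association")
})
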