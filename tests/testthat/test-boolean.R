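test_that("the marked-set DNF has exactly the marked satisfying assignments", {
  e <- dnf_from_marked(c("0000", "0001", "0100"), c("A", "B", "C", "D"))
  expect_setequal(satisfying_set(e), c("0000", "0001", "0100"))

  e1 <- dnf_from_marked("1", "A")
  expect_equal(format_boolexpr(e1), "A")

  set.seed(31)
  for (trial in 1:10) {
    marked <- random_bitstrings(4, sample(1:10, 1))
    e <- dnf_from_marked(marked, c("A", "B", "C", "D"))
    expect_setequal(satisfying_set(e), marked)
  }
})

test_that("minimization factors the three-minterm example into ~A & ~C & (~B | ~D)", {
  e <- dnf_from_marked(c("0000", "0001", "0100"), c("A", "B", "C", "D"))
  s <- simplify_expr(e)
  expect_equal(format_boolexpr(s), "~A & ~C & (~B | ~D)")
  expect_setequal(satisfying_set(s), c("0000", "0001", "0100"))
})

test_that("minimization preserves the satisfying set and never adds literals", {
  count_lits <- function(x) qpatent:::count_literals(x$root)
  # single minterm stays itself
  e <- dnf_from_marked("101", c("A", "B", "C"))
  expect_equal(format_boolexpr(simplify_expr(e)), "A & ~B & C")

  # the full cube collapses to TRUE
  all8 <- vapply(0:7, qpatent:::int_to_bits, character(1), width = 3)
  e <- dnf_from_marked(all8, c("A", "B", "C"))
  expect_equal(format_boolexpr(simplify_expr(e)), "TRUE")

  set.seed(37)
  for (trial in 1:20) {
    marked <- random_bitstrings(4, sample(1:12, 1))
    e <- dnf_from_marked(marked, c("A", "B", "C", "D"))
    s <- simplify_expr(e)
    expect_setequal(satisfying_set(s), marked)
    expect_lte(count_lits(s), count_lits(e))
    # deterministic output
    expect_equal(format_boolexpr(simplify_expr(e)), format_boolexpr(s))
  }
})

test_that("expression text round trips through the parser", {
  for (txt in c("~A & ~C & (~B | ~D)", "A", "~B", "A & B | C",
                "(A | ~B) & C")) {
    e <- parse_boolexpr(txt)
    expect_equal(format_boolexpr(parse_boolexpr(format_boolexpr(e))),
                 format_boolexpr(e))
  }
  expect_error(parse_boolexpr("A & (B"), "unbalanced")
})

test_that("compiled expression circuits compute the indicator and clean their scratch", {
  # the factored example: one scratch qubit for the OR clause
  e <- parse_boolexpr("~A & ~C & (~B | ~D)", variables = c("A", "B", "C", "D"))
  circ <- circuit_from_expr(e)
  expect_equal(circ$n_ancilla, 2L) # target + one scratch
  for (x in 0:15) {
    bits <- qpatent:::int_to_bits(x, 4)
    want <- as.integer(eval_expr(e, bits))
    expect_equal(oracle_indicator(circ, x, 4L), want, info = bits)
  }

  # constant true: a single X on the target
  ct <- circuit_from_expr(parse_boolexpr("TRUE", variables = "A"))
  expect_equal(vapply(ct$gates, `[[`, character(1), "kind"), "X")

  # random supported forms over three variables
  set.seed(41)
  vars <- c("A", "B", "C")
  # distinct variables within each product/clause so controls stay distinct
  rand_lits <- function(k) {
    paste0(sample(c("", "~"), k, replace = TRUE), sample(vars, k))
  }
  for (trial in 1:10) {
    form <- sample(c("term", "clause", "andof", "sop"), 1)
    txt <- switch(form,
      term = paste(rand_lits(2), collapse = " & "),
      clause = paste(rand_lits(2), collapse = " | "),
      andof = {
        l <- rand_lits(3)
        paste0(l[1], " & (", l[2], " | ", l[3], ")")
      },
      sop = {
        l <- rand_lits(3)
        paste0(l[1], " & ", l[2], " | ", l[3])
      })
    e <- parse_boolexpr(txt, variables = vars)
    circ <- circuit_from_expr(e)
    for (x in 0:7) {
      bits <- qpatent:::int_to_bits(x, 3)
      expect_equal(oracle_indicator(circ, x, 3L),
                   as.integer(eval_expr(e, bits)), info = paste(txt, bits))
    }
  }
})

test_that("compressed and uncompressed oracles are equivalent, the compressed one smaller", {
  marked <- c("0000", "0001", "0100")
  plain <- build_patent_oracle(marked, 4L, n_ancilla = 1L)$circuit
  e <- simplify_expr(dnf_from_marked(marked, c("A", "B", "C", "D")))
  compressed <- circuit_from_expr(e)
  expect_true(oracles_equivalent(plain, compressed, 4L))

  n1 <- sum(count_gates(decompose_circuit(plain)))
  n2 <- sum(count_gates(decompose_circuit(compressed)))
  expect_lte(n2, n1)
})

test_that("oracle equivalence distinguishes different marked sets", {
  a <- build_patent_oracle(c("00", "11"), 2L, n_ancilla = 1L)$circuit
  b <- build_patent_oracle("00", 2L, n_ancilla = 1L)$circuit
  expect_true(oracles_equivalent(a, a, 2L))
  expect_false(oracles_equivalent(a, b, 2L))
  expect_error(oracles_equivalent(a, b, 11L), "too large")
})
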