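test_that("mark_state flips the ancilla exactly on its bitstring", {
  # "010": X conjugation on the first and third data qubits (the zero bits)
  circ <- mark_state("010", 3L, n_ancilla = 1L)
  xq <- vapply(Filter(function(g) g$kind == "X", circ$gates),
               function(g) g$qubits, integer(1))
  expect_equal(sort(unique(xq)), c(0L, 2L))
  for (x in 0:7) {
    expect_equal(oracle_indicator(circ, x, 3L), as.integer(x == 2L),
                 info = paste("x =", x))
  }

  # all-ones needs no X conjugation
  circ <- mark_state("111", 3L, n_ancilla = 1L)
  expect_equal(sum(vapply(circ$gates, function(g) g$kind == "X", logical(1))), 0L)
  expect_equal(oracle_indicator(circ, 7L, 3L), 1L)
})

test_that("patent oracles compute the marked-set indicator", {
  o <- build_patent_oracle(c("11", "00"), 2L)
  for (x in 0:3) {
    expect_equal(oracle_indicator(o$circuit, x, 2L),
                 as.integer(x %in% c(0L, 3L)))
  }

  empty <- build_patent_oracle(character(0), n_data = 2L)
  expect_equal(length(empty$circuit$gates), 0L)

  set.seed(5)
  for (trial in 1:5) {
    marked <- random_bitstrings(4, sample(1:6, 1))
    o <- build_patent_oracle(marked, 4L)
    idx <- vapply(marked, function(b) strtoi(b, base = 2), numeric(1))
    for (x in 0:15) {
      expect_equal(oracle_indicator(o$circuit, x, 4L),
                   as.integer(x %in% idx))
    }
  }
  expect_error(build_patent_oracle(c("01", "001")), "one width")
})

test_that("the intersection oracle is the (-1)^[x in M and K] diagonal with clean ancillas", {
  om <- build_patent_oracle(c("11", "00"), 2L)
  ok <- build_patent_oracle("00", 3L)
  io <- build_intersection_oracle(om, ok)
  expect_equal(io$marked_intersection, "00")
  U <- ref_circuit_unitary(io$circuit)
  # restricted to data x ancilla |00>, diagonal -1 only on |00>
  for (x in 0:3) {
    col <- U[, x * 4 + 1L]
    expect_equal(Mod(col[x * 4 + 1L]), 1, tolerance = 1e-9)
    expect_equal(Re(col[x * 4 + 1L]), ifelse(x == 0, -1, 1), tolerance = 1e-9)
  }

  set.seed(11)
  for (trial in 1:8) {
    m <- random_bitstrings(4, sample(0:8, 1))
    k <- random_bitstrings(4, sample(0:8, 1))
    om <- build_patent_oracle(m, 4L, n_data = 4L)
    ok <- build_patent_oracle(k, 5L, n_data = 4L)
    io <- build_intersection_oracle(om, ok)
    expect_setequal(io$marked_intersection, intersect(m, k))
    both <- vapply(intersect(m, k), function(b) strtoi(b, 2), numeric(1))
    n <- 6L
    for (x in 0:15) {
      out <- amps(simulate(io$circuit, basis_state(n, x * 4L)))
      i <- which.max(Mod(out))
      expect_equal(i - 1L, x * 4L)              # diagonal, ancillas at |00>
      expect_equal(out[i], complex(real = ifelse(x %in% both, -1, 1)),
                   tolerance = 1e-9)
    }
  }
})

test_that("the intersection oracle is self-inverse", {
  om <- build_patent_oracle(c("101", "010"), 3L)
  ok <- build_patent_oracle(c("010", "111"), 4L)
  io <- build_intersection_oracle(om, ok)
  twice <- concat_circuits(io$circuit, io$circuit)
  U <- ref_circuit_unitary(twice)
  expect_lt(max(Mod(U - diag(2^5))), 1e-9)
})

test_that("oracle construction validates registers", {
  om <- build_patent_oracle("00", 2L)
  ok3 <- build_patent_oracle("000", 3L)
  expect_error(build_intersection_oracle(om, ok3), "different data-register")
  ok_same <- build_patent_oracle("01", 2L)
  expect_error(build_intersection_oracle(om, ok_same), "distinct target")
})

test_that("uncompute_garbage leaves ancillas clean and copies f(x)", {
  # V_f = identity: f = 0, g = 0 on registers x=q0, f=q1, g=q2
  vf <- circuit(3, 0L, list())
  u <- uncompute_garbage(vf, 1L, 2L, 3L)
  out <- amps(simulate(u, basis_state(4, 8L))) # x = 1
  expect_equal(which.max(Mod(out)) - 1L, 8L)      # |1,0,0,0>

  # V_f: CNOT x->f and CNOT x->g computes f(x)=x with garbage g(x)=x
  vf <- circuit(3, 0L, list(gate_cnot(0, 1), gate_cnot(0, 2)))
  u <- uncompute_garbage(vf, 1L, 2L, 3L)
  for (x in 0:1) {
    out <- amps(simulate(u, basis_state(4, x * 8L)))
    expect_equal(which.max(Mod(out)) - 1L, x * 8L + x) # |x,0,0,f(x)=x>
  }

  # random classical reversible computations on a 2-bit input:
  # x = q0 q1, f = q2, g = q3, out = q4
  set.seed(23)
  for (trial in 1:5) {
    gates <- lapply(1:6, function(i) {
      pick <- sample(3, 1)
      if (pick == 1) gate_x(sample(2:3, 1))
      else if (pick == 2) gate_cnot(sample(0:1, 1), sample(2:3, 1))
      else gate_mcx(0:1, sample(2:3, 1))
    })
    vf <- circuit(4, 0L, gates)
    # keep only computations with f and g starting from |00>
    u <- uncompute_garbage(vf, 2L, 3L, 4L)
    for (x in 0:3) {
      out <- amps(simulate(u, basis_state(5, x * 8L)))
      i <- which.max(Mod(out)) - 1L
      expect_equal(Mod(out[i + 1L]), 1, tolerance = 1e-9)
      expect_equal(bitwShiftR(i, 3L), x)        # data unchanged
      expect_equal(bitwAnd(i, 6L), 0L)          # f and garbage back to zero
      # the copied bit matches what V_f alone computes
      vout <- amps(simulate(vf, basis_state(4, x * 4L)))
      fx <- bitwAnd(bitwShiftR(which.max(Mod(vout)) - 1L, 1L), 1L)
      expect_equal(bitwAnd(i, 1L), fx)
    }
  }

  expect_error(uncompute_garbage(vf, 2L, 3L, 3L), "match the f register|overlap")
})
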