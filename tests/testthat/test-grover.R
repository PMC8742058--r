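test_that("diffusion reflects about the uniform state", {
  for (n in 2:3) {
    N <- 2^n
    U <- ref_circuit_unitary(diffusion(n))
    s <- rep(1 / sqrt(N), N)
    target <- 2 * (s %o% s) - diag(N)
    expect_lt(phase_dist(U, target), 1e-9)

    # |s> is fixed (up to phase); orthogonal states are negated
    out <- U %*% s
    expect_lt(phase_dist(as.complex(out), as.complex(s)), 1e-9)
    v <- c(1, -1, rep(0, N - 2)) / sqrt(2)
    expect_lt(phase_dist(as.complex(U %*% v), as.complex(-v)), 1e-9)
  }
})

test_that("the iteration count follows the standard schedule", {
  expect_equal(iteration_count(4, 1), 1L)
  expect_equal(iteration_count(256, 2), 8L)
  expect_equal(iteration_count(16, 16), 0L)
  expect_equal(iteration_count(1024, 1), 25L)
  expect_error(iteration_count(8, 0), "M must")
  expect_error(iteration_count(8, 9), "M must")
})

grover_amp <- function(n_data, marked) {
  om <- build_patent_oracle(marked, n_data)
  ok <- build_patent_oracle(marked, n_data + 1L)
  io <- build_intersection_oracle(om, ok)
  plan <- grover_plan(n_data, length(marked))
  list(res = run_grover(io, plan, shots = 64, seed = 1), plan = plan)
}

test_that("two data qubits with one marked state reach certainty in one iteration", {
  g <- grover_amp(2L, "00")
  expect_equal(g$plan$k, 1L)
  expect_equal(g$res$data_probabilities[1], 1, tolerance = 1e-9)
})

test_that("k = 0 leaves the uniform distribution", {
  om <- build_patent_oracle("000", 3L)
  ok <- build_patent_oracle("000", 4L)
  io <- build_intersection_oracle(om, ok)
  res <- run_grover(io, grover_plan(3L, 1L, k = 0L), shots = 32, seed = 2)
  expect_equal(res$data_probabilities, rep(1 / 8, 8), tolerance = 1e-12)
})

test_that("final amplitudes match the closed form sin((2k+1) theta)/sqrt(M)", {
  set.seed(53)
  for (n_data in c(2L, 3L, 5L, 8L)) {
    N <- 2^n_data
    for (M in c(1L, 2L, 4L)) {
      if (M > N) next
      marked <- vapply(sample(0:(N - 1L), M), qpatent:::int_to_bits,
                       character(1), width = n_data)
      g <- grover_amp(n_data, marked)
      theta <- asin(sqrt(M / N))
      want <- sin((2 * g$plan$k + 1) * theta) / sqrt(M)
      for (b in marked) {
        x <- strtoi(b, 2)
        amp <- g$res$amplitudes[x * 4L + 1L]
        expect_equal(Mod(amp), abs(want), tolerance = 1e-9,
                     info = paste(n_data, M, b))
      }
      # success probability at the scheduled k is at least 1 - M/N
      succ <- sum(g$res$data_probabilities[vapply(marked, strtoi, numeric(1),
                                                  base = 2) + 1L])
      expect_gte(succ, 1 - M / N - 1e-9)
      # ancillas never end excited
      anc <- g$res$probabilities[bitwAnd(0:(4 * N - 1L), 3L) != 0L]
      expect_lt(sum(anc), 1e-12)
    }
  }
})

test_that("sampling is reproducible, conserving and statistically sound", {
  p <- c(0, 1, 0, 0)
  expect_equal(sample_counts(p, 100, seed = 9), c(0L, 100L, 0L, 0L))

  p <- rep(0.25, 4)
  a <- sample_counts(p, 1024, seed = 4)
  b <- sample_counts(p, 1024, seed = 4)
  expect_identical(a, b)
  expect_equal(sum(a), 1024L)

  big <- sample_counts(p, 1e5, seed = 5)
  sigma <- sqrt(1e5 * 0.25 * 0.75)
  expect_true(all(abs(big - 25000) < 5 * sigma))

  expect_error(sample_counts(c(0.5, 0.4), 10), "sum to 1")
})

test_that("the worked patent pair recovers CCCO and OCCC at states 2 and 128", {
  pm <- markush_patent("CC{R1}", rules = list(R1 = c("CO", "OC")))
  pk <- markush_patent("O{R2}", rules = list(R2 = c("CCC", "CCO", "COO")))
  cmp <- compare_patents(pm, pk, table = co_code_table(), shots = 1024,
                         seed = 3)
  expect_false(cmp$no_solution)
  expect_equal(cmp$overlap_indices, c(2L, 128L))
  expect_setequal(cmp$overlap_compounds, c("CCCO", "OCCC"))

  # swapping the patents leaves the verified overlap unchanged
  cmp2 <- compare_patents(pk, pm, table = co_code_table(), shots = 1024,
                          seed = 3)
  expect_equal(cmp2$overlap_compounds, cmp$overlap_compounds)

  rep <- comparison_report(cmp)
  expect_equal(nrow(rep), 256L)
  expect_equal(sum(rep$verified_overlap), 2L)
  expect_equal(rep$decoded_smiles[rep$basis_index == 2], "CCCO")
  expect_equal(sum(rep$counts), 1024L)
})

test_that("identical single-compound patents amplify that compound to near certainty", {
  p <- markush_patent("CC{R1}", rules = list(R1 = "CO"))
  cmp <- compare_patents(p, p, table = co_code_table(), seed = 1)
  expect_setequal(cmp$overlap_compounds, c("CCCO", "OCCC"))
  expect_gte(sum(cmp$data_probabilities[cmp$overlap_indices + 1L]), 0.9)
})

test_that("disjoint patents report no solution", {
  pm <- markush_patent("{R1}", rules = list(R1 = "CC"))
  pk <- markush_patent("{R1}", rules = list(R1 = "OO"))
  cmp <- compare_patents(pm, pk, table = co_code_table(), seed = 8)
  expect_true(cmp$no_solution)
  expect_equal(length(cmp$overlap_compounds), 0L)
})

test_that("ten repeated sampled correct-fractions straddle the exact probability", {
  g <- grover_amp(3L, c("001", "110"))
  pstar <- sum(g$res$data_probabilities[c(1, 6) + 1L])
  shots <- 1024L
  fr <- vapply(1:10, function(r) {
    cts <- sample_counts(g$res$data_probabilities, shots, seed = 100 + r)
    sum(cts[c(1, 6) + 1L]) / shots
  }, numeric(1))
  se <- sqrt(pstar * (1 - pstar) / (10 * shots))
  expect_lt(abs(mean(fr) - pstar), 3 * se + 1e-12)
})
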