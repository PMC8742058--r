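#' Grover diffusion operator
#'
#' Reflection about the uniform superposition of the data register:
#' Hadamards and X gates on every data qubit conjugating a multi-controlled
#' Z. Equals `2|s><s| - I` up to global phase; ancillas are untouched.
#'
#' @param n_data Number of data qubits.
#' @param n_ancilla Ancillas present in the register (gates act on data
#'   qubits only).
#' @return A `quantum_circuit`.
#' @export
diffusion <- function(n_data, n_ancilla = 0L) {
  stopifnot(n_data >= 1)
  dq <- 0:(n_data - 1L)
  hs <- lapply(dq, gate_h)
  xs <- lapply(dq, gate_x)
  mid <- if (n_data == 1) list(gate_z(0L)) else list(gate_mcz(dq))
  circuit(n_data, n_ancilla, c(hs, xs, mid, xs, hs))
}

#' Grover iteration count
#'
#' The standard schedule `k = floor((pi/4) sqrt(N/M))` for `M` solutions in
#' a search space of size `N`; `k` falls back to 0 whenever the uniform
#' state's success probability already meets or exceeds the post-iteration
#' value (e.g. when every state is a solution).
#'
#' @param N Search-space size.
#' @param M Number of solutions (`1 <= M <= N`).
#' @return Integer iteration count.
#' @examples
#' iteration_count(4, 1)   # 1
#' iteration_count(256, 2) # 8
#' @export
iteration_count <- function(N, M) {
  stopifnot(N >= 1)
  if (M < 1 || M > N) {
    stop("M must satisfy 1 <= M <= N (the no-solution case is handled by ",
         "the comparison pipeline)")
  }
  theta <- asin(sqrt(M / N))
  k <- floor((pi / 4) * sqrt(N / M))
  if (sin((2 * k + 1) * theta)^2 < M / N) k <- 0
  as.integer(k)
}

#' Plan a Grover run
#' @param n_data Data-register width; the search space has `N = 2^n_data`
#'   states.
#' @param M Number of solutions.
#' @param k Iteration count; defaults to [iteration_count()].
#' @return A `grover_plan`.
#' @export
grover_plan <- function(n_data, M, k = NULL) {
  N <- 2^n_data
  if (is.null(k)) k <- iteration_count(N, M)
  structure(list(n_data = as.integer(n_data), N = N, M = as.integer(M),
                 k = as.integer(k)),
            class = "grover_plan")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Sample measurement counts from a probability distribution
#'
#' Multinomial draw over basis states, reproducible for a given seed.
#' @param probabilities Numeric vector summing to 1.
#' @param shots Number of shots.
#' @param seed Optional integer seed.
#' @return Integer vector of counts (same length, sums to `shots`).
#' @export
sample_counts <- function(probabilities, shots, seed = NULL) {
  if (abs(sum(probabilities) - 1) > 1e-8) stop("probabilities must sum to 1")
  probabilities <- pmax(probabilities, 0)
  with_seed(seed, as.integer(stats::rmultinom(1, shots, probabilities)))
}

#' Run Grover amplitude amplification around an intersection oracle
#'
#' Initializes the data register in the uniform superposition (H on every
#' data qubit), applies `k` repetitions of oracle + diffusion, and returns
#' the exact final amplitudes plus seeded sampled counts of the data
#' register.
#'
#' @param oracle An `intersection_oracle` (or any phase-oracle
#'   `quantum_circuit` whose ancillas start and end in zero).
#' @param plan A `grover_plan` matching the oracle's data register.
#' @param shots Shots to sample (default 1024).
#' @param seed Optional integer seed for sampling.
#' @return A `grover_result` with the final `state`, full-register
#'   `probabilities`, `data_probabilities`, Table-style `state_index`
#'   (ancilla bits as the most significant digits, so ancilla-excited states
#'   land at indices `>= 2^n_data`), sampled `counts`, and the `plan`.
#' @export
run_grover <- function(oracle, plan, shots = 1024L, seed = NULL) {
  circ <- if (inherits(oracle, "intersection_oracle")) oracle$circuit else oracle
  stopifnot(inherits(circ, "quantum_circuit"))
  if (circ$n_data != plan$n_data) stop("oracle register does not match plan")
  n <- n_qubits(circ)
  nd <- circ$n_data
  na <- circ$n_ancilla
  state <- basis_state(n)
  for (q in 0:(nd - 1L)) state <- apply_gate(state, gate_h(q))
  diff_gates <- diffusion(nd, na)$gates
  if (plan$k > 0) {
    for (rep in seq_len(plan$k)) {
      for (g in circ$gates) state <- apply_gate(state, g)
      for (g in diff_gates) state <- apply_gate(state, g)
    }
  }
  probs <- state_probabilities(state)
  dprobs <- data_probabilities(state, nd)
  counts <- sample_counts(dprobs, shots, seed)
  # internal index is data*2^na + anc; reported index puts ancillas on top
  idx <- 0:(2^n - 1L)
  state_index <- bitwAnd(idx, 2^na - 1L) * 2^nd + bitwShiftR(idx, na)
  structure(list(state = state, amplitudes = unclass(state),
                 probabilities = probs, data_probabilities = dprobs,
                 state_index = state_index, counts = counts,
                 shots = as.integer(shots), plan = plan),
            class = "grover_result")
}

#' Assemble the full Grover search circuit
#'
#' Initial Hadamards on the data register followed by `k` repetitions of
#' oracle + diffusion, as a single circuit (useful for export and noisy
#' simulation).
#'
#' @param oracle An `intersection_oracle` or phase-oracle `quantum_circuit`.
#' @param plan A `grover_plan`.
#' @param include_init Include the initial Hadamard layer (default TRUE).
#' @return A `quantum_circuit`.
#' @export
grover_circuit <- function(oracle, plan, include_init = TRUE) {
  circ <- if (inherits(oracle, "intersection_oracle")) oracle$circuit else oracle
  nd <- circ$n_data
  gates <- if (include_init) lapply(0:(nd - 1L), gate_h) else list()
  step <- c(circ$gates, diffusion(nd, circ$n_ancilla)$gates)
  for (i in seq_len(plan$k)) gates <- c(gates, step)
  circuit(nd, circ$n_ancilla, gates)
}

#' @export
print.grover_result <- function(x, ...) {
  cat("Grover search result: N =", x$plan$N, ", M =", x$plan$M,
      ", k =", x$plan$k, "\n")
  top <- order(x$data_probabilities, decreasing = TRUE)
  top <- top[x$data_probabilities[top] > 1.5 / x$plan$N]
  top <- utils::head(top, 8)
  for (i in top) {
    cat(sprintf("  |%d> P = %.4f\n", i - 1L, x$data_probabilities[i]))
  }
  invisible(x)
}

expand_claims <- function(claims, table) {
  unique(unlist(lapply(claims, function(s) {
    tryCatch(alternative_notations(s, table = table),
             error = function(e) s)
  }), use.names = FALSE))
}

#' Compare two Markush patents by quantum search
#'
#' End-to-end pipeline: enumerate both claim languages, close them under
#' alternative linear notations, encode every compound as a basis state with
#' a shared maximum length, build the two membership oracles and the
#' intersection oracle, amplify with the standard Grover schedule (the
#' solution count is taken from the classical enumerations), and decode the
#' high-probability measured states, keeping exactly those verified to lie
#' in both claim sets.
#'
#' @param patent_m,patent_k `markush_patent` objects.
#' @param table Optional `code_table`; by default one is built over the
#'   symbols occurring in the enumerated claims.
#' @param shots Shots for sampling (default 1024).
#' @param seed Optional seed for sampling.
#' @param max_len Symbol budget per compound; defaults to the longest claim
#'   across both patents.
#' @param limit Enumeration cap per patent.
#' @return A `patent_comparison` with the verified `overlap_compounds`,
#'   their `overlap_indices`, a `no_solution` flag, the underlying
#'   `grover_result` (NULL when no solution exists), the code `table`,
#'   `max_len` and both encoded claim sets.
#' @export
compare_patents <- function(patent_m, patent_k, table = NULL, shots = 1024L,
                            seed = NULL, max_len = NULL, limit = 1e5L) {
  claims_m <- enumerate_claims(patent_m, limit)
  claims_k <- enumerate_claims(patent_k, limit)
  if (is.null(table)) {
    syms <- sort(unique(unlist(strsplit(c(claims_m, claims_k), ""))))
    table <- build_code_table(syms)
  }
  claims_m <- expand_claims(claims_m, table)
  claims_k <- expand_claims(claims_k, table)
  tok_len <- function(s) length(tokenize_smiles(s, table))
  if (is.null(max_len)) {
    max_len <- max(vapply(c(claims_m, claims_k), tok_len, integer(1)))
  }
  enc <- function(claims) {
    vapply(claims, function(s) encode_smiles(s, table, max_len)$bitstring,
           character(1))
  }
  marked_m <- enc(claims_m)
  marked_k <- enc(claims_k)
  n_data <- max_len * table$bits_per_symbol
  if (n_data + 2L > MAX_QUBITS) {
    stop("comparison needs ", n_data + 2L, " qubits, above the simulator cap")
  }
  inter <- intersect(marked_m, marked_k)
  M <- length(inter)
  N <- 2^n_data
  if (M == 0) {
    # no solution: nothing to amplify; uniform outcome, no candidate verifies
    dprobs <- rep(1 / N, N)
    counts <- sample_counts(dprobs, shots, seed)
    res <- NULL
    candidates <- integer(0)
  } else {
    om <- build_patent_oracle(unname(marked_m), n_data, n_ancilla = 2L)
    ok <- build_patent_oracle(unname(marked_k), n_data + 1L, n_ancilla = 2L)
    io <- build_intersection_oracle(om, ok)
    res <- run_grover(io, grover_plan(n_data, M), shots, seed)
    dprobs <- res$data_probabilities
    counts <- res$counts
    candidates <- which(dprobs >= 1 / N - 1e-9) - 1L
  }
  overlap <- character(0)
  overlap_idx <- integer(0)
  for (x in candidates) {
    bits <- int_to_bits(x, n_data)
    smi <- tryCatch(decode_bitstring(bits, table), error = function(e) NULL)
    if (is.null(smi)) next
    if ((bits %in% marked_m) && (bits %in% marked_k)) {
      overlap <- c(overlap, smi)
      overlap_idx <- c(overlap_idx, x)
    }
  }
  o <- order(overlap_idx)
  structure(list(overlap_compounds = overlap[o],
                 overlap_indices = overlap_idx[o],
                 no_solution = (M == 0), grover = res,
                 data_probabilities = dprobs, counts = counts,
                 table = table, max_len = max_len,
                 marked_m = sort(unname(marked_m)),
                 marked_k = sort(unname(marked_k)),
                 n_data = n_data),
            class = "patent_comparison")
}

#' @export
print.patent_comparison <- function(x, ...) {
  if (x$no_solution) {
    cat("No overlapping compounds (empty claim intersection).\n")
  } else {
    cat("Verified overlapping compounds:\n")
    for (i in seq_along(x$overlap_compounds)) {
      cat(sprintf("  |%d>  %s\n", x$overlap_indices[i], x$overlap_compounds[i]))
    }
  }
  invisible(x)
}

#' Tabulate a patent comparison for reporting
#'
#' One row per data basis state: index, bitstring, decoded SMILES (NA when
#' the bit pattern is not a valid padded encoding), final amplitude
#' magnitude, probability, sampled counts and the verified-overlap flag.
#'
#' @param cmp A `patent_comparison`.
#' @return A data frame.
#' @export
comparison_report <- function(cmp) {
  stopifnot(inherits(cmp, "patent_comparison"))
  N <- 2^cmp$n_data
  idx <- 0:(N - 1L)
  bits <- vapply(idx, int_to_bits, character(1), width = cmp$n_data)
  smi <- vapply(bits, function(b) {
    tryCatch(decode_bitstring(b, cmp$table), error = function(e) NA_character_)
  }, character(1))
  if (is.null(cmp$grover)) {
    amps <- rep(1 / sqrt(N), N)
  } else {
    # amplitude of each data state with the ancillas at |00>
    amps <- Mod(cmp$grover$amplitudes[idx * 4L + 1L])
  }
  data.frame(basis_index = idx, bitstring = bits, decoded_smiles = unname(smi),
             amplitude = amps, probability = cmp$data_probabilities,
             counts = cmp$counts,
             verified_overlap = idx %in% cmp$overlap_indices,
             stringsAsFactors = FALSE)
}
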