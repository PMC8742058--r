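#' Mark a single basis state into an ancilla
#'
#' X-conjugated multi-controlled X: X gates on every data qubit whose bit is
#' 0, an MCX with all data qubits as controls onto the target ancilla, then
#' the X gates again. The ancilla flips exactly when the data register
#' equals `bits`.
#'
#' @param bits Bitstring of width `n_data` identifying the state.
#' @param target_ancilla Absolute qubit index of the indicator ancilla
#'   (defaults to the first ancilla, `nchar(bits)`).
#' @param n_ancilla Ancilla count of the register (default 2, matching the
#'   intersection layout).
#' @return A `quantum_circuit` over `n_data + n_ancilla` qubits.
#' @export
mark_state <- function(bits, target_ancilla = nchar(bits), n_ancilla = 2L) {
  if (!grepl("^[01]+$", bits)) stop("`bits` must be a non-empty bitstring")
  n_data <- nchar(bits)
  if (target_ancilla < n_data || target_ancilla >= n_data + n_ancilla) {
    stop("target ancilla must lie in the ancilla register")
  }
  b <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
  zeros <- which(b == 0L) - 1L
  xs <- lapply(zeros, gate_x)
  gates <- c(xs,
             list(gate_mcx(0:(n_data - 1L), target_ancilla)),
             xs)
  circuit(n_data, n_ancilla, gates)
}

#' Build a patent-membership oracle
#'
#' Concatenates one [mark_state()] block per marked bitstring (in
#' lexicographic order, for determinism) so the circuit computes
#' `|x>|a> -> |x>|a XOR f(x)>` where `f(x) = 1` iff `x` is in `marked`.
#'
#' @param marked Character vector of bitstrings, all of one width (may be
#'   empty, giving the identity circuit — then `n_data` must be supplied).
#' @param target_ancilla Absolute qubit index of the indicator ancilla.
#' @param n_data Data-register width; inferred from `marked` when omitted.
#' @param n_ancilla Ancilla count of the register (default 2).
#' @return A `patent_oracle` with fields `marked`, `target_ancilla`,
#'   `n_data`, `circuit`.
#' @export
build_patent_oracle <- function(marked, target_ancilla = NULL, n_data = NULL,
                                n_ancilla = 2L) {
  marked <- sort(unique(as.character(marked)))
  if (length(marked) > 0) {
    w <- unique(nchar(marked))
    if (length(w) != 1) stop("marked bitstrings must share one width")
    if (is.null(n_data)) n_data <- w
    if (n_data != w) stop("marked width ", w, " does not match n_data ", n_data)
  } else if (is.null(n_data)) {
    stop("`n_data` is required when `marked` is empty")
  }
  if (is.null(target_ancilla)) target_ancilla <- n_data
  blocks <- lapply(marked, mark_state, target_ancilla = target_ancilla,
                   n_ancilla = n_ancilla)
  circ <- circuit(n_data, n_ancilla,
                  do.call(c, c(lapply(blocks, `[[`, "gates"), list(list()))))
  structure(list(marked = marked, target_ancilla = as.integer(target_ancilla),
                 n_data = as.integer(n_data), circuit = circ),
            class = "patent_oracle")
}

#' Join two patent oracles into a phase intersection oracle
#'
#' Runs both membership oracles, applies a controlled-Z between the two
#' indicator ancillas (phase kickback: a -1 phase lands exactly on states
#' marked by both patents; the controlled-Z in place of a Toffoli saves one
#' qubit), then reverses both oracles so the ancillas return to `|00>` on
#' every basis state.
#'
#' @param oracle_m,oracle_k `patent_oracle` objects over the same data
#'   register with distinct target ancillas.
#' @return An `intersection_oracle` with fields `circuit`,
#'   `marked_intersection`, `n_data`.
#' @export
build_intersection_oracle <- function(oracle_m, oracle_k) {
  stopifnot(inherits(oracle_m, "patent_oracle"),
            inherits(oracle_k, "patent_oracle"))
  if (oracle_m$n_data != oracle_k$n_data) {
    stop("the two oracles act on different data-register widths")
  }
  if (oracle_m$target_ancilla == oracle_k$target_ancilla) {
    stop("the two oracles must use distinct target ancillas")
  }
  cm <- oracle_m$circuit; ck <- oracle_k$circuit
  if (n_qubits(cm) != n_qubits(ck)) stop("oracle registers differ in size")
  gates <- c(cm$gates, ck$gates,
             list(gate_cz(oracle_m$target_ancilla, oracle_k$target_ancilla)),
             inverse(ck)$gates, inverse(cm)$gates)
  structure(
    list(circuit = circuit(cm$n_data, cm$n_ancilla, gates),
         marked_intersection = intersect(oracle_m$marked, oracle_k$marked),
         n_data = oracle_m$n_data),
    class = "intersection_oracle"
  )
}

#' Copy-then-uncompute pattern for garbage registers
#'
#' Given a reversible computation `V_f |x,0,0> = |x,f(x),g(x)>`, returns the
#' circuit `|x,0,0,0> -> |x,0,0,f(x)>`: run `V_f`, CNOT-copy the f register
#' onto the out register bitwise, then run the inverse of `V_f` so both the
#' f register and the garbage register return to zero for every input.
#'
#' @param compute_circuit A `quantum_circuit` implementing `V_f`.
#' @param f_register Qubit indices holding `f(x)` after `V_f`.
#' @param garbage_register Qubit indices of the temporary workspace.
#' @param out_register Fresh qubit indices receiving the copy of `f(x)`;
#'   must be disjoint from the compute circuit's register and match
#'   `f_register` in length.
#' @return A `quantum_circuit` over the extended register.
#' @export
uncompute_garbage <- function(compute_circuit, f_register, garbage_register,
                              out_register) {
  stopifnot(inherits(compute_circuit, "quantum_circuit"))
  f_register <- as.integer(f_register)
  garbage_register <- as.integer(garbage_register)
  out_register <- as.integer(out_register)
  if (length(out_register) != length(f_register)) {
    stop("out register must match the f register in width")
  }
  nc <- n_qubits(compute_circuit)
  if (any(out_register < nc)) {
    stop("out register overlaps the compute circuit's register")
  }
  if (length(intersect(out_register, c(f_register, garbage_register))) > 0) {
    stop("registers overlap")
  }
  total <- max(nc, max(out_register) + 1L)
  copy <- mapply(gate_cnot, f_register, out_register, SIMPLIFY = FALSE)
  circuit(total, 0L,
          c(compute_circuit$gates, copy, inverse(compute_circuit)$gates))
}
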