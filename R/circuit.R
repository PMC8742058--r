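#' Quantum gates
#'
#' Gate constructors for the circuit model. Qubits are indexed from 0;
#' qubit 0 is the most significant bit of the basis-state index, so the
#' register read left to right matches the encoding module's big-endian
#' bitstrings. For controlled kinds, controls precede the target.
#'
#' @param q,q1,q2,control,target,controls,qubits Qubit indices (0-based).
#' @param matrix Unitary matrix for `gate_u` (2^k x 2^k for k qubits).
#' @return A `quantum_gate`.
#' @name gates
NULL

new_gate <- function(kind, qubits, matrix = NULL) {
  qubits <- as.integer(qubits)
  if (anyDuplicated(qubits)) stop("gate qubits must be distinct")
  structure(list(kind = kind, qubits = qubits, matrix = matrix),
            class = "quantum_gate")
}

#' @rdname gates
#' @export
gate_h <- function(q) new_gate("H", q)

#' @rdname gates
#' @export
gate_x <- function(q) new_gate("X", q)

#' @rdname gates
#' @export
gate_z <- function(q) new_gate("Z", q)

#' @rdname gates
#' @export
gate_cnot <- function(control, target) new_gate("CNOT", c(control, target))

#' @rdname gates
#' @export
gate_cz <- function(q1, q2) new_gate("CZ", c(q1, q2))

#' @rdname gates
#' @export
gate_mcx <- function(controls, target) new_gate("MCX", c(controls, target))

#' @rdname gates
#' @export
gate_mcz <- function(qubits) new_gate("MCZ", qubits)

#' @rdname gates
#' @export
gate_u <- function(matrix, qubits) {
  k <- length(qubits)
  if (!is.matrix(matrix) || any(dim(matrix) != 2^k)) {
    stop("matrix must be ", 2^k, " x ", 2^k, " for ", k, " qubit(s)")
  }
  dev <- max(Mod(Conj(t(matrix)) %*% matrix - diag(2^k)))
  if (dev > 1e-10) stop("matrix is not unitary (deviation ", signif(dev, 3), ")")
  new_gate("U", qubits, matrix)
}

MAX_QUBITS <- 14L

#' Build a quantum circuit
#'
#' An ordered gate list over `n_data` data qubits followed by `n_ancilla`
#' ancilla qubits. Dense statevector simulation caps the register at 14
#' qubits.
#'
#' @param n_data Number of data qubits.
#' @param n_ancilla Number of ancilla qubits.
#' @param gates List of `quantum_gate` objects.
#' @return A `quantum_circuit`.
#' @export
circuit <- function(n_data, n_ancilla = 0L, gates = list()) {
  n <- as.integer(n_data) + as.integer(n_ancilla)
  if (n < 1) stop("circuit needs at least one qubit")
  if (n > MAX_QUBITS) {
    stop("register of ", n, " qubits exceeds the dense-simulation cap of ",
         MAX_QUBITS)
  }
  if (inherits(gates, "quantum_gate")) gates <- list(gates)
  for (g in gates) {
    if (!inherits(g, "quantum_gate")) stop("gates must be quantum_gate objects")
    if (any(g$qubits < 0 | g$qubits >= n)) {
      stop("gate addresses qubit outside [0, ", n, ")")
    }
  }
  structure(list(n_data = as.integer(n_data),
                 n_ancilla = as.integer(n_ancilla), gates = gates),
            class = "quantum_circuit")
}

n_qubits <- function(circ) circ$n_data + circ$n_ancilla

#' @export
print.quantum_circuit <- function(x, ...) {
  cat("Quantum circuit: ", x$n_data, " data + ", x$n_ancilla,
      " ancilla qubits, ", length(x$gates), " gates\n", sep = "")
  invisible(x)
}

#' Concatenate circuits over the same register
#' @param ... `quantum_circuit` objects with equal register sizes.
#' @return A `quantum_circuit`.
#' @export
concat_circuits <- function(...) {
  cs <- list(...)
  base <- cs[[1]]
  for (cc in cs[-1]) {
    if (cc$n_data != base$n_data || cc$n_ancilla != base$n_ancilla) {
      stop("register sizes differ")
    }
  }
  circuit(base$n_data, base$n_ancilla, do.call(c, lapply(cs, `[[`, "gates")))
}

#' Computational basis statevector
#' @param n_qubits Register size.
#' @param index Basis-state index (0-based, qubit 0 most significant).
#' @return A `statevector` (complex vector of length `2^n_qubits`).
#' @export
basis_state <- function(n_qubits, index = 0) {
  amp <- complex(2^n_qubits)
  amp[index + 1] <- 1 + 0i
  structure(amp, n_qubits = as.integer(n_qubits), class = "statevector")
}

qubit_weight <- function(n, q) bitwShiftL(1L, n - 1L - as.integer(q))

#' Apply one gate to a statevector
#'
#' The gate's unitary acts on its named qubits and the identity elsewhere.
#' @param state A `statevector`.
#' @param gate A `quantum_gate`.
#' @return The new `statevector`.
#' @export
apply_gate <- function(state, gate) {
  n <- attr(state, "n_qubits")
  if (any(gate$qubits < 0 | gate$qubits >= n)) {
    stop("gate addresses qubit outside [0, ", n, ")")
  }
  amp <- unclass(state)
  N <- length(amp)
  i <- 0:(N - 1L)
  k <- gate$kind
  if (k %in% c("H", "X", "Z")) {
    w <- qubit_weight(n, gate$qubits[1])
    i0 <- i[bitwAnd(i, w) == 0L] + 1L
    i1 <- i0 + w
    if (k == "X") {
      tmp <- amp[i0]; amp[i0] <- amp[i1]; amp[i1] <- tmp
    } else if (k == "Z") {
      amp[i1] <- -amp[i1]
    } else {
      s <- 1 / sqrt(2)
      a0 <- amp[i0]; a1 <- amp[i1]
      amp[i0] <- s * (a0 + a1)
      amp[i1] <- s * (a0 - a1)
    }
  } else if (k %in% c("CNOT", "MCX")) {
    nq <- length(gate$qubits)
    wt <- qubit_weight(n, gate$qubits[nq])
    cm <- sum(vapply(gate$qubits[-nq], qubit_weight, integer(1), n = n))
    sel <- i[bitwAnd(i, cm) == cm & bitwAnd(i, wt) == 0L]
    i0 <- sel + 1L; i1 <- i0 + wt
    tmp <- amp[i0]; amp[i0] <- amp[i1]; amp[i1] <- tmp
  } else if (k %in% c("CZ", "MCZ")) {
    m <- sum(vapply(gate$qubits, qubit_weight, integer(1), n = n))
    sel <- i[bitwAnd(i, m) == m] + 1L
    amp[sel] <- -amp[sel]
  } else if (k == "U") {
    qs <- gate$qubits
    kq <- length(qs)
    ws <- vapply(qs, qubit_weight, integer(1), n = n)
    offsets <- vapply(0:(2^kq - 1L), function(m) {
      sum(ws[bitwAnd(bitwShiftR(m, (kq - 1L):0L), 1L) == 1L])
    }, integer(1))
    gm <- sum(ws)
    rest <- i[bitwAnd(i, gm) == 0L]
    idx <- outer(rest, offsets, `+`) + 1L
    A <- matrix(amp[idx], nrow = length(rest))
    amp[idx] <- A %*% t(gate$matrix)
  } else {
    stop("unknown gate kind: ", k)
  }
  structure(amp, n_qubits = n, class = "statevector")
}

#' Simulate a circuit exactly
#'
#' Applies the gates left to right to `initial` (all-zeros basis state by
#' default) and returns the exact final statevector. Deterministic.
#'
#' @param circ A `quantum_circuit`.
#' @param initial Optional `statevector` of matching register size.
#' @return The final `statevector`.
#' @export
simulate <- function(circ, initial = NULL) {
  n <- n_qubits(circ)
  state <- if (is.null(initial)) basis_state(n) else initial
  if (attr(state, "n_qubits") != n) stop("register sizes disagree")
  for (g in circ$gates) state <- apply_gate(state, g)
  state
}

#' Invert a circuit
#'
#' Reverses the gate order and replaces each gate with its adjoint (the
#' complex conjugate transpose applied in reverse order), so a circuit
#' followed by its inverse is the identity on every basis state.
#'
#' @param circ A `quantum_circuit`.
#' @return The inverse `quantum_circuit`.
#' @export
inverse <- function(circ) {
  stopifnot(inherits(circ, "quantum_circuit"))
  inv <- lapply(rev(circ$gates), function(g) {
    if (g$kind == "U") gate_u(Conj(t(g$matrix)), g$qubits) else g
  })
  circuit(circ$n_data, circ$n_ancilla, inv)
}

#' Tally gates of a decomposed circuit
#'
#' Counts single-qubit gates and CNOTs. Any undecomposed multi-qubit gate
#' (CZ, MCX, MCZ or a wide U) is rejected; run [decompose_circuit()] first.
#'
#' @param circ A `quantum_circuit`.
#' @return Named integer vector `c(single_qubit = ..., cnot = ...)`.
#' @export
count_gates <- function(circ) {
  single <- 0L; cnot <- 0L
  for (g in circ$gates) {
    if (g$kind %in% c("H", "X", "Z") ||
        (g$kind == "U" && length(g$qubits) == 1)) {
      single <- single + 1L
    } else if (g$kind == "CNOT") {
      cnot <- cnot + 1L
    } else {
      stop("undecomposed multi-qubit gate present: ", g$kind)
    }
  }
  c(single_qubit = single, cnot = cnot)
}

#' Measurement probabilities of a statevector
#' @param state A `statevector`.
#' @return Numeric vector of squared amplitude magnitudes (sums to 1).
#' @export
state_probabilities <- function(state) {
  p <- Mod(as.vector(unclass(state)))^2
  p / sum(p)
}

#' Marginal probabilities of the data register
#'
#' Sums probabilities over ancilla configurations for each data basis state.
#' @param state A `statevector` over `n_data + n_ancilla` qubits (data
#'   qubits first, i.e. most significant).
#' @param n_data Number of data qubits.
#' @return Numeric vector of length `2^n_data`.
#' @export
data_probabilities <- function(state, n_data) {
  n <- attr(state, "n_qubits")
  p <- state_probabilities(state)
  if (n == n_data) return(p)
  na <- n - n_data
  rowSums(matrix(p, nrow = 2^n_data, byrow = TRUE))
}
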