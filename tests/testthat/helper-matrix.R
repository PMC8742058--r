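# Independent brute-force oracle: full gate unitaries built directly from
# the gate definitions (kronecker embedding for one-qubit kinds, explicit
# bit-logic permutations/diagonals for the controlled kinds), never through
# the package's statevector kernel.

# amplitudes of a statevector as a bare complex vector
amps <- function(state) as.vector(unclass(state))

ID2 <- diag(2)
HMAT <- matrix(1 / sqrt(2) * c(1, 1, 1, -1), 2, 2)
XMAT <- matrix(c(0, 1, 1, 0), 2, 2)
ZMAT <- diag(c(1, -1))

ref_bit <- function(i, q, n) bitwAnd(bitwShiftR(i, n - 1L - q), 1L)

ref_embed_1q <- function(op, q, n) {
  mats <- rep(list(ID2), n)
  mats[[q + 1L]] <- op
  Reduce(kronecker, mats)
}

ref_gate_unitary <- function(gate, n) {
  N <- 2L^n
  k <- gate$kind
  qs <- gate$qubits
  if (k %in% c("H", "X", "Z")) {
    op <- switch(k, H = HMAT, X = XMAT, Z = ZMAT)
    return(ref_embed_1q(op, qs[1], n))
  }
  if (k == "U" && length(qs) == 1) return(ref_embed_1q(gate$matrix, qs, n))
  if (k %in% c("CNOT", "MCX")) {
    ctrl <- qs[-length(qs)]
    tgt <- qs[length(qs)]
    U <- matrix(0, N, N)
    for (x in 0:(N - 1L)) {
      fire <- all(vapply(ctrl, function(q) ref_bit(x, q, n) == 1L, logical(1)))
      y <- if (fire) bitwXor(x, bitwShiftL(1L, n - 1L - tgt)) else x
      U[y + 1L, x + 1L] <- 1
    }
    return(U)
  }
  if (k %in% c("CZ", "MCZ")) {
    d <- vapply(0:(N - 1L), function(x) {
      if (all(vapply(qs, function(q) ref_bit(x, q, n) == 1L, logical(1)))) -1 else 1
    }, numeric(1))
    return(diag(d))
  }
  if (k == "U") {
    kq <- length(qs)
    U <- matrix(0i, N, N)
    for (x in 0:(N - 1L)) {
      subx <- sum(vapply(seq_len(kq), function(j) {
        ref_bit(x, qs[j], n) * 2L^(kq - j)
      }, numeric(1)))
      for (suby in 0:(2^kq - 1L)) {
        y <- x
        for (j in seq_len(kq)) {
          bit <- bitwAnd(bitwShiftR(suby, kq - j), 1L)
          w <- bitwShiftL(1L, n - 1L - qs[j])
          y <- if (bit == 1L) bitwOr(y, w) else bitwAnd(y, bitwNot(w))
        }
        U[y + 1L, x + 1L] <- gate$matrix[suby + 1L, subx + 1L]
      }
    }
    return(U)
  }
  stop("unhandled kind in reference oracle: ", k)
}

ref_circuit_unitary <- function(circ) {
  n <- circ$n_data + circ$n_ancilla
  U <- diag(2L^n)
  for (g in circ$gates) U <- ref_gate_unitary(g, n) %*% U
  U
}

# distance up to one global phase, anchored at the largest entry of B
phase_dist <- function(A, B) {
  i <- which.max(Mod(B))
  ph <- A[i] / B[i]
  ph <- ph / Mod(ph)
  max(Mod(A - ph * B))
}

random_unitary_2 <- function() {
  m <- matrix(stats::rnorm(4), 2, 2) + 1i * matrix(stats::rnorm(4), 2, 2)
  qr.Q(qr(m))
}

random_circuit <- function(n, len) {
  gates <- lapply(seq_len(len), function(i) {
    kind <- sample(c("H", "X", "Z", "CNOT", "CZ", "MCX", "MCZ", "U1"), 1)
    qs <- sample(0:(n - 1L), min(n, sample(1:3, 1)))
    switch(kind,
      H = gate_h(qs[1]), X = gate_x(qs[1]), Z = gate_z(qs[1]),
      CNOT = if (n >= 2) gate_cnot(qs[1], qs[2] %||% ((qs[1] + 1) %% n))
             else gate_x(qs[1]),
      CZ = if (n >= 2 && length(qs) >= 2) gate_cz(qs[1], qs[2]) else gate_z(qs[1]),
      MCX = if (length(qs) >= 2) gate_mcx(qs[-length(qs)], qs[length(qs)])
            else gate_x(qs[1]),
      MCZ = gate_mcz(qs),
      U1 = gate_u(random_unitary_2(), qs[1])
    )
  })
  circuit(n, 0L, gates)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

random_bitstrings <- function(width, howmany) {
  unique(vapply(seq_len(howmany), function(i) {
    paste(sample(c("0", "1"), width, replace = TRUE), collapse = "")
  }, character(1)))
}

# indicator bit written by an oracle circuit on basis input x (ancillas 0)
oracle_indicator <- function(circ, x, ancilla) {
  n <- circ$n_data + circ$n_ancilla
  na <- circ$n_ancilla
  out <- amps(simulate(circ, basis_state(n, x * 2^na)))
  i <- which.max(Mod(out))
  expect_equal(Mod(out[i]), 1, tolerance = 1e-9)
  idx <- i - 1L
  bitwAnd(bitwShiftR(idx, n - 1L - ancilla), 1L)
}
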