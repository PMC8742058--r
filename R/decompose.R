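# Synthesis of multi-controlled gates into {single-qubit, CNOT}.
#
# Scheme: ZYZ-based controlled-U for one control, the textbook T-gate
# Toffoli for two, and above that the ancilla-free recursion
#   C^k(U) = C_{ck}(V) . C^{k-1}X . C_{ck}(V^dag) . C^{k-1}X . C^{k-1}(V)
# with V^2 = U. Gate counts grow ~3^k; fine at the register sizes the
# dense simulator supports.

rz_mat <- function(theta) {
  diag(c(exp(-1i * theta / 2), exp(1i * theta / 2)))
}

ry_mat <- function(theta) {
  matrix(c(cos(theta / 2), sin(theta / 2),
           -sin(theta / 2), cos(theta / 2)), 2, 2)
}

# U = exp(i alpha) Rz(beta) Ry(gamma) Rz(delta)
zyz_angles <- function(u) {
  alpha <- Arg(u[1, 1] * u[2, 2] - u[1, 2] * u[2, 1]) / 2
  v <- exp(-1i * alpha) * u
  gamma <- 2 * atan2(Mod(v[2, 1]), Mod(v[1, 1]))
  if (Mod(v[1, 1]) < 1e-12) {
    s <- Arg(v[2, 1]); beta <- s; delta <- -s
  } else if (Mod(v[2, 1]) < 1e-12) {
    s <- -Arg(v[1, 1]); beta <- s; delta <- s
  } else {
    sp <- -2 * Arg(v[1, 1]); sm <- 2 * Arg(v[2, 1])
    beta <- (sp + sm) / 2; delta <- (sp - sm) / 2
  }
  list(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
}

is_close <- function(a, b, tol = 1e-12) max(Mod(a - b)) < tol

# gates for U on `target` controlled by single `control`
controlled_u_gates <- function(control, target, u) {
  x_mat <- matrix(c(0, 1, 1, 0), 2, 2)
  if (is_close(u, x_mat, 1e-12)) return(list(gate_cnot(control, target)))
  ang <- zyz_angles(u)
  A <- rz_mat(ang$beta) %*% ry_mat(ang$gamma / 2)
  B <- ry_mat(-ang$gamma / 2) %*% rz_mat(-(ang$delta + ang$beta) / 2)
  C <- rz_mat((ang$delta - ang$beta) / 2)
  ph <- diag(c(1, exp(1i * ang$alpha)))
  out <- list()
  if (!is_close(C, diag(2))) out <- c(out, list(gate_u(C, target)))
  out <- c(out, list(gate_cnot(control, target)))
  if (!is_close(B, diag(2))) out <- c(out, list(gate_u(B, target)))
  out <- c(out, list(gate_cnot(control, target)))
  if (!is_close(A, diag(2))) out <- c(out, list(gate_u(A, target)))
  if (!is_close(ph, diag(2))) out <- c(out, list(gate_u(ph, control)))
  out
}

# principal square root of a 2x2 unitary
sqrtm2 <- function(u) {
  e <- eigen(u)
  v <- e$vectors
  v %*% diag(sqrt(e$values + 0i)) %*% solve(v)
}

t_mat <- function() diag(c(1, exp(1i * pi / 4)))
tdg_mat <- function() diag(c(1, exp(-1i * pi / 4)))

toffoli_gates <- function(a, b, t) {
  list(
    gate_h(t),
    gate_cnot(b, t), gate_u(tdg_mat(), t),
    gate_cnot(a, t), gate_u(t_mat(), t),
    gate_cnot(b, t), gate_u(tdg_mat(), t),
    gate_cnot(a, t), gate_u(t_mat(), b), gate_u(t_mat(), t),
    gate_h(t),
    gate_cnot(a, b), gate_u(t_mat(), a), gate_u(tdg_mat(), b),
    gate_cnot(a, b)
  )
}

mcu_gates <- function(controls, target, u) {
  k <- length(controls)
  x_mat <- matrix(c(0, 1, 1, 0), 2, 2)
  if (k == 0) return(list(gate_u(u, target)))
  if (k == 1) return(controlled_u_gates(controls, target, u))
  if (k == 2 && is_close(u, x_mat, 1e-12)) {
    return(toffoli_gates(controls[1], controls[2], target))
  }
  v <- sqrtm2(u)
  last <- controls[k]
  rest <- controls[-k]
  c(controlled_u_gates(last, target, v),
    mcu_gates(rest, last, x_mat),
    controlled_u_gates(last, target, Conj(t(v))),
    mcu_gates(rest, last, x_mat),
    mcu_gates(rest, target, v))
}

#' Decompose a multi-controlled X gate
#'
#' Returns an ancilla-free circuit over `n_controls + 1` qubits (controls
#' `0..n_controls-1`, target `n_controls`) using only single-qubit gates and
#' CNOT, whose composed unitary equals the multi-controlled X permutation up
#' to global phase.
#'
#' @param n_controls Number of control qubits (>= 1).
#' @return A `quantum_circuit`.
#' @export
decompose_mcx <- function(n_controls) {
  stopifnot(n_controls >= 1)
  x_mat <- matrix(c(0, 1, 1, 0), 2, 2)
  gates <- if (n_controls == 1) {
    list(gate_cnot(0, 1))
  } else {
    mcu_gates(0:(n_controls - 1L), n_controls, x_mat)
  }
  circuit(n_controls + 1L, 0L, gates)
}

remap_gates <- function(gates, mapping) {
  lapply(gates, function(g) new_gate(g$kind, mapping[g$qubits + 1L], g$matrix))
}

#' Decompose a circuit into single-qubit gates and CNOTs
#'
#' H, X, Z, CNOT and one-qubit U gates pass through; CZ, MCZ and MCX are
#' synthesized via [decompose_mcx()] (Z-type gates through Hadamard
#' conjugation of the last qubit). Multi-qubit U gates are rejected.
#'
#' @param circ A `quantum_circuit`.
#' @return An equivalent `quantum_circuit` (up to global phase) containing
#'   only single-qubit gates and CNOTs.
#' @export
decompose_circuit <- function(circ) {
  out <- list()
  for (g in circ$gates) {
    kq <- length(g$qubits)
    if (g$kind %in% c("H", "X", "Z", "CNOT") || (g$kind == "U" && kq == 1)) {
      out <- c(out, list(g))
    } else if (g$kind %in% c("CZ", "MCZ")) {
      if (kq == 1) { out <- c(out, list(gate_z(g$qubits))); next }
      t <- g$qubits[kq]
      inner <- if (kq == 2) {
        list(gate_cnot(g$qubits[1], t))
      } else {
        remap_gates(decompose_mcx(kq - 1L)$gates, g$qubits)
      }
      out <- c(out, list(gate_h(t)), inner, list(gate_h(t)))
    } else if (g$kind == "MCX") {
      out <- c(out, remap_gates(decompose_mcx(kq - 1L)$gates, g$qubits))
    } else {
      stop("cannot decompose multi-qubit U gate")
    }
  }
  circuit(circ$n_data, circ$n_ancilla, out)
}
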