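#' Construct a noise model
#'
#' Error channels mirroring a superconducting device: per-gate depolarizing
#' error (1- and 2-qubit rates), thermal relaxation over each gate's
#' duration governed by per-qubit T1/T2, and a readout bit-flip matrix.
#' Each family can be switched on/off and rescaled independently for
#' one-error-type-at-a-time scaling experiments.
#'
#' @param p_depol_1q,p_depol_2q Depolarizing probability per single-qubit /
#'   CNOT gate.
#' @param t1,t2 Relaxation and dephasing time constants (same time unit as
#'   `gate_durations`); must satisfy `t2 <= 2 * t1`.
#' @param gate_durations Named numeric vector of gate durations; names among
#'   `"1q"`, `"cnot"`.
#' @param readout 2x2 row-stochastic matrix: `readout[a + 1, b + 1]` is the
#'   probability of reading bit `b` given state `a`.
#' @param scale Named factors for families `thermal`, `depolarizing`,
#'   `readout` (1 = nominal). Scaling the thermal family scales the decay
#'   rates `1/t1`, `1/t2`; probabilities are clipped to `[0, 1]` with a
#'   warning if scaling pushes them out.
#' @return A `noise_model`.
#' @export
noise_model <- function(p_depol_1q = 0, p_depol_2q = 0,
                        t1 = Inf, t2 = Inf,
                        gate_durations = c("1q" = 50, cnot = 300),
                        readout = diag(2),
                        scale = c(thermal = 1, depolarizing = 1, readout = 1)) {
  readout <- as.matrix(readout)
  if (any(dim(readout) != 2) || any(abs(rowSums(readout) - 1) > 1e-9) ||
      any(readout < -1e-12)) {
    stop("readout must be a 2x2 row-stochastic matrix")
  }
  if (t2 > 2 * t1) stop("unphysical relaxation times: t2 > 2 * t1")
  sc <- c(thermal = 1, depolarizing = 1, readout = 1)
  sc[names(scale)] <- scale
  structure(list(p_depol_1q = p_depol_1q, p_depol_2q = p_depol_2q,
                 t1 = t1, t2 = t2, gate_durations = gate_durations,
                 readout = readout, scale = sc),
            class = "noise_model")
}

#' A synthetic device-like default noise model
#'
#' Plausible parameters at the scale of a small superconducting device
#' (times in nanoseconds). These values are synthetic defaults for
#' experimentation, not a calibration snapshot of any machine.
#' @return A `noise_model`.
#' @export
default_noise_model <- function() {
  noise_model(p_depol_1q = 0.002, p_depol_2q = 0.02,
              t1 = 60e3, t2 = 80e3,
              gate_durations = c("1q" = 50, cnot = 300),
              readout = matrix(c(0.97, 0.03, 0.03, 0.97), 2, 2, byrow = TRUE))
}

clip_prob <- function(p, what) {
  if (p < 0 || p > 1) {
    warning(what, " scaled outside [0,1]; clipped")
    p <- min(max(p, 0), 1)
  }
  p
}

scaled_params <- function(noise) {
  sc <- noise$scale
  ro <- noise$readout
  f <- sc[["readout"]]
  ro_sc <- matrix(c(1 - clip_prob(ro[1, 2] * f, "readout flip"),
                    clip_prob(ro[1, 2] * f, "readout flip"),
                    clip_prob(ro[2, 1] * f, "readout flip"),
                    1 - clip_prob(ro[2, 1] * f, "readout flip")),
                  2, 2, byrow = TRUE)
  list(p1 = clip_prob(noise$p_depol_1q * sc[["depolarizing"]], "p_depol_1q"),
       p2 = clip_prob(noise$p_depol_2q * sc[["depolarizing"]], "p_depol_2q"),
       t1 = noise$t1 / sc[["thermal"]],
       t2 = noise$t2 / sc[["thermal"]],
       readout = ro_sc)
}

# ---- density-matrix kernels --------------------------------------------------

pauli_1q <- list(
  I = diag(2),
  X = matrix(c(0, 1, 1, 0), 2, 2),
  Y = matrix(c(0, 1i, -1i, 0), 2, 2),
  Z = diag(c(1, -1))
)

embed_1q <- function(op, q, n) {
  mats <- rep(list(diag(2)), n)
  mats[[q + 1L]] <- op
  Reduce(kronecker, mats)
}

#' Density matrix of a pure state
#' @param state A `statevector`.
#' @return Complex matrix `|psi><psi|`.
#' @export
density_from_state <- function(state) {
  v <- as.complex(unclass(state))
  v %o% Conj(v)
}

check_density <- function(rho) {
  if (abs(sum(diag(rho)) - 1) > 1e-8) stop("density matrix trace is not 1")
  if (max(Mod(rho - Conj(t(rho)))) > 1e-8) stop("density matrix not Hermitian")
  invisible(rho)
}

#' Depolarizing channel
#'
#' With probability `p` the named qubits are replaced by the maximally mixed
#' state (implemented as the uniform Pauli twirl over those qubits, which
#' traces them out and re-inserts identity/2 per qubit); with probability
#' `1 - p` the state is untouched. Trace preserving.
#'
#' @param rho Density matrix over `n` qubits (dimension `2^n`).
#' @param p Depolarizing probability in `[0, 1]`.
#' @param qubits Qubit indices the channel acts on.
#' @return The output density matrix.
#' @export
depolarizing_channel <- function(rho, p, qubits) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0) return(rho)
  n <- as.integer(round(log2(nrow(rho))))
  mix <- matrix(0, nrow(rho), ncol(rho))
  k <- length(qubits)
  combos <- expand.grid(rep(list(seq_along(pauli_1q)), k))
  for (r in seq_len(nrow(combos))) {
    op <- diag(2^n)
    for (j in seq_len(k)) {
      op <- op %*% embed_1q(pauli_1q[[combos[r, j]]], qubits[j], n)
    }
    mix <- mix + op %*% rho %*% Conj(t(op))
  }
  (1 - p) * rho + p * mix / 4^k
}

#' Thermal relaxation channel on one qubit
#'
#' Amplitude damping with probability `1 - exp(-duration/t1)` composed with
#' pure dephasing chosen so the off-diagonal elements scale by
#' `exp(-duration/t2)` overall. Requires `t2 <= 2 * t1`.
#'
#' @param rho Density matrix.
#' @param t1,t2 Time constants.
#' @param duration Gate duration (same unit).
#' @param qubit Qubit index (default 0; `rho` may be a single-qubit matrix).
#' @return The output density matrix.
#' @export
thermal_relaxation_channel <- function(rho, t1, t2, duration, qubit = 0L) {
  if (t2 > 2 * t1) stop("unphysical relaxation times: t2 > 2 * t1")
  stopifnot(duration >= 0)
  if (duration == 0 || (is.infinite(t1) && is.infinite(t2))) return(rho)
  n <- as.integer(round(log2(nrow(rho))))
  gam <- 1 - exp(-duration / t1)
  # extra dephasing beyond what amplitude damping already provides
  resid <- exp(-duration / t2 + duration / (2 * t1))
  pz <- (1 - resid) / 2
  k_ad <- list(matrix(c(1, 0, 0, sqrt(1 - gam)), 2, 2),
               matrix(c(0, 0, sqrt(gam), 0), 2, 2))
  k_pd <- list(sqrt(1 - pz) * diag(2), sqrt(pz) * pauli_1q$Z)
  kraus <- list()
  for (a in k_pd) for (b in k_ad) kraus <- c(kraus, list(a %*% b))
  out <- matrix(0, nrow(rho), ncol(rho))
  for (kk in kraus) {
    K <- embed_1q(kk, qubit, n)
    out <- out + K %*% rho %*% Conj(t(K))
  }
  out
}

#' Apply readout error to an outcome distribution
#'
#' Independent per-qubit classical bit-flip mixing: element `[a+1, b+1]` of
#' a qubit's matrix is the probability of reading `b` given true outcome
#' `a`. Total probability is conserved.
#'
#' @param probabilities Numeric vector over `2^q` outcomes (qubit 0 is the
#'   most significant bit).
#' @param readout A single 2x2 row-stochastic matrix (used for every qubit)
#'   or a list of one matrix per qubit.
#' @return Perturbed probability vector.
#' @export
apply_readout_error <- function(probabilities, readout) {
  N <- length(probabilities)
  q <- as.integer(round(log2(N)))
  mats <- if (is.list(readout)) readout else rep(list(as.matrix(readout)), q)
  if (length(mats) != q) stop("need one readout matrix per qubit")
  p <- probabilities
  i <- 0:(N - 1L)
  for (qq in seq_len(q) - 1L) {
    M <- mats[[qq + 1L]]
    if (any(abs(rowSums(M) - 1) > 1e-9)) stop("readout matrix not row-stochastic")
    w <- bitwShiftL(1L, q - 1L - qq)
    i0 <- i[bitwAnd(i, w) == 0L] + 1L
    i1 <- i0 + w
    p0 <- p[i0]; p1 <- p[i1]
    p[i0] <- M[1, 1] * p0 + M[2, 1] * p1
    p[i1] <- M[1, 2] * p0 + M[2, 2] * p1
  }
  p
}

full_gate_unitary <- function(gate, n) {
  N <- 2^n
  U <- matrix(0i, N, N)
  for (x in 0:(N - 1L)) {
    U[, x + 1L] <- unclass(apply_gate(basis_state(n, x), gate))
  }
  U
}

#' Noisy simulation of a circuit
#'
#' Density-matrix evolution: after each gate, depolarizing error at the 1- or
#' 2-qubit rate on the touched qubits, then thermal relaxation for the
#' gate's duration on each touched qubit. Readout error perturbs the final
#' data-register distribution before sampling. Idle-qubit relaxation is not
#' modeled. The register is capped at 7 qubits.
#'
#' @param circ A `quantum_circuit`; decomposed automatically to single-qubit
#'   gates and CNOTs if wider gates are present.
#' @param noise A `noise_model`.
#' @param shots Shots to sample.
#' @param seed Optional seed.
#' @param initial_h Apply Hadamards to the data register before the circuit
#'   (convenience for oracle circuits that assume a uniform start).
#' @return List with `counts` (data-register outcomes), `probabilities`
#'   (post-readout data distribution), `ideal_probabilities` and `rho`.
#' @export
simulate_noisy <- function(circ, noise, shots = 1024L, seed = NULL,
                           initial_h = FALSE) {
  stopifnot(inherits(circ, "quantum_circuit"), inherits(noise, "noise_model"))
  n <- n_qubits(circ)
  if (n > 7) stop("register too large for density-matrix mode (max 7 qubits)")
  gates <- circ$gates
  if (initial_h) gates <- c(lapply(0:(circ$n_data - 1L), gate_h), gates)
  needs_dec <- any(vapply(gates, function(g) {
    !(g$kind %in% c("H", "X", "Z", "CNOT") ||
        (g$kind == "U" && length(g$qubits) == 1))
  }, logical(1)))
  if (needs_dec) {
    gates <- decompose_circuit(circuit(circ$n_data, circ$n_ancilla, gates))$gates
  }
  par <- scaled_params(noise)
  dur <- noise$gate_durations
  rho <- density_from_state(basis_state(n))
  for (g in gates) {
    U <- full_gate_unitary(g, n)
    rho <- U %*% rho %*% Conj(t(U))
    two_q <- g$kind == "CNOT"
    p <- if (two_q) par$p2 else par$p1
    if (p > 0) rho <- depolarizing_channel(rho, p, g$qubits)
    d <- unname(if (two_q) dur["cnot"] else dur["1q"])
    if (is.finite(par$t1) || is.finite(par$t2)) {
      for (q in g$qubits) {
        rho <- thermal_relaxation_channel(rho, par$t1, par$t2, d, q)
      }
    }
  }
  pfull <- pmax(Re(diag(rho)), 0)
  pfull <- pfull / sum(pfull)
  nd <- circ$n_data
  pdata <- if (n == nd) pfull else {
    rowSums(matrix(pfull, nrow = 2^nd, byrow = TRUE))
  }
  pread <- apply_readout_error(pdata, par$readout)
  counts <- sample_counts(pread, shots, seed)
  list(counts = counts, probabilities = pread, ideal_probabilities = pdata,
       rho = rho)
}

family_only <- function(noise, family, factor) {
  sc <- c(thermal = 0, depolarizing = 0, readout = 0)
  sc[family] <- factor
  m <- noise
  if (sc[["thermal"]] == 0) { m$t1 <- Inf; m$t2 <- Inf; sc[["thermal"]] <- 1 }
  if (sc[["depolarizing"]] == 0) { m$p_depol_1q <- 0; m$p_depol_2q <- 0; sc[["depolarizing"]] <- 1 }
  if (sc[["readout"]] == 0) { m$readout <- diag(2); sc[["readout"]] <- 1 }
  m$scale <- sc
  m
}

#' One-error-type-at-a-time scaling experiment
#'
#' For a chosen error family, enables only that family, scales its
#' parameters by each factor, runs `repeats` sampled experiments of `shots`
#' shots, and reports the mean fraction of shots landing on the known
#' correct data-register outcomes with a 95% confidence interval over
#' repeats.
#'
#' @param circ Circuit under test (data register measured).
#' @param noise Base `noise_model`.
#' @param family One of `"thermal"`, `"depolarizing"`, `"readout"`.
#' @param correct_states Character vector of correct data-register
#'   bitstrings.
#' @param factors Scale factors (default `c(0.5, 1, 2)`).
#' @param shots,repeats Sampling protocol (defaults 1024 x 10).
#' @param seed Optional base seed; repeat `r` at factor index `i` uses
#'   `seed + 1000 * i + r`.
#' @param initial_h Passed to [simulate_noisy()].
#' @return Data frame with columns `family`, `factor`, `mean_correct`,
#'   `ci_lo`, `ci_hi`.
#' @export
error_scaling_experiment <- function(circ, noise, family, correct_states,
                                     factors = c(0.5, 1, 2), shots = 1024L,
                                     repeats = 10L, seed = NULL,
                                     initial_h = FALSE) {
  if (!family %in% c("thermal", "depolarizing", "readout")) {
    stop("unknown error family: ", family)
  }
  nd <- circ$n_data
  idx <- vapply(correct_states, bits_to_int, numeric(1)) + 1
  rows <- lapply(seq_along(factors), function(i) {
    m <- family_only(noise, family, factors[i])
    base <- simulate_noisy(circ, m, shots = shots,
                           seed = if (is.null(seed)) NULL else seed + 1000 * i,
                           initial_h = initial_h)
    fr <- vapply(seq_len(repeats), function(r) {
      cts <- sample_counts(base$probabilities, shots,
                           if (is.null(seed)) NULL else seed + 1000 * i + r)
      sum(cts[idx]) / shots
    }, numeric(1))
    mu <- mean(fr)
    half <- if (repeats > 1) {
      stats::qt(0.975, repeats - 1) * stats::sd(fr) / sqrt(repeats)
    } else 0
    data.frame(family = family, factor = factors[i], mean_correct = mu,
               ci_lo = mu - half, ci_hi = mu + half)
  })
  do.call(rbind, rows)
}

#' Read a noise model from a YAML config
#'
#' Keys: `t1`, `t2`, `p_depol_1q`, `p_depol_2q`, `gate_durations` (map),
#' `readout` (flat 2x2, row major), `scale` (map of family factors).
#' @param path File path.
#' @return A `noise_model`.
#' @export
read_noise_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  for (k in c("p_depol_1q", "p_depol_2q", "t1", "t2")) {
    if (!is.null(cfg[[k]])) args[[k]] <- cfg[[k]]
  }
  if (!is.null(cfg$gate_durations)) {
    args$gate_durations <- unlist(cfg$gate_durations)
  }
  if (!is.null(cfg$readout)) {
    args$readout <- matrix(unlist(cfg$readout), 2, 2, byrow = TRUE)
  }
  if (!is.null(cfg$scale)) args$scale <- unlist(cfg$scale)
  do.call(noise_model, args)
}
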