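#' Export a circuit to OpenQASM 2.0
#'
#' Supported kinds map to `h`, `x`, `z`, `cx`, `cz`, `ccx`; single-qubit U
#' gates are written as `u3` (ZYZ angles, global phase dropped); MCX/MCZ
#' gates with more than two controls are expanded with
#' [decompose_circuit()] before writing. The named gate set round-trips
#' bit-exactly through [read_qasm()].
#'
#' @param circ A `quantum_circuit`.
#' @param path Optional file path; when NULL the QASM text is returned.
#' @return The QASM text, invisibly when written to a file.
#' @export
write_qasm <- function(circ, path = NULL) {
  n <- n_qubits(circ)
  needs <- any(vapply(circ$gates, function(g) {
    (g$kind == "MCX" && length(g$qubits) > 3) ||
      (g$kind == "MCZ" && length(g$qubits) > 2) ||
      (g$kind == "U" && length(g$qubits) > 1)
  }, logical(1)))
  if (needs) circ <- decompose_circuit(circ)
  fmt_q <- function(qs) paste(sprintf("q[%d]", qs), collapse = ",")
  lines <- c("OPENQASM 2.0;", "include \"qelib1.inc\";",
             sprintf("qreg q[%d];", n))
  for (g in circ$gates) {
    qs <- g$qubits
    line <- switch(g$kind,
      H = sprintf("h %s;", fmt_q(qs)),
      X = sprintf("x %s;", fmt_q(qs)),
      Z = sprintf("z %s;", fmt_q(qs)),
      CNOT = sprintf("cx %s;", fmt_q(qs)),
      CZ = sprintf("cz %s;", fmt_q(qs)),
      MCX = if (length(qs) == 2) sprintf("cx %s;", fmt_q(qs))
            else sprintf("ccx %s;", fmt_q(qs)),
      MCZ = if (length(qs) == 1) sprintf("z %s;", fmt_q(qs))
            else sprintf("cz %s;", fmt_q(qs)),
      U = {
        a <- zyz_angles(g$matrix)
        sprintf("u3(%.17g,%.17g,%.17g) %s;", a$gamma, a$beta, a$delta,
                fmt_q(qs))
      },
      stop("cannot export gate kind ", g$kind)
    )
    lines <- c(lines, line)
  }
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(lines, path)
  invisible(text)
}

u3_matrix <- function(theta, phi, lambda) {
  matrix(c(cos(theta / 2), exp(1i * phi) * sin(theta / 2),
           -exp(1i * lambda) * sin(theta / 2),
           exp(1i * (phi + lambda)) * cos(theta / 2)), 2, 2)
}

#' Import an OpenQASM 2.0 circuit
#'
#' Accepts the gate subset written by [write_qasm()] (`h x z cx cz ccx u3`);
#' `creg`, `measure`, `barrier` and comments are ignored.
#'
#' @param path File path, or a character vector of QASM lines via `text`.
#' @param text Optional QASM text (overrides `path`).
#' @param n_data Data-qubit count of the resulting circuit; defaults to the
#'   full register (no ancillas).
#' @return A `quantum_circuit`.
#' @export
read_qasm <- function(path = NULL, text = NULL, n_data = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE))
  } else {
    readLines(path, warn = FALSE)
  }
  lines <- sub("//.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  n <- NA_integer_
  gates <- list()
  for (ln in lines) {
    if (grepl("^(OPENQASM|include|creg|barrier|measure)", ln)) next
    m <- regmatches(ln, regexec("^qreg\\s+\\w+\\[(\\d+)\\];$", ln))[[1]]
    if (length(m) == 2) { n <- as.integer(m[2]); next }
    m <- regmatches(ln, regexec(
      "^([a-z0-9]+)\\s*(\\(([^)]*)\\))?\\s+(.*);$", ln))[[1]]
    if (length(m) == 0) stop("cannot parse QASM line: ", ln)
    op <- m[2]; argstr <- m[4]; qstr <- m[5]
    qs <- as.integer(regmatches(qstr, gregexpr("(?<=\\[)\\d+(?=\\])", qstr,
                                               perl = TRUE))[[1]])
    g <- switch(op,
      h = gate_h(qs[1]), x = gate_x(qs[1]), z = gate_z(qs[1]),
      cx = gate_cnot(qs[1], qs[2]), cz = gate_cz(qs[1], qs[2]),
      ccx = gate_mcx(qs[1:2], qs[3]),
      u3 = {
        ang <- as.numeric(strsplit(argstr, ",", fixed = TRUE)[[1]])
        gate_u(u3_matrix(ang[1], ang[2], ang[3]), qs[1])
      },
      stop("unsupported QASM gate: ", op)
    )
    gates <- c(gates, list(g))
  }
  if (is.na(n)) stop("QASM input lacks a qreg declaration")
  if (is.null(n_data)) n_data <- n
  circuit(n_data, n - n_data, gates)
}
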