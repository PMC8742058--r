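#' Boolean expressions over named variables
#'
#' Lightweight AST used by the oracle-compression path: literals
#' (`variable` or `~variable`), AND, OR and constants. The printable dialect
#' is e.g. `~A & ~C & (~B | ~D)`, with `&` binding tighter than `|`.
#'
#' @param variables Ordered character vector of variable names; variable 1
#'   corresponds to the leftmost bit of a marked bitstring.
#' @param root AST node (internal representation).
#' @return A `boolean_expr`.
#' @keywords internal
new_boolean_expr <- function(variables, root) {
  structure(list(variables = variables, root = root), class = "boolean_expr")
}

lit_node <- function(var, neg) list(op = "lit", var = var, neg = neg)
and_node <- function(args) if (length(args) == 1) args[[1]] else list(op = "and", args = args)
or_node <- function(args) if (length(args) == 1) args[[1]] else list(op = "or", args = args)
const_node <- function(value) list(op = "const", value = value)

eval_node <- function(node, env) {
  switch(node$op,
    lit = if (node$neg) !env[[node$var]] else env[[node$var]],
    and = all(vapply(node$args, eval_node, logical(1), env = env)),
    or = any(vapply(node$args, eval_node, logical(1), env = env)),
    const = node$value,
    stop("bad node op ", node$op)
  )
}

#' Evaluate a Boolean expression on one assignment
#' @param expr A `boolean_expr`.
#' @param bits Bitstring assigning variables in order (1 = TRUE).
#' @return Logical scalar.
#' @export
eval_expr <- function(expr, bits) {
  v <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]]) == 1L
  if (length(v) != length(expr$variables)) stop("assignment width mismatch")
  eval_node(expr$root, stats::setNames(as.list(v), expr$variables))
}

#' Satisfying assignments of a Boolean expression
#' @param expr A `boolean_expr`.
#' @return Character vector of bitstrings (variable 1 leftmost), sorted.
#' @export
satisfying_set <- function(expr) {
  k <- length(expr$variables)
  if (k > 20) stop("too many variables for exhaustive evaluation")
  bits <- vapply(0:(2^k - 1), int_to_bits, character(1), width = k)
  bits[vapply(bits, function(b) eval_expr(expr, b), logical(1))]
}

#' Sum-of-products expression for a marked set
#'
#' One product term per marked bitstring, literal polarity taken from the
#' bit (0 gives the negated literal), so the satisfying set equals the
#' marked set exactly.
#'
#' @param marked Character vector of bitstrings of one width.
#' @param variables Variable names, one per bit position.
#' @return A `boolean_expr` in DNF.
#' @examples
#' e <- dnf_from_marked(c("0000", "0001", "0100"), c("A", "B", "C", "D"))
#' format_boolexpr(e)
#' @export
dnf_from_marked <- function(marked, variables) {
  marked <- sort(unique(as.character(marked)))
  variables <- as.character(variables)
  if (length(marked) == 0) return(new_boolean_expr(variables, const_node(FALSE)))
  if (any(nchar(marked) != length(variables))) {
    stop("bitstring width does not match the variable count")
  }
  terms <- lapply(marked, function(b) {
    v <- as.integer(strsplit(b, "", fixed = TRUE)[[1]])
    and_node(mapply(function(var, bit) lit_node(var, bit == 0L),
                    variables, v, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  })
  new_boolean_expr(variables, or_node(terms))
}

# ---- Quine-McCluskey ---------------------------------------------------------

# implicants as (value, mask): mask bits are don't-cares; bit 1 of value =
# uncomplemented variable; positions counted with variable 1 as the MSB
qm_primes <- function(minterms, k) {
  cur <- unique(data.frame(value = as.integer(minterms), mask = 0L))
  primes <- data.frame(value = integer(0), mask = integer(0))
  while (nrow(cur) > 0) {
    combined <- rep(FALSE, nrow(cur))
    nxt <- list()
    for (i in seq_len(nrow(cur))) {
      for (j in seq_len(nrow(cur))) {
        if (i >= j || cur$mask[i] != cur$mask[j]) next
        d <- bitwXor(cur$value[i], cur$value[j])
        if (sum(bitwAnd(bitwShiftR(d, 0:(k - 1)), 1L)) == 1L) {
          combined[i] <- TRUE; combined[j] <- TRUE
          nxt[[length(nxt) + 1]] <- c(bitwAnd(cur$value[i], bitwNot(d)),
                                      bitwOr(cur$mask[i], d))
        }
      }
    }
    primes <- rbind(primes, cur[!combined, , drop = FALSE])
    cur <- if (length(nxt) == 0) {
      data.frame(value = integer(0), mask = integer(0))
    } else {
      m <- unique(do.call(rbind, nxt))
      data.frame(value = m[, 1], mask = m[, 2])
    }
  }
  unique(primes)
}

implicant_pattern <- function(value, mask, k) {
  bits <- character(k)
  for (pos in seq_len(k)) {
    w <- bitwShiftL(1L, k - pos)
    bits[pos] <- if (bitwAnd(mask, w) != 0L) "-" else
      as.character(as.integer(bitwAnd(value, w) != 0L))
  }
  paste(bits, collapse = "")
}

implicant_covers <- function(value, mask, minterm) {
  bitwAnd(bitwXor(value, minterm), bitwNot(mask)) == 0L
}

qm_cover <- function(primes, minterms, k) {
  pat <- vapply(seq_len(nrow(primes)),
                function(i) implicant_pattern(primes$value[i], primes$mask[i], k),
                character(1))
  ord <- order(pat)
  primes <- primes[ord, , drop = FALSE]
  pat <- pat[ord]
  covers <- vapply(seq_len(nrow(primes)), function(i) {
    vapply(minterms, implicant_covers,
           logical(1), value = primes$value[i], mask = primes$mask[i])
  }, logical(length(minterms)))
  covers <- matrix(covers, nrow = length(minterms))
  chosen <- logical(nrow(primes))
  covered <- logical(length(minterms))
  # essential primes first
  for (m in seq_along(minterms)) {
    who <- which(covers[m, ])
    if (length(who) == 1) chosen[who] <- TRUE
  }
  covered <- apply(covers[, chosen, drop = FALSE], 1, any)
  while (!all(covered)) {
    gain <- vapply(seq_len(nrow(primes)), function(i) {
      if (chosen[i]) -1L else sum(covers[, i] & !covered)
    }, integer(1))
    pick <- which.max(gain) # ties: first in lexicographic pattern order
    chosen[pick] <- TRUE
    covered <- covered | covers[, pick]
  }
  primes[chosen, , drop = FALSE]
}

implicant_literals <- function(value, mask, variables) {
  k <- length(variables)
  lits <- list()
  for (pos in seq_len(k)) {
    w <- bitwShiftL(1L, k - pos)
    if (bitwAnd(mask, w) == 0L) {
      lits[[length(lits) + 1]] <- lit_node(variables[pos],
                                           bitwAnd(value, w) == 0L)
    }
  }
  lits
}

lit_key <- function(node) paste0(if (node$neg) "~" else "", node$var)

count_literals <- function(node) {
  switch(node$op,
    lit = 1L,
    const = 0L,
    sum(vapply(node$args, count_literals, integer(1)))
  )
}

#' Minimize a Boolean expression
#'
#' Quine-McCluskey prime-implicant computation, a deterministic
#' essential-then-greedy cover (ties broken lexicographically), and
#' shared-literal factoring of the resulting sum of products. The output is
#' logically equivalent to the input (identical satisfying set) with at most
#' the input's literal count; when every residual product is a single
#' literal the result takes the AND-of-clauses form that
#' [circuit_from_expr()] compiles with one scratch qubit per OR clause.
#'
#' @param expr A `boolean_expr`.
#' @return An equivalent, simplified `boolean_expr`.
#' @examples
#' e <- dnf_from_marked(c("0000", "0001", "0100"), c("A", "B", "C", "D"))
#' format_boolexpr(simplify_expr(e)) # "~A & ~C & (~B | ~D)"
#' @export
simplify_expr <- function(expr) {
  stopifnot(inherits(expr, "boolean_expr"))
  k <- length(expr$variables)
  sat <- satisfying_set(expr)
  if (length(sat) == 0) return(new_boolean_expr(expr$variables, const_node(FALSE)))
  if (length(sat) == 2^k) return(new_boolean_expr(expr$variables, const_node(TRUE)))
  minterms <- vapply(sat, bits_to_int, numeric(1))
  primes <- qm_primes(as.integer(minterms), k)
  cover <- qm_cover(primes, as.integer(minterms), k)
  terms <- lapply(seq_len(nrow(cover)), function(i) {
    implicant_literals(cover$value[i], cover$mask[i], expr$variables)
  })
  if (length(terms) == 1) {
    return(new_boolean_expr(expr$variables, and_node(terms[[1]])))
  }
  keys <- lapply(terms, function(t) vapply(t, lit_key, character(1)))
  common <- Reduce(intersect, keys)
  if (length(common) > 0) {
    residual <- lapply(seq_along(terms), function(i) {
      terms[[i]][!(keys[[i]] %in% common)]
    })
    common_lits <- terms[[1]][keys[[1]] %in% common]
    if (any(lengths(residual) == 0)) {
      # some product equals the common factor, which absorbs the rest
      return(new_boolean_expr(expr$variables, and_node(common_lits)))
    }
    if (all(lengths(residual) == 1)) {
      lits <- lapply(residual, `[[`, 1)
      lits <- lits[order(match(vapply(lits, `[[`, character(1), "var"),
                               expr$variables))]
      clause <- or_node(lits)
      return(new_boolean_expr(expr$variables,
                              and_node(c(common_lits, list(clause)))))
    }
  }
  new_boolean_expr(expr$variables,
                   or_node(lapply(terms, and_node)))
}

# ---- text format -------------------------------------------------------------

format_node <- function(node, in_and = FALSE) {
  switch(node$op,
    lit = paste0(if (node$neg) "~" else "", node$var),
    const = if (node$value) "TRUE" else "FALSE",
    and = paste(vapply(node$args, function(a) {
      s <- format_node(a, in_and = TRUE)
      if (a$op == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " & "),
    or = {
      s <- paste(vapply(node$args, format_node, character(1)), collapse = " | ")
      s
    }
  )
}

#' Print a Boolean expression in the `~A & (~B | ~D)` dialect
#' @param expr A `boolean_expr`.
#' @return Character scalar.
#' @export
format_boolexpr <- function(expr) format_node(expr$root)

#' @export
print.boolean_expr <- function(x, ...) {
  cat(format_boolexpr(x), "\n")
  invisible(x)
}

#' Parse the `~A & ~C & (~B | ~D)` dialect
#'
#' `&` binds tighter than `|`; `~` negates a variable or a parenthesized
#' group is not supported (negation applies to variables only, matching the
#' printer). Round trips with [format_boolexpr()].
#'
#' @param text Expression text.
#' @param variables Optional variable ordering; defaults to first-appearance
#'   order.
#' @return A `boolean_expr`.
#' @export
parse_boolexpr <- function(text, variables = NULL) {
  toks <- regmatches(text, gregexpr("[A-Za-z_][A-Za-z0-9_]*|[~&|()]", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else ""
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (peek() == "|") { take(); args <- c(args, list(parse_and())) }
    or_node(args)
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (peek() == "&") { take(); args <- c(args, list(parse_factor())) }
    and_node(args)
  }
  parse_factor <- function() {
    t <- take()
    if (t == "~") {
      v <- take()
      if (!grepl("^[A-Za-z_]", v)) stop("~ must precede a variable")
      return(lit_node(v, TRUE))
    }
    if (t == "(") {
      e <- parse_or()
      if (take() != ")") stop("unbalanced parentheses")
      return(e)
    }
    if (t == "TRUE") return(const_node(TRUE))
    if (t == "FALSE") return(const_node(FALSE))
    if (grepl("^[A-Za-z_]", t)) return(lit_node(t, FALSE))
    stop("unexpected token: ", t)
  }
  root <- parse_or()
  if (pos <= length(toks)) stop("trailing input after expression")
  if (is.null(variables)) {
    collect <- function(n) {
      switch(n$op, lit = n$var, const = character(0),
             unlist(lapply(n$args, collect)))
    }
    variables <- unique(collect(root))
  }
  new_boolean_expr(variables, root)
}

# ---- circuit synthesis -------------------------------------------------------

# literal controls: returns list(pre = X gates, controls = qubit indices)
term_controls <- function(lits, varpos) {
  pre <- list(); ctrl <- integer(0)
  for (l in lits) {
    q <- varpos[[l$var]]
    if (l$neg) pre <- c(pre, list(gate_x(q)))
    ctrl <- c(ctrl, q)
  }
  list(pre = pre, controls = ctrl)
}

# gates computing OR(lits) XOR'd into `target` (De Morgan via one MCX)
or_clause_gates <- function(lits, varpos, target) {
  pre <- list(); ctrl <- integer(0)
  for (l in lits) {
    q <- varpos[[l$var]]
    if (!l$neg) pre <- c(pre, list(gate_x(q))) # control on NOT(literal)
    ctrl <- c(ctrl, q)
  }
  c(pre, list(gate_mcx(ctrl, target), gate_x(target)), rev(pre))
}

norm_lits <- function(node) if (node$op == "lit") list(node) else node$args

#' Compile a simplified Boolean expression into an indicator circuit
#'
#' Produces a circuit computing `|x>|a> -> |x>|a XOR f(x)>` on the target
#' ancilla. Supported forms: a constant; a literal or product of literals
#' (X-conjugated MCX); an OR of literals (De Morgan); an AND of clauses,
#' each a literal or an OR of literals (one scratch qubit per OR clause,
#' computed, fed as an extra control, then uncomputed); and a sum of
#' products (one scratch per product, combined by De Morgan, all scratches
#' uncomputed).
#'
#' @param expr A `boolean_expr`, typically from [simplify_expr()].
#' @param target_ancilla Absolute index of the indicator ancilla; defaults
#'   to the first qubit after the data register.
#' @return A `quantum_circuit`; scratch ancillas (if any) follow the target.
#' @export
circuit_from_expr <- function(expr, target_ancilla = NULL) {
  stopifnot(inherits(expr, "boolean_expr"))
  k <- length(expr$variables)
  varpos <- stats::setNames(as.list(0:(k - 1L)), expr$variables)
  if (is.null(target_ancilla)) target_ancilla <- k
  root <- expr$root
  mk <- function(gates, n_scratch) {
    circuit(k, as.integer(target_ancilla - k + 1L + n_scratch), gates)
  }
  if (root$op == "const") {
    return(mk(if (root$value) list(gate_x(target_ancilla)) else list(), 0L))
  }
  is_lit_and <- root$op == "lit" ||
    (root$op == "and" && all(vapply(root$args, function(a) a$op == "lit", logical(1))))
  if (is_lit_and) {
    tc <- term_controls(norm_lits(root), varpos)
    return(mk(c(tc$pre, list(gate_mcx(tc$controls, target_ancilla)),
                rev(tc$pre)), 0L))
  }
  if (root$op == "or" &&
      all(vapply(root$args, function(a) a$op == "lit", logical(1)))) {
    return(mk(or_clause_gates(root$args, varpos, target_ancilla), 0L))
  }
  if (root$op == "and") {
    ok <- vapply(root$args, function(a) {
      a$op == "lit" || (a$op == "or" &&
        all(vapply(a$args, function(l) l$op == "lit", logical(1))))
    }, logical(1))
    if (!all(ok)) stop("unsupported expression form for circuit synthesis")
    lits <- Filter(function(a) a$op == "lit", root$args)
    ors <- Filter(function(a) a$op == "or", root$args)
    scratch <- target_ancilla + seq_along(ors)
    compute <- list()
    for (i in seq_along(ors)) {
      compute <- c(compute, or_clause_gates(ors[[i]]$args, varpos, scratch[i]))
    }
    tc <- term_controls(lits, varpos)
    # clause computations contain only self-inverse gates, so reversing the
    # list uncomputes the scratch qubits
    gates <- c(compute, tc$pre,
               list(gate_mcx(c(tc$controls, scratch), target_ancilla)),
               rev(tc$pre), rev(compute))
    return(mk(gates, length(ors)))
  }
  if (root$op == "or") {
    terms <- lapply(root$args, norm_lits)
    if (!all(vapply(unlist(terms, recursive = FALSE), function(l) l$op == "lit",
                    logical(1)))) {
      stop("unsupported expression form for circuit synthesis")
    }
    scratch <- target_ancilla + seq_along(terms)
    compute <- list()
    for (i in seq_along(terms)) {
      tc <- term_controls(terms[[i]], varpos)
      compute <- c(compute, tc$pre,
                   list(gate_mcx(tc$controls, scratch[i])), rev(tc$pre))
    }
    or_block <- c(lapply(scratch, gate_x),
                  list(gate_mcx(scratch, target_ancilla),
                       gate_x(target_ancilla)),
                  lapply(scratch, gate_x))
    return(mk(c(compute, or_block, rev(compute)), length(terms)))
  }
  stop("unsupported expression form for circuit synthesis")
}

#' Check two indicator oracles for equivalence on the data register
#'
#' Simulates both circuits on every data basis state with all ancillas at
#' zero and compares the indicator written to the first ancilla (and the
#' induced phases, up to one global phase). Ancillas beyond the indicator
#' must return to zero. Exhaustive, so the data register is capped at 10
#' qubits.
#'
#' @param a,b `quantum_circuit` objects whose first `n_data` qubits are the
#'   data register and whose qubit `n_data` is the indicator ancilla.
#' @param n_data Data-register width.
#' @return TRUE or FALSE.
#' @export
oracles_equivalent <- function(a, b, n_data) {
  if (n_data > 10) stop("data register too large for exhaustive comparison")
  probe <- function(circ) {
    n <- n_qubits(circ)
    na <- n - n_data
    out <- vector("list", 2^n_data)
    for (x in 0:(2^n_data - 1L)) {
      st <- simulate(circ, basis_state(n, x * 2^na))
      amp <- unclass(st)
      i <- which.max(Mod(amp))
      if (Mod(amp[i]) < 1 - 1e-8) return(NULL) # not a classical action
      idx <- i - 1L
      data_part <- bitwShiftR(idx, na)
      anc <- bitwAnd(idx, 2^na - 1L)
      f <- bitwAnd(bitwShiftR(anc, na - 1L), 1L) # first ancilla bit
      rest <- bitwAnd(anc, 2^(na - 1L) - 1L)
      if (data_part != x || (na > 1 && rest != 0L)) return(NULL)
      out[[x + 1L]] <- c(f = f, phase = amp[i])
    }
    list(f = vapply(out, function(o) Re(o["f"]), numeric(1)),
         phase = vapply(out, function(o) o["phase"], complex(1)))
  }
  pa <- probe(a); pb <- probe(b)
  if (is.null(pa) || is.null(pb)) return(FALSE)
  if (!all(pa$f == pb$f)) return(FALSE)
  rel <- pa$phase / pb$phase
  all(Mod(rel - rel[1]) < 1e-8)
}
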