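#' Build a fixed-width symbol code table
#'
#' Maps each SMILES symbol to a distinct bitstring of width
#' `ceil(log2(n_symbols + 1))`, reserving the all-ones code for the padding
#' ("empty") symbol used to right-pad short compounds. By default codes are
#' assigned in input order starting at zero; an explicit `codes` vector can
#' pin particular assignments (e.g. `C = "00"`, `O = "10"` with empty `11`,
#' the convention under which `"OCC"` encodes to `"10000011"`).
#'
#' @param symbols Character vector of distinct SMILES tokens. Tokens are
#'   usually single characters; multi-character tokens (e.g. `"Cl"`) are
#'   allowed and kept intact by the tokenizer.
#' @param codes Optional named character vector of bitstrings overriding the
#'   default assignment for some or all symbols. All given codes must share
#'   one width, which then fixes `bits_per_symbol`.
#' @param bits_per_symbol Optional integer forcing a wider code than the
#'   minimum.
#' @return An object of class `code_table` with fields `symbols`, `codes`
#'   (named character vector symbol -> bitstring), `bits_per_symbol` and
#'   `empty_code`.
#' @examples
#' tb <- build_code_table(c("C", "O"), codes = c(C = "00", O = "10"))
#' tb$empty_code # "11"
#' @export
build_code_table <- function(symbols, codes = NULL, bits_per_symbol = NULL) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0) stop("`symbols` must be non-empty")
  dup <- symbols[duplicated(symbols)]
  if (length(dup) > 0) {
    stop("duplicate symbol in code table: ", paste(unique(dup), collapse = ", "))
  }
  min_bits <- ceiling(log2(length(symbols) + 1))
  bits <- if (is.null(bits_per_symbol)) min_bits else as.integer(bits_per_symbol)
  if (!is.null(codes)) {
    widths <- unique(nchar(codes))
    if (length(widths) != 1) stop("all override codes must share one width")
    if (is.null(bits_per_symbol)) bits <- widths
  }
  if (bits < min_bits) {
    stop(length(symbols), " symbols plus the empty symbol need at least ",
         min_bits, " bits per symbol")
  }
  empty_code <- strrep("1", bits)
  assigned <- character(length(symbols))
  names(assigned) <- symbols
  taken <- empty_code
  if (!is.null(codes)) {
    if (is.null(names(codes)) || any(!nzchar(names(codes)))) {
      stop("`codes` must be a named vector")
    }
    unknown <- setdiff(names(codes), symbols)
    if (length(unknown) > 0) {
      stop("override for symbol not in `symbols`: ",
           paste(unknown, collapse = ", "))
    }
    if (any(!grepl("^[01]+$", codes))) stop("codes must be bitstrings")
    if (empty_code %in% codes) {
      stop("the all-ones code is reserved for the empty symbol")
    }
    if (anyDuplicated(codes)) stop("override codes must be distinct")
    assigned[names(codes)] <- codes
    taken <- c(taken, unname(codes))
  }
  # remaining symbols get the lowest free codes in input order
  pool <- vapply(seq_len(2^bits) - 1L, int_to_bits, character(1), width = bits)
  pool <- setdiff(pool, taken)
  need <- which(!nzchar(assigned))
  assigned[need] <- pool[seq_along(need)]
  structure(
    list(symbols = symbols, codes = assigned,
         bits_per_symbol = as.integer(bits), empty_code = empty_code),
    class = "code_table"
  )
}

#' @export
print.code_table <- function(x, ...) {
  cat("Symbol code table (", x$bits_per_symbol, " bits per symbol)\n", sep = "")
  for (s in x$symbols) cat("  ", s, " -> ", x$codes[[s]], "\n", sep = "")
  cat("  <empty> -> ", x$empty_code, "\n", sep = "")
  invisible(x)
}

#' Number of data qubits needed for a string register
#'
#' A string of `n_symbols_in_string` symbols drawn from an alphabet of
#' `n_distinct_symbols` (counting the padding symbol) needs
#' `n_symbols_in_string * ceil(log2(n_distinct_symbols))` qubits.
#'
#' @param n_symbols_in_string Symbol count of the (padded) string.
#' @param n_distinct_symbols Alphabet size including the empty symbol.
#' @return Integer qubit count.
#' @examples
#' required_qubits(3, 4) # 6
#' @export
required_qubits <- function(n_symbols_in_string, n_distinct_symbols) {
  stopifnot(n_symbols_in_string >= 1, n_distinct_symbols >= 1)
  as.integer(n_symbols_in_string * ceiling(log2(n_distinct_symbols)))
}

#' Tokenize a SMILES string against a code table
#'
#' Longest-match tokenization over the table's symbols, so multi-character
#' tokens such as "Cl" are recognized when present in the table.
#' @param smiles Character scalar.
#' @param table A `code_table`.
#' @return Character vector of tokens (length 0 for the empty string).
#' @export
tokenize_smiles <- function(smiles, table) {
  stopifnot(inherits(table, "code_table"))
  if (!nzchar(smiles)) return(character(0))
  syms <- table$symbols[order(-nchar(table$symbols))]
  out <- character(0)
  rest <- smiles
  while (nzchar(rest)) {
    hit <- NULL
    for (s in syms) {
      if (startsWith(rest, s)) { hit <- s; break }
    }
    if (is.null(hit)) {
      stop("unknown SMILES token at \"", substr(rest, 1, 1), "\" in \"",
           smiles, "\"")
    }
    out <- c(out, hit)
    rest <- substr(rest, nchar(hit) + 1L, nchar(rest))
  }
  out
}

#' Encode a SMILES string as a computational basis state
#'
#' Concatenates the per-symbol codes and appends the empty code until the
#' string occupies `max_len` symbol slots; the resulting bitstring, read
#' left to right as a big-endian binary number, is the basis-state index.
#'
#' @param smiles Character scalar (may be empty).
#' @param table A `code_table`.
#' @param max_len Maximum symbol count; shorter strings are padded.
#' @return An `encoded_compound` with fields `smiles`, `bitstring`,
#'   `basis_index`.
#' @examples
#' tb <- build_code_table(c("C", "O"), codes = c(C = "00", O = "10"))
#' encode_smiles("OCC", tb, 4)$bitstring   # "10000011"
#' encode_smiles("CCCO", tb, 4)$basis_index # 2
#' @export
encode_smiles <- function(smiles, table, max_len) {
  stopifnot(inherits(table, "code_table"), max_len >= 1)
  tokens <- tokenize_smiles(smiles, table)
  if (length(tokens) > max_len) {
    stop("\"", smiles, "\" has ", length(tokens),
         " symbols, more than max_len = ", max_len)
  }
  parts <- c(unname(table$codes[tokens]),
             rep(table$empty_code, max_len - length(tokens)))
  bitstring <- paste(parts, collapse = "")
  structure(
    list(smiles = smiles, bitstring = bitstring,
         basis_index = bits_to_int(bitstring)),
    class = "encoded_compound"
  )
}

#' Decode a bitstring back to a SMILES string
#'
#' Inverse of [encode_smiles()]: splits the bitstring into fixed-width codes,
#' strips the trailing run of empty codes and maps the rest back to symbols.
#' Padding codes are only legal as a contiguous suffix.
#'
#' @param bits Bitstring whose width is a multiple of the table's
#'   `bits_per_symbol`.
#' @param table A `code_table`.
#' @return Character scalar.
#' @export
decode_bitstring <- function(bits, table) {
  stopifnot(inherits(table, "code_table"))
  b <- table$bits_per_symbol
  if (!grepl("^[01]*$", bits)) stop("`bits` must be a bitstring")
  if (nchar(bits) %% b != 0) {
    stop("bitstring width ", nchar(bits), " is not a multiple of ", b)
  }
  n <- nchar(bits) %/% b
  if (n == 0) return("")
  chunks <- substring(bits, (seq_len(n) - 1) * b + 1, seq_len(n) * b)
  is_pad <- chunks == table$empty_code
  if (any(is_pad) && any(!is_pad[seq(match(TRUE, is_pad), n)])) {
    stop("non-padding code after a padding code in \"", bits, "\"")
  }
  body <- chunks[!is_pad]
  rev_map <- stats::setNames(names(table$codes), table$codes)
  unknown <- setdiff(body, names(rev_map))
  if (length(unknown) > 0) {
    stop("code not in table: ", paste(unknown, collapse = ", "))
  }
  paste(rev_map[body], collapse = "")
}

#' Alternative linear notations of an unbranched chain
#'
#' One molecule admits several SMILES strings; for an unbranched chain the
#' linear notations are the string and its reversal (with multi-character
#' tokens kept intact). Branched or ring-containing input is rejected; a
#' custom enumerator can be supplied for such cases via `enumerator`.
#'
#' @param smiles Character scalar.
#' @param table Optional `code_table` used to tokenize multi-character
#'   symbols; single-character tokens assumed when omitted.
#' @param enumerator Optional function `smiles -> character vector`
#'   replacing the built-in reversal rule.
#' @return Character vector: the set of equivalent notations.
#' @examples
#' alternative_notations("CCCO") # "CCCO" "OCCC"
#' @export
alternative_notations <- function(smiles, table = NULL, enumerator = NULL) {
  if (!is.null(enumerator)) return(unique(enumerator(smiles)))
  if (grepl("[()0-9%]", smiles)) {
    stop("general notation enumeration for branched or ring SMILES is not ",
         "built in; pass an `enumerator` function")
  }
  tokens <- if (is.null(table)) {
    strsplit(smiles, "", fixed = TRUE)[[1]]
  } else {
    tokenize_smiles(smiles, table)
  }
  unique(c(smiles, paste(rev(tokens), collapse = "")))
}

#' Read or write a code table as two-column text
#'
#' Format: one `symbol<TAB>code` pair per line; the row whose symbol is
#' `EMPTY` names the padding code.
#' @param path File path.
#' @return For the reader, a `code_table`.
#' @export
read_code_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) stop("malformed code table line: ", lines[bad[1]])
  sym <- vapply(parts, `[[`, character(1), 1)
  code <- vapply(parts, `[[`, character(1), 2)
  is_empty <- sym == "EMPTY"
  tb <- build_code_table(sym[!is_empty],
                         codes = stats::setNames(code[!is_empty], sym[!is_empty]))
  if (any(is_empty) && code[is_empty][1] != tb$empty_code) {
    stop("EMPTY row must carry the all-ones code ", tb$empty_code)
  }
  tb
}

#' @rdname read_code_table
#' @param table A `code_table` to write.
#' @export
write_code_table <- function(table, path) {
  stopifnot(inherits(table, "code_table"))
  lines <- c(paste(table$symbols, unname(table$codes[table$symbols]), sep = "\t"),
             paste("EMPTY", table$empty_code, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a SMILES list file
#'
#' One compound per line; blank lines and `#` comments ignored.
#' @param path File path.
#' @return Character vector of SMILES strings.
#' @export
read_smiles_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

# ---- bit helpers (shared across modules) ------------------------------------

int_to_bits <- function(x, width) {
  stopifnot(x >= 0, x < 2^width)
  paste(as.integer(bitwAnd(bitwShiftR(as.integer(x), (width - 1):0), 1L)),
        collapse = "")
}

bits_to_int <- function(bits) {
  v <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
  sum(v * 2^((length(v) - 1):0))
}
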