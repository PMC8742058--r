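#' The two-symbol code table of the worked encoding examples
#'
#' Carbon to `00`, oxygen to `10`, the empty symbol to the all-ones `11`
#' (the remaining code `01` is free for a third symbol).
#' @return A `code_table`.
#' @export
co_code_table <- function() {
  build_code_table(c("C", "O"), codes = c(C = "00", O = "10"))
}

#' Specification for a synthetic patent-pair fixture
#'
#' @param seed Integer seed; all fixture randomness flows from it.
#' @param alphabet_size Number of chemical symbols in the code table.
#' @param max_len Maximum symbol count per claimed compound.
#' @param claims_per_patent Claimed compounds per patent (before notation
#'   closure).
#' @param planted_overlap Number of compounds claimed by both patents.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, alphabet_size = 3L, max_len = 3L,
                         claims_per_patent = 4L, planted_overlap = 1L) {
  stopifnot(planted_overlap <= claims_per_patent, alphabet_size >= 1,
            max_len >= 1, planted_overlap >= 0)
  structure(list(seed = as.integer(seed),
                 alphabet_size = as.integer(alphabet_size),
                 max_len = as.integer(max_len),
                 claims_per_patent = as.integer(claims_per_patent),
                 planted_overlap = as.integer(planted_overlap)),
            class = "fixture_spec")
}

fixture_alphabet <- c("C", "O", "N", "S", "P", "F", "B", "I")

#' Generate a synthetic patent pair with a planted overlap
#'
#' Builds two single-R-group patents whose enumerated claim languages,
#' closed under alternative linear notations, intersect in exactly the
#' planted compounds. Compounds are sampled as canonical representatives
#' (the lexicographic minimum of a chain and its reversal) so reversal
#' closure cannot create accidental extra overlaps. Deterministic per seed.
#'
#' Presets: `"fig1f"` gives the 2-data-qubit target sets `{11, 00}` versus
#' `{00}` (raw marked bitstrings, no grammar); `"table1"` gives the
#' 8-data-qubit pair whose overlap encodes to basis states 2 and 128.
#'
#' @param spec A `fixture_spec` (ignored when `preset` is given).
#' @param preset Optional preset name.
#' @return A `patent_fixture`: fields `patent_m`, `patent_k`, `table`,
#'   `max_len`, `marked_m`, `marked_k` (encoded bitstrings after notation
#'   closure), `expected_overlap` (SMILES strings; for `"fig1f"` raw
#'   bitstrings), `n_data`.
#' @export
generate_fixture <- function(spec = fixture_spec(), preset = NULL) {
  if (!is.null(preset)) {
    if (preset == "fig1f") {
      return(structure(list(
        patent_m = NULL, patent_k = NULL, table = NULL, max_len = NA,
        marked_m = c("00", "11"), marked_k = "00",
        expected_overlap = "00", n_data = 2L
      ), class = "patent_fixture"))
    }
    if (preset == "table1") {
      tb <- co_code_table()
      pm <- markush_patent("CC{R1}", rules = list(R1 = c("CO", "OC")))
      pk <- markush_patent("O{R2}", rules = list(R2 = c("CCC", "CCO", "COO")))
      return(fixture_from_patents(pm, pk, tb, max_len = 4L,
                                  expected = c("CCCO", "OCCC")))
    }
    stop("unknown preset: ", preset)
  }
  stopifnot(inherits(spec, "fixture_spec"))
  a <- spec$alphabet_size
  if (a > length(fixture_alphabet)) {
    stop("alphabet_size capped at ", length(fixture_alphabet))
  }
  syms <- fixture_alphabet[seq_len(a)]
  tb <- build_code_table(syms)
  n_data <- spec$max_len * tb$bits_per_symbol
  if (n_data + 2L > MAX_QUBITS) {
    stop("fixture needs ", n_data + 2L, " qubits, above the simulator cap")
  }
  need <- 2L * spec$claims_per_patent - spec$planted_overlap
  n_strings <- sum(a^(1:spec$max_len))
  if (need > n_strings / 2) stop("infeasible fixture spec: not enough distinct compounds")
  canon <- character(0)
  with_seed(spec$seed, {
    while (length(canon) < need) {
      len <- sample.int(spec$max_len, 1)
      s <- paste(sample(syms, len, replace = TRUE), collapse = "")
      r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
      canon <- unique(c(canon, min(s, r)))
    }
  })
  shared <- canon[seq_len(spec$planted_overlap)]
  rest <- canon[-seq_len(spec$planted_overlap)]
  only_m <- rest[seq_len(spec$claims_per_patent - spec$planted_overlap)]
  only_k <- rest[spec$claims_per_patent - spec$planted_overlap +
                   seq_len(spec$claims_per_patent - spec$planted_overlap)]
  pm <- markush_patent("{R1}", rules = list(R1 = c(shared, only_m)))
  pk <- markush_patent("{R1}", rules = list(R1 = c(shared, only_k)))
  expected <- sort(unique(unlist(lapply(shared, alternative_notations,
                                        table = tb))))
  fixture_from_patents(pm, pk, tb, max_len = spec$max_len, expected = expected)
}

fixture_from_patents <- function(pm, pk, tb, max_len, expected) {
  closure <- function(p) expand_claims(enumerate_claims(p), tb)
  enc <- function(claims) {
    sort(vapply(claims, function(s) encode_smiles(s, tb, max_len)$bitstring,
                character(1), USE.NAMES = FALSE))
  }
  structure(list(
    patent_m = pm, patent_k = pk, table = tb, max_len = max_len,
    marked_m = enc(closure(pm)), marked_k = enc(closure(pk)),
    expected_overlap = sort(expected),
    n_data = max_len * tb$bits_per_symbol
  ), class = "patent_fixture")
}

#' @export
print.patent_fixture <- function(x, ...) {
  cat("Synthetic patent-pair fixture: ", x$n_data, " data qubits, |M| = ",
      length(x$marked_m), ", |K| = ", length(x$marked_k),
      ", planted overlap = {", paste(x$expected_overlap, collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}
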