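#' Define a Markush patent claim grammar
#'
#' A Markush structure is an invariant core plus variable substituents
#' (R groups), each defined by production rules that may reference further
#' R groups. Here the core and every production are strings in which
#' `{NAME}` marks an R-group reference; `terminals` gives the constant
#' variation symbol (conventionally `R`) its list of terminal SMILES
#' fragments. The reference graph must be acyclic so that the claimed
#' language is finite.
#'
#' @param core Character scalar, e.g. `"CC{R1}"`.
#' @param rules Named list: R-group name -> character vector of productions
#'   (each a string, possibly with `{NAME}` references).
#' @param terminals Named list: variation symbol -> character vector of
#'   terminal fragments (no references allowed).
#' @return A `markush_patent` object.
#' @examples
#' p <- markush_patent("CC{R1}", rules = list(R1 = "{R}O"),
#'                     terminals = list(R = "C"))
#' enumerate_claims(p) # "CCCO"
#' @export
markush_patent <- function(core, rules = list(), terminals = list()) {
  stopifnot(is.character(core), length(core) == 1)
  rules <- lapply(rules, as.character)
  terminals <- lapply(terminals, as.character)
  for (nm in names(terminals)) {
    if (any(grepl("\\{", terminals[[nm]]))) {
      stop("terminal fragments may not contain references: ", nm)
    }
  }
  both <- intersect(names(rules), names(terminals))
  if (length(both) > 0) {
    stop("name used both as rule and terminal: ", paste(both, collapse = ", "))
  }
  pat <- structure(
    list(core = core, rules = rules, terminals = terminals),
    class = "markush_patent"
  )
  refs <- unique(unlist(c(
    list(placeholder_names(core)),
    lapply(unlist(rules), placeholder_names)
  )))
  defined <- c(names(rules), names(terminals))
  missing <- setdiff(refs, defined)
  if (length(missing) > 0) {
    stop("R group referenced but not defined: ", paste(missing, collapse = ", "))
  }
  check_acyclic(pat)
  pat
}

#' @export
print.markush_patent <- function(x, ...) {
  cat("Markush patent claim\n  core: ", x$core, "\n", sep = "")
  for (nm in names(x$rules)) {
    cat("  ", nm, " -> ", paste(x$rules[[nm]], collapse = " | "), "\n", sep = "")
  }
  for (nm in names(x$terminals)) {
    cat("  ", nm, " := {", paste(x$terminals[[nm]], collapse = ", "), "}\n",
        sep = "")
  }
  invisible(x)
}

placeholder_names <- function(s) {
  m <- gregexpr("\\{[A-Za-z0-9_]+\\}", s)[[1]]
  if (m[1] == -1) return(character(0))
  gsub("[{}]", "", regmatches(s, gregexpr("\\{[A-Za-z0-9_]+\\}", s))[[1]])
}

# split a production string into literal / reference segments
split_segments <- function(s) {
  out <- list()
  while (nzchar(s)) {
    m <- regexpr("\\{[A-Za-z0-9_]+\\}", s)
    if (m == -1) {
      out[[length(out) + 1]] <- list(kind = "lit", value = s)
      break
    }
    if (m > 1) {
      out[[length(out) + 1]] <- list(kind = "lit",
                                     value = substr(s, 1, m - 1))
    }
    ref <- substr(s, m + 1, m + attr(m, "match.length") - 2)
    out[[length(out) + 1]] <- list(kind = "ref", value = ref)
    s <- substr(s, m + attr(m, "match.length"), nchar(s))
  }
  out
}

check_acyclic <- function(pat) {
  color <- new.env(parent = emptyenv())
  visit <- function(name, path) {
    st <- mget(name, envir = color, ifnotfound = "white")[[1]]
    if (st == "grey") {
      cyc <- c(path[which(path == name)[1]:length(path)], name)
      stop("cyclic R-group grammar: ", paste(cyc, collapse = " -> "))
    }
    if (st == "black") return(invisible())
    assign(name, "grey", envir = color)
    if (name %in% names(pat$rules)) {
      for (prod in pat$rules[[name]]) {
        for (ref in placeholder_names(prod)) visit(ref, c(path, name))
      }
    }
    assign(name, "black", envir = color)
  }
  for (ref in placeholder_names(pat$core)) visit(ref, character(0))
  for (nm in names(pat$rules)) visit(nm, character(0))
  invisible(pat)
}

expand_name <- function(pat, name, memo) {
  if (!is.null(memo[[name]])) return(memo[[name]])
  res <- if (name %in% names(pat$terminals)) {
    pat$terminals[[name]]
  } else {
    unlist(lapply(pat$rules[[name]], function(prod) {
      expand_string(pat, prod, memo)
    }), use.names = FALSE)
  }
  memo[[name]] <- res
  res
}

expand_string <- function(pat, s, memo) {
  segs <- split_segments(s)
  acc <- ""
  for (seg in segs) {
    pieces <- if (seg$kind == "lit") seg$value else expand_name(pat, seg$value, memo)
    # depth-first: earlier segments vary slowest, production order preserved
    acc <- as.vector(vapply(acc, function(a) paste0(a, pieces),
                            character(length(pieces))))
  }
  acc
}

#' Enumerate the compounds claimed by a Markush grammar
#'
#' Expands every R-group reference by its productions depth-first in the
#' order given, deduplicates the resulting SMILES strings, and truncates at
#' `limit`. The order is deterministic.
#'
#' @param patent A `markush_patent`.
#' @param limit Maximum number of distinct strings returned.
#' @return Character vector of claimed SMILES strings.
#' @export
enumerate_claims <- function(patent, limit = 1e6L) {
  stopifnot(inherits(patent, "markush_patent"), limit >= 1)
  check_acyclic(patent)
  memo <- new.env(parent = emptyenv())
  out <- unique(expand_string(patent, patent$core, memo))
  utils::head(out, limit)
}

#' Count claim derivations without enumeration
#'
#' Dynamic programming over the R-group graph: the count of a production is
#' the product of its segments' counts and the count of an R group is the
#' sum over its productions. Counts derivations, so duplicate strings arising
#' from different derivations are counted separately (unlike
#' [enumerate_claims()], which deduplicates).
#'
#' @param patent A `markush_patent`.
#' @return Numeric count (may exceed integer range).
#' @export
count_claims <- function(patent) {
  stopifnot(inherits(patent, "markush_patent"))
  check_acyclic(patent)
  memo <- new.env(parent = emptyenv())
  count_name <- function(name) {
    if (!is.null(memo[[name]])) return(memo[[name]])
    res <- if (name %in% names(patent$terminals)) {
      length(patent$terminals[[name]])
    } else {
      sum(vapply(patent$rules[[name]], count_string, numeric(1)))
    }
    memo[[name]] <- res
    res
  }
  count_string <- function(s) {
    segs <- split_segments(s)
    prod(vapply(segs, function(seg) {
      if (seg$kind == "lit") 1 else count_name(seg$value)
    }, numeric(1)))
  }
  count_string(patent$core)
}

#' Read a patent claim specification file
#'
#' YAML with keys `core` (string containing `{NAME}` placeholders), `rules`
#' (map name -> list of production strings) and `terminals` (map variation
#' symbol -> list of fragments). Acyclicity is validated on load.
#'
#' @param path File path.
#' @return A `markush_patent`.
#' @export
read_patent <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$core)) stop("patent file needs a `core` key")
  markush_patent(cfg$core,
                 rules = if (is.null(cfg$rules)) list() else cfg$rules,
                 terminals = if (is.null(cfg$terminals)) list() else cfg$terminals)
}
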