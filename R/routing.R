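#' Coupling graph of a device
#'
#' Physical qubit connectivity: two-qubit gates between non-adjacent qubits
#' incur routing (SWAP) overhead.
#'
#' @param edges Two-column matrix or data frame of undirected edges between
#'   physical qubit ids.
#' @param nodes Optional vector of node ids (defaults to those appearing in
#'   `edges`).
#' @return A `coupling_graph`.
#' @export
coupling_graph <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns")
  if (is.null(nodes)) nodes <- sort(unique(as.vector(edges)))
  if (!all(as.vector(edges) %in% nodes)) {
    stop("edge references an undeclared node")
  }
  structure(list(nodes = nodes, edges = edges), class = "coupling_graph")
}

#' A 5-qubit T-shaped coupling layout
#'
#' Edges 0-1, 1-2, 1-3, 3-4, as on small superconducting devices of the
#' ibmq_vigo family; qubit 1 has the largest connectivity.
#' @return A `coupling_graph`.
#' @export
vigo_coupling <- function() {
  coupling_graph(rbind(c(0, 1), c(1, 2), c(1, 3), c(3, 4)))
}

#' Read a coupling graph from an edge-list text file
#'
#' One `a b` pair per line; `#` comments ignored.
#' @param path File path.
#' @return A `coupling_graph`.
#' @export
read_coupling_graph <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
  if (any(lengths(parts) != 2)) stop("malformed edge line")
  coupling_graph(do.call(rbind, parts))
}

#' Routing cost of a circuit under a qubit mapping
#'
#' SWAP-equivalent overhead: the sum over two-qubit gates of the
#' shortest-path length between the mapped endpoints minus one. Zero when
#' every two-qubit gate touches adjacent physical qubits.
#'
#' @param circ A `quantum_circuit` containing only single- and two-qubit
#'   gates (decompose wider gates first).
#' @param coupling A `coupling_graph`.
#' @param mapping Integer vector: `mapping[i + 1]` is the physical qubit for
#'   logical qubit `i`. Must be injective onto the graph's nodes.
#' @return Integer cost.
#' @export
routing_cost <- function(circ, coupling, mapping) {
  stopifnot(inherits(circ, "quantum_circuit"),
            inherits(coupling, "coupling_graph"))
  mapping <- as.numeric(mapping)
  if (anyDuplicated(mapping)) stop("mapping must be injective")
  if (!all(mapping %in% coupling$nodes)) {
    stop("mapping targets a qubit outside the coupling graph")
  }
  g <- igraph::graph_from_edgelist(
    matrix(as.character(coupling$edges), ncol = 2), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(coupling$nodes),
                                    igraph::V(g)$name))
  dmat <- igraph::distances(g)
  cost <- 0L
  for (gt in circ$gates) {
    if (length(gt$qubits) == 1) next
    if (length(gt$qubits) > 2) {
      stop("decompose gates wider than two qubits before routing")
    }
    a <- as.character(mapping[gt$qubits[1] + 1L])
    b <- as.character(mapping[gt$qubits[2] + 1L])
    d <- dmat[a, b]
    if (!is.finite(d)) stop("mapped endpoints are disconnected")
    cost <- cost + as.integer(d) - 1L
  }
  cost
}
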