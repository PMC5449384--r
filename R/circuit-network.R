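#' @include AllGenerics.R
NULL

## Canonical, locale-independent edge orientation: u precedes v in the radix
## (byte-wise) order of node ids. Positive current flows u -> v.
.canonicalizeEdges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  ids <- sort(unique(c(edges$u, edges$v)), method = "radix")
  swap <- match(edges$u, ids) > match(edges$v, ids)
  if (any(swap)) {
    tmp <- edges$u[swap]
    edges$u[swap] <- edges$v[swap]
    edges$v[swap] <- tmp
  }
  rownames(edges) <- NULL
  edges
}

#' Construct a resistor network
#'
#' Builds a validated [CircuitNetwork-class] from node and edge tables.
#' Edge endpoint order is canonicalized (byte-order of the ids) so the sign
#' convention for currents is deterministic and orientation-free.
#'
#' @param nodes data.frame with columns \code{id}, \code{kind}
#'   (\code{internal}/\code{anode}/\code{cathode}), optional \code{x},
#'   \code{y} (default 0) and \code{fixedVoltage} (required non-NA for
#'   anodes/cathodes, NA for internal nodes).
#' @param edges data.frame with columns \code{u}, \code{v},
#'   \code{resistance} (ohms, > 0) and optional \code{role} (default
#'   \code{"capillary"}).
#' @return a [CircuitNetwork-class].
#' @export
#' @examples
#' nd <- data.frame(id = c("a", "m", "b"),
#'                  kind = c("cathode", "internal", "anode"),
#'                  fixedVoltage = c(0, NA, 10))
#' net <- CircuitNetwork(nd, data.frame(u = c("a", "m"), v = c("m", "b"),
#'                                      resistance = 1))
#' solveCircuit(net)
CircuitNetwork <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (is.null(nodes$x)) nodes$x <- 0
  if (is.null(nodes$y)) nodes$y <- 0
  if (is.null(nodes$fixedVoltage)) nodes$fixedVoltage <- NA_real_
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  nodes$fixedVoltage <- as.numeric(nodes$fixedVoltage)
  nodes <- nodes[, c("id", "kind", "x", "y", "fixedVoltage")]
  rownames(nodes) <- NULL
  if (is.null(edges$role)) edges$role <- "capillary"
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  edges$resistance <- as.numeric(edges$resistance)
  edges$role <- as.character(edges$role)
  edges <- .canonicalizeEdges(edges[, c("u", "v", "resistance", "role")])
  new("CircuitNetwork", nodes = nodes, edges = edges)
}

#' @rdname circuit-accessors
setMethod("nodeTable", "CircuitNetwork", function(x) x@nodes)

#' @rdname circuit-accessors
setMethod("edgeTable", "CircuitNetwork", function(x) x@edges)

#' @rdname circuit-accessors
setMethod("voltages", "CircuitSolution", function(x) x@voltages)

#' @rdname circuit-accessors
setMethod("currents", "CircuitSolution", function(x) x@currents)

#' @rdname circuit-accessors
setMethod("kclResidualMax", "CircuitSolution", function(x) x@kclResidualMax)

setMethod("show", "CircuitNetwork", function(object) {
  nd <- object@nodes
  cat("CircuitNetwork:", nrow(nd), "nodes (",
      sum(nd$kind == "anode"), "anodes,",
      sum(nd$kind == "cathode"), "cathodes ),",
      nrow(object@edges), "edges\n")
})

setMethod("show", "CircuitSolution", function(object) {
  cat("CircuitSolution:", length(object@voltages), "node voltages in [",
      format(min(object@voltages), digits = 6), ",",
      format(max(object@voltages), digits = 6), "] V;",
      nrow(object@currents), "edge currents; max KCL residual",
      format(object@kclResidualMax, digits = 3), "A\n")
})
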