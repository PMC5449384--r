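#' @include AllClasses.R
NULL

#' Accessors for circuit containers
#'
#' \code{nodeTable} and \code{edgeTable} return the node and edge
#' data.frames of a [CircuitNetwork-class] or of the network inside a
#' [LobuleLattice-class]. \code{circuit} extracts the underlying
#' [CircuitNetwork-class] from a lattice. \code{voltages} and
#' \code{currents} return the solved state of a [CircuitSolution-class];
#' \code{kclResidualMax} its recorded worst node-balance violation.
#'
#' @param x a CircuitNetwork, LobuleLattice or CircuitSolution.
#' @return \code{nodeTable}, \code{edgeTable}, \code{currents}: a
#'   data.frame; \code{voltages}: a named numeric vector (volts);
#'   \code{circuit}: a CircuitNetwork; \code{kclResidualMax}: a number
#'   (amperes).
#' @name circuit-accessors
#' @examples
#' lat <- buildLobule(LatticeConfig())
#' head(nodeTable(lat))
#' sol <- solveCircuit(circuit(lat))
#' range(voltages(sol))
NULL

#' @rdname circuit-accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname circuit-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname circuit-accessors
#' @export
setGeneric("circuit", function(x) standardGeneric("circuit"))

#' @rdname circuit-accessors
#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))

#' @rdname circuit-accessors
#' @export
setGeneric("currents", function(x) standardGeneric("currents"))

#' @rdname circuit-accessors
#' @export
setGeneric("kclResidualMax", function(x) standardGeneric("kclResidualMax"))

#' Accessors for lobule lattices
#'
#' \code{hexIds} lists the hexagon (lobule) identifiers, \code{"col,row"}
#' in axial coordinates with odd columns offset upward. \code{hexMembership}
#' returns one hexagon's node membership (center / inner ring / boundary
#' ring). \code{anodeNode} returns the node id of a hexagon's central
#' feeding-arteriole anode. \code{hexAdjacency} returns, for every hexagon,
#' the hexagons sharing a collector-venule boundary edge.
#' \code{latticeConfig} returns the [LatticeConfig-class].
#'
#' @param x a [LobuleLattice-class].
#' @param hexagon a hexagon id such as \code{"2,2"}.
#' @name lattice-accessors
#' @examples
#' lat <- tileLattice(LatticeConfig(rows = 3L, cols = 3L))
#' hexIds(lat)
#' anodeNode(lat, "1,1")
NULL

#' @rdname lattice-accessors
#' @export
setGeneric("hexIds", function(x) standardGeneric("hexIds"))

#' @rdname lattice-accessors
#' @export
setGeneric("hexMembership", function(x, hexagon) standardGeneric("hexMembership"))

#' @rdname lattice-accessors
#' @export
setGeneric("anodeNode", function(x, hexagon) standardGeneric("anodeNode"))

#' @rdname lattice-accessors
#' @export
setGeneric("hexAdjacency", function(x) standardGeneric("hexAdjacency"))

#' @rdname lattice-accessors
#' @export
setGeneric("latticeConfig", function(x) standardGeneric("latticeConfig"))
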