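#' @include solver.R
NULL

## Flat-top hexagon geometry in integer "key" units (kx = 4x, ky = 4y/sqrt(3))
## so that shared corners and edge midpoints of adjacent hexagons coincide on
## exact integer coordinates. Circumradius 1; odd columns offset upward by
## half a hexagon height (odd-q layout).
.CORNER_OFF <- list(c(4, 0), c(2, 2), c(-2, 2), c(-4, 0), c(-2, -2), c(2, -2))
.MID_OFF    <- list(c(3, 1), c(0, 2), c(-3, 1), c(-3, -1), c(0, -2), c(3, -1))
.INNER_OFF  <- list(c(2, 0), c(1, 1), c(-1, 1), c(-2, 0), c(-1, -1), c(1, -1))

#' Hexagon identifiers
#'
#' Hexagons are addressed as \code{"col,row"}, zero-based, columns left to
#' right and rows bottom to top, odd columns offset upward by half a hexagon.
#'
#' @param col,row zero-based hexagon coordinates.
#' @return a character hexagon id.
#' @export
#' @examples hexId(2, 2)
hexId <- function(col, row) paste0(col, ",", row)

#' Collector-venule boundary resistance by Poiseuille scaling
#'
#' Laminar-flow (Poiseuille) resistance is inversely proportional to the
#' fourth power of the vessel radius, so a collector venule whose diameter
#' is \code{diameterRatio} times the capillary diameter has resistance
#' \code{capillaryResistance / diameterRatio^4}. With 16-ohm capillaries the
#' physiological ratio range \[1, 2\] maps onto boundary resistances of
#' 16 down to 1 ohm.
#'
#' @param capillaryResistance ohms, > 0.
#' @param diameterRatio dimensionless, >= 1.
#' @return ohms.
#' @export
#' @examples
#' boundaryResistance(16, 1)  # 16
#' boundaryResistance(16, 2)  # 1
boundaryResistance <- function(capillaryResistance, diameterRatio) {
  if (!is.numeric(capillaryResistance) || !is.finite(capillaryResistance) ||
      capillaryResistance <= 0)
    stop("capillaryResistance must be a positive finite number")
  if (!is.numeric(diameterRatio) || any(!is.finite(diameterRatio)) ||
      any(diameterRatio < 1))
    stop("diameterRatio must be >= 1")
  capillaryResistance / diameterRatio^4
}

#' Lattice configuration
#'
#' Physiological defaults follow the source model: 16-ohm capillary
#' segments, equal-diameter collector venules (ratio 1, hence 16-ohm
#' boundaries), 51 V anodes and 23 V cathodes (choroidal arteriolar and
#' venous pressures in mmHg), and a 5 x 5 honeycomb. The \code{"figure6"}
#' preset uses the alternative 50 V / 10 V sources; all reported influx
#' percentages are ratios and insensitive to the preset at matched geometry.
#'
#' @param rows,cols hexagon counts.
#' @param capillaryResistance ohms per capillary segment.
#' @param diameterRatio collector-venule/capillary diameter ratio in \[1, 2\].
#' @param anodeVoltage,cathodeVoltage source voltages, volts.
#' @param preset \code{"methods"} (51/23 V, the default) or
#'   \code{"figure6"} (50/10 V). Explicit voltage arguments override it.
#' @return a [LatticeConfig-class].
#' @export
#' @examples
#' LatticeConfig()
#' LatticeConfig(diameterRatio = 2, preset = "figure6")
LatticeConfig <- function(rows = 5L, cols = 5L, capillaryResistance = 16,
                          diameterRatio = 1, anodeVoltage = NULL,
                          cathodeVoltage = NULL,
                          preset = c("methods", "figure6")) {
  preset <- match.arg(preset)
  pv <- if (preset == "methods") c(51, 23) else c(50, 10)
  if (is.null(anodeVoltage)) anodeVoltage <- pv[1]
  if (is.null(cathodeVoltage)) cathodeVoltage <- pv[2]
  new("LatticeConfig", rows = as.integer(rows), cols = as.integer(cols),
      capillaryResistance = as.numeric(capillaryResistance),
      diameterRatio = as.numeric(diameterRatio),
      anodeVoltage = as.numeric(anodeVoltage),
      cathodeVoltage = as.numeric(cathodeVoltage))
}

setMethod("show", "LatticeConfig", function(object) {
  cat("LatticeConfig:", object@rows, "x", object@cols, "hexagons;",
      "capillary", object@capillaryResistance, "ohm;",
      "boundary", format(boundaryResistance(object@capillaryResistance,
                                            object@diameterRatio),
                         digits = 6),
      "ohm (diameter ratio", object@diameterRatio, ");",
      "anode", object@anodeVoltage, "V, cathode", object@cathodeVoltage, "V\n")
})

## Core honeycomb builder. Shared corners, edge midpoints and boundary edges
## of adjacent hexagons are deduplicated through their integer positions;
## a shared collector venule is one vessel and gets its resistance once.
## Cathodes sit on the globally consistent alternate-corner class
## (kx mod 6 == 4), so adjacent hexagons always agree on corner polarity.
.buildHexLattice <- function(config) {
  rows <- config@rows; cols <- config@cols
  rc <- config@capillaryResistance
  rb <- boundaryResistance(rc, config@diameterRatio)
  va <- config@anodeVoltage; vc <- config@cathodeVoltage

  nodeId <- function(k) paste0("n", k[1], "_", k[2])
  nodeEnv <- new.env(parent = emptyenv())
  addNode <- function(k, kind = "internal", v = NA_real_) {
    id <- nodeId(k)
    if (is.null(nodeEnv[[id]]))
      nodeEnv[[id]] <- list(id = id, kx = k[1], ky = k[2], kind = kind, v = v)
    id
  }
  edgeEnv <- new.env(parent = emptyenv())
  eu <- character(0); ev <- character(0); er <- numeric(0); erl <- character(0)
  edgeHex <- list()  # boundary-edge key -> hexagon ids sharing it
  addEdge <- function(a, b, R, role, hex = NULL) {
    key <- paste(sort(c(a, b), method = "radix"), collapse = "|")
    if (is.null(edgeEnv[[key]])) {
      edgeEnv[[key]] <- TRUE
      eu <<- c(eu, a); ev <<- c(ev, b); er <<- c(er, R); erl <<- c(erl, role)
    }
    if (!is.null(hex))
      edgeHex[[key]] <<- c(edgeHex[[key]], hex)
    invisible(key)
  }

  hexes <- list()
  for (c0 in seq_len(cols) - 1L) {
    for (r0 in seq_len(rows) - 1L) {
      hid <- hexId(c0, r0)
      ctr <- c(6L * c0, 4L * r0 + 2L * (c0 %% 2L))
      centerId <- addNode(ctr, "anode", va)
      inner <- vapply(.INNER_OFF, function(o) addNode(ctr + o), character(1))
      corner <- character(6); mid <- character(6)
      for (k in 1:6) {
        ck <- ctr + .CORNER_OFF[[k]]
        corner[k] <- if ((ck[1] %% 6L) == 4L) addNode(ck, "cathode", vc)
                     else addNode(ck)
        mid[k] <- addNode(ctr + .MID_OFF[[k]])
      }
      for (k in 1:6) {
        k2 <- (k %% 6L) + 1L
        addEdge(centerId, inner[k], rc, "capillary")
        addEdge(inner[k], inner[k2], rc, "capillary")
        addEdge(inner[k], corner[k], rc, "capillary")
        addEdge(inner[k], mid[k], rc, "capillary")
        addEdge(inner[k2], mid[k], rc, "capillary")
        addEdge(corner[k], mid[k], rb, "collector_venule", hex = hid)
        addEdge(mid[k], corner[k2], rb, "collector_venule", hex = hid)
      }
      hexes[[hid]] <- list(col = c0, row = r0, center = centerId,
                           inner = inner, boundary = c(corner, mid))
    }
  }

  nl <- as.list(nodeEnv)
  nl <- nl[sort(names(nl), method = "radix")]
  nodes <- data.frame(
    id = vapply(nl, `[[`, character(1), "id"),
    kind = vapply(nl, `[[`, character(1), "kind"),
    x = vapply(nl, function(n) n$kx / 4, numeric(1)),
    y = vapply(nl, function(n) n$ky * sqrt(3) / 4, numeric(1)),
    fixedVoltage = vapply(nl, `[[`, numeric(1), "v"),
    row.names = NULL)
  edges <- data.frame(u = eu, v = ev, resistance = er, role = erl,
                      row.names = NULL)
  network <- CircuitNetwork(nodes, edges)

  adjacency <- stats::setNames(vector("list", length(hexes)), names(hexes))
  for (key in names(edgeHex)) {
    hs <- unique(edgeHex[[key]])
    if (length(hs) > 1)
      for (h in hs)
        adjacency[[h]] <- unique(c(adjacency[[h]], setdiff(hs, h)))
  }
  adjacency <- lapply(adjacency, function(v) {
    if (is.null(v)) character(0) else sort(v, method = "radix")
  })

  new("LobuleLattice", network = network, hexes = hexes, config = config,
      adjacency = adjacency)
}

#' Build a single choriocapillaris lobule circuit
#'
#' One dual-layered hexagon: a central feeding-arteriole anode, an inner
#' ring of 6 capillary junctions, and a 12-node boundary ring (6 corners and
#' 6 edge midpoints). The interior is fully triangulated with capillary
#' edges at \code{capillaryResistance}; the boundary ring carries
#' collector-venule edges at the Poiseuille-scaled resistance; cathodes
#' (draining venules) sit at every other corner. 19 nodes, 42 edges.
#'
#' @param config a [LatticeConfig-class]; its \code{rows}/\code{cols} are
#'   ignored (a single hexagon is built).
#' @return a [LobuleLattice-class] with one hexagon.
#' @export
#' @examples
#' lob <- buildLobule(LatticeConfig())
#' nrow(nodeTable(lob))  # 19
buildLobule <- function(config = LatticeConfig()) {
  validObject(config)
  cfg <- config
  cfg@rows <- 1L
  cfg@cols <- 1L
  .buildHexLattice(cfg)
}

#' Tile lobule hexagons into a choriocapillaris lattice
#'
#' Arranges \code{rows x cols} lobule hexagons in a plane-filling honeycomb.
#' Adjacent hexagons share boundary nodes and collector-venule edges (each
#' shared venule appears once); corner cathodes are shared by all hexagons
#' meeting there, with a globally consistent alternate-corner placement.
#'
#' @param config a [LatticeConfig-class].
#' @return a [LobuleLattice-class].
#' @export
#' @examples
#' lat <- tileLattice(LatticeConfig())
#' length(hexIds(lat))  # 25
tileLattice <- function(config = LatticeConfig()) {
  validObject(config)
  .buildHexLattice(config)
}

#' @rdname circuit-accessors
setMethod("circuit", "LobuleLattice", function(x) x@network)

#' @rdname circuit-accessors
setMethod("nodeTable", "LobuleLattice", function(x) x@network@nodes)

#' @rdname circuit-accessors
setMethod("edgeTable", "LobuleLattice", function(x) x@network@edges)

#' @rdname lattice-accessors
setMethod("hexIds", "LobuleLattice", function(x) names(x@hexes))

.getHex <- function(x, hexagon) {
  h <- x@hexes[[hexagon]]
  if (is.null(h))
    stop("unknown hexagon '", hexagon, "'; available: ",
         paste(utils::head(names(x@hexes), 5), collapse = ", "),
         if (length(x@hexes) > 5) ", ..." else "")
  h
}

#' @rdname lattice-accessors
setMethod("hexMembership", "LobuleLattice", function(x, hexagon) {
  h <- .getHex(x, hexagon)
  list(center = h$center, inner = h$inner, boundary = h$boundary)
})

#' @rdname lattice-accessors
setMethod("anodeNode", "LobuleLattice", function(x, hexagon)
  .getHex(x, hexagon)$center)

#' @rdname lattice-accessors
setMethod("hexAdjacency", "LobuleLattice", function(x) x@adjacency)

#' @rdname lattice-accessors
setMethod("latticeConfig", "LobuleLattice", function(x) x@config)

setMethod("show", "LobuleLattice", function(object) {
  nd <- object@network@nodes
  cat("LobuleLattice:", object@config@rows, "x", object@config@cols,
      "hexagons;", nrow(nd), "nodes (",
      sum(nd$kind == "anode"), "anodes,",
      sum(nd$kind == "cathode"), "cathodes );",
      nrow(object@network@edges), "edges\n")
})
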