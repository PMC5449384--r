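#' @include AllClasses.R
NULL

.NODE_KINDS <- c("internal", "anode", "cathode")
.EDGE_ROLES <- c("capillary", "collector_venule", "terminal_arteriole_link")
.SCENARIO_KINDS <- c("normal", "single_disconnect", "sector_disconnect", "custom")
.EMBOLISM_PATTERNS <- c("scattered", "segmental")
.ORDER_LEVELS <- c("connected", "first_order", "second_order", "deeper")

#' CircuitNetwork: a resistive network with fixed-voltage terminals
#'
#' A direct-current resistor network. Nodes are junctions ("confluence
#' points") of the vascular analogue: internal nodes are free unknowns,
#' anodes and cathodes carry a fixed voltage (the pressure boundary
#' condition). Edges are resistors with a physiological role label.
#'
#' @slot nodes data.frame with columns \code{id} (character, unique),
#'   \code{kind} (one of \code{internal}, \code{anode}, \code{cathode}),
#'   \code{x}, \code{y} (layout coordinates, never used in the physics) and
#'   \code{fixedVoltage} (volts; \code{NA} exactly when kind is internal).
#' @slot edges data.frame with columns \code{u}, \code{v} (node ids,
#'   canonically ordered so \code{u} precedes \code{v}), \code{resistance}
#'   (ohms, strictly positive and finite) and \code{role} (one of
#'   \code{capillary}, \code{collector_venule},
#'   \code{terminal_arteriole_link}). Positive current flows from \code{u}
#'   to \code{v}.
#'
#' @seealso [CircuitNetwork()], [solveCircuit()], [assembleSystem()]
#' @exportClass CircuitNetwork
setClass("CircuitNetwork",
         representation(nodes = "data.frame", edges = "data.frame"))

setValidity("CircuitNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character(0)
  needN <- c("id", "kind", "x", "y", "fixedVoltage")
  needE <- c("u", "v", "resistance", "role")
  if (!all(needN %in% names(nd)))
    return(paste("nodes must have columns:", paste(needN, collapse = ", ")))
  if (!all(needE %in% names(ed)))
    return(paste("edges must have columns:", paste(needE, collapse = ", ")))
  if (anyDuplicated(nd$id))
    msgs <- c(msgs, "node ids must be unique")
  if (!all(nd$kind %in% .NODE_KINDS))
    msgs <- c(msgs, "node kind must be internal, anode or cathode")
  fixed <- nd$kind != "internal"
  if (any(is.na(nd$fixedVoltage[fixed])) || any(!is.finite(nd$fixedVoltage[fixed])))
    msgs <- c(msgs, "anode/cathode nodes must carry a finite fixedVoltage")
  if (any(!is.na(nd$fixedVoltage[!fixed])))
    msgs <- c(msgs, "internal nodes must not carry a fixedVoltage")
  if (!any(fixed))
    msgs <- c(msgs, "network must contain at least one fixed-voltage node")
  if (nrow(ed) > 0) {
    if (any(!is.finite(ed$resistance)) || any(ed$resistance <= 0))
      msgs <- c(msgs, "edge resistances must be finite and > 0")
    if (!all(ed$role %in% .EDGE_ROLES))
      msgs <- c(msgs, "unknown edge role")
    if (any(ed$u == ed$v))
      msgs <- c(msgs, "self-loop edges are not allowed")
    bad <- !(ed$u %in% nd$id) | !(ed$v %in% nd$id)
    if (any(bad))
      msgs <- c(msgs, paste("edge endpoints missing from nodes:",
                            paste(unique(c(ed$u[bad], ed$v[bad])), collapse = ", ")))
    if (anyDuplicated(paste(ed$u, ed$v)))
      msgs <- c(msgs, "parallel edges are not allowed")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' CircuitSolution: solved node voltages and signed edge currents
#'
#' @slot voltages named numeric vector, volts, one entry per network node.
#' @slot currents data.frame with columns \code{u}, \code{v},
#'   \code{resistance}, \code{role}, \code{current} (amperes, positive from
#'   \code{u} to \code{v}).
#' @slot kclResidualMax maximum absolute node-balance violation over free
#'   nodes, amperes.
#'
#' @seealso [solveCircuit()], [kclResidual()]
#' @exportClass CircuitSolution
setClass("CircuitSolution",
         representation(voltages = "numeric", currents = "data.frame",
                        kclResidualMax = "numeric"))

setValidity("CircuitSolution", function(object) {
  if (is.null(names(object@voltages)) && length(object@voltages) > 0)
    return("voltages must be named by node id")
  if (length(object@kclResidualMax) != 1 || object@kclResidualMax < 0)
    return("kclResidualMax must be a single non-negative number")
  TRUE
})

#' LatticeConfig: physiological parameters of the lobule lattice
#'
#' @slot rows,cols hexagon counts of the honeycomb (default 5 x 5).
#' @slot capillaryResistance ohms per capillary segment (default 16).
#' @slot diameterRatio collector-venule diameter over capillary diameter,
#'   dimensionless in \[1, 2\]; boundary resistance follows Poiseuille's
#'   fourth-power law, \code{capillaryResistance / diameterRatio^4}.
#' @slot anodeVoltage,cathodeVoltage volts at the feeding-arteriole anodes
#'   and draining-venule cathodes (defaults 51 and 23, matching choroidal
#'   arteriolar/venous pressures in mmHg).
#'
#' @seealso [LatticeConfig()], [tileLattice()]
#' @exportClass LatticeConfig
setClass("LatticeConfig",
         representation(rows = "integer", cols = "integer",
                        capillaryResistance = "numeric",
                        diameterRatio = "numeric",
                        anodeVoltage = "numeric", cathodeVoltage = "numeric"))

setValidity("LatticeConfig", function(object) {
  msgs <- character(0)
  if (object@rows < 1L || object@cols < 1L)
    msgs <- c(msgs, "rows and cols must be >= 1")
  if (!is.finite(object@capillaryResistance) || object@capillaryResistance <= 0)
    msgs <- c(msgs, "capillaryResistance must be > 0")
  if (!is.finite(object@diameterRatio) || object@diameterRatio < 1)
    msgs <- c(msgs, "diameterRatio must be >= 1")
  if (!(object@anodeVoltage > object@cathodeVoltage))
    msgs <- c(msgs, "anodeVoltage must exceed cathodeVoltage")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' LobuleLattice: a honeycomb of choriocapillaris lobule circuits
#'
#' Wraps a [CircuitNetwork-class] with the hexagon bookkeeping needed by the
#' perfusion metrics: which nodes belong to which lobule, where each lobule's
#' anode sits, and which lobules share a collector-venule boundary edge.
#'
#' @slot network the underlying [CircuitNetwork-class].
#' @slot hexes named list (names \code{"col,row"}), each entry a list with
#'   \code{col}, \code{row}, \code{center} (anode node id), \code{inner}
#'   (6 interior-ring node ids) and \code{boundary} (12 boundary-ring node
#'   ids: 6 corners then 6 edge midpoints). Boundary nodes shared between
#'   adjacent hexagons appear in both memberships but once in the network.
#' @slot config the [LatticeConfig-class] used to build (and possibly
#'   perturb) the lattice.
#' @slot adjacency named list: for each hexagon, the ids of hexagons sharing
#'   a boundary (collector venule) edge with it.
#'
#' @seealso [buildLobule()], [tileLattice()], [applyScenario()]
#' @exportClass LobuleLattice
setClass("LobuleLattice",
         representation(network = "CircuitNetwork", hexes = "list",
                        config = "LatticeConfig", adjacency = "list"))

setValidity("LobuleLattice", function(object) {
  nd <- object@network@nodes
  msgs <- character(0)
  if (length(object@hexes) == 0)
    return("lattice must contain at least one hexagon")
  for (h in object@hexes) {
    ids <- c(h$center, h$inner, h$boundary)
    if (!all(ids %in% nd$id)) {
      msgs <- c(msgs, "hexagon membership references unknown nodes")
      break
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Scenario: an embolism perturbation of the lattice
#'
#' @slot kind one of \code{normal} (no perturbation),
#'   \code{single_disconnect} (one feeding arteriole embolized),
#'   \code{sector_disconnect} (a contiguous sector, as after posterior
#'   ciliary artery occlusion) or \code{custom}.
#' @slot hexagons character vector of hexagon ids (\code{"col,row"}) whose
#'   anodes are disconnected.
#' @slot diameterRatio collector-venule/capillary diameter ratio applied to
#'   the boundary edges when the scenario is applied.
#'
#' @seealso [normalScenario()], [singleDisconnect()], [sectorDisconnect()],
#'   [applyScenario()]
#' @exportClass Scenario
setClass("Scenario",
         representation(kind = "character", hexagons = "character",
                        diameterRatio = "numeric"))

setValidity("Scenario", function(object) {
  msgs <- character(0)
  if (length(object@kind) != 1 || !(object@kind %in% .SCENARIO_KINDS))
    msgs <- c(msgs, paste("kind must be one of:",
                          paste(.SCENARIO_KINDS, collapse = ", ")))
  else {
    n <- length(object@hexagons)
    if (object@kind == "normal" && n != 0)
      msgs <- c(msgs, "normal scenario must disconnect no hexagons")
    if (object@kind == "single_disconnect" && n != 1)
      msgs <- c(msgs, "single_disconnect must name exactly one hexagon")
    if (object@kind == "sector_disconnect" && n < 1)
      msgs <- c(msgs, "sector_disconnect must name at least one hexagon")
  }
  if (anyDuplicated(object@hexagons))
    msgs <- c(msgs, "duplicate hexagon ids")
  if (!is.finite(object@diameterRatio) || object@diameterRatio < 1)
    msgs <- c(msgs, "diameterRatio must be >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' EmbolismModel: a randomized embolism-pattern generator
#'
#' Emulates the two angiographic perfusion-defect categories: scattered
#' lobular defects (independent terminal-arteriole emboli) and segmental
#' defects (occlusion of a posterior ciliary artery supplying a contiguous
#' sector).
#'
#' @slot pattern \code{"scattered"} or \code{"segmental"}.
#' @slot disconnectProbability per-lobule disconnection probability
#'   (scattered pattern).
#' @slot sectorSize number of hexagons in the contiguous sector (segmental
#'   pattern).
#' @slot seed integer RNG seed; identical seeds give identical scenarios.
#'
#' @seealso [EmbolismModel()], [sampleScenario()], [batchRun()]
#' @exportClass EmbolismModel
setClass("EmbolismModel",
         representation(pattern = "character",
                        disconnectProbability = "numeric",
                        sectorSize = "integer", seed = "integer"))

setValidity("EmbolismModel", function(object) {
  msgs <- character(0)
  if (length(object@pattern) != 1 || !(object@pattern %in% .EMBOLISM_PATTERNS))
    msgs <- c(msgs, "pattern must be 'scattered' or 'segmental'")
  p <- object@disconnectProbability
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
    msgs <- c(msgs, "disconnectProbability must lie in [0, 1]")
  if (length(object@sectorSize) != 1 || object@sectorSize < 1L)
    msgs <- c(msgs, "sectorSize must be >= 1")
  if (length(object@seed) != 1 || is.na(object@seed))
    msgs <- c(msgs, "seed must be a single integer")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
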