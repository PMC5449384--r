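#' @include scenario.R
NULL

.hexEdgeSel <- function(lattice, hexagon) {
  h <- .getHex(lattice, hexagon)
  ed <- lattice@network@edges
  interior <- c(h$center, h$inner)
  list(h = h, ed = ed,
       inA = ed$u %in% h$boundary & ed$v %in% interior,   # boundary -> interior
       inB = ed$v %in% h$boundary & ed$u %in% interior)
}

#' Electric influx into a lobule
#'
#' Sum of positive currents entering the hexagon's interior node set (the
#' center and the inner ring) across boundary-to-interior edges, plus the
#' anode's injected current when the feeding arteriole is connected.
#' Boundary-ring throughflow along the collector venules is not counted.
#' In a fully perfused lobule no current crosses the boundary inward, so the
#' influx equals the anode injection; in a disconnected lobule all influx
#' arrives across the boundary from adjacent lobules.
#'
#' @param lattice the (possibly perturbed) [LobuleLattice-class].
#' @param solution a [CircuitSolution-class] solved on
#'   \code{circuit(lattice)}.
#' @param hexagon a hexagon id.
#' @return amperes (non-negative).
#' @export
#' @examples
#' lat <- tileLattice(LatticeConfig())
#' sol <- solveCircuit(circuit(lat))
#' hexInflux(lat, sol, "2,2")
hexInflux <- function(lattice, solution, hexagon) {
  s <- .hexEdgeSel(lattice, hexagon)
  cur <- solution@currents$current
  influx <- sum(pmax(cur[s$inA], 0)) + sum(pmax(-cur[s$inB], 0))
  nd <- lattice@network@nodes
  if (nd$kind[match(s$h$center, nd$id)] == "anode")
    influx <- influx + nodeInjection(solution, s$h$center)
  influx
}

#' Average current of a lobule
#'
#' Mean absolute current over the hexagon's capillary (interior grid) edges.
#'
#' @inheritParams hexInflux
#' @return amperes.
#' @export
averageCurrent <- function(lattice, solution, hexagon) {
  h <- .getHex(lattice, hexagon)
  ed <- lattice@network@edges
  ids <- c(h$center, h$inner, h$boundary)
  sel <- ed$role == "capillary" & ed$u %in% ids & ed$v %in% ids
  if (!any(sel)) return(0)
  mean(abs(solution@currents$current[sel]))
}

#' Per-hexagon influx of the fully perfused twin lattice
#'
#' Builds and solves the fully connected lattice under \code{config} (at its
#' diameter ratio) and returns each hexagon's influx. This is the reference
#' against which perturbed-lattice percentages are computed: the same-index
#' hexagon of an identically configured, unperturbed lattice.
#'
#' @param config a [LatticeConfig-class].
#' @param tolerance solver KCL tolerance, amperes.
#' @return named numeric vector, amperes, one entry per hexagon.
#' @export
referenceInflux <- function(config = LatticeConfig(), tolerance = 1e-9) {
  lat <- tileLattice(config)
  sol <- solveCircuit(lat@network, tolerance = tolerance)
  ids <- names(lat@hexes)
  stats::setNames(
    vapply(ids, function(h) hexInflux(lat, sol, h), numeric(1)), ids)
}

#' Influx of a lobule as a percentage of its perfused reference
#'
#' \code{100 * hexInflux(hexagon) / reference}. The default reference is the
#' influx of the same-index hexagon in a fully connected twin lattice under
#' the same configuration (see [referenceInflux()]).
#'
#' @inheritParams hexInflux
#' @param reference reference influx in amperes; when \code{NULL} the twin
#'   lattice is solved and the same-index hexagon used.
#' @return percent.
#' @export
#' @examples
#' lat <- applyScenario(tileLattice(LatticeConfig()), singleDisconnect("2,2"))
#' sol <- solveCircuit(circuit(lat))
#' influxRatio(lat, sol, "2,2")  # ~27.3
influxRatio <- function(lattice, solution, hexagon, reference = NULL) {
  if (is.null(reference))
    reference <- referenceInflux(lattice@config)[[hexagon]]
  if (!is.finite(reference) || reference <= 0)
    stop("reference influx must be positive")
  100 * hexInflux(lattice, solution, hexagon) / reference
}

#' Per-lobule perfusion metrics table
#'
#' One row per hexagon: embolic order, influx (amperes), average capillary
#' current (amperes), influx as percent of the same-index hexagon in the
#' fully perfused twin lattice (\code{ratio_pct}), and, as an alternative
#' reference, percent of the mean influx of the adjacent connected hexagons
#' in the same solution (\code{ratio_adjacent_pct}; \code{NA} when a hexagon
#' has no connected neighbour).
#'
#' @param lattice a (possibly perturbed) [LobuleLattice-class].
#' @param solution a [CircuitSolution-class] solved on its network.
#' @param reference optional named vector from [referenceInflux()]; computed
#'   from the lattice's config when omitted.
#' @return a data.frame with columns \code{hexagon}, \code{col}, \code{row},
#'   \code{order}, \code{influx_A}, \code{average_current_A},
#'   \code{ratio_pct}, \code{ratio_adjacent_pct}.
#' @export
#' @examples
#' lat <- applyScenario(tileLattice(LatticeConfig()), singleDisconnect("2,2"))
#' m <- hexMetrics(lat, solveCircuit(circuit(lat)))
#' m[m$order != "connected", ]
hexMetrics <- function(lattice, solution, reference = NULL) {
  ids <- names(lattice@hexes)
  if (is.null(reference)) reference <- referenceInflux(lattice@config)
  ord <- classifyOrder(lattice)
  influx <- vapply(ids, function(h) hexInflux(lattice, solution, h),
                   numeric(1))
  avg <- vapply(ids, function(h) averageCurrent(lattice, solution, h),
                numeric(1))
  conn <- ids[ord[ids] == "connected"]
  adjRef <- vapply(ids, function(h) {
    nb <- intersect(lattice@adjacency[[h]], conn)
    if (length(nb) == 0) NA_real_ else mean(influx[nb])
  }, numeric(1))
  data.frame(
    hexagon = ids,
    col = vapply(lattice@hexes, `[[`, integer(1), "col"),
    row = vapply(lattice@hexes, `[[`, integer(1), "row"),
    order = as.character(ord[ids]),
    influx_A = unname(influx),
    average_current_A = unname(avg),
    ratio_pct = unname(100 * influx / reference[ids]),
    ratio_adjacent_pct = unname(100 * influx / adjRef),
    row.names = NULL)
}

#' Run one embolism experiment end to end
#'
#' Builds the lattice for \code{config}, applies \code{scenario}, solves the
#' nodal system and tabulates per-lobule metrics against the fully perfused
#' twin reference.
#'
#' @param config a [LatticeConfig-class].
#' @param scenario a [Scenario-class].
#' @param tolerance solver KCL tolerance, amperes.
#' @return a list with elements \code{lattice} (perturbed
#'   [LobuleLattice-class]), \code{solution} ([CircuitSolution-class]),
#'   \code{metrics} (data.frame from [hexMetrics()]) and \code{reference}
#'   (named vector from [referenceInflux()]).
#' @export
#' @examples
#' ex <- runExperiment(LatticeConfig(), singleDisconnect("2,2"))
#' subset(ex$metrics, order == "first_order")$ratio_pct
runExperiment <- function(config = LatticeConfig(),
                          scenario = normalScenario(config@diameterRatio),
                          tolerance = 1e-9) {
  base <- tileLattice(config)
  lat <- applyScenario(base, scenario)
  sol <- solveCircuit(lat@network, tolerance = tolerance)
  ref <- referenceInflux(lat@config, tolerance = tolerance)
  list(lattice = lat, solution = sol,
       metrics = hexMetrics(lat, sol, reference = ref), reference = ref)
}

#' Sweep the collector-venule boundary resistance
#'
#' Re-runs a scenario over a series of collector-venule/capillary diameter
#' ratios and summarizes, per ratio: the boundary resistance, the mean
#' influx percentage by embolic order, and the mean per-hexagon average
#' capillary current. Regenerates the boundary-resistance response curves of
#' the model (more even, higher flow at low boundary resistance in perfused
#' lobules; lower relative influx in embolized ones).
#'
#' @param config a [LatticeConfig-class].
#' @param scenario a [Scenario-class]; its own diameter ratio is overridden
#'   by each swept value.
#' @param ratios numeric vector of diameter ratios in \[1, 2\].
#' @return a data.frame with one row per ratio and columns
#'   \code{diameter_ratio}, \code{boundary_ohm}, \code{connected_pct},
#'   \code{first_order_pct}, \code{second_order_pct}, \code{deeper_pct}
#'   (NA where an order is absent) and \code{mean_hexagon_current_A}.
#' @export
#' @examples
#' sweepBoundaryResistance(LatticeConfig(), singleDisconnect("2,2"),
#'                         ratios = c(1, 2))
sweepBoundaryResistance <- function(config, scenario, ratios) {
  stopifnot(is(config, "LatticeConfig"), is(scenario, "Scenario"))
  if (any(!is.finite(ratios)) || any(ratios < 1))
    stop("ratios must be finite and >= 1")
  empty <- data.frame(diameter_ratio = numeric(0), boundary_ohm = numeric(0),
                      connected_pct = numeric(0), first_order_pct = numeric(0),
                      second_order_pct = numeric(0), deeper_pct = numeric(0),
                      mean_hexagon_current_A = numeric(0))
  if (length(ratios) == 0) return(empty)
  base <- tileLattice(config)
  rows <- lapply(ratios, function(r) {
    sc <- scenario
    sc@diameterRatio <- r
    lat <- applyScenario(base, sc)
    sol <- solveCircuit(lat@network)
    m <- hexMetrics(lat, sol, reference = referenceInflux(lat@config))
    byOrder <- function(o) {
      v <- m$ratio_pct[m$order == o]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    data.frame(diameter_ratio = r,
               boundary_ohm = boundaryResistance(
                 config@capillaryResistance, r),
               connected_pct = byOrder("connected"),
               first_order_pct = byOrder("first_order"),
               second_order_pct = byOrder("second_order"),
               deeper_pct = byOrder("deeper"),
               mean_hexagon_current_A = mean(m$average_current_A))
  })
  do.call(rbind, rows)
}

#' Format a percentage at reporting precision
#'
#' One decimal place, two below 0.1 percent; full precision is retained in
#' all computed tables, this formatter is applied only at the reporting
#' layer (CLI output, show methods).
#'
#' @param pct numeric percentages.
#' @return character vector.
#' @export
#' @examples formatPct(c(27.28031, 0.04158))
formatPct <- function(pct) {
  ifelse(is.na(pct), NA_character_,
         ifelse(abs(pct) < 0.1, sprintf("%.2f", pct), sprintf("%.1f", pct)))
}
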