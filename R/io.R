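#' @include synthetic.R
NULL

.nodesToJSONList <- function(nd) {
  lapply(seq_len(nrow(nd)), function(i) {
    rec <- list(id = nd$id[i], kind = nd$kind[i],
                position = c(nd$x[i], nd$y[i]))
    if (!is.na(nd$fixedVoltage[i])) rec$fixed_voltage <- nd$fixedVoltage[i]
    rec
  })
}

.edgesToJSONList <- function(ed) {
  lapply(seq_len(nrow(ed)), function(i)
    list(endpoints = c(ed$u[i], ed$v[i]), resistance = ed$resistance[i],
         role = ed$role[i]))
}

#' Read and write circuit networks as JSON
#'
#' Schema: an object with \code{nodes} (records with \code{id},
#' \code{kind}, \code{position} \[x, y\] and, for anodes/cathodes,
#' \code{fixed_voltage}) and \code{edges} (records with \code{endpoints}
#' \[u, v\], \code{resistance}, \code{role}). Numbers are written at full
#' precision; a write/read cycle reproduces the network exactly.
#'
#' @param network a [CircuitNetwork-class].
#' @param path file path.
#' @return \code{writeCircuitJSON}: the path, invisibly;
#'   \code{readCircuitJSON}: a [CircuitNetwork-class].
#' @name circuit-json
#' @examples
#' lob <- buildLobule(LatticeConfig())
#' f <- tempfile(fileext = ".json")
#' writeCircuitJSON(circuit(lob), f)
#' identical(nodeTable(readCircuitJSON(f)), nodeTable(lob))
NULL

#' @rdname circuit-json
#' @export
writeCircuitJSON <- function(network, path) {
  stopifnot(is(network, "CircuitNetwork"))
  obj <- list(nodes = .nodesToJSONList(network@nodes),
              edges = .edgesToJSONList(network@edges))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

.parseNodesJSON <- function(nodes) {
  data.frame(
    id = vapply(nodes, function(n) as.character(n$id), character(1)),
    kind = vapply(nodes, function(n) as.character(n$kind), character(1)),
    x = vapply(nodes, function(n) as.numeric(n$position[[1]]), numeric(1)),
    y = vapply(nodes, function(n) as.numeric(n$position[[2]]), numeric(1)),
    fixedVoltage = vapply(nodes, function(n)
      if (is.null(n$fixed_voltage)) NA_real_ else as.numeric(n$fixed_voltage),
      numeric(1)),
    row.names = NULL)
}

.parseEdgesJSON <- function(edges) {
  data.frame(
    u = vapply(edges, function(e) as.character(e$endpoints[[1]]), character(1)),
    v = vapply(edges, function(e) as.character(e$endpoints[[2]]), character(1)),
    resistance = vapply(edges, function(e) as.numeric(e$resistance),
                        numeric(1)),
    role = vapply(edges, function(e) as.character(e$role), character(1)),
    row.names = NULL)
}

#' @rdname circuit-json
#' @export
readCircuitJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  CircuitNetwork(.parseNodesJSON(obj$nodes), .parseEdgesJSON(obj$edges))
}

.configToList <- function(config) {
  list(rows = config@rows, cols = config@cols,
       capillary_resistance = config@capillaryResistance,
       diameter_ratio = config@diameterRatio,
       anode_voltage = config@anodeVoltage,
       cathode_voltage = config@cathodeVoltage)
}

.configFromList <- function(lst) {
  preset <- if (!is.null(lst$preset)) lst$preset else "methods"
  LatticeConfig(
    rows = if (is.null(lst$rows)) 5L else lst$rows,
    cols = if (is.null(lst$cols)) 5L else lst$cols,
    capillaryResistance = if (is.null(lst$capillary_resistance)) 16
                          else lst$capillary_resistance,
    diameterRatio = if (is.null(lst$diameter_ratio)) 1 else lst$diameter_ratio,
    anodeVoltage = lst$anode_voltage,     # NULL falls back to the preset
    cathodeVoltage = lst$cathode_voltage,
    preset = preset)
}

#' Read and write lobule lattices as JSON
#'
#' Extends the circuit schema (see [writeCircuitJSON()]) with a
#' \code{config} block and a \code{hexagons} block recording each hexagon's
#' center, inner-ring and boundary-ring node ids. Hexagon adjacency is
#' rebuilt on read from the shared boundary edges.
#'
#' @param lattice a [LobuleLattice-class].
#' @param path file path.
#' @name lattice-json
NULL

#' @rdname lattice-json
#' @export
writeLatticeJSON <- function(lattice, path) {
  stopifnot(is(lattice, "LobuleLattice"))
  obj <- list(
    config = .configToList(lattice@config),
    nodes = .nodesToJSONList(lattice@network@nodes),
    edges = .edgesToJSONList(lattice@network@edges),
    hexagons = lapply(lattice@hexes, function(h)
      list(col = h$col, row = h$row, center = h$center,
           inner = as.list(h$inner), boundary = as.list(h$boundary))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname lattice-json
#' @export
readLatticeJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  network <- CircuitNetwork(.parseNodesJSON(obj$nodes),
                            .parseEdgesJSON(obj$edges))
  hexes <- lapply(obj$hexagons, function(h)
    list(col = as.integer(h$col), row = as.integer(h$row),
         center = as.character(h$center),
         inner = vapply(h$inner, as.character, character(1)),
         boundary = vapply(h$boundary, as.character, character(1))))
  names(hexes) <- names(obj$hexagons)
  config <- .configFromList(obj$config)
  ## rebuild adjacency: hexagons sharing >= 2 boundary nodes share an edge
  ids <- names(hexes)
  adjacency <- stats::setNames(lapply(ids, function(i) {
    bi <- hexes[[i]]$boundary
    nb <- ids[vapply(ids, function(j)
      j != i && length(intersect(bi, hexes[[j]]$boundary)) >= 2, logical(1))]
    sort(nb, method = "radix")
  }), ids)
  new("LobuleLattice", network = network, hexes = hexes, config = config,
      adjacency = adjacency)
}

#' Export a solution as CSV tables
#'
#' Writes a node table (\code{node_id,voltage}) and an edge table
#' (\code{u,v,resistance,role,current}); currents are signed positive from
#' \code{u} to \code{v}.
#'
#' @param solution a [CircuitSolution-class].
#' @param nodesPath,edgesPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeSolutionCSV <- function(solution, nodesPath, edgesPath) {
  stopifnot(is(solution, "CircuitSolution"))
  nd <- data.frame(node_id = names(solution@voltages),
                   voltage = unname(solution@voltages))
  utils::write.csv(nd, nodesPath, row.names = FALSE)
  utils::write.csv(solution@currents, edgesPath, row.names = FALSE,
                   quote = FALSE)
  invisible(c(nodesPath, edgesPath))
}

.isYAML <- function(path) grepl("\\.ya?ml$", path, ignore.case = TRUE)

#' Read and write scenario files
#'
#' A scenario file is JSON or YAML (by extension) with fields \code{kind},
#' \code{hexagons} and either \code{diameter_ratio} or an explicit
#' \code{boundary_resistance} (converted through the Poiseuille relation
#' against \code{capillary_resistance}, default 16 ohm).
#'
#' @param scenario a [Scenario-class].
#' @param path file path (\code{.json}, \code{.yaml} or \code{.yml}).
#' @name scenario-files
NULL

#' @rdname scenario-files
#' @export
writeScenarioFile <- function(scenario, path) {
  stopifnot(is(scenario, "Scenario"))
  obj <- list(kind = scenario@kind, hexagons = as.list(scenario@hexagons),
              diameter_ratio = scenario@diameterRatio)
  if (.isYAML(path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                            pretty = TRUE)
  invisible(path)
}

#' @rdname scenario-files
#' @export
readScenarioFile <- function(path) {
  obj <- if (.isYAML(path)) yaml::read_yaml(path)
         else jsonlite::read_json(path)
  ratio <- obj$diameter_ratio
  if (is.null(ratio) && !is.null(obj$boundary_resistance)) {
    rc <- if (is.null(obj$capillary_resistance)) 16
          else obj$capillary_resistance
    ratio <- (rc / obj$boundary_resistance)^(1 / 4)
  }
  if (is.null(ratio)) ratio <- 1
  hex <- unname(vapply(obj$hexagons, as.character, character(1)))
  kind <- if (is.null(obj$kind)) "custom" else obj$kind
  new("Scenario", kind = kind, hexagons = hex,
      diameterRatio = as.numeric(ratio))
}

#' Read a lattice configuration file
#'
#' JSON or YAML with fields \code{rows}, \code{cols},
#' \code{capillary_resistance}, \code{diameter_ratio},
#' \code{anode_voltage}, \code{cathode_voltage} and/or \code{preset}
#' (\code{"methods"} or \code{"figure6"}); missing fields take the defaults
#' of [LatticeConfig()].
#'
#' @param path file path.
#' @return a [LatticeConfig-class].
#' @export
readConfigFile <- function(path) {
  obj <- if (.isYAML(path)) yaml::read_yaml(path)
         else jsonlite::read_json(path)
  .configFromList(obj)
}
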