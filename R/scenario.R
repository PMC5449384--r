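#' @include lobule-mesh.R
NULL

#' Embolism scenarios
#'
#' Constructors for the perturbations applied to a lobule lattice.
#' \code{normalScenario()} leaves every feeding arteriole connected.
#' \code{singleDisconnect()} embolizes one terminal arteriole: the named
#' hexagon's anode loses its fixed voltage and becomes a passive junction
#' (the arteriole stump keeps its wiring). \code{sectorDisconnect()}
#' embolizes a contiguous block of hexagons, as after occlusion of a
#' posterior ciliary artery. \code{customScenario()} accepts any set of
#' hexagons.
#'
#' @param hexagon a hexagon id such as \code{"2,2"}.
#' @param hexagons character vector of hexagon ids forming a contiguous
#'   block (contiguity is checked against the lattice by
#'   [applyScenario()]).
#' @param diameterRatio collector-venule/capillary diameter ratio in
#'   \[1, 2\] applied to the boundary edges.
#' @return a [Scenario-class].
#' @name scenarios
#' @examples
#' singleDisconnect("2,2")
#' sectorDisconnect(defaultSector(LatticeConfig()))
NULL

#' @rdname scenarios
#' @export
normalScenario <- function(diameterRatio = 1)
  new("Scenario", kind = "normal", hexagons = character(0),
      diameterRatio = as.numeric(diameterRatio))

#' @rdname scenarios
#' @export
singleDisconnect <- function(hexagon = "2,2", diameterRatio = 1)
  new("Scenario", kind = "single_disconnect",
      hexagons = as.character(hexagon),
      diameterRatio = as.numeric(diameterRatio))

#' @rdname scenarios
#' @export
sectorDisconnect <- function(hexagons, diameterRatio = 1)
  new("Scenario", kind = "sector_disconnect",
      hexagons = as.character(hexagons),
      diameterRatio = as.numeric(diameterRatio))

#' @rdname scenarios
#' @export
customScenario <- function(hexagons, diameterRatio = 1)
  new("Scenario", kind = "custom", hexagons = as.character(hexagons),
      diameterRatio = as.numeric(diameterRatio))

#' Default occluded sector of a lattice
#'
#' The frozen default sector used by the posterior-ciliary-artery occlusion
#' experiment: the 3 x 3 block of hexagons in the upper-left corner of the
#' lattice (columns 0-2, top three rows). On a 5 x 5 lattice it yields five
#' first-order and three second-order disconnected hexagons plus one deeper
#' corner hexagon.
#'
#' @param config a [LatticeConfig-class].
#' @return character vector of hexagon ids.
#' @export
#' @examples defaultSector(LatticeConfig())
defaultSector <- function(config = LatticeConfig()) {
  validObject(config)
  cols <- seq_len(min(3L, config@cols)) - 1L
  rows <- seq(max(0L, config@rows - 3L), config@rows - 1L)
  as.vector(outer(cols, rows, hexId))
}

setMethod("show", "Scenario", function(object) {
  cat("Scenario:", object@kind,
      if (length(object@hexagons))
        paste0("(", paste(object@hexagons, collapse = " "), ")") else "",
      "; diameter ratio", object@diameterRatio, "\n")
})

.hexDistances <- function(lattice, sources) {
  ## hexagon-graph BFS distance from the source set (shared-edge adjacency)
  adj <- lattice@adjacency
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

.checkContiguous <- function(lattice, hexagons) {
  if (length(hexagons) <= 1) return(TRUE)
  adj <- lapply(lattice@adjacency[hexagons], intersect, hexagons)
  seen <- hexagons[1]
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(hexagons)
}

#' Apply an embolism scenario to a lobule lattice
#'
#' Demotes the anodes of the scenario's hexagons to free internal nodes
#' (fixed voltage removed, wiring kept: the embolized arteriole stump stays
#' a passive junction) and sets every collector-venule boundary edge to the
#' Poiseuille resistance implied by the scenario's diameter ratio.
#'
#' @param lattice a [LobuleLattice-class].
#' @param scenario a [Scenario-class].
#' @return a new [LobuleLattice-class] holding the perturbed network; the
#'   untouched input is not modified.
#' @export
#' @examples
#' lat <- tileLattice(LatticeConfig())
#' emb <- applyScenario(lat, singleDisconnect("2,2"))
#' sum(nodeTable(emb)$kind == "anode")  # 24
applyScenario <- function(lattice, scenario) {
  stopifnot(is(lattice, "LobuleLattice"), is(scenario, "Scenario"))
  validObject(scenario)
  unknown <- setdiff(scenario@hexagons, names(lattice@hexes))
  if (length(unknown))
    stop("unknown hexagon index: ", paste(unknown, collapse = ", "))
  if (scenario@kind == "sector_disconnect" &&
      !.checkContiguous(lattice, scenario@hexagons))
    stop("sector_disconnect hexagons must form a contiguous block")
  net <- lattice@network
  nd <- net@nodes
  ed <- net@edges
  drop <- vapply(lattice@hexes[scenario@hexagons], `[[`, character(1),
                 "center")
  sel <- nd$id %in% drop
  nd$kind[sel] <- "internal"
  nd$fixedVoltage[sel] <- NA_real_
  rb <- boundaryResistance(lattice@config@capillaryResistance,
                           scenario@diameterRatio)
  ed$resistance[ed$role == "collector_venule"] <- rb
  cfg <- lattice@config
  cfg@diameterRatio <- scenario@diameterRatio
  new("LobuleLattice", network = new("CircuitNetwork", nodes = nd, edges = ed),
      hexes = lattice@hexes, config = cfg, adjacency = lattice@adjacency)
}

#' Hexagons whose anode is disconnected
#'
#' Read back from the lattice's network which lobules have lost their
#' feeding-arteriole anode (center node no longer of kind \code{anode}).
#'
#' @param lattice a [LobuleLattice-class].
#' @return character vector of hexagon ids.
#' @export
disconnectedHexagons <- function(lattice) {
  nd <- lattice@network@nodes
  anodeIds <- nd$id[nd$kind == "anode"]
  centers <- vapply(lattice@hexes, `[[`, character(1), "center")
  names(centers)[!(centers %in% anodeIds)]
}

#' Classify lobules by embolic order
#'
#' Connected hexagons are \code{connected}; disconnected hexagons sharing a
#' boundary edge with a connected one are \code{first_order}; those at
#' hexagon-graph distance 2 from the connected set are \code{second_order};
#' anything farther is \code{deeper}.
#'
#' @param lattice a [LobuleLattice-class], normally the output of
#'   [applyScenario()].
#' @param scenario optional [Scenario-class]; when omitted the disconnected
#'   set is read from the lattice itself.
#' @return a named factor (levels \code{connected}, \code{first_order},
#'   \code{second_order}, \code{deeper}) over all hexagons.
#' @export
#' @examples
#' lat <- applyScenario(tileLattice(LatticeConfig()), singleDisconnect("2,2"))
#' table(classifyOrder(lat))
classifyOrder <- function(lattice, scenario = NULL) {
  stopifnot(is(lattice, "LobuleLattice"))
  dis <- if (is.null(scenario)) disconnectedHexagons(lattice)
         else scenario@hexagons
  ids <- names(lattice@hexes)
  conn <- setdiff(ids, dis)
  ord <- stats::setNames(rep("connected", length(ids)), ids)
  if (length(dis) > 0) {
    if (length(conn) == 0) {
      ord[] <- "deeper"
    } else {
      dist <- .hexDistances(lattice, conn)
      ord[dist == 1] <- "first_order"
      ord[dist == 2] <- "second_order"
      ord[dist > 2] <- "deeper"
    }
  }
  factor(ord, levels = .ORDER_LEVELS)
}
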