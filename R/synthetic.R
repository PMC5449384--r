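#' @include metrics.R
NULL

#' Construct an embolism-pattern generator
#'
#' @param pattern \code{"scattered"} (independent per-lobule emboli, the
#'   scattered angiographic defect category) or \code{"segmental"} (one
#'   contiguous sector, the posterior-ciliary-artery defect category).
#' @param disconnectProbability per-lobule disconnection probability for the
#'   scattered pattern (default 0.2).
#' @param sectorSize hexagon count of the segmental block (default 9, a
#'   3 x 3-sized sector).
#' @param seed integer RNG seed.
#' @return an [EmbolismModel-class].
#' @export
#' @examples
#' EmbolismModel("scattered", disconnectProbability = 0.3, seed = 42L)
EmbolismModel <- function(pattern = c("scattered", "segmental"),
                          disconnectProbability = 0.2, sectorSize = 9L,
                          seed = 1L) {
  pattern <- match.arg(pattern)
  new("EmbolismModel", pattern = pattern,
      disconnectProbability = as.numeric(disconnectProbability),
      sectorSize = as.integer(sectorSize), seed = as.integer(seed))
}

setMethod("show", "EmbolismModel", function(object) {
  cat("EmbolismModel:", object@pattern,
      if (object@pattern == "scattered")
        paste0("(p = ", object@disconnectProbability, ")")
      else paste0("(sector size ", object@sectorSize, ")"),
      "; seed", object@seed, "\n")
})

## Run expr with a locally seeded RNG; the caller's .Random.seed is restored.
.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a randomized embolism scenario
#'
#' Scattered pattern: every hexagon's anode is disconnected independently
#' with the model's probability. Segmental pattern: a contiguous block of
#' \code{sectorSize} hexagons grown by breadth-first accretion from a
#' randomly chosen corner hexagon, ties broken by hexagon id order.
#' Reproducible: the same (model, config) pair always yields the same
#' scenario, and the caller's RNG state is left untouched.
#'
#' @param model an [EmbolismModel-class].
#' @param config a [LatticeConfig-class]; the scenario inherits its
#'   diameter ratio.
#' @param seed optional seed overriding the model's (used by [batchRun()]
#'   for replicate streams).
#' @return a [Scenario-class] (\code{normal} when nothing is disconnected).
#' @export
#' @examples
#' sampleScenario(EmbolismModel("segmental", sectorSize = 9L, seed = 7L),
#'                LatticeConfig())
sampleScenario <- function(model, config = LatticeConfig(), seed = NULL) {
  stopifnot(is(model, "EmbolismModel"), is(config, "LatticeConfig"))
  validObject(model)
  nHex <- as.integer(config@rows) * as.integer(config@cols)
  if (model@pattern == "segmental" && model@sectorSize > nHex)
    stop("sectorSize exceeds the number of hexagons in the lattice")
  if (is.null(seed)) seed <- model@seed
  ratio <- config@diameterRatio
  .withLocalSeed(seed, {
    if (model@pattern == "scattered") {
      ids <- as.vector(outer(seq_len(config@cols) - 1L,
                             seq_len(config@rows) - 1L, hexId))
      ids <- sort(ids, method = "radix")
      hit <- stats::runif(length(ids)) < model@disconnectProbability
      dis <- ids[hit]
      if (length(dis) == 0) normalScenario(ratio)
      else customScenario(dis, ratio)
    } else {
      lat <- tileLattice(config)
      corners <- c(hexId(0, 0), hexId(config@cols - 1L, 0),
                   hexId(0, config@rows - 1L),
                   hexId(config@cols - 1L, config@rows - 1L))
      corners <- unique(corners)
      start <- corners[sample.int(length(corners), 1)]
      block <- start
      frontier <- start
      while (length(block) < model@sectorSize) {
        cand <- setdiff(
          sort(unique(unlist(lat@adjacency[frontier], use.names = FALSE)),
               method = "radix"),
          block)
        if (length(cand) == 0) break
        take <- utils::head(cand, model@sectorSize - length(block))
        block <- c(block, take)
        frontier <- take
      }
      sectorDisconnect(block, ratio)
    }
  })
}

#' Batch-run randomized embolism scenarios
#'
#' Draws \code{nReplicates} independent scenarios from the model (replicate
#' \code{i} uses seed \code{model@seed + i - 1}), solves each on the
#' configured lattice, and summarizes influx percentages by embolic order.
#'
#' @param model an [EmbolismModel-class].
#' @param config a [LatticeConfig-class].
#' @param nReplicates number of independent scenarios (>= 1).
#' @return a list with \code{replicates} (data.frame: \code{replicate},
#'   \code{seed}, \code{order}, \code{mean_ratio_pct}, \code{n_hexagons})
#'   and \code{pooled} (data.frame: \code{order}, \code{mean_ratio_pct},
#'   \code{sd_ratio_pct}, \code{n_replicates}), pooling the per-replicate
#'   order means.
#' @export
#' @examples
#' br <- batchRun(EmbolismModel("scattered", disconnectProbability = 0.3,
#'                              seed = 1L),
#'                LatticeConfig(rows = 3L, cols = 3L), nReplicates = 3)
#' br$pooled
batchRun <- function(model, config = LatticeConfig(), nReplicates = 10) {
  stopifnot(nReplicates >= 1)
  base <- tileLattice(config)
  ref <- referenceInflux(config)
  rows <- vector("list", nReplicates)
  for (i in seq_len(nReplicates)) {
    sd_i <- model@seed + i - 1L
    sc <- sampleScenario(model, config, seed = sd_i)
    lat <- applyScenario(base, sc)
    sol <- solveCircuit(lat@network)
    m <- hexMetrics(lat, sol, reference = ref)
    agg <- stats::aggregate(ratio_pct ~ order, data = m, FUN = mean)
    cnt <- table(m$order)[as.character(agg$order)]
    rows[[i]] <- data.frame(replicate = i, seed = sd_i,
                            order = as.character(agg$order),
                            mean_ratio_pct = agg$ratio_pct,
                            n_hexagons = as.integer(cnt))
  }
  reps <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(split(reps, reps$order), function(d) {
    data.frame(order = d$order[1], mean_ratio_pct = mean(d$mean_ratio_pct),
               sd_ratio_pct = stats::sd(d$mean_ratio_pct),
               n_replicates = nrow(d))
  }))
  rownames(pooled) <- NULL
  list(replicates = reps, pooled = pooled)
}
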