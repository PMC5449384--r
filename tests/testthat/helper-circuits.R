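# Shared fixtures: small hand-built circuits, a random connected-network
# generator, and a dense brute-force nodal solver kept deliberately
# independent of the package's sparse assembly (per-pair scans, full-matrix
# Dirichlet rows, base::solve).

# The two-free-node illustration circuit: fixed p (0 V) and q (10 V);
# free r (p-r via R1, q-r via R2) and s (p-s via R3, q-s via R4), bridged
# by r-s via R5.
workedExampleNetwork <- function(R1 = 1, R2 = 1, R3 = 1, R4 = 1, R5 = 1,
                                 vp = 0, vq = 10) {
  nd <- data.frame(id = c("p", "q", "r", "s"),
                   kind = c("cathode", "anode", "internal", "internal"),
                   fixedVoltage = c(vp, vq, NA, NA))
  ed <- data.frame(u = c("p", "q", "p", "q", "r"),
                   v = c("r", "r", "s", "s", "s"),
                   resistance = c(R1, R2, R3, R4, R5))
  CircuitNetwork(nd, ed)
}

dividerNetwork <- function(R1 = 1, R2 = 1, va = 10) {
  nd <- data.frame(id = c("a", "m", "b"),
                   kind = c("cathode", "internal", "anode"),
                   fixedVoltage = c(0, NA, va))
  CircuitNetwork(nd, data.frame(u = c("a", "m"), v = c("m", "b"),
                                resistance = c(R1, R2)))
}

randomConnectedNetwork <- function(nNodes, nFixed = 2) {
  ids <- sprintf("n%02d", seq_len(nNodes))
  # random spanning tree guarantees connectivity; extra edges add cycles
  parent <- vapply(2:nNodes, function(i) sample.int(i - 1, 1), integer(1))
  u <- ids[parent]
  v <- ids[2:nNodes]
  nExtra <- sample.int(nNodes, 1)
  for (k in seq_len(nExtra)) {
    pair <- sample.int(nNodes, 2)
    a <- ids[min(pair)]; b <- ids[max(pair)]
    if (!any((u == a & v == b) | (u == b & v == a))) {
      u <- c(u, a); v <- c(v, b)
    }
  }
  resistance <- 10^stats::runif(length(u), -1, 2)
  fixedIdx <- sample.int(nNodes, nFixed)
  kind <- rep("internal", nNodes)
  kind[fixedIdx] <- sample(c("anode", "cathode"), nFixed, replace = TRUE)
  fv <- rep(NA_real_, nNodes)
  fv[fixedIdx] <- stats::runif(nFixed, -10, 50)
  nd <- data.frame(id = ids, kind = kind, fixedVoltage = fv)
  CircuitNetwork(nd, data.frame(u = u, v = v, resistance = resistance))
}

# Dense brute-force solve of the full Kirchhoff system: one row per node,
# identity rows for fixed nodes, per-node edge scans for free nodes.
denseOracleSolve <- function(network) {
  nd <- nodeTable(network)
  ed <- edgeTable(network)
  n <- nrow(nd)
  M <- matrix(0, n, n, dimnames = list(nd$id, nd$id))
  b <- numeric(n)
  for (i in seq_len(n)) {
    id <- nd$id[i]
    if (nd$kind[i] != "internal") {
      M[i, i] <- 1
      b[i] <- nd$fixedVoltage[i]
    } else {
      for (e in seq_len(nrow(ed))) {
        other <- if (ed$u[e] == id) ed$v[e]
                 else if (ed$v[e] == id) ed$u[e]
                 else next
        g <- 1 / ed$resistance[e]
        M[i, i] <- M[i, i] + g
        M[i, other] <- M[i, other] - g
      }
    }
  }
  stats::setNames(as.numeric(solve(M, b)), nd$id)
}

# Max voltage discrepancy between the package solver and the dense oracle
# over nNetworks random connected networks (5-30 nodes, log-uniform
# resistances, 1-3 fixed nodes). Also checks KCL, global conservation and
# the maximum principle on each network; returns the worst voltage error.
checkSolverAgainstOracle <- function(nNetworks = 100) {
  worst <- 0
  for (k in seq_len(nNetworks)) {
    net <- randomConnectedNetwork(sample(5:30, 1), sample(1:3, 1))
    sol <- solveCircuit(net)
    oracle <- denseOracleSolve(net)
    worst <- max(worst, max(abs(voltages(sol)[names(oracle)] - oracle)))
    nd <- nodeTable(net)
    fixedIds <- nd$id[nd$kind != "internal"]
    inj <- vapply(fixedIds, function(id) nodeInjection(sol, id), numeric(1))
    totalSource <- sum(pmax(inj, 0))
    # with a single fixed node the network carries no current and the
    # balance is pure rounding noise; 1e-12 A floors the relative bound
    expect_lt(kclResidual(net, sol), 1e-9 * totalSource + 1e-12)
    expect_lt(abs(sum(inj)), 1e-9 * totalSource + 1e-12)
    expect_true(all(voltages(sol) >= min(nd$fixedVoltage, na.rm = TRUE) - 1e-9))
    expect_true(all(voltages(sol) <= max(nd$fixedVoltage, na.rm = TRUE) + 1e-9))
  }
  worst
}

# Influx percentages at the six endpoint settings of the embolism
# experiments (single disconnection and default-sector occlusion, boundary
# at 16 and 1 ohm), recomputed from scratch.
endpointPercentages <- function() {
  cfg <- LatticeConfig()
  single <- vapply(c(1, 2), function(r) {
    ex <- runExperiment(cfg, singleDisconnect("2,2", diameterRatio = r))
    ex$metrics$ratio_pct[ex$metrics$hexagon == "2,2"]
  }, numeric(1))
  sector <- lapply(c(1, 2), function(r) {
    ex <- runExperiment(cfg, sectorDisconnect(defaultSector(cfg),
                                              diameterRatio = r))
    m <- ex$metrics
    c(first = mean(m$ratio_pct[m$order == "first_order"]),
      second = mean(m$ratio_pct[m$order == "second_order"]))
  })
  c(single_16 = single[1], single_1 = single[2],
    first_16 = sector[[1]][["first"]], first_1 = sector[[2]][["first"]],
    second_16 = sector[[1]][["second"]], second_1 = sector[[2]][["second"]])
}
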