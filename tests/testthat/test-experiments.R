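test_that("the normal scenario leaves the lattice unchanged", {
  lat <- tileLattice(LatticeConfig())
  out <- applyScenario(lat, normalScenario(diameterRatio = 1))
  expect_identical(nodeTable(out), nodeTable(lat))
  expect_identical(edgeTable(out), edgeTable(lat))
})

test_that("a single disconnection demotes exactly one anode and reverses its gradient", {
  lat <- tileLattice(LatticeConfig())
  emb <- applyScenario(lat, singleDisconnect("2,2"))
  expect_equal(sum(nodeTable(emb)$kind == "anode"),
               sum(nodeTable(lat)$kind == "anode") - 1)
  expect_identical(disconnectedHexagons(emb), "2,2")
  sol <- solveCircuit(circuit(emb))
  vStump <- voltages(sol)[anodeNode(emb, "2,2")]
  expect_lt(vStump, 51)
  expect_gt(vStump, 23)
  expect_error(applyScenario(lat, singleDisconnect("9,9")), "unknown hexagon")
})

test_that("influx equals anode injection when connected and stays positive when embolized", {
  lat <- tileLattice(LatticeConfig())
  emb <- applyScenario(lat, singleDisconnect("2,2"))
  sol <- solveCircuit(circuit(emb))
  # a distant connected hexagon still receives exactly its anode current
  expect_equal(hexInflux(emb, sol, "4,4"),
               nodeInjection(sol, anodeNode(emb, "4,4")),
               tolerance = 1e-6)
  expect_gt(hexInflux(emb, sol, "2,2"), 0)
})

test_that("influx attenuates across each additional lobule boundary", {
  cfg <- LatticeConfig(rows = 3L, cols = 3L)
  lat <- tileLattice(cfg)
  center <- "1,1"
  ring <- c(center, hexAdjacency(lat)[[center]])
  solo <- solveCircuit(circuit(applyScenario(lat, singleDisconnect(center))))
  deep <- solveCircuit(circuit(applyScenario(lat, customScenario(ring))))
  latSolo <- applyScenario(lat, singleDisconnect(center))
  latDeep <- applyScenario(lat, customScenario(ring))
  expect_lt(hexInflux(latDeep, deep, center),
            hexInflux(latSolo, solo, center))
})

test_that("a lobule's influx ratio against itself is 100 percent", {
  lat <- tileLattice(LatticeConfig())
  sol <- solveCircuit(circuit(lat))
  expect_equal(influxRatio(lat, sol, "2,2"), 100, tolerance = 1e-9)
  expect_error(influxRatio(lat, sol, "2,2", reference = 0), "positive")
})

test_that("disconnected influx ratio rises monotonically with boundary resistance", {
  ratios <- (16 / seq(16, 1, length.out = 9))^(1 / 4)  # 9 points over [1,16] ohm
  tab <- sweepBoundaryResistance(LatticeConfig(), singleDisconnect("2,2"),
                                 ratios)
  expect_equal(nrow(tab), 9)
  tab <- tab[order(tab$boundary_ohm), ]
  expect_true(all(diff(tab$first_order_pct) > 0))
  expect_true(all(tab$first_order_pct < 100))
  # perfused lobules flow less as the venule narrows
  expect_true(all(diff(tab$mean_hexagon_current_A) < 0))
})

test_that("embolic order classification follows hexagon-graph distance", {
  cfg <- LatticeConfig()
  lat <- tileLattice(cfg)
  single <- classifyOrder(applyScenario(lat, singleDisconnect("2,2")))
  expect_identical(as.character(single[["2,2"]]), "first_order")
  expect_true(all(single[names(single) != "2,2"] == "connected"))
  # 2x2 corner block: the corner hexagon's only neighbours lie inside the
  # block, so it sits one shell deeper than its three companions
  block22 <- applyScenario(lat, sectorDisconnect(c("0,0", "0,1", "1,0", "1,1")))
  ord22 <- classifyOrder(block22)
  expect_true(all(ord22[c("0,1", "1,0", "1,1")] == "first_order"))
  expect_identical(as.character(ord22[["0,0"]]), "second_order")
  # the default 3x3 sector splits into first, second and deeper shells
  sector <- defaultSector(cfg)
  ord33 <- classifyOrder(applyScenario(lat, sectorDisconnect(sector)))
  expect_identical(sort(names(ord33)[ord33 == "first_order"]),
                   sort(c("0,2", "1,2", "2,2", "2,3", "2,4")))
  expect_identical(sort(names(ord33)[ord33 == "second_order"]),
                   sort(c("0,3", "1,3", "1,4")))
  expect_identical(names(ord33)[ord33 == "deeper"], "0,4")
})

test_that("sector occlusions preserve the connected > first > second ordering", {
  cfg <- LatticeConfig()
  lat <- tileLattice(cfg)
  sectors <- list(defaultSector(cfg),
                  c("0,0", "0,1", "1,0", "1,1", "2,0", "2,1"),
                  c("3,3", "3,4", "4,3", "4,4"))
  for (r in c(1, 1.5, 2)) {
    for (sec in sectors) {
      ex <- runExperiment(cfg, sectorDisconnect(sec, diameterRatio = r))
      m <- ex$metrics
      byOrder <- tapply(m$ratio_pct, m$order, mean)
      expect_gt(byOrder[["connected"]], byOrder[["first_order"]])
      if (!is.na(byOrder[["second_order"]]))
        expect_gt(byOrder[["first_order"]], byOrder[["second_order"]])
      expect_true(all(m$ratio_pct[m$order != "connected"] < 100))
    }
  }
})

test_that("boundary-resistance sweeps are deterministic and handle edge cases", {
  cfg <- LatticeConfig()
  sc <- singleDisconnect("2,2")
  t1 <- sweepBoundaryResistance(cfg, sc, c(1, 2))
  t2 <- sweepBoundaryResistance(cfg, sc, c(1, 2))
  expect_identical(t1, t2)
  expect_gt(t1$mean_hexagon_current_A[t1$diameter_ratio == 2],
            t1$mean_hexagon_current_A[t1$diameter_ratio == 1])
  empty <- sweepBoundaryResistance(cfg, sc, numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(sweepBoundaryResistance(cfg, sc, c(1, 0.5)), ">= 1")
})

test_that("average current vanishes without sources and metrics tables are reproducible", {
  cfg <- LatticeConfig(rows = 3L, cols = 3L)
  lat <- tileLattice(cfg)
  dead <- applyScenario(lat, customScenario(hexIds(lat)))
  sol <- solveCircuit(circuit(dead))
  expect_equal(max(abs(currents(sol)$current)), 0, tolerance = 1e-12)
  expect_equal(averageCurrent(dead, sol, "1,1"), 0, tolerance = 1e-12)
  emb <- applyScenario(lat, singleDisconnect("1,1"))
  s1 <- solveCircuit(circuit(emb))
  ref <- referenceInflux(cfg)
  expect_identical(hexMetrics(emb, s1, ref), hexMetrics(emb, s1, ref))
})
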