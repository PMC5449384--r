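test_that("Poiseuille boundary scaling maps diameter ratios to resistances", {
  expect_equal(boundaryResistance(16, 1), 16)
  expect_equal(boundaryResistance(16, 2), 1)
  expect_equal(boundaryResistance(16, 1.5), 16 / 1.5^4, tolerance = 1e-12)
  expect_error(boundaryResistance(-16, 1), "positive")
  expect_error(boundaryResistance(16, 0.5), ">= 1")
})

test_that("a single lobule has the dual-layered triangulated geometry", {
  lob <- buildLobule(LatticeConfig())
  nd <- nodeTable(lob)
  ed <- edgeTable(lob)
  expect_equal(nrow(nd), 19)
  expect_equal(nrow(ed), 42)
  expect_equal(sum(nd$kind == "anode"), 1)
  expect_equal(sum(nd$kind == "cathode"), 3)
  expect_equal(sum(ed$role == "capillary"), 30)
  expect_equal(sum(ed$role == "collector_venule"), 12)
  expect_true(all(ed$resistance[ed$role == "capillary"] == 16))
  mem <- hexMembership(lob, "0,0")
  expect_length(mem$inner, 6)
  expect_length(mem$boundary, 12)
  expect_identical(anodeNode(lob, "0,0"), mem$center)
})

test_that("flow in a single lobule is centrifugal on every radial capillary edge", {
  lob <- buildLobule(LatticeConfig())
  sol <- solveCircuit(circuit(lob))
  nd <- nodeTable(lob)
  ctr <- nd[nd$kind == "anode", ]
  r <- stats::setNames(sqrt((nd$x - ctr$x)^2 + (nd$y - ctr$y)^2), nd$id)
  cur <- currents(sol)
  cap <- cur[cur$role == "capillary", ]
  radial <- abs(r[cap$u] - r[cap$v]) > 1e-9
  outward <- ifelse(r[cap$v] > r[cap$u], cap$current, -cap$current)
  expect_true(all(outward[radial] > 0))
})

test_that("a single lobule is invariant under 120-degree rotation", {
  lob <- buildLobule(LatticeConfig())
  sol <- solveCircuit(circuit(lob))
  nd <- nodeTable(lob)
  ctr <- nd[nd$kind == "anode", ]
  dx <- nd$x - ctr$x
  dy <- nd$y - ctr$y
  rx <- -dx / 2 - sqrt(3) / 2 * dy + ctr$x
  ry <- sqrt(3) / 2 * dx - dy / 2 + ctr$y
  rot <- vapply(seq_len(nrow(nd)), function(i) {
    j <- which(abs(nd$x - rx[i]) < 1e-9 & abs(nd$y - ry[i]) < 1e-9)
    nd$id[j]
  }, character(1))
  v <- voltages(sol)
  expect_equal(unname(v[rot]), unname(v[nd$id]), tolerance = 1e-12)
})

test_that("a 1x1 tiling is the single lobule", {
  cfg <- LatticeConfig(rows = 1L, cols = 1L)
  expect_identical(nodeTable(tileLattice(cfg)), nodeTable(buildLobule(cfg)))
  expect_identical(edgeTable(tileLattice(cfg)), edgeTable(buildLobule(cfg)))
})

test_that("lattice node and edge counts match the frozen construction", {
  sizes <- list(c(3L, 3L, 131L, 346L, 9L, 15L),
                c(5L, 5L, 339L, 938L, 25L, 35L),
                c(7L, 7L, 643L, 1818L, 49L, 63L))
  for (s in sizes) {
    lat <- tileLattice(LatticeConfig(rows = s[1], cols = s[2]))
    nd <- nodeTable(lat)
    expect_equal(nrow(nd), s[3])
    expect_equal(nrow(edgeTable(lat)), s[4])
    expect_equal(sum(nd$kind == "anode"), s[5])
    expect_equal(sum(nd$kind == "cathode"), s[6])
  }
})

test_that("shared collector venules appear once and every capillary edge is interior to one hexagon", {
  lat <- tileLattice(LatticeConfig(rows = 3L, cols = 3L))
  ed <- edgeTable(lat)
  expect_false(anyDuplicated(paste(ed$u, ed$v)) > 0)
  owners <- function(sel) {
    vapply(which(sel), function(e) {
      sum(vapply(hexIds(lat), function(h) {
        mem <- hexMembership(lat, h)
        all(c(ed$u[e], ed$v[e]) %in% c(mem$center, mem$inner, mem$boundary))
      }, logical(1)))
    }, numeric(1))
  }
  # capillary edges belong to exactly one hexagon; venule edges lie on
  # hexagon boundaries (one hexagon at the rim, two when shared)
  expect_true(all(owners(ed$role == "capillary") == 1))
  nVen <- owners(ed$role == "collector_venule")
  expect_true(all(nVen %in% c(1, 2)))
  expect_true(any(nVen == 2))
})

test_that("every anode sources and every cathode sinks current in the perfused lattice", {
  lat <- tileLattice(LatticeConfig())
  sol <- solveCircuit(circuit(lat))
  nd <- nodeTable(lat)
  anodeInj <- vapply(nd$id[nd$kind == "anode"],
                     function(id) nodeInjection(sol, id), numeric(1))
  cathInj <- vapply(nd$id[nd$kind == "cathode"],
                    function(id) nodeInjection(sol, id), numeric(1))
  expect_true(all(anodeInj > 0))
  expect_true(all(cathInj < 0))
})

test_that("no current crosses into a perfused lobule's interior", {
  lat <- tileLattice(LatticeConfig())
  sol <- solveCircuit(circuit(lat))
  for (h in hexIds(lat)) {
    inward <- hexInflux(lat, sol, h) -
      nodeInjection(sol, anodeNode(lat, h))
    expect_lt(abs(inward), 1e-6 * nodeInjection(sol, anodeNode(lat, h)))
  }
})

test_that("lowering boundary resistance raises and evens out lobular flow", {
  cfg16 <- LatticeConfig(diameterRatio = 1)
  cfg1 <- LatticeConfig(diameterRatio = 2)
  stat <- function(cfg) {
    lat <- tileLattice(cfg)
    sol <- solveCircuit(circuit(lat))
    avg <- vapply(hexIds(lat),
                  function(h) averageCurrent(lat, sol, h), numeric(1))
    mem <- hexMembership(lat, "2,2")
    ed <- edgeTable(lat)
    ids <- unlist(mem)
    sel <- ed$role == "capillary" & ed$u %in% ids & ed$v %in% ids
    ic <- abs(currents(sol)$current[sel])
    c(mean = mean(avg), cv = stats::sd(ic) / mean(ic))
  }
  s16 <- stat(cfg16)
  s1 <- stat(cfg1)
  expect_gt(s1[["mean"]], s16[["mean"]])
  expect_lt(s1[["cv"]], s16[["cv"]])
})

test_that("interior lobules of a large lattice are translationally equivalent", {
  lat <- tileLattice(LatticeConfig(rows = 7L, cols = 7L))
  sol <- solveCircuit(circuit(lat))
  interior <- as.vector(outer(1:5, 1:5, hexId))
  inj <- vapply(interior,
                function(h) nodeInjection(sol, anodeNode(lat, h)),
                numeric(1))
  expect_lt((max(inj) - min(inj)) / mean(inj), 0.01)
})
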