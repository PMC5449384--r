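test_that("two-resistor divider assembles to a 1x1 system and solves to the midpoint", {
  net <- dividerNetwork()
  sys <- assembleSystem(net)
  expect_identical(sys$freeIds, "m")
  expect_equal(as.numeric(sys$matrix), 2)
  expect_equal(sys$rhs, 10)
  sol <- solveCircuit(net)
  expect_equal(unname(voltages(sol)["m"]), 5)
  cur <- currents(sol)
  expect_equal(abs(cur$current), c(5, 5))
  # positive current flows from the high-voltage side toward the low side
  vm <- voltages(sol)
  expect_true(all(sign(cur$current) ==
                    sign(vm[cur$u] - vm[cur$v])))
})

test_that("worked-example network assembles with the Kirchhoff row structure", {
  R <- c(2, 3, 5, 11, 7)  # R1..R5
  net <- workedExampleNetwork(R[1], R[2], R[3], R[4], R[5], vp = 0, vq = 10)
  sys <- assembleSystem(net)
  A <- as.matrix(sys$matrix)
  i <- match(c("r", "s"), sys$freeIds)
  expect_equal(A[i[1], i[1]], 1 / R[1] + 1 / R[2] + 1 / R[5])
  expect_equal(A[i[2], i[2]], 1 / R[3] + 1 / R[4] + 1 / R[5])
  expect_equal(A[i[1], i[2]], -1 / R[5])
  expect_equal(A[i[2], i[1]], -1 / R[5])
  expect_equal(sys$rhs[i[1]], 10 / R[2])
  expect_equal(sys$rhs[i[2]], 10 / R[4])
})

test_that("assembly equals an independent edge-by-edge accumulation on a random network", {
  set.seed(101)
  net <- randomConnectedNetwork(10, 2)
  sys <- assembleSystem(net)
  A <- as.matrix(sys$matrix)
  nd <- nodeTable(net)
  ed <- edgeTable(net)
  # independent accumulation: scan the edge list once per free node
  for (i in seq_along(sys$freeIds)) {
    id <- sys$freeIds[i]
    diag_i <- 0
    rhs_i <- 0
    off <- stats::setNames(rep(0, length(sys$freeIds)), sys$freeIds)
    for (e in seq_len(nrow(ed))) {
      other <- if (ed$u[e] == id) ed$v[e]
               else if (ed$v[e] == id) ed$u[e] else next
      g <- 1 / ed$resistance[e]
      diag_i <- diag_i + g
      k <- nd$kind[nd$id == other]
      if (k == "internal") off[other] <- off[other] - g
      else rhs_i <- rhs_i + g * nd$fixedVoltage[nd$id == other]
    }
    off[id] <- diag_i
    expect_equal(A[i, ], unname(off[sys$freeIds]))
    expect_equal(sys$rhs[i], rhs_i)
  }
})

test_that("the symmetric all-equal worked example solves to 5 V at both free nodes", {
  sol <- solveCircuit(workedExampleNetwork())
  expect_equal(unname(voltages(sol)[c("r", "s")]), c(5, 5),
               tolerance = 1e-12)
})

test_that("invalid networks are rejected with informative errors", {
  nd <- data.frame(id = c("a", "b"), kind = c("anode", "internal"),
                   fixedVoltage = c(1, NA))
  expect_error(CircuitNetwork(nd, data.frame(u = "a", v = "b",
                                             resistance = 0)),
               "resistance")
  expect_error(CircuitNetwork(nd, data.frame(u = "a", v = "b",
                                             resistance = -1)),
               "resistance")
  expect_error(CircuitNetwork(nd, data.frame(u = c("a", "a"), v = c("b", "b"),
                                             resistance = 1)),
               "parallel")
  # disconnected network: the error names the unreachable component
  nd2 <- data.frame(id = c("a", "b", "c", "d"),
                    kind = c("anode", "internal", "internal", "internal"),
                    fixedVoltage = c(1, NA, NA, NA))
  net2 <- CircuitNetwork(nd2, data.frame(u = c("a", "c"), v = c("b", "d"),
                                         resistance = 1))
  expect_error(assembleSystem(net2), "disconnected.*c, d")
  # all nodes fixed: nothing to solve
  nd3 <- data.frame(id = c("a", "b"), kind = c("anode", "cathode"),
                    fixedVoltage = c(1, 0))
  net3 <- CircuitNetwork(nd3, data.frame(u = "a", v = "b", resistance = 1))
  expect_error(assembleSystem(net3), "free")
})

test_that("perturbing one node voltage raises the KCL residual by its total conductance", {
  # chain a(0 V) -[2 ohm]- m -[3 ohm]- b(10 V)
  net <- dividerNetwork(R1 = 2, R2 = 3)
  sol <- solveCircuit(net)
  expect_lt(kclResidual(net, sol), 1e-12)
  volt <- voltages(sol)
  volt["m"] <- volt["m"] + 1
  ed <- edgeTable(net)
  pert <- new("CircuitSolution", voltages = volt,
              currents = cbind(ed, current = (volt[ed$u] - volt[ed$v]) /
                                 ed$resistance),
              kclResidualMax = 0)
  expect_equal(kclResidual(net, pert), 1 / 2 + 1 / 3)
})

test_that("KCL residual is zero by convention when every node is fixed", {
  nd <- data.frame(id = c("a", "b"), kind = c("anode", "cathode"),
                   fixedVoltage = c(10, 0))
  net <- CircuitNetwork(nd, data.frame(u = "a", v = "b", resistance = 5))
  sol <- new("CircuitSolution", voltages = c(a = 10, b = 0),
             currents = cbind(edgeTable(net), current = 2),
             kclResidualMax = 0)
  expect_identical(kclResidual(net, sol), 0)
  # mismatched network/solution pairs are refused
  expect_error(kclResidual(dividerNetwork(), sol), "correspond")
})
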