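#' @include circuit-network.R
NULL

.connectedComponents <- function(network) {
  nd <- network@nodes
  ed <- network@edges
  g <- igraph::graph_from_data_frame(ed[, c("u", "v")], directed = FALSE,
                                     vertices = nd$id)
  comp <- igraph::components(g)
  split(nd$id, comp$membership[nd$id])
}

#' Assemble the Kirchhoff nodal system of a resistor network
#'
#' Writes Kirchhoff's current law at every free (internal) node: the signed
#' currents \eqn{(V_i - V_j)/R_{ij}} over the incident edges sum to zero.
#' Fixed-voltage (Dirichlet) nodes are eliminated by substitution, so the
#' system has one row per free node, diagonal entries
#' \eqn{\sum_j 1/R_{ij}}, off-diagonal entries \eqn{-1/R_{ij}} for free
#' neighbours \eqn{j}, and a constant vector accumulating
#' \eqn{\sum V_{fixed}/R} over fixed neighbours.
#'
#' @param network a [CircuitNetwork-class]; must be connected and contain at
#'   least one free node.
#' @return a list with elements \code{matrix} (sparse symmetric
#'   positive-definite conductance matrix over free nodes), \code{rhs}
#'   (constant vector, amperes), \code{freeIds} and \code{fixedIds}
#'   (node id vectors, in matrix order) and \code{fixedVoltages}
#'   (named vector).
#' @export
#' @examples
#' nd <- data.frame(id = c("p", "q", "r", "s"),
#'                  kind = c("cathode", "anode", "internal", "internal"),
#'                  fixedVoltage = c(0, 10, NA, NA))
#' ed <- data.frame(u = c("p", "q", "p", "q", "r"),
#'                  v = c("r", "r", "s", "s", "s"),
#'                  resistance = c(1, 2, 3, 4, 5))
#' assembleSystem(CircuitNetwork(nd, ed))$matrix
assembleSystem <- function(network) {
  stopifnot(is(network, "CircuitNetwork"))
  validObject(network)
  comps <- .connectedComponents(network)
  if (length(comps) > 1) {
    nd0 <- network@nodes
    fixedIds0 <- nd0$id[nd0$kind != "internal"]
    # name the component(s) no source can reach; fall back to the smallest
    anchored <- vapply(comps, function(ids) any(ids %in% fixedIds0),
                       logical(1))
    stray <- if (any(!anchored)) comps[!anchored]
             else comps[which.min(lengths(comps))]
    stop("network is disconnected; unreachable component: ",
         paste(unlist(stray), collapse = ", "))
  }
  nd <- network@nodes
  ed <- network@edges
  freeIds <- nd$id[nd$kind == "internal"]
  if (length(freeIds) == 0)
    stop("network has no free (internal) node; nothing to solve")
  fixedIds <- nd$id[nd$kind != "internal"]
  fixedVoltages <- stats::setNames(nd$fixedVoltage[nd$kind != "internal"],
                                   fixedIds)
  g <- 1 / ed$resistance
  ui <- match(ed$u, freeIds)  # NA when the endpoint is fixed
  vi <- match(ed$v, freeIds)
  n <- length(freeIds)
  i <- c(ui[!is.na(ui)], vi[!is.na(vi)])
  x <- c(g[!is.na(ui)], g[!is.na(vi)])
  both <- !is.na(ui) & !is.na(vi)
  i <- c(i, ui[both], vi[both])
  j <- c(ui[!is.na(ui)], vi[!is.na(vi)], vi[both], ui[both])
  x <- c(x, -g[both], -g[both])
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  rhs <- numeric(n)
  uFixed <- !is.na(vi) & is.na(ui)
  vFixed <- !is.na(ui) & is.na(vi)
  if (any(uFixed)) {
    contrib <- tapply(g[uFixed] * fixedVoltages[ed$u[uFixed]],
                      vi[uFixed], sum)
    rhs[as.integer(names(contrib))] <- rhs[as.integer(names(contrib))] + contrib
  }
  if (any(vFixed)) {
    contrib <- tapply(g[vFixed] * fixedVoltages[ed$v[vFixed]],
                      ui[vFixed], sum)
    rhs[as.integer(names(contrib))] <- rhs[as.integer(names(contrib))] + contrib
  }
  list(matrix = A, rhs = rhs, freeIds = freeIds, fixedIds = fixedIds,
       fixedVoltages = fixedVoltages)
}

#' Solve a resistor network by Kirchhoff nodal analysis
#'
#' Assembles the free-node conductance system (see [assembleSystem()]),
#' solves it by sparse direct factorization, and derives the signed edge
#' currents \eqn{(V_u - V_v)/R}. The worst Kirchhoff current-law violation
#' over free nodes is recomputed from the currents and must not exceed
#' \code{tolerance}.
#'
#' @param network a [CircuitNetwork-class].
#' @param tolerance maximum admissible absolute KCL residual, amperes
#'   (default \code{1e-9}, far below any percent-level perfusion effect).
#' @return a [CircuitSolution-class].
#' @export
#' @examples
#' nd <- data.frame(id = c("a", "m", "b"),
#'                  kind = c("cathode", "internal", "anode"),
#'                  fixedVoltage = c(0, NA, 10))
#' ed <- data.frame(u = c("a", "m"), v = c("m", "b"), resistance = 1)
#' sol <- solveCircuit(CircuitNetwork(nd, ed))
#' voltages(sol)["m"]  # 5 V midpoint of the two-resistor divider
solveCircuit <- function(network, tolerance = 1e-9) {
  sys <- assembleSystem(network)
  v <- as.numeric(Matrix::solve(sys$matrix, sys$rhs))
  volt <- c(stats::setNames(v, sys$freeIds), sys$fixedVoltages)
  volt <- volt[network@nodes$id]
  ed <- network@edges
  cur <- ed
  cur$current <- if (nrow(ed)) (volt[ed$u] - volt[ed$v]) / ed$resistance
                 else numeric(0)
  rownames(cur) <- NULL
  sol <- new("CircuitSolution", voltages = volt, currents = cur,
             kclResidualMax = 0)
  res <- kclResidual(network, sol)
  if (!is.finite(res) || res > tolerance)
    stop("KCL residual ", format(res), " A exceeds tolerance ",
         format(tolerance), " A (singular or ill-conditioned system?)")
  sol@kclResidualMax <- res
  sol
}

#' Maximum Kirchhoff current-law residual of a solution
#'
#' Recomputes, independently of the solver, the node balance
#' \eqn{|\sum_j (V_i - V_j)/R_{ij}|} at every free node and returns the
#' maximum. Zero by convention when the network has no free node.
#'
#' @param network the [CircuitNetwork-class] the solution was computed on.
#' @param solution a [CircuitSolution-class] for the same network.
#' @return amperes (non-negative scalar).
#' @export
kclResidual <- function(network, solution) {
  stopifnot(is(network, "CircuitNetwork"), is(solution, "CircuitSolution"))
  nd <- network@nodes
  volt <- solution@voltages
  cur <- solution@currents
  if (!setequal(names(volt), nd$id) || nrow(cur) != nrow(network@edges))
    stop("solution does not correspond to this network")
  freeIds <- nd$id[nd$kind == "internal"]
  if (length(freeIds) == 0) return(0)
  flow <- c(cur$current, -cur$current)        # out of u, out of v
  at <- c(cur$u, cur$v)
  keep <- at %in% freeIds
  if (!any(keep)) return(0)
  bal <- tapply(flow[keep], at[keep], sum)
  max(abs(bal))
}

#' Net current injected at a fixed-voltage node
#'
#' Sum of signed currents leaving \code{node} into the network; positive for
#' a sourcing anode, negative for a sinking cathode.
#'
#' @param solution a [CircuitSolution-class].
#' @param node a node id.
#' @return amperes.
#' @export
nodeInjection <- function(solution, node) {
  cur <- solution@currents
  sum(cur$current[cur$u == node]) - sum(cur$current[cur$v == node])
}
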