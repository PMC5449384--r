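#' @include io.R
NULL

#' Render a current field as an arrow plot
#'
#' One arrow per edge, oriented by the sign of the current and with line
#' width proportional to its magnitude (scaled to the 95th percentile so a
#' few dominant currents do not flatten the rest; a scale bar states the
#' reference current). Collector-venule boundary edges are drawn over a
#' light underlay so lobule boundaries stand out; anodes are marked as
#' filled red points (open when disconnected), cathodes as blue points.
#' Edges carrying no current are omitted. Output is SVG or PNG by file
#' extension and deterministic for fixed inputs.
#'
#' @param lattice a [LobuleLattice-class].
#' @param solution a [CircuitSolution-class] solved on its network.
#' @param path output file ending in \code{.svg} or \code{.png}.
#' @param title optional plot title.
#' @return invisibly, the path.
#' @export
#' @examples
#' lat <- tileLattice(LatticeConfig(rows = 2L, cols = 2L))
#' sol <- solveCircuit(circuit(lat))
#' f <- tempfile(fileext = ".svg")
#' renderCurrentField(lat, sol, f)
renderCurrentField <- function(lattice, solution, path, title = NULL) {
  stopifnot(is(lattice, "LobuleLattice"), is(solution, "CircuitSolution"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png")) stop("path must end in .svg or .png")
  nd <- lattice@network@nodes
  cur <- solution@currents
  xs <- stats::setNames(nd$x, nd$id)
  ys <- stats::setNames(nd$y, nd$id)
  q95 <- stats::quantile(abs(cur$current), 0.95, names = FALSE)
  if (!is.finite(q95) || q95 <= 0) q95 <- 1
  w <- 2 + 5 * (lattice@config@cols - 1) * 1.5 / 4
  h <- 2 + 5 * (lattice@config@rows) * sqrt(3) / 4
  if (ext == "svg") grDevices::svg(path, width = w, height = h)
  else grDevices::png(path, width = 150 * w, height = 150 * h, res = 150)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 1, if (is.null(title)) 1 else 2, 1))
  graphics::plot(NA, xlim = range(nd$x) + c(-0.7, 0.7),
                 ylim = range(nd$y) + c(-0.7, 0.7), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = title)
  isB <- cur$role == "collector_venule"
  graphics::segments(xs[cur$u[isB]], ys[cur$u[isB]],
                     xs[cur$v[isB]], ys[cur$v[isB]],
                     col = "grey80", lwd = 5)
  for (i in seq_len(nrow(cur))) {
    I <- cur$current[i]
    if (I == 0) next
    from <- if (I > 0) cur$u[i] else cur$v[i]
    to <- if (I > 0) cur$v[i] else cur$u[i]
    lwd <- max(0.3, 3 * min(abs(I) / q95, 1.5))
    graphics::arrows(xs[from], ys[from], xs[to], ys[to], length = 0.05,
                     lwd = lwd,
                     col = if (isB[i]) "grey40" else "black")
  }
  anodes <- nd$id[nd$kind == "anode"]
  cathodes <- nd$id[nd$kind == "cathode"]
  stumps <- setdiff(vapply(lattice@hexes, `[[`, character(1), "center"),
                    anodes)
  graphics::points(xs[anodes], ys[anodes], pch = 19, col = "red3", cex = 1.1)
  if (length(stumps))
    graphics::points(xs[stumps], ys[stumps], pch = 1, col = "red3",
                     cex = 1.1)
  graphics::points(xs[cathodes], ys[cathodes], pch = 19, col = "blue3",
                   cex = 0.9)
  x0 <- min(nd$x)
  y0 <- min(nd$y) - 0.6
  graphics::segments(x0, y0, x0 + 1, y0, lwd = 3)
  graphics::text(x0 + 0.5, y0 - 0.02, pos = 1, cex = 0.7,
                 sprintf("%.3g A", q95))
  invisible(path)
}
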