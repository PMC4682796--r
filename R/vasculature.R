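# Vessel network: node/segment tables, pre-existing capillary grid,
# Poiseuille flow solve (Kirchhoff nodal analysis) and wall shear rates.

#' Construct a vessel network from node and segment tables
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (mm), `is_inlet`,
#'   `is_outlet`; a `pressure` column is added by [solve_flow()].
#' @param segments data.frame with columns `id`, `from`, `to` (node ids),
#'   `radius` (m), `length` (m), `origin` ("preexisting" or "neovessel");
#'   `flow` (m^3/s, signed from->to), `shear` (1/s) and `hematocrit` are
#'   filled by [solve_flow()] / the angiogenesis step.
#' @return Object of class `vessel_network`.
#' @export
vessel_network <- function(nodes, segments) {
  stopifnot(all(c("id", "x", "y", "is_inlet", "is_outlet") %in% names(nodes)),
            all(c("id", "from", "to", "radius", "length", "origin") %in% names(segments)))
  if (any(segments$radius <= 0)) stop("all segment radii must be > 0")
  if (any(segments$length <= 0)) stop("all segment lengths must be > 0")
  if (!"pressure" %in% names(nodes)) nodes$pressure <- NA_real_
  for (col in c("flow", "shear")) if (!col %in% names(segments)) segments[[col]] <- NA_real_
  if (!"hematocrit" %in% names(segments)) segments$hematocrit <- NA_real_
  segments$surface <- 2 * pi * segments$radius * segments$length
  segments$volume <- pi * segments$radius^2 * segments$length
  structure(list(nodes = nodes, segments = segments), class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d nodes, %d segments (%d neovessel), %d inlets, %d outlets\n",
              nrow(x$nodes), nrow(x$segments),
              sum(x$segments$origin == "neovessel"),
              sum(x$nodes$is_inlet), sum(x$nodes$is_outlet)))
  invisible(x)
}

#' Pre-existing capillary grid
#'
#' Builds the regular pre-existing vasculature: horizontal and vertical
#' vessel lines at every multiple of `vessel_spacing` along each dimension
#' (boundary lines included), discretized into segments one grid cell long
#' so each segment maps onto one grid cell. Crossing points share a node.
#' Left-edge line ends are flagged inlets and right-edge ends outlets
#' (configurable downstream via the node flags).
#'
#' @param grid A [grid_spec()].
#' @param vessel_spacing Line spacing in mm; must divide the domain size and
#'   be an integer multiple of the cell width.
#' @param radius Vessel radius in m (default 10 um, baseline capillary).
#' @param hematocrit Hematocrit assigned to every pre-existing segment.
#' @return A `vessel_network` with all segments flagged `preexisting`.
#' @examples
#' net <- build_preexisting_grid(grid_spec(64), 0.25)
#' @export
build_preexisting_grid <- function(grid, vessel_spacing = 0.25, radius = 1e-5,
                                   hematocrit = 0.45) {
  m <- grid$L / vessel_spacing
  if (abs(m - round(m)) > 1e-9)
    stop("vessel_spacing must divide the domain size")
  m <- round(m)
  c_per <- vessel_spacing / grid$h
  if (abs(c_per - round(c_per)) > 1e-9)
    stop("vessel_spacing must be an integer number of grid cells")
  c_per <- round(c_per)
  n <- grid$n
  h_mm <- grid$h
  line_pos <- (0:m) * vessel_spacing        # mm, includes both boundaries
  tick <- (0:n) * h_mm                      # node positions along a line
  key <- function(x, y) paste(round(x / h_mm), round(y / h_mm))

  node_env <- new.env(parent = emptyenv())
  nx <- ny <- numeric(0)
  get_node <- function(x, y) {
    k <- key(x, y)
    id <- node_env[[k]]
    if (is.null(id)) {
      id <- length(nx) + 1L
      nx[id] <<- x; ny[id] <<- y
      node_env[[k]] <- id
    }
    id
  }
  from <- to <- integer(0)
  add_line <- function(horizontal, coord) {
    ids <- if (horizontal) vapply(tick, function(t) get_node(t, coord), 1L)
           else            vapply(tick, function(t) get_node(coord, t), 1L)
    from <<- c(from, ids[-length(ids)])
    to <<- c(to, ids[-1L])
  }
  for (p in line_pos) add_line(TRUE, p)
  for (p in line_pos) add_line(FALSE, p)

  nodes <- data.frame(id = seq_along(nx), x = nx, y = ny)
  # inlets: left ends of horizontal lines; outlets: right ends
  on_line_y <- vapply(nodes$y, function(y) any(abs(y - line_pos) < 1e-9), TRUE)
  nodes$is_inlet <- nodes$x < 1e-12 & on_line_y
  nodes$is_outlet <- nodes$x > grid$L - 1e-12 & on_line_y
  segments <- data.frame(id = seq_along(from), from = from, to = to,
                         radius = radius, length = h_mm * 1e-3,
                         origin = "preexisting", hematocrit = hematocrit)
  vessel_network(nodes, segments)
}

#' Poiseuille wall shear rate
#'
#' `Srt = 4 |Q| / (pi R^3)` for volumetric flow `Q` through a cylindrical
#' vessel of radius `R`.
#'
#' @param Q Flow rate, m^3/s (sign ignored).
#' @param R Radius, m (> 0).
#' @return Shear rate in 1/s.
#' @export
shear_rate <- function(Q, R) {
  if (any(R <= 0)) stop("R must be > 0")
  4 * abs(Q) / (pi * R^3)
}

#' Solve network blood flow
#'
#' Kirchhoff nodal analysis with Poiseuille conductances
#' `g = pi R^4 / (8 mu L)`: nodal pressures solve the sparse linear system
#' with Dirichlet pressures at inlet/outlet nodes; segment flows and shear
#' rates are populated. Dead-end branches carry zero flow. Every connected
#' component must contain at least one pressure-fixed node.
#'
#' @param network A `vessel_network` with inlet/outlet flags set.
#' @param p_in,p_out Inlet/outlet pressures (Pa).
#' @param viscosity Blood viscosity (Pa s).
#' @return The network with `nodes$pressure`, `segments$flow` (signed
#'   from->to) and `segments$shear` filled.
#' @export
solve_flow <- function(network, p_in = 500, p_out = 0, viscosity = 3e-3) {
  nodes <- network$nodes
  seg <- network$segments
  if (!any(nodes$is_inlet) || !any(nodes$is_outlet))
    stop("flow solve needs at least one inlet and one outlet")
  nn <- nrow(nodes)
  g <- pi * seg$radius^4 / (8 * viscosity * seg$length)
  # weighted graph Laplacian
  A <- Matrix::sparseMatrix(i = c(seg$from, seg$to, seg$from, seg$to),
                            j = c(seg$to, seg$from, seg$from, seg$to),
                            x = c(-g, -g, g, g), dims = c(nn, nn))
  fixed <- nodes$is_inlet | nodes$is_outlet
  p_fix <- ifelse(nodes$is_inlet, p_in, p_out)[fixed]
  free <- which(!fixed)
  # components without a fixed node make the reduced system singular
  gr <- igraph::graph_from_edgelist(cbind(seg$from, seg$to), directed = FALSE)
  if (igraph::vcount(gr) < nn) gr <- igraph::add_vertices(gr, nn - igraph::vcount(gr))
  comp <- igraph::components(gr)$membership
  bad <- setdiff(unique(comp), unique(comp[fixed]))
  if (length(bad))
    stop(sprintf("network component %d has no inlet/outlet: flow system is singular", bad[1]))
  p <- numeric(nn)
  p[fixed] <- p_fix
  if (length(free)) {
    rhs <- as.numeric(-A[free, fixed, drop = FALSE] %*% p_fix)
    p[free] <- as.vector(Matrix::solve(A[free, free, drop = FALSE],
                                       Matrix::Matrix(rhs, ncol = 1)))
  }
  seg$flow <- g * (p[seg$from] - p[seg$to])
  seg$shear <- shear_rate(seg$flow, seg$radius)
  nodes$pressure <- p
  network$nodes <- nodes
  network$segments <- seg
  network
}

#' Interior-node flow conservation residual
#'
#' Maximum relative imbalance of signed flows at nodes that are neither
#' inlets nor outlets, normalized by the total inflow. Used as the network
#' validity invariant after every flow solve and anastomosis event.
#'
#' @param network A flow-solved `vessel_network`.
#' @return Single number (relative residual).
#' @export
flow_conservation_residual <- function(network) {
  seg <- network$segments
  nodes <- network$nodes
  bal <- numeric(nrow(nodes))
  bal_add <- tapply(c(-seg$flow, seg$flow), c(seg$from, seg$to), sum)
  bal[as.integer(names(bal_add))] <- bal_add
  interior <- !(nodes$is_inlet | nodes$is_outlet)
  scale <- max(abs(seg$flow), .Machine$double.xmin)
  max(abs(bal[interior])) / scale
}

#' Rasterize a network onto a grid
#'
#' Maps each segment to the grid cell containing its midpoint (segments are
#' one cell long by construction). Returns the vessel characteristic
#' function and per-cell aggregates used by the oxygen and drug modules.
#'
#' @param network A `vessel_network`.
#' @param grid A [grid_spec()].
#' @return List: `mask` (n x n, 1 where a vessel lies), `cell` (per-segment
#'   linear cell index), `hematocrit` (n x n max segment hematocrit per cell).
#' @export
rasterize_network <- function(network, grid) {
  seg <- network$segments
  nodes <- network$nodes
  mx <- (nodes$x[seg$from] + nodes$x[seg$to]) / 2
  my <- (nodes$y[seg$from] + nodes$y[seg$to]) / 2
  i <- pmin(pmax(floor(mx / grid$h) + 1L, 1L), grid$n)
  j <- pmin(pmax(floor(my / grid$h) + 1L, 1L), grid$n)
  cell <- (j - 1L) * grid$n + i
  mask <- matrix(0, grid$n, grid$n)
  mask[unique(cell)] <- 1
  hem <- matrix(0, grid$n, grid$n)
  hc <- seg$hematocrit
  hc[is.na(hc)] <- 0
  agg <- tapply(hc, cell, max)
  hem[as.integer(names(agg))] <- agg
  list(mask = mask, cell = cell, hematocrit = hem)
}
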