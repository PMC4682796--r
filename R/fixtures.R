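# Deterministic toy fixtures used throughout the test suites: small vessel
# networks with documented radii/lengths and disc tumors. No RNG.

#' Toy vessel networks
#'
#' Small deterministic networks for unit tests and examples:
#' * `single_segment` — two nodes 1 mm apart, one 10-um segment.
#' * `y_branch` — inlet segment splitting into two identical children
#'   (4 nodes, 3 segments, 1 bifurcation).
#' * `ladder` — two parallel 3-segment rails with 2 rungs (a 2-loop
#'   resistor ladder; flows are checked against a dense nodal solve).
#' * `grid3x3` — 3 x 3 crossing lines on a 1-mm domain.
#'
#' @param kind One of `"single_segment"`, `"y_branch"`, `"ladder"`,
#'   `"grid3x3"`.
#' @param radius Segment radius (m).
#' @return A `vessel_network` (not yet flow-solved).
#' @export
make_toy_network <- function(kind = c("single_segment", "y_branch", "ladder",
                                      "grid3x3"),
                             radius = 1e-5) {
  kind <- match.arg(kind)
  node <- function(id, x, y, inlet = FALSE, outlet = FALSE)
    data.frame(id = id, x = x, y = y, is_inlet = inlet, is_outlet = outlet)
  seg <- function(id, from, to, r = radius, len = 1e-3)
    data.frame(id = id, from = from, to = to, radius = r, length = len,
               origin = "preexisting", hematocrit = 0.45)
  switch(kind,
    single_segment = vessel_network(
      rbind(node(1, 0, 0, inlet = TRUE), node(2, 1, 0, outlet = TRUE)),
      seg(1, 1, 2)),
    y_branch = vessel_network(
      rbind(node(1, 0, 0, inlet = TRUE), node(2, 1, 0),
            node(3, 2, 0.5, outlet = TRUE), node(4, 2, -0.5, outlet = TRUE)),
      rbind(seg(1, 1, 2), seg(2, 2, 3), seg(3, 2, 4))),
    ladder = {
      # nodes: rail A 1-2-3-4 (top), rail B 5-6-7-8 (bottom); rungs 2-6, 3-7
      nodes <- rbind(node(1, 0, 1, inlet = TRUE), node(2, 1, 1),
                     node(3, 2, 1), node(4, 3, 1, outlet = TRUE),
                     node(5, 0, 0, inlet = TRUE), node(6, 1, 0),
                     node(7, 2, 0), node(8, 3, 0, outlet = TRUE))
      segs <- rbind(seg(1, 1, 2), seg(2, 2, 3, r = 8e-6), seg(3, 3, 4),
                    seg(4, 5, 6, r = 12e-6), seg(5, 6, 7), seg(6, 7, 8, r = 9e-6),
                    seg(7, 2, 6, r = 7e-6), seg(8, 3, 7, r = 11e-6))
      vessel_network(nodes, segs)
    },
    grid3x3 = build_preexisting_grid(grid_spec(8, domain_mm = 1), 0.5,
                                     radius = radius))
}

#' Toy disc tumor
#'
#' Disc-shaped tumor at a given centre: signed-distance level set, all
#' cells initially proliferating.
#'
#' @param radius_mm Disc radius (mm); must be below half the domain.
#' @param grid A [grid_spec()].
#' @param center Centre (mm, length 2); default domain centre.
#' @return A `tumor_state`.
#' @export
make_toy_tumor <- function(radius_mm, grid, center = NULL) {
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  if (radius_mm >= grid$L / 2) stop("radius_mm must be < half the domain size")
  if (is.null(center)) center <- c(grid$L / 2, grid$L / 2)
  xc <- cell_centers(grid)
  r <- sqrt(outer((xc - center[1])^2, rep(1, grid$n)) +
            outer(rep(1, grid$n), (xc - center[2])^2))
  tumor_state(grid, r - radius_mm)
}
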