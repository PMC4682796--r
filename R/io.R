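# Output interfaces: CSV tables for networks, time series and field
# snapshots, JSON summaries, and quick base-graphics renders.

#' Write a vessel network to CSV tables
#'
#' Two files: `<stem>_nodes.csv` (id, x, y, inlet/outlet flags, pressure)
#' and `<stem>_segments.csv` (id, endpoints, radius_m, length_m, origin,
#' flow, shear, hematocrit).
#'
#' @param network A `vessel_network`.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_network_csv <- function(network, stem) {
  pn <- paste0(stem, "_nodes.csv")
  ps <- paste0(stem, "_segments.csv")
  utils::write.csv(network$nodes, pn, row.names = FALSE)
  seg <- network$segments
  names(seg)[names(seg) == "radius"] <- "radius_m"
  names(seg)[names(seg) == "length"] <- "length_m"
  utils::write.csv(seg, ps, row.names = FALSE)
  invisible(c(pn, ps))
}

#' Write a vessel network as a JSON graph dump
#'
#' @param network A `vessel_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(network, path) {
  jsonlite::write_json(list(nodes = network$nodes, segments = network$segments),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a field snapshot to CSV
#'
#' Plain-text snapshot of a grid field: a comment header records the time
#' stamp, units and grid spec; the body is the n x n value matrix.
#'
#' @param field `scalar_field` or matrix.
#' @param path Output path.
#' @param grid Grid (when `field` is a matrix).
#' @param time Time stamp recorded in the header.
#' @param units Unit string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path, grid = NULL, time = NA, units = "") {
  if (inherits(field, "scalar_field")) { grid <- field$grid; field <- field$values }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# time=%s units=%s n=%d domain_mm=%g",
                     format(time), units, grid$n, grid$L), con)
  utils::write.table(field, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the growth/treatment time series to CSV
#'
#' @param history data.frame from [sim_history()] or a treatment `series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Quick rendering of a simulation state
#'
#' Base-graphics heat map of a field with the vasculature and tumor
#' interface overlaid. Intended for interactive inspection, not
#' publication figures.
#'
#' @param sim A `tumor_sim`.
#' @param what Field to show: "sigma", "taf", or a matrix.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, NULL.
#' @export
plot_sim <- function(sim, what = "sigma", ...) {
  M <- if (is.matrix(what)) what else switch(what, sigma = sim$sigma,
                                             taf = sim$taf, sim$sigma)
  xc <- cell_centers(sim$grid)
  graphics::image(xc, xc, M, asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  seg <- sim$net$segments; nodes <- sim$net$nodes
  graphics::segments(nodes$x[seg$from], nodes$y[seg$from],
                     nodes$x[seg$to], nodes$y[seg$to],
                     col = ifelse(seg$origin == "neovessel", "brown", "grey30"),
                     lwd = 0.5)
  graphics::contour(xc, xc, sim$tumor$phi, levels = 0, add = TRUE,
                    drawlabels = FALSE, lwd = 2)
  invisible(NULL)
}
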