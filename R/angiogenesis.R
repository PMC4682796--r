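# TAF-driven sprouting angiogenesis: tumor angiogenic factor released by
# hypoxic tissue, lattice random walk of sprout tips biased by chemotaxis
# (TAF gradients) and haptotaxis (ECM gradients), anastomosis into the
# flowing network.

#' Angiogenesis parameters
#'
#' @param D_taf TAF diffusivity (mm^2/day).
#' @param lambda_taf TAF decay rate (1/day); together with `D_taf` this sets
#'   the TAF halo length `sqrt(D_taf / lambda_taf)` around hypoxic tissue.
#' @param s_taf TAF source rate on hypoxic cells (1/day); the steady TAF is
#'   bounded by `s_taf / lambda_taf`.
#' @param D_tip Random-motility weight of the tip walk (dimensionless).
#' @param chi_taf Chemotaxis weight on per-cell TAF differences.
#' @param chi_ecm Haptotaxis weight on per-cell ECM differences.
#' @param taf_threshold Minimum TAF for sprout initiation from a vessel cell.
#' @param sprout_rate Initiation probability per vessel cell per day is
#'   `sprout_rate * T` above threshold.
#' @param branch_rate Branching probability per active tip per day is
#'   `branch_rate * T`.
#' @param max_tips Cap on simultaneously active tips.
#' @param neovessel_hematocrit_frac Hematocrit in perfused neovessels as a
#'   fraction of the normal hematocrit `HD`.
#' @return Object of class `angio_params`.
#' @export
angio_params <- function(D_taf = 0.8, lambda_taf = 20, s_taf = 20,
                         D_tip = 1, chi_taf = 40, chi_ecm = 0,
                         taf_threshold = 0.05, sprout_rate = 1,
                         branch_rate = 0.5, max_tips = 40,
                         neovessel_hematocrit_frac = 0.5) {
  if (any(c(D_taf, lambda_taf, s_taf, D_tip, chi_taf, chi_ecm,
            taf_threshold, sprout_rate, branch_rate) < 0))
    stop("all angiogenesis coefficients must be >= 0")
  structure(list(D_taf = D_taf, lambda_taf = lambda_taf, s_taf = s_taf,
                 D_tip = D_tip, chi_taf = chi_taf, chi_ecm = chi_ecm,
                 taf_threshold = taf_threshold, sprout_rate = sprout_rate,
                 branch_rate = branch_rate, max_tips = as.integer(max_tips),
                 neovessel_hematocrit_frac = neovessel_hematocrit_frac),
            class = "angio_params")
}

#' Update the TAF field
#'
#' One implicit diffusion--decay step with a uniform source on hypoxic
#' cells: `dT/dt = D_taf Lap(T) + s_taf 1_hypoxic - lambda_taf T`. TAF
#' stays non-negative and below `s_taf / lambda_taf`.
#'
#' @param taf TAF matrix (or scalar_field).
#' @param hypoxic_mask Logical matrix of hypoxic tumor cells.
#' @param params An [angio_params()].
#' @param dt Time step (days).
#' @param grid A [grid_spec()].
#' @return Updated TAF matrix.
#' @export
update_taf <- function(taf, hypoxic_mask, params, dt, grid) {
  stepper <- make_diffusion_stepper(grid, params$D_taf, params$lambda_taf, dt)
  stepper(field_values(taf, grid), params$s_taf * hypoxic_mask)
}

#' Tip move probabilities on the lattice stencil
#'
#' Discretized endothelial-cell conservation on one stencil: the weight of
#' staying is the motility `D_tip`; each of the 4 neighbour moves gets
#' `max(0, D_tip + chi_taf * dT + chi_ecm * dE)` with `dT`, `dE` the
#' per-cell field differences towards that neighbour. Probabilities are the
#' normalized weights; if all weights vanish the tip stays.
#'
#' @param dT Length-4 numeric: TAF difference to the +x, -x, +y, -y cells.
#' @param dE Length-4 numeric: ECM differences, same order.
#' @param params An [angio_params()].
#' @return Length-5 probability vector (stay, +x, -x, +y, -y) summing to 1.
#' @export
sprout_move_probs <- function(dT, dE = c(0, 0, 0, 0), params = angio_params()) {
  w <- c(params$D_tip,
         pmax(params$D_tip + params$chi_taf * dT + params$chi_ecm * dE, 0))
  if (sum(w) == 0) return(c(1, 0, 0, 0, 0))
  w / sum(w)
}

# One sprouting update: initiate tips on vessel cells with high TAF, move
# each active tip one lattice step, create neovessel segments, anastomose
# when a tip lands on a cell already occupied by vasculature. Consumes RNG;
# callers seed for reproducibility. `sim` is the simulation environment.
step_angiogenesis <- function(sim, dt) {
  par <- sim$cfg_angio
  grid <- sim$grid
  taf <- sim$taf
  n <- grid$n

  occupied <- sim$raster$mask > 0   # vessel occupancy incl. neovessels
  cell_of <- function(i, j) (j - 1L) * n + i

  # --- initiation -----------------------------------------------------------
  if (length(sim$tips) < par$max_tips) {
    cand <- which(occupied & taf > par$taf_threshold)
    if (length(cand)) {
      pr <- pmin(par$sprout_rate * taf[cand] * dt, 1)
      new_cells <- cand[stats::runif(length(cand)) < pr]
      if (length(new_cells) > 8L) new_cells <- sample(new_cells, 8L)
      for (cl in new_cells) {
        if (length(sim$tips) >= par$max_tips) break
        i <- ((cl - 1L) %% n) + 1L
        j <- ((cl - 1L) %/% n) + 1L
        node_id <- .nearest_network_node(sim$net, (i - 0.5) * grid$h, (j - 0.5) * grid$h)
        sim$tips[[length(sim$tips) + 1L]] <- list(i = i, j = j, node = node_id)
      }
    }
  }
  if (!length(sim$tips)) return(invisible(sim))

  # --- tip moves ------------------------------------------------------------
  E <- sim$tumor$E
  keep <- logical(length(sim$tips))
  changed <- FALSE
  new_tips <- list()
  for (k in seq_along(sim$tips)) {
    tip <- sim$tips[[k]]
    i <- tip$i; j <- tip$j
    ip <- min(i + 1L, n); im <- max(i - 1L, 1L)
    jp <- min(j + 1L, n); jm <- max(j - 1L, 1L)
    dT <- c(taf[ip, j] - taf[i, j], taf[im, j] - taf[i, j],
            taf[i, jp] - taf[i, j], taf[i, jm] - taf[i, j])
    dE <- c(E[ip, j] - E[i, j], E[im, j] - E[i, j],
            E[i, jp] - E[i, j], E[i, jm] - E[i, j])
    pr <- sprout_move_probs(dT, dE, par)
    mv <- sample.int(5L, 1L, prob = pr)
    if (mv == 1L) { keep[k] <- TRUE; next }                   # stay
    di <- c(0L, 1L, -1L, 0L, 0L)[mv]; dj <- c(0L, 0L, 0L, 1L, -1L)[mv]
    i2 <- i + di; j2 <- j + dj
    if (i2 < 1L || i2 > n || j2 < 1L || j2 > n) { keep[k] <- FALSE; next }  # domain exit
    hit <- occupied[i2, j2]
    res <- .append_neovessel(sim, tip, i2, j2, fuse = hit)
    changed <- TRUE
    occupied[i2, j2] <- TRUE
    if (hit) { keep[k] <- FALSE } else {
      tip$i <- i2; tip$j <- j2; tip$node <- res
      keep[k] <- TRUE
      sim$tips[[k]] <- tip
      # branching
      if (stats::runif(1) < min(par$branch_rate * taf[i2, j2] * dt, 1) &&
          length(sim$tips) + length(new_tips) < par$max_tips)
        new_tips[[length(new_tips) + 1L]] <- tip
    }
  }
  sim$tips <- c(sim$tips[keep], new_tips)
  if (changed) sim$network_dirty <- TRUE
  invisible(sim)
}

# nearest network node to (x, y) in mm
.nearest_network_node <- function(net, x, y) {
  d2 <- (net$nodes$x - x)^2 + (net$nodes$y - y)^2
  which.min(d2)
}

# Append one neovessel segment from tip$node to cell (i2, j2); returns the id
# of the new (or fused) endpoint node. With fuse = TRUE the endpoint is the
# nearest existing node (anastomosis) instead of a new node.
.append_neovessel <- function(sim, tip, i2, j2, fuse = FALSE) {
  grid <- sim$grid
  x2 <- (i2 - 0.5) * grid$h; y2 <- (j2 - 0.5) * grid$h
  net <- sim$net
  if (fuse) {
    end_id <- .nearest_network_node(net, x2, y2)
    if (end_id == tip$node) return(end_id)   # no self-loop segments
  } else {
    end_id <- nrow(net$nodes) + 1L
    net$nodes <- rbind(net$nodes,
                       data.frame(id = end_id, x = x2, y = y2,
                                  is_inlet = FALSE, is_outlet = FALSE,
                                  pressure = NA_real_))
  }
  from <- tip$node
  x1 <- net$nodes$x[from]; y1 <- net$nodes$y[from]
  len <- max(sqrt((x2 - x1)^2 + (y2 - y1)^2), grid$h) * 1e-3   # m
  radius <- sim$cfg_vessels$radius
  seg <- data.frame(id = nrow(net$segments) + 1L, from = from, to = end_id,
                    radius = radius, length = len, origin = "neovessel",
                    flow = 0, shear = 0, hematocrit = 0,
                    surface = 2 * pi * radius * len,
                    volume = pi * radius^2 * len)
  net$segments <- rbind(net$segments, seg)
  sim$net <- net
  sim$raster <- rasterize_network(net, grid)
  end_id
}

#' Perfuse newly formed vessels
#'
#' Re-solves network flow after angiogenesis events. Segments lying on
#' inlet-to-outlet paths (including anastomosed neovessel loops) receive
#' flow and shear; dead-end sprouts carry zero flow, hence zero shear and
#' (by advective starvation) no nanoparticle supply. Perfused neovessels
#' are assigned the neovessel hematocrit fraction; unperfused ones carry
#' zero hematocrit and release no oxygen.
#'
#' @param network A `vessel_network`.
#' @param angio An [angio_params()].
#' @param HD Normal hematocrit (from [oxygen_params()]).
#' @param ... Passed to [solve_flow()] (`p_in`, `p_out`, `viscosity`).
#' @return The flow-solved network with neovessel hematocrits assigned.
#' @export
perfuse_new_vessels <- function(network, angio = angio_params(), HD = 0.45, ...) {
  network <- solve_flow(network, ...)
  seg <- network$segments
  qscale <- max(abs(seg$flow))
  neo <- seg$origin == "neovessel"
  perfused <- abs(seg$flow) > 1e-10 * qscale
  seg$hematocrit[neo] <- ifelse(perfused[neo],
                                angio$neovessel_hematocrit_frac * HD, 0)
  network$segments <- seg
  network
}
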