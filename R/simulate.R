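# Simulation orchestration: the coupled growth loop (oxygen -> region
# classification -> proliferation -> Darcy flow -> interface advection ->
# TAF/angiogenesis), nanoparticle injection at the grown vasculature, and
# the treatment loop coupling drug release to tumor regression.

#' Initialize a coupled simulation
#'
#' Builds the grid, the pre-existing capillary network (flow-solved), the
#' seed tumor nodule (a disc-shaped level set at the domain centre) and the
#' initial oxygen/TAF fields from a configuration list (see
#' [default_config()]).
#'
#' @param config Configuration list; missing entries take defaults.
#' @return An environment of class `tumor_sim` holding the mutable
#'   simulation state (`grid`, `net`, `raster`, `tumor`, `sigma`, `taf`,
#'   `tips`, `time`, `history`).
#' @export
sim_init <- function(config = default_config()) {
  cfg <- validate_config(config)
  sim <- new.env(parent = emptyenv())
  class(sim) <- "tumor_sim"
  sim$cfg <- cfg
  sim$grid <- grid_spec(cfg$grid$n_cells, cfg$grid$domain_mm,
                        cfg$grid$length_scale_mm)
  sim$cfg_growth <- do.call(growth_params, cfg$tumor[names(cfg$tumor) %in%
                            names(formals(growth_params))])
  sim$cfg_oxy <- do.call(oxygen_params, cfg$oxygen)
  sim$cfg_angio <- do.call(angio_params, cfg$angiogenesis)
  sim$cfg_vessels <- cfg$vessels
  sim$net <- build_preexisting_grid(sim$grid, cfg$vessels$spacing_mm,
                                    cfg$vessels$radius,
                                    hematocrit = sim$cfg_oxy$HD)
  sim$net <- solve_flow(sim$net, cfg$vessels$p_in, cfg$vessels$p_out,
                        cfg$vessels$viscosity)
  sim$raster <- rasterize_network(sim$net, sim$grid)
  sim$network_dirty <- FALSE
  ctr <- sim$grid$L / 2
  xc <- cell_centers(sim$grid)
  r <- sqrt(outer(xc - ctr, rep(1, sim$grid$n))^2 +
            outer(rep(1, sim$grid$n), xc - ctr)^2)
  sim$tumor <- tumor_state(sim$grid, r - cfg$tumor$seed_radius_mm)
  sim$taf <- matrix(0, sim$grid$n, sim$grid$n)
  sim$tips <- list()
  sim$sigma <- matrix(1, sim$grid$n, sim$grid$n)
  sim$time <- 0
  sim$history <- list()
  set.seed(cfg$seed)
  sim
}

#' @export
print.tumor_sim <- function(x, ...) {
  cat(sprintf("<tumor_sim> t = %.2f days\n", x$time))
  print(x$tumor)
  invisible(x)
}

# One coupled growth step. G is the current drug field (matrix) or NULL.
# With angiogenesis = FALSE the vascular network is frozen (treatment runs).
grow_step <- function(sim, dt, G = NULL, angiogenesis = TRUE) {
  # a tumor below a few cells is treated as eradicated: the continuum
  # description has no meaning at sub-resolution sizes
  if (sum(sim$tumor$phi < 0) < 4L) {
    sim$tumor$phi[] <- sim$grid$L
    sim$tumor$masks <- list(tumor = sim$tumor$phi < 0,
                            P = sim$tumor$phi < 0,
                            H = sim$tumor$phi < 0, N = sim$tumor$phi < 0)
    sim$time <- sim$time + dt
    sim$history[[length(sim$history) + 1L]] <-
      data.frame(time_days = sim$time, area_mm2 = 0, area_P = 0,
                 area_H = 0, area_N = 0, max_sigma = max(sim$sigma),
                 min_sigma = min(sim$sigma),
                 max_G = if (is.null(G)) 0 else max(G))
    return(invisible(sim))
  }
  if (isTRUE(sim$network_dirty)) {
    sim$net <- perfuse_new_vessels(sim$net, sim$cfg_angio, sim$cfg_oxy$HD,
                                   p_in = sim$cfg_vessels$p_in,
                                   p_out = sim$cfg_vessels$p_out,
                                   viscosity = sim$cfg_vessels$viscosity)
    sim$raster <- rasterize_network(sim$net, sim$grid)
    sim$network_dirty <- FALSE
  }
  p_i <- relative_interstitial_pressure(sim$tumor, sim$cfg_oxy$ifp_length_mm)
  ox <- solve_oxygen_regions(sim$raster, sim$tumor, sim$cfg_oxy,
                             sim$cfg_growth, p_i, sim$sigma)
  sim$sigma <- ox$sigma
  sim$tumor <- ox$state
  Gm <- if (is.null(G)) 0 else G
  lp <- net_proliferation(sim$tumor, sim$sigma, Gm, sim$cfg_growth)
  if (min(sim$tumor$phi) > -3 * sim$grid$h) {
    # under-resolved avascular nodule: the level set cannot transport
    # features a couple of cells wide, but in this well-mixed limit the
    # lesion is an exponentially growing disc; advance the interface
    # uniformly at the mean-rate normal speed (exact for a disc)
    r_eff <- sqrt(max(tumor_area(sim$tumor), sim$grid$h^2) / pi)
    lp_mean <- mean(lp[sim$tumor$masks$tumor])
    sim$tumor$phi <- sim$tumor$phi - dt * lp_mean * r_eff / 2
    sim$tumor$masks$tumor <- sim$tumor$phi < 0
  } else {
    sim$tumor <- solve_pressure_velocity(sim$tumor, lp, sim$cfg_growth)
    sim$tumor <- advance_interface(sim$tumor, dt)
  }
  if (angiogenesis) {
    sim$taf <- update_taf(sim$taf, sim$tumor$masks$H, sim$cfg_angio, dt, sim$grid)
    step_angiogenesis(sim, dt)
  }
  sim$time <- sim$time + dt
  h2 <- sim$grid$h^2
  sim$history[[length(sim$history) + 1L]] <-
    data.frame(time_days = sim$time,
               area_mm2 = tumor_area(sim$tumor),
               area_P = sum(sim$tumor$masks$P) * h2,
               area_H = sum(sim$tumor$masks$H) * h2,
               area_N = sum(sim$tumor$masks$N) * h2,
               max_sigma = max(sim$sigma),
               min_sigma = min(sim$sigma),
               max_G = if (is.null(G)) 0 else max(G))
  invisible(sim)
}

#' Run the growth phase
#'
#' Advances the coupled tumor/vasculature system by `days` of model time
#' with step `dt`.
#'
#' @param sim A `tumor_sim` from [sim_init()].
#' @param days Duration (days).
#' @param dt Growth time step (days).
#' @return The simulation (invisibly); growth history in `sim$history`.
#' @export
sim_grow <- function(sim, days, dt = sim$cfg$tumor$dt_days) {
  nstep <- round(days / dt)
  for (k in seq_len(nstep)) grow_step(sim, dt)
  invisible(sim)
}

#' Growth history as a data frame
#'
#' @param sim A `tumor_sim`.
#' @return data.frame of the per-step area/oxygen records.
#' @export
sim_history <- function(sim) do.call(rbind, sim$history)

#' Inject nanoparticles at the current vasculature
#'
#' Runs the injection/washout transport of [run_injection()] on the
#' current (perfused) network and stores the bound distribution in the
#' simulation.
#'
#' @param sim A `tumor_sim` (typically grown to the injection day).
#' @param formulation An [np_formulation()].
#' @param duration_s Injection pulse duration (s).
#' @param dt_s Transport time step (s).
#' @return The `np_state` (also stored as `sim$np`).
#' @export
sim_inject <- function(sim, formulation, duration_s = 3600, dt_s = 60) {
  if (isTRUE(sim$network_dirty)) {
    sim$net <- perfuse_new_vessels(sim$net, sim$cfg_angio, sim$cfg_oxy$HD,
                                   p_in = sim$cfg_vessels$p_in,
                                   p_out = sim$cfg_vessels$p_out,
                                   viscosity = sim$cfg_vessels$viscosity)
    sim$raster <- rasterize_network(sim$net, sim$grid)
    sim$network_dirty <- FALSE
  }
  sim$np <- run_injection(sim$net, formulation, duration_s, dt_s)
  sim$formulation <- formulation
  sim$np
}

#' Deep-copy a simulation state
#'
#' Treatment runs (and IC50 bisection in particular) restart repeatedly
#' from the same post-injection state; this clones the mutable
#' environment so each run leaves the cached state untouched.
#'
#' @param sim A `tumor_sim`.
#' @return An independent copy.
#' @export
sim_clone <- function(sim) {
  out <- new.env(parent = emptyenv())
  for (nm in ls(sim, all.names = TRUE)) assign(nm, get(nm, envir = sim), envir = out)
  class(out) <- "tumor_sim"
  out
}

#' Run a treatment window
#'
#' Couples zero-order drug release from the bound nanoparticles, implicit
#' drug diffusion--decay, and the tumor response through the
#' drug-modulated net proliferation rate, over `hours` of model time. The
#' vascular network is frozen for the window (vascular remodeling is slow
#' compared to the 72-h treatment horizon), which also makes every
#' treatment run bit-deterministic.
#'
#' @param sim A `tumor_sim` carrying an injected `np` state; the input
#'   state is not modified (an internal clone is advanced).
#' @param lambda_effect Drug potency (death rate per unit drug).
#' @param drug A [drug_params()].
#' @param hours Treatment horizon (h).
#' @param dt_days Coupled time step (days; default 0.025 = 36 min).
#' @return List: `series` (data.frame time_h, area_mm2, rel_area, total_G,
#'   max_G), `min_rel_area`, `nadir_h`, `area0`, and the advanced clone as
#'   `sim`.
#' @export
sim_treat <- function(sim, lambda_effect, drug = drug_params(), hours = 72,
                      dt_days = 0.025) {
  if (is.null(sim$np)) stop("no nanoparticles injected: call sim_inject() first")
  run <- sim_clone(sim)
  run$cfg_growth$lambda_effect <- lambda_effect
  payload <- payload_state(run$np, run$net, run$formulation, drug, run$grid)
  stepper <- make_diffusion_stepper(run$grid, drug$D_G * drug$D_ref,
                                    drug$lambda_decay, dt_days)
  G <- matrix(0, run$grid$n, run$grid$n)
  area0 <- tumor_area(run$tumor)
  nstep <- ceiling(hours / 24 / dt_days)
  rows <- vector("list", nstep)
  for (k in seq_len(nstep)) {
    st <- step_drug(G, payload, drug, dt_days, run$grid, stepper)
    G <- st$G; payload <- st$payload
    grow_step(run, dt_days, G = G, angiogenesis = FALSE)
    tm <- run$tumor$masks$tumor
    expo <- if (any(tm)) tumor_drug_exposure(G, tm, run$grid)
            else list(total = 0, max = 0)
    rows[[k]] <- data.frame(time_h = k * dt_days * 24,
                            area_mm2 = tumor_area(run$tumor),
                            total_G = expo$total, max_G = expo$max)
  }
  series <- do.call(rbind, rows)
  series$rel_area <- series$area_mm2 / area0
  imin <- which.min(series$rel_area)
  list(series = series, min_rel_area = series$rel_area[imin],
       nadir_h = series$time_h[imin], area0 = area0, sim = run)
}
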