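# Quasi-steady oxygen field: vascular extravasation gated by hematocrit and
# interstitial pressure, region-dependent tissue uptake, necrotic decay.

#' Oxygen transport parameters
#'
#' The oxygen field is quasi-steady (it equilibrates much faster than
#' tissue growth) and normalized to [0, 1]. Uptake/transfer rates are per
#' day; only their ratios to the diffusivity matter, through the diffusion
#' lengths `sqrt(D / lambda)`.
#'
#' @param D_sigma Oxygen diffusivity (mm^2/day). The default, with the
#'   default proliferating-tissue uptake, gives a 100 um diffusion length,
#'   matching the 100-200 um proliferating rim thickness.
#' @param lambda_ev Transfer (extravasation) rate from vessel cells (1/day).
#' @param lambda_tissue Uptake by normal tissue (1/day).
#' @param lambda_tumor Uptake in the proliferating region (1/day).
#' @param q_s Uptake in the hypoxic region (1/day).
#' @param lambda_necrotic Decay rate in the necrotic region (1/day).
#' @param HD Normal blood hematocrit.
#' @param h_min Minimum relative hematocrit (`h / HD`) required for oxygen
#'   extravasation.
#' @param k_pi Weight of the convective (interstitial-pressure) reduction
#'   of extravasation, in [0, 1].
#' @param ifp_length_mm Screening length (mm) of the interstitial
#'   pressure profile (see [relative_interstitial_pressure()]).
#' @return Object of class `oxygen_params`.
#' @export
oxygen_params <- function(D_sigma = 100, lambda_ev = 8e4,
                          lambda_tissue = 1100, lambda_tumor = 10000,
                          q_s = 3000, lambda_necrotic = 4000,
                          HD = 0.45, h_min = 0.25, k_pi = 1.0,
                          ifp_length_mm = 0.05) {
  vals <- c(D_sigma, lambda_ev, lambda_tissue, lambda_tumor, q_s,
            lambda_necrotic, HD, h_min)
  if (any(vals < 0)) stop("all oxygen rates must be >= 0")
  if (k_pi < 0 || k_pi > 1) stop("k_pi must lie in [0, 1]")
  structure(list(D_sigma = D_sigma, lambda_ev = lambda_ev,
                 lambda_tissue = lambda_tissue, lambda_tumor = lambda_tumor,
                 q_s = q_s, lambda_necrotic = lambda_necrotic,
                 HD = HD, h_min = h_min, k_pi = k_pi,
                 ifp_length_mm = ifp_length_mm),
            class = "oxygen_params")
}

#' Oxygen extravasation rate field
#'
#' Per-cell extravasation rate
#' `lambda_ev * 1_vessel * max(h/HD - h_min, 0) * (1 - k_pi * p_i/p_e) * (1 - sigma)`:
#' zero off-vessel, zero when the local hematocrit is below the minimum,
#' reduced where the interstitial pressure is high, and driven by the
#' transmural gradient `(1 - sigma)`. The hematocrit term is clamped at
#' zero so `h_min` acts as a truly minimal hematocrit for extravasation.
#'
#' @param raster Output of [rasterize_network()] (vessel mask + hematocrit).
#' @param sigma Oxygen field (matrix or scalar_field, values in [0, 1]).
#' @param p_i Interstitial pressure relative to the effective pressure
#'   scale, i.e. `p_i / p_e` in [0, 1] (matrix/scalar).
#' @param params An [oxygen_params()].
#' @param grid A [grid_spec()].
#' @return Matrix of extravasation rates (1/day).
#' @export
extravasation_field <- function(raster, sigma, p_i, params, grid) {
  sv <- field_values(sigma, grid)
  pv <- field_values(p_i, grid)
  hterm <- pmax(raster$hematocrit / params$HD - params$h_min, 0)
  params$lambda_ev * raster$mask * hterm *
    pmax(1 - params$k_pi * pv, 0) * (1 - sv)
}

#' Solve the quasi-steady oxygen field
#'
#' Steady reaction--diffusion balance between vascular extravasation
#' (linear in `1 - sigma`) and region-dependent uptake. Because the source
#' is affine in sigma, the linearized system
#' `(-D Lap + lambda_sink + c) sigma = c` with
#' `c = lambda_ev 1_vessel (h/HD - h_min)_+ (1 - k_pi p_i/p_e)` is solved
#' in one sparse solve; the maximum principle guarantees `sigma` in [0, 1].
#'
#' @param raster Output of [rasterize_network()].
#' @param state A `tumor_state` whose masks select the uptake rate
#'   (`lambda_tissue` outside the tumor, `lambda_tumor` in the
#'   proliferating region, `q_s` hypoxic, `lambda_necrotic` necrotic).
#' @param params An [oxygen_params()].
#' @param p_i Relative interstitial pressure field (see
#'   [extravasation_field()]); default 0.
#' @return A `scalar_field` with sigma in [0, 1].
#' @export
solve_oxygen <- function(raster, state, params, p_i = 0) {
  grid <- state$grid
  sink <- matrix(params$lambda_tissue, grid$n, grid$n)
  sink[state$masks$P] <- params$lambda_tumor
  sink[state$masks$H] <- params$q_s
  sink[state$masks$N] <- params$lambda_necrotic
  cc <- extravasation_field(raster, 0, p_i, params, grid)  # coefficient at sigma = 0
  sigma <- solve_steady_rd(grid, params$D_sigma, cc, sink + cc)
  sigma$values <- pmin(pmax(sigma$values, 0), 1)  # round-off guard only
  sigma
}

#' Self-consistent oxygen field and region classification
#'
#' The uptake rate in [solve_oxygen()] depends on the region masks, which
#' in turn depend on the oxygen field through the thresholds: a
#' discontinuous fixed-point problem. Solving it naively once per growth
#' step can flip the whole lesion between an all-proliferating and a
#' hypoxic/necrotic labelling on alternate steps. This routine iterates
#' classification and solve with damping (`sigma <- (sigma + solve)/2`)
#' until the masks stop changing (or `max_iter`), yielding the
#' threshold-consistent mixed state.
#'
#' @param raster Output of [rasterize_network()].
#' @param state A `tumor_state`.
#' @param params An [oxygen_params()].
#' @param growth A [growth_params()] (thresholds).
#' @param p_i Relative interstitial pressure field.
#' @param sigma_prev Previous oxygen field (warm start), matrix or NULL.
#' @param max_iter Iteration cap.
#' @return List: `sigma` (matrix), `state` (with consistent masks).
#' @export
solve_oxygen_regions <- function(raster, state, params, growth, p_i = 0,
                                 sigma_prev = NULL, max_iter = 6) {
  sigma <- if (is.null(sigma_prev)) matrix(1, state$grid$n, state$grid$n)
           else sigma_prev
  masks_prev <- NULL
  for (it in seq_len(max_iter)) {
    state <- classify_regions(state, sigma, growth)
    key <- c(state$masks$P, state$masks$N)
    if (!is.null(masks_prev) && identical(key, masks_prev)) break
    masks_prev <- key
    solved <- solve_oxygen(raster, state, params, p_i)
    sigma <- if (it == 1) solved$values else (sigma + solved$values) / 2
  }
  state <- classify_regions(state, sigma, growth)
  list(sigma = sigma, state = state)
}

#' Relative interstitial pressure field
#'
#' Solid tumors carry an elevated interstitial fluid pressure (IFP) that
#' plateaus in the core and falls to the normal-tissue level across the
#' margin. The relative pressure `p_i / p_e` entering the extravasation
#' switch is modeled by the screened profile
#' `(-l^2 Lap + 1) psi = 1_tumor` under zero-flux boundaries: `psi ~ 1`
#' deeper than the screening length `l` inside the lesion, ~0.5 at the
#' interface, and decays over `l` outside. A nodule much smaller than `l`
#' keeps low pressure everywhere (its vessels exchange freely); as the
#' lesion outgrows `l`, interior vessels progressively lose oxygen (and
#' convective) exchange, and regain it when treatment shrinks the lesion.
#'
#' @param state A `tumor_state`.
#' @param ifp_length_mm Screening length of the IFP profile (mm).
#' @return Matrix with values in [0, 1].
#' @export
relative_interstitial_pressure <- function(state, ifp_length_mm = 0.05) {
  grid <- state$grid
  tum <- state$masks$tumor
  if (!any(tum)) return(matrix(0, grid$n, grid$n))
  key <- sprintf("ifp_%d_%.12g_%.6g", grid$n, grid$h, ifp_length_mm)
  if (is.null(.nv_cache[[key]])) {
    A <- -ifp_length_mm^2 * grid_laplacian(grid) + Matrix::Diagonal(grid$n^2)
    .nv_cache[[key]] <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  }
  psi <- matrix(as.vector(Matrix::solve(.nv_cache[[key]], as.vector(1 * tum))),
                grid$n, grid$n)
  pmin(pmax(psi, 0), 1)
}
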