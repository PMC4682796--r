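# Continuum tumor: level-set interface, region classification by oxygen,
# net proliferation with drug modulation, Darcy pressure/velocity, and
# interface advection with area accounting.

#' Tumor growth parameters
#'
#' Rates are per day; thresholds apply to the normalized oxygen field
#' (sigma in [0, 1]).
#'
#' @param lambda_M Mitosis rate (1/day).
#' @param lambda_A Apoptosis rate (1/day).
#' @param lambda_N Necrotic volume-loss rate (1/day).
#' @param lambda_effect Drug-induced death-rate coefficient (per unit drug);
#'   the quantity tuned by the IC50 procedure.
#' @param mu Darcy cell mobility (sets the pressure scale only; the velocity
#'   field is independent of `mu`).
#' @param chi_E Haptotaxis coefficient (default 0: pure Darcy flow; the ECM
#'   field is uniform unless configured otherwise).
#' @param sigma_H Hypoxia threshold on sigma (proliferating above).
#' @param sigma_N Necrosis threshold on sigma (necrotic below); requires
#'   `0 <= sigma_N < sigma_H <= 1`.
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(lambda_M = 1.2, lambda_A = 0.25, lambda_N = 0.35,
                          lambda_effect = 0, mu = 1, chi_E = 0,
                          sigma_H = 0.5, sigma_N = 0.3) {
  if (any(c(lambda_M, lambda_A, lambda_N, lambda_effect, mu) < 0))
    stop("all rates must be >= 0")
  if (!(sigma_N >= 0 && sigma_N < sigma_H && sigma_H <= 1))
    stop("thresholds must satisfy 0 <= sigma_N < sigma_H <= 1")
  structure(list(lambda_M = lambda_M, lambda_A = lambda_A, lambda_N = lambda_N,
                 lambda_effect = lambda_effect, mu = mu, chi_E = chi_E,
                 sigma_H = sigma_H, sigma_N = sigma_N),
            class = "growth_params")
}

#' Tumor state
#'
#' The tumor occupies the region where the level-set field `phi` is
#' negative; `phi` is maintained as an approximate signed distance (mm).
#' Region masks partition the tumor into proliferating / hypoxic / necrotic
#' tissue according to oxygen thresholds.
#'
#' @param grid A [grid_spec()].
#' @param phi Level-set matrix (negative inside the tumor).
#' @param E ECM density field (matrix), uniform 1 by default.
#' @return Object of class `tumor_state` with elements `grid`, `phi`, `E`,
#'   `masks` (list of logical matrices `tumor`, `P`, `H`, `N`), `P_field`
#'   (oncotic pressure, filled by [solve_pressure_velocity()]).
#' @export
tumor_state <- function(grid, phi, E = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(phi), all(dim(phi) == grid$n))
  if (is.null(E)) E <- matrix(1, grid$n, grid$n)
  masks <- list(tumor = phi < 0,
                P = phi < 0, H = matrix(FALSE, grid$n, grid$n),
                N = matrix(FALSE, grid$n, grid$n))
  structure(list(grid = grid, phi = phi, E = E, masks = masks,
                 P_field = matrix(0, grid$n, grid$n)),
            class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  a <- tumor_area(x)
  cat(sprintf("<tumor_state> area %.4g mm^2 (equiv. diameter %.0f um); P/H/N cells %d/%d/%d\n",
              a, 2000 * sqrt(a / pi),
              sum(x$masks$P), sum(x$masks$H), sum(x$masks$N)))
  invisible(x)
}

#' Tumor area from the level set
#'
#' Area of the region `phi < 0` using a smoothed Heaviside of width
#' `1.5 h` for sub-cell accuracy.
#'
#' @param state A `tumor_state` (or a phi matrix with `grid` supplied).
#' @param grid Grid, when `state` is a matrix.
#' @return Area in mm^2.
#' @export
tumor_area <- function(state, grid = NULL) {
  if (inherits(state, "tumor_state")) { phi <- state$phi; grid <- state$grid }
  else phi <- state
  eps <- 1.5 * grid$h
  x <- -phi / eps
  H <- ifelse(x < -1, 0, ifelse(x > 1, 1, 0.5 * (1 + x + sin(pi * x) / pi)))
  sum(H) * grid$h^2
}

#' Area-equivalent tumor diameter
#'
#' @inheritParams tumor_area
#' @return Diameter in micrometres of the circle with the tumor's area.
#' @export
equivalent_diameter_um <- function(state, grid = NULL) {
  2000 * sqrt(tumor_area(state, grid) / pi)
}

#' Classify tumor regions by oxygen
#'
#' Inside the tumor: proliferating where `sigma >= sigma_H`, hypoxic where
#' `sigma_N <= sigma < sigma_H`, necrotic where `sigma < sigma_N`. Cells
#' outside the tumor belong to no region. The three masks partition the
#' tumor mask by construction.
#'
#' @param state A `tumor_state`.
#' @param sigma Oxygen field (scalar_field or matrix, values in [0, 1]).
#' @param params A [growth_params()].
#' @return The state with updated `masks`.
#' @export
classify_regions <- function(state, sigma, params) {
  sv <- field_values(sigma, state$grid)
  if (min(sv) < -1e-9 || max(sv) > 1 + 1e-9) stop("sigma must lie in [0, 1]")
  tum <- state$phi < 0
  state$masks <- list(tumor = tum,
                      P = tum & sv >= params$sigma_H,
                      H = tum & sv >= params$sigma_N & sv < params$sigma_H,
                      N = tum & sv < params$sigma_N)
  state
}

#' Net proliferation rate field
#'
#' Piecewise rate (1/day): `lambda_M * sigma * (1 - lambda_effect * G) -
#' lambda_A` in the proliferating region, 0 in the hypoxic region,
#' `-lambda_N` in the necrotic region, 0 outside the tumor. The drug acts
#' only on proliferating cells (cell-cycle dependent action); when
#' `lambda_effect * G >= 1` the local rate turns negative and drug-induced
#' death shrinks the tumor.
#'
#' @param state A `tumor_state` with current masks.
#' @param sigma Oxygen field.
#' @param G Drug concentration field (>= 0).
#' @param params A [growth_params()].
#' @return Matrix of net proliferation rates.
#' @export
net_proliferation <- function(state, sigma, G, params) {
  sv <- field_values(sigma, state$grid)
  Gv <- field_values(G, state$grid)
  if (min(Gv) < 0) stop("G must be >= 0")
  lp <- matrix(0, state$grid$n, state$grid$n)
  lp[state$masks$P] <- params$lambda_M * sv[state$masks$P] *
    (1 - params$lambda_effect * Gv[state$masks$P]) - params$lambda_A
  lp[state$masks$N] <- -params$lambda_N
  lp
}

#' Oncotic pressure and Darcy velocity
#'
#' Solves `-mu * Lap(P) = lambda_p - chi_E * Lap(E)` over the whole domain
#' (`lambda_p = 0` in host tissue, which is displaced incompressibly) with
#' a far-field condition `P = 0` on the domain boundary, then assembles
#' `v = -mu grad(P) + chi_E grad(E)`. Inside the tumor the velocity
#' satisfies the divergence theorem exactly as with an interface Dirichlet
#' condition (for a disc with uniform `lambda_p`, `|v|(r) = lambda_p r/2`),
#' but the field is continuous across the interface, which the level-set
#' advection requires.
#'
#' @param state A `tumor_state`.
#' @param lambda_p Net proliferation matrix from [net_proliferation()].
#' @param params A [growth_params()].
#' @return The state with `P_field` set and `vx`, `vy` (mm/day) attached.
#' @export
solve_pressure_velocity <- function(state, lambda_p, params) {
  grid <- state$grid
  tum <- state$masks$tumor
  lap <- grid_laplacian(grid)
  K <- 1e8 * params$mu / grid$h^2          # far-field Dirichlet penalty
  pen <- matrix(0, grid$n, grid$n)
  pen[1, ] <- K; pen[grid$n, ] <- K; pen[, 1] <- K; pen[, grid$n] <- K
  A <- -params$mu * lap + Matrix::Diagonal(x = as.vector(pen))
  rhs <- as.vector(ifelse(tum, lambda_p, 0))
  if (params$chi_E != 0)
    rhs <- rhs - params$chi_E * as.vector(lap %*% as.vector(state$E)) * as.vector(tum)
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  P <- matrix(as.vector(Matrix::solve(fac, rhs)), grid$n, grid$n)
  gP <- grad_centered(P, grid$h)
  vx <- -params$mu * gP$gx
  vy <- -params$mu * gP$gy
  if (params$chi_E != 0) {
    gE <- grad_centered(state$E, grid$h)
    vx <- vx + params$chi_E * gE$gx
    vy <- vy + params$chi_E * gE$gy
  }
  state$P_field <- P
  state$vx <- vx
  state$vy <- vy
  state
}

# --- level-set machinery ---------------------------------------------------

# First-order upwind advection step of phi by velocity (vx, vy), one step dt.
advect_upwind <- function(phi, vx, vy, h, dt) {
  dxm <- (phi - shift_xm(phi)) / h
  dxp <- (shift_xp(phi) - phi) / h
  dym <- (phi - shift_ym(phi)) / h
  dyp <- (shift_yp(phi) - phi) / h
  phi - dt * (pmax(vx, 0) * dxm + pmin(vx, 0) * dxp +
              pmax(vy, 0) * dym + pmin(vy, 0) * dyp)
}

# Godunov reinitialization towards |grad phi| = 1 with the subcell fix of
# Russo & Smereka: cells adjacent to the zero contour relax towards the
# signed-distance estimate phi0/|grad phi0| of the INPUT field, which pins
# the interface and prevents the area drift of plain reinitialization.
reinitialize_levelset <- function(phi, h, iters = 8) {
  phi0 <- phi
  S <- phi0 / sqrt(phi0^2 + h^2)
  near <- (phi0 * shift_xm(phi0) < 0) | (phi0 * shift_xp(phi0) < 0) |
          (phi0 * shift_ym(phi0) < 0) | (phi0 * shift_yp(phi0) < 0)
  # Godunov gradient of the input field: an exact signed distance then has
  # |grad phi0| = 1, so reinitialization leaves it untouched (no drift)
  dxm0 <- (phi0 - shift_xm(phi0)) / h; dxp0 <- (shift_xp(phi0) - phi0) / h
  dym0 <- (phi0 - shift_ym(phi0)) / h; dyp0 <- (shift_yp(phi0) - phi0) / h
  gp0 <- sqrt(pmax(pmax(dxm0, 0)^2, pmin(dxp0, 0)^2) +
              pmax(pmax(dym0, 0)^2, pmin(dyp0, 0)^2))
  gm0 <- sqrt(pmax(pmin(dxm0, 0)^2, pmax(dxp0, 0)^2) +
              pmax(pmin(dym0, 0)^2, pmax(dyp0, 0)^2))
  gn0 <- pmax(ifelse(phi0 > 0, gp0, gm0), 1e-12)
  D <- pmin(pmax(phi0 / gn0, -2 * h), 2 * h)  # near-interface distance estimate
  dtau <- 0.5 * h
  for (k in seq_len(iters)) {
    dxm <- (phi - shift_xm(phi)) / h
    dxp <- (shift_xp(phi) - phi) / h
    dym <- (phi - shift_ym(phi)) / h
    dyp <- (shift_yp(phi) - phi) / h
    ap <- pmax(dxm, 0); am <- pmin(dxp, 0)
    bp <- pmax(dym, 0); bm <- pmin(dyp, 0)
    gpos <- sqrt(pmax(ap^2, am^2) + pmax(bp^2, bm^2))
    an <- pmin(dxm, 0); ax <- pmax(dxp, 0)
    bn <- pmin(dym, 0); bx <- pmax(dyp, 0)
    gneg <- sqrt(pmax(an^2, ax^2) + pmax(bn^2, bx^2))
    grad <- ifelse(phi > 0, gpos, gneg)
    upd <- phi - dtau * S * (grad - 1)
    upd[near] <- phi[near] - (dtau / h) * (sign(phi0[near]) * abs(phi[near]) - D[near])
    phi <- upd
  }
  phi
}

#' Advance the tumor interface
#'
#' Advects the level set with the Darcy velocity by first-order upwind
#' differencing (sub-stepped to keep the CFL number below 0.5) and
#' reinitializes the level set towards a signed distance. For smooth
#' velocity fields the area change over `dt` tracks the divergence theorem
#' `dA/dt = integral of lambda_p over the tumor`.
#'
#' @param state A `tumor_state` returned by [solve_pressure_velocity()]
#'   (must carry `vx`, `vy`).
#' @param dt Time step in days.
#' @param reinit Logical: reinitialize after advection (default TRUE).
#' @return The advanced `tumor_state`.
#' @export
advance_interface <- function(state, dt, reinit = TRUE) {
  if (is.null(state$vx)) stop("state has no velocity: call solve_pressure_velocity() first")
  if (dt <= 0) stop("dt must be > 0")
  grid <- state$grid
  vmax <- max(abs(state$vx), abs(state$vy))
  nsub <- max(1L, ceiling(vmax * dt / (0.5 * grid$h)))
  if (nsub > 1000L) stop("CFL violation: velocity too large for dt; use a smaller dt")
  phi <- state$phi
  for (k in seq_len(nsub))
    phi <- advect_upwind(phi, state$vx, state$vy, grid$h, dt / nsub)
  if (reinit) phi <- reinitialize_levelset(phi, grid$h)
  phi <- pmin(pmax(phi, -grid$L), grid$L)
  if (any(!is.finite(phi)))
    stop("level set became non-finite: advection unstable for this dt")
  state$phi <- phi
  state$masks$tumor <- phi < 0
  state
}
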