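# Treatment-efficacy analysis: scenario runner (grow -> inject -> treat),
# IC50 bisection on the drug potency, and formulation sweeps.
#
# "Reducing the tumor by 50% of its original area" is evaluated at the
# post-injection NADIR: the minimum of area(t)/area(injection) over the
# observation horizon. The nadir (typically near 24 h, followed by
# regrowth) is well defined, whereas a fixed-time reading would depend on
# arbitrary sampling.

#' Treatment scenario
#'
#' Bundles everything one run needs: the NP formulation, drug parameters,
#' the simulation configuration (growth, vessels, oxygen, angiogenesis),
#' the injection day and the observation horizon.
#'
#' @param formulation An [np_formulation()].
#' @param drug A [drug_params()].
#' @param config Simulation configuration (see [default_config()]).
#' @param injection_day Day of systemic NP injection (default 18).
#' @param horizon_h Post-injection observation horizon in hours (default 72).
#' @param lambda_effect Drug potency for a plain [run_scenario()] call.
#' @return Object of class `treatment_scenario`.
#' @export
treatment_scenario <- function(formulation = np_formulation(),
                               drug = drug_params(),
                               config = default_config(),
                               injection_day = 18, horizon_h = 72,
                               lambda_effect = 0) {
  if (horizon_h <= 0) stop("horizon_h must be > 0")
  structure(list(formulation = formulation, drug = drug,
                 config = validate_config(config),
                 injection_day = injection_day, horizon_h = horizon_h,
                 lambda_effect = lambda_effect),
            class = "treatment_scenario")
}

#' Grow the scenario's tumor to the injection day
#'
#' The growth phase depends only on the configuration (not on the NP
#' formulation), so its result is cached and shared across every
#' formulation and every bisection iterate of a sweep.
#'
#' @param scenario A [treatment_scenario()].
#' @return A grown `tumor_sim` (deterministic given `config$seed`).
#' @export
grow_to_injection <- function(scenario) {
  sim <- sim_init(scenario$config)
  sim_grow(sim, scenario$injection_day)
  sim
}

#' Run one treatment scenario
#'
#' Executes growth to the injection day (or reuses a cached grown state),
#' the NP injection/washout, and the drug-release/tumor-response window.
#' Deterministic given the configuration seed.
#'
#' @param scenario A [treatment_scenario()].
#' @param grown Optional cached result of [grow_to_injection()].
#' @param lambda_effect Drug potency; defaults to the scenario's.
#' @return The [sim_treat()] result, plus `grown` and `np` entries.
#' @export
run_scenario <- function(scenario, grown = NULL, lambda_effect = NULL) {
  if (is.null(grown)) grown <- grow_to_injection(scenario)
  if (is.null(grown$np) ||
      !identical(grown$formulation, scenario$formulation))
    sim_inject(grown, scenario$formulation)
  le <- if (is.null(lambda_effect)) scenario$lambda_effect else lambda_effect
  out <- sim_treat(grown, le, scenario$drug, scenario$horizon_h)
  out$grown <- grown
  out$np <- grown$np
  out
}

#' Tune the drug potency to the 50% regression point (IC50)
#'
#' Bisection on `lambda_effect` until the minimum relative tumor area over
#' the horizon is within `tol` of `target` (default 0.5). The efficacy
#' measure of a formulation is `1/lambda_IC50`: a formulation needing less
#' potency to halve the tumor is the more effective delivery vehicle.
#'
#' The objective must be monotone non-increasing in `lambda_effect` (more
#' potency, no larger tumor); the initial bracket is `[0, lambda_hi]` and
#' is expanded once (x10) if `lambda_hi` cannot reach the target. If even
#' the expanded bracket cannot, the formulation is reported as a
#' low-efficacy outcome (`converged = FALSE`) rather than an error.
#'
#' @param objective `function(lambda_effect) -> min relative area` (for
#'   full simulations, see [ic50_for_state()]).
#' @param lambda_hi Initial upper bracket for the potency.
#' @param target Relative-area target (default 0.5).
#' @param tol Convergence tolerance on |min relative area - target|.
#' @param max_iter Maximum bisection iterations.
#' @return Object of class `efficacy_result`: `lambda_ic50`,
#'   `rel_efficacy = 1/lambda_ic50`, `min_rel_area` at the returned value,
#'   `converged`, and the bisection `trace` (data.frame).
#' @export
tune_ic50 <- function(objective, lambda_hi, target = 0.5, tol = 0.01,
                      max_iter = 40) {
  trace <- list()
  note <- function(l, a) trace[[length(trace) + 1L]] <<-
    data.frame(lambda_effect = l, min_rel_area = a)
  a_hi <- objective(lambda_hi); note(lambda_hi, a_hi)
  if (a_hi > target) {                       # expand once
    lambda_hi <- 10 * lambda_hi
    a_hi <- objective(lambda_hi); note(lambda_hi, a_hi)
    if (a_hi > target)
      return(structure(list(lambda_ic50 = NA_real_, rel_efficacy = NA_real_,
                            min_rel_area = a_hi, converged = FALSE,
                            outcome = "low-efficacy formulation",
                            trace = do.call(rbind, trace)),
                       class = "efficacy_result"))
  }
  lo <- 0; hi <- lambda_hi
  a_mid <- a_hi; mid <- hi
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    a_mid <- objective(mid); note(mid, a_mid)
    if (abs(a_mid - target) < tol) break
    if (a_mid > target) lo <- mid else hi <- mid
  }
  structure(list(lambda_ic50 = mid, rel_efficacy = 1 / mid,
                 min_rel_area = a_mid,
                 converged = abs(a_mid - target) < tol,
                 outcome = "ic50",
                 trace = do.call(rbind, trace)),
            class = "efficacy_result")
}

#' @export
print.efficacy_result <- function(x, ...) {
  if (is.na(x$lambda_ic50))
    cat("<efficacy_result> low-efficacy formulation (target unreachable)\n")
  else
    cat(sprintf("<efficacy_result> lambda_IC50 = %.4g, 1/lambda_IC50 = %.4g, min rel. area %.3f (%s)\n",
                x$lambda_ic50, x$rel_efficacy, x$min_rel_area,
                if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' IC50 tuning on a prepared simulation state
#'
#' Builds the bisection objective from a grown + injected simulation:
#' each evaluation clones the cached state and runs the treatment window.
#' The upper bracket is chosen from a potency-free probe run so that
#' `lambda_hi * max(G) = deep_kill` (deep-kill regime, default 10).
#'
#' @param grown A grown `tumor_sim` with an injected `np` state.
#' @param drug A [drug_params()].
#' @param horizon_h Observation horizon (h).
#' @param target,tol,max_iter Passed to [tune_ic50()].
#' @param deep_kill Target of `lambda_hi * maxG` for the initial bracket.
#' @return An `efficacy_result` (the potency-free probe's peak drug
#'   concentration is attached as `max_G_probe`).
#' @export
ic50_for_state <- function(grown, drug = drug_params(), horizon_h = 72,
                           target = 0.5, tol = 0.01, max_iter = 40,
                           deep_kill = 10) {
  if (is.null(grown$np)) stop("state has no injected nanoparticles")
  probe <- sim_treat(grown, 0, drug, horizon_h)
  maxG <- max(probe$series$max_G)
  if (maxG <= 0) {
    return(structure(list(lambda_ic50 = NA_real_, rel_efficacy = NA_real_,
                          min_rel_area = probe$min_rel_area, converged = FALSE,
                          outcome = "no drug delivered", trace = NULL,
                          max_G_probe = 0),
                     class = "efficacy_result"))
  }
  obj <- function(l) sim_treat(grown, l, drug, horizon_h)$min_rel_area
  res <- tune_ic50(obj, lambda_hi = deep_kill / maxG, target = target,
                   tol = tol, max_iter = max_iter)
  res$max_G_probe <- maxG
  res
}

#' Sweep formulations (and drug diffusivities)
#'
#' One row per `alpha x d` cell: the tuned IC50 potency and relative
#' efficacy at the standard diffusivity; optionally, for each `D_G` value,
#' the minimum relative area reached when the potency is held at the
#' cell's `lambda_IC50` (the drug-diffusivity experiment). The growth
#' phase is computed once and cached across the whole sweep; per-cell
#' failures are recorded in the `error` column and the sweep continues.
#'
#' @param scenario Base [treatment_scenario()].
#' @param alphas Neovessel affinities to sweep (1/m^2).
#' @param diameters_nm NP diameters in nm.
#' @param D_G_values Optional drug diffusivities for the fixed-potency
#'   regression sweep.
#' @param grown Optional cached grown state.
#' @param tol IC50 tolerance on the relative-area criterion.
#' @return tidy data.frame: `alpha`, `d_nm`, `lambda_ic50`, `rel_efficacy`,
#'   `min_rel_area`, then one `min_rel_area_DG_<v>` column per diffusivity.
#' @export
sweep_formulations <- function(scenario, alphas = c(1e8, 1e10, 1e12),
                               diameters_nm = c(100, 600, 1000),
                               D_G_values = NULL, grown = NULL, tol = 0.01) {
  if (is.null(grown)) grown <- grow_to_injection(scenario)
  rows <- list()
  for (alpha in alphas) for (d_nm in diameters_nm) {
    row <- data.frame(alpha = alpha, d_nm = d_nm, lambda_ic50 = NA_real_,
                      rel_efficacy = NA_real_, min_rel_area = NA_real_,
                      error = NA_character_)
    res <- tryCatch({
      f <- np_formulation(d = d_nm * 1e-9, alpha_neo = alpha,
                          beta = scenario$formulation$beta,
                          gamma = scenario$formulation$gamma)
      sim_inject(grown, f)
      ic <- ic50_for_state(grown, scenario$drug, scenario$horizon_h, tol = tol)
      row$lambda_ic50 <- ic$lambda_ic50
      row$rel_efficacy <- ic$rel_efficacy
      row$min_rel_area <- ic$min_rel_area
      if (!is.null(D_G_values) && !is.na(ic$lambda_ic50)) {
        for (dg in D_G_values) {
          dpar <- scenario$drug; dpar$D_G <- dg
          tr <- sim_treat(grown, ic$lambda_ic50, dpar, scenario$horizon_h)
          row[[sprintf("min_rel_area_DG_%g", dg)]] <- tr$min_rel_area
        }
      }
      row
    }, error = function(e) { row$error <- conditionMessage(e); row })
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    # align columns across rows
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA_real_
    r[all_cols]
  }))
  rownames(out) <- NULL
  out
}
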