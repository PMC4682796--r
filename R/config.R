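# Configuration: nested defaults, YAML loading, strict validation.
# The config file is YAML with one section per model component; unknown
# keys are rejected so typos cannot silently fall back to defaults.

#' Default simulation configuration
#'
#' Nested list with every tunable parameter of the model and its default.
#' Sections: `grid`, `vessels`, `tumor`, `oxygen`, `angiogenesis`, `np`,
#' `drug`, plus the RNG `seed` and `schema` version. Defaults are the
#' baseline study conditions: a 2 x 2 mm field of view, a pre-existing
#' capillary grid with 250 um spacing and 10 um radius, a sub-50-um seed
#' nodule, and growth rates under which the lesion reaches ~750 um
#' equivalent diameter at day 18.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    schema = 1L,
    seed = 1L,
    grid = list(n_cells = 96L, domain_mm = 2, length_scale_mm = 0.1),
    vessels = list(spacing_mm = 0.25, radius = 1e-5,
                   p_in = 500, p_out = 0, viscosity = 3e-3),
    tumor = list(seed_radius_mm = 0.04, dt_days = 0.1,
                 lambda_M = 1.2, lambda_A = 0.25, lambda_N = 0.35,
                 lambda_effect = 0, mu = 1, chi_E = 0,
                 sigma_H = 0.5, sigma_N = 0.3),
    oxygen = list(D_sigma = 100, lambda_ev = 8e4, lambda_tissue = 1100,
                  lambda_tumor = 10000, q_s = 3000, lambda_necrotic = 4000,
                  HD = 0.45, h_min = 0.25, k_pi = 1.0,
                  ifp_length_mm = 0.05),
    angiogenesis = list(D_taf = 0.8, lambda_taf = 20, s_taf = 20,
                        D_tip = 1, chi_taf = 40, chi_ecm = 0,
                        taf_threshold = 0.05, sprout_rate = 1,
                        branch_rate = 0.5, max_tips = 40,
                        neovessel_hematocrit_frac = 0.5),
    np = list(d = 100e-9, alpha_neo = 1e12, beta = 1e-4, gamma = 1e4,
              delta1 = 0.45, delta2 = 1.57, d_ref = 100e-9,
              injection_duration_s = 3600, dt_s = 60),
    drug = list(D_G = 0.022, D_ref = 4, half_life_h = 6,
                release_time_ref_h = 12)
  )
}

# constraint checks beyond structural validation; each entry: path, test,
# message fragment
.config_checks <- list(
  list(c("np", "alpha_neo"), function(v) v >= 0, "must be >= 0"),
  list(c("np", "d"), function(v) v > 0, "must be > 0"),
  list(c("vessels", "spacing_mm"), function(v) v > 0, "must be > 0"),
  list(c("vessels", "radius"), function(v) v > 0, "must be > 0"),
  list(c("vessels", "viscosity"), function(v) v > 0, "must be > 0"),
  list(c("grid", "n_cells"), function(v) v >= 8, "must be >= 8"),
  list(c("tumor", "seed_radius_mm"), function(v) v > 0, "must be > 0"),
  list(c("tumor", "dt_days"), function(v) v > 0, "must be > 0"),
  list(c("drug", "D_G"), function(v) v > 0 && v <= 1, "must lie in (0, 1]"),
  list(c("drug", "half_life_h"), function(v) v > 0, "must be > 0"),
  list(c("oxygen", "k_pi"), function(v) v >= 0 && v <= 1, "must lie in [0, 1]")
)

#' Validate (and complete) a configuration
#'
#' Fills missing entries with defaults, rejects unknown keys (naming the
#' offending key) and enforces the parameter constraints.
#'
#' @param config Possibly partial nested configuration list.
#' @return The completed configuration.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  merge_section <- function(d, c, path) {
    if (is.null(c)) return(d)
    unknown <- setdiff(names(c), names(d))
    if (length(unknown))
      stop(sprintf("unknown configuration key: %s%s",
                   if (nchar(path)) paste0(path, ".") else "", unknown[1]))
    for (nm in names(c)) {
      if (is.list(d[[nm]])) d[[nm]] <- merge_section(d[[nm]], c[[nm]],
                                                     paste0(path, if (nchar(path)) "." else "", nm))
      else d[[nm]] <- c[[nm]]
    }
    d
  }
  cfg <- merge_section(def, config, "")
  for (chk in .config_checks) {
    v <- cfg[[chk[[1]][1]]][[chk[[1]][2]]]
    if (!chk[[2]](v))
      stop(sprintf("configuration key %s %s (got %s)",
                   paste(chk[[1]], collapse = "."), chk[[3]], format(v)))
  }
  # seed tumor must fit well inside the domain
  if (cfg$tumor$seed_radius_mm >= cfg$grid$domain_mm / 2)
    stop("configuration key tumor.seed_radius_mm must be < half the domain size")
  cfg
}

#' Load a configuration file
#'
#' Reads a YAML configuration, applies defaults and validates. An empty
#' file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @param overrides Optional nested list applied on top of the file.
#' @return Validated configuration list.
#' @export
load_config <- function(path, overrides = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(overrides)) {
    for (sec in names(overrides)) {
      if (is.list(overrides[[sec]]))
        for (k in names(overrides[[sec]])) raw[[sec]][[k]] <- overrides[[sec]][[k]]
      else raw[[sec]] <- overrides[[sec]]
    }
  }
  validate_config(raw)
}

#' Save a configuration file
#'
#' @param config Configuration list (validated before writing).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- validate_config(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
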