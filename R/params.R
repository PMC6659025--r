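#' Trait parameters of a life-history strategy
#'
#' Bundles the metabolic, feeding and mortality coefficients that define one
#' species or strategy. Units follow the g / year / degree-Celsius convention
#' used throughout the package: weights in grams, rates per year.
#'
#' @param beta Specific dynamic action (SDA): fraction of ingested food spent
#'   on digestion/assimilation (dimensionless).
#' @param phi_e Fraction of food lost to egestion and excretion
#'   (dimensionless). `beta + phi_e` must be below 1.
#' @param k Coefficient of standard metabolism (g^(1-n) y^-1).
#' @param k_a Coefficient of active metabolism (g y^-1 at full activity);
#'   active costs scale isometrically with weight.
#' @param n Weight exponent of standard metabolism.
#' @param gamma_theta Encountered-food coefficient: clearance-rate coefficient
#'   times resource availability (g^(1-p) y^-1).
#' @param p Weight exponent of the clearance rate.
#' @param h Coefficient of the maximum consumption rate (g^(1-q) y^-1).
#' @param q Weight exponent of maximum consumption.
#' @param rho Baseline mortality coefficient: mortality at w = 1 g with zero
#'   activity (y^-1).
#' @param mu Activity-related mortality coefficient (y^-1).
#'
#' @return A named list of class `trait_params`.
#' @seealso [fish_preset()] for the two built-in trait scenarios.
#' @export
trait_params <- function(beta = 0.15, phi_e = 0.25, k = 1, k_a = 4, n = 0.88,
                         gamma_theta = 60, p = 0.8, h = 30, q = 0.8,
                         rho = 0.1, mu = 6) {
  x <- list(beta = beta, phi_e = phi_e, k = k, k_a = k_a, n = n,
            gamma_theta = gamma_theta, p = p, h = h, q = q,
            rho = rho, mu = mu)
  validate_trait_params(x)
  structure(x, class = c("trait_params", "fin_params_block"))
}

#' Thermal and oxygen parameters
#'
#' Temperature scaling of metabolic rates (Arrhenius), the shape of the
#' maximum oxygen supply (MOS) curve, ambient dissolved oxygen, and the
#' oxygen cost of metabolism.
#'
#' @param E_a Activation energy of the Arrhenius scaling (eV).
#' @param T0 Reference temperature at which the Arrhenius factor equals 1
#'   (degrees C).
#' @param T_max Lethal temperature: oxygen supply is zero here and the model
#'   is undefined above it (degrees C).
#' @param T_opt Temperature at which oxygen supply is maximal (degrees C);
#'   must lie below `T_max`. Setting it close to `T_max` emulates a MOS that
#'   rises right up to the lethal temperature.
#' @param eta Doming exponent of the MOS curve: large values give a
#'   pronounced dome, values near zero a nearly monotone rise.
#' @param zeta Level of oxygen supply at `T_opt` (g y^-1, per unit w^n).
#' @param omega Oxygen cost per unit of mass metabolized (g O2 per g). Only
#'   the ratio `zeta / omega` is identifiable (the sign of the aerobic scope
#'   depends on it alone); the default 0.01 is calibrated so that,
#'   with the preset `zeta` values, aerobic scope constrains activity of a
#'   10 g fish only at the extremes of the 5-26 degree range under a
#'   dome-shaped MOS, and never below the lethal temperature without doming
#'   (see the methods vignette).
#' @param C_crit Ambient O2 concentration at which oxygen supply ceases
#'   (mg L^-1).
#' @param C_50 Ambient O2 concentration at which supply has dropped to half
#'   of its saturation level (mg L^-1).
#' @param l Ambient dissolved O2 at 5 degrees C (mg L^-1); the default
#'   approximates seawater saturation at 5 C, 35 PSU.
#' @param o2_decay Exponential decline coefficient of dissolved O2 with
#'   temperature (per degree C).
#'
#' @return A named list of class `thermal_params`.
#' @export
thermal_params <- function(E_a = 0.52, T0 = 15, T_max = 26, T_opt = 20,
                           eta = 3, zeta = 0.5, omega = 0.01,
                           C_crit = 2, C_50 = 4, l = 10, o2_decay = 0.01851) {
  x <- list(E_a = E_a, T0 = T0, T_max = T_max, T_opt = T_opt, eta = eta,
            zeta = zeta, omega = omega, C_crit = C_crit, C_50 = C_50,
            l = l, o2_decay = o2_decay)
  validate_thermal_params(x)
  structure(x, class = c("thermal_params", "fin_params_block"))
}

#' Maturation reaction norm parameters
#'
#' The schedule shifting surplus energy from somatic growth to reproduction:
#' a logistic function of weight (and optionally age) with midpoint `w_star`.
#'
#' @param w_star Reaction-norm intercept: weight at 50% allocation to
#'   reproduction (g). `NA` means "not yet calibrated"; [calibrate_wstar()]
#'   fills it by maximizing lifetime reproductive output at the reference
#'   temperature.
#' @param c_mrn Steepness of the logistic allocation function (g^-1).
#' @param slope Reaction-norm slope in the age-size plane (g per year); 0
#'   gives the flat reaction norm used throughout the standard scenarios.
#' @return A named list of class `mrn_params`.
#' @export
mrn_params <- function(w_star = NA_real_, c_mrn = 0.5, slope = 0) {
  x <- list(w_star = w_star, c_mrn = c_mrn, slope = slope)
  validate_mrn_params(x)
  structure(x, class = c("mrn_params", "fin_params_block"))
}

#' Simulation settings
#'
#' Grids, integration horizon and numerical tolerances. The model itself is
#' deterministic; `random_seed` is reserved for reproducibility bookkeeping.
#'
#' @param T_grid Temperatures at which sweeps are evaluated (degrees C).
#' @param food_multipliers Multipliers applied to `gamma_theta` in sweeps;
#'   the standard scenarios use 2/3, 1 and 4/3 (encountered food 40/60/80).
#' @param w0 Initial weight for growth integration (g).
#' @param t_horizon Integration horizon (years).
#' @param condition_factor Length-weight coefficient in w = a L^3
#'   (g cm^-3); 0.01 maps 10 g to 10 cm.
#' @param w_floor Lower bound on weight during integration (g): starving fish
#'   may shrink but not below this floor.
#' @param tau_grid_n Number of grid points for the activity optimizer.
#' @param cache_n Number of log-spaced weight points for the activity cache
#'   used inside the growth ODE.
#' @param ode_rtol Relative tolerance of the growth integrator.
#' @param wstar_tol Relative tolerance of the reaction-norm calibration.
#' @param random_seed Reserved; the pipeline is deterministic.
#' @return A named list of class `sim_settings`.
#' @export
sim_settings <- function(T_grid = seq(5, 26, by = 0.25),
                         food_multipliers = c(2 / 3, 1, 4 / 3),
                         w0 = 0.1, t_horizon = 100, condition_factor = 0.01,
                         w_floor = 0.01, tau_grid_n = 2001, cache_n = 2001,
                         ode_rtol = 1e-8, wstar_tol = 1e-3,
                         random_seed = NA_integer_) {
  x <- list(T_grid = T_grid, food_multipliers = food_multipliers, w0 = w0,
            t_horizon = t_horizon, condition_factor = condition_factor,
            w_floor = w_floor, tau_grid_n = tau_grid_n, cache_n = cache_n,
            ode_rtol = ode_rtol, wstar_tol = wstar_tol,
            random_seed = random_seed)
  validate_sim_settings(x)
  structure(x, class = c("sim_settings", "fin_params_block"))
}

fail_field <- function(field, msg) {
  stop("invalid parameter `", field, "`: ", msg, call. = FALSE)
}

check_num <- function(x, field, positive = FALSE, lower = -Inf, upper = Inf,
                      allow_na = FALSE) {
  if (length(x) != 1) fail_field(field, "must be a single number")
  if (is.na(x)) {
    if (allow_na) return(invisible(TRUE))
    fail_field(field, "must not be NA")
  }
  if (!is.numeric(x)) fail_field(field, "must be a single number")
  if (positive && x <= 0) fail_field(field, "must be > 0")
  if (x < lower) fail_field(field, paste("must be >=", lower))
  if (x > upper) fail_field(field, paste("must be <=", upper))
  invisible(TRUE)
}

validate_trait_params <- function(x) {
  check_num(x$beta, "beta", lower = 0)
  check_num(x$phi_e, "phi_e", lower = 0)
  if (x$beta + x$phi_e >= 1) {
    fail_field("beta", "beta + phi_e must be < 1 (assimilated fraction must be positive)")
  }
  for (f in c("k", "k_a", "gamma_theta", "h", "rho", "mu")) {
    check_num(x[[f]], f, positive = TRUE)
  }
  for (f in c("n", "p", "q")) {
    check_num(x[[f]], f, positive = TRUE, upper = 1)
  }
  invisible(x)
}

validate_thermal_params <- function(x) {
  for (f in c("eta", "zeta", "omega", "l")) check_num(x[[f]], f, positive = TRUE)
  for (f in c("E_a", "T0", "T_max", "T_opt", "C_crit", "C_50", "o2_decay")) {
    check_num(x[[f]], f)
  }
  if (x$T_opt >= x$T_max) fail_field("T_opt", "must be below T_max")
  if (x$C_crit >= x$C_50) fail_field("C_crit", "must be below C_50")
  invisible(x)
}

validate_mrn_params <- function(x) {
  check_num(x$w_star, "w_star", positive = TRUE, allow_na = TRUE)
  check_num(x$c_mrn, "c_mrn", positive = TRUE)
  check_num(x$slope, "slope")
  invisible(x)
}

validate_sim_settings <- function(x) {
  if (!is.numeric(x$T_grid) || length(x$T_grid) < 1) {
    fail_field("T_grid", "must be a numeric vector")
  }
  if (!is.numeric(x$food_multipliers) || any(x$food_multipliers <= 0)) {
    fail_field("food_multipliers", "must be positive numbers")
  }
  check_num(x$w0, "w0", positive = TRUE)
  check_num(x$t_horizon, "t_horizon", positive = TRUE)
  check_num(x$condition_factor, "condition_factor", positive = TRUE)
  check_num(x$w_floor, "w_floor", positive = TRUE)
  check_num(x$tau_grid_n, "tau_grid_n", lower = 11)
  check_num(x$cache_n, "cache_n", lower = 11)
  check_num(x$ode_rtol, "ode_rtol", positive = TRUE)
  check_num(x$wstar_tol, "wstar_tol", positive = TRUE)
  check_num(x$random_seed, "random_seed", allow_na = TRUE)
  invisible(x)
}

new_fish_params <- function(traits, thermal, mrn, sim,
                            strategy = NA_character_,
                            mos_regime = NA_character_,
                            preset = NA_character_) {
  structure(
    list(traits = traits, thermal = thermal, mrn = mrn, sim = sim,
         strategy = strategy, mos_regime = mos_regime, preset = preset),
    class = "fish_params"
  )
}

#' Validate a full parameter bundle
#'
#' Runs every block invariant and returns the bundle invisibly; raises an
#' error naming the offending field otherwise.
#'
#' @param params A `fish_params` bundle.
#' @return `params`, invisibly.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "fish_params"))
  validate_trait_params(params$traits)
  validate_thermal_params(params$thermal)
  validate_mrn_params(params$mrn)
  validate_sim_settings(params$sim)
  invisible(params)
}

.preset_names <- c("slow_dome", "slow_nodome", "fast_dome", "fast_nodome")

#' Published parameter presets
#'
#' The two trait scenarios (slow and fast strategy) crossed with the two
#' oxygen-supply regimes (dome-shaped MOS peaking at 20 C, or a MOS rising
#' almost to the lethal temperature). `w_star` is left uncalibrated (see
#' [calibrate_wstar()]); `omega` and `l` are package defaults documented in
#' [thermal_params()].
#'
#' @param name One of `"slow_dome"`, `"slow_nodome"`, `"fast_dome"`,
#'   `"fast_nodome"`.
#' @return A `fish_params` bundle.
#' @examples
#' p <- fish_preset("slow_dome")
#' p$traits$k
#' @export
fish_preset <- function(name) {
  if (!(is.character(name) && length(name) == 1 && name %in% .preset_names)) {
    stop("unknown preset `", paste(name, collapse = ","),
         "`; available: ", paste(.preset_names, collapse = ", "),
         call. = FALSE)
  }
  strategy <- sub("_.*", "", name)
  mos <- sub(".*_", "", name)
  traits <- if (strategy == "slow") {
    trait_params(k = 1, k_a = 4, n = 0.88, h = 30, rho = 0.1, mu = 6)
  } else {
    trait_params(k = 1.5, k_a = 2, n = 0.75, h = 60, rho = 1, mu = 1)
  }
  zeta <- if (strategy == "slow") 0.5 else 1
  thermal <- if (mos == "dome") {
    thermal_params(eta = 3, T_opt = 20, zeta = zeta)
  } else {
    thermal_params(eta = 0.1, T_opt = 25, zeta = zeta)
  }
  new_fish_params(traits, thermal, mrn_params(), sim_settings(),
                  strategy = strategy, mos_regime = mos, preset = name)
}

#' @export
print.fish_params <- function(x, ...) {
  cat("<fish_params>",
      if (!is.na(x$preset)) paste0("preset: ", x$preset) else "custom", "\n")
  cat("  strategy:", x$strategy, " MOS regime:", x$mos_regime, "\n")
  fmt <- function(b) paste(names(b), unlist(lapply(b, format, digits = 4)),
                           sep = "=", collapse = ", ")
  cat("  traits: ", fmt(x$traits), "\n", sep = "")
  cat("  thermal:", fmt(x$thermal), "\n", sep = " ")
  cat("  mrn:    ", fmt(x$mrn), "\n", sep = "")
  cat("  sim:     w0=", x$sim$w0, " g, horizon=", x$sim$t_horizon,
      " y, T grid ", min(x$sim$T_grid), "-", max(x$sim$T_grid), " C\n",
      sep = "")
  invisible(x)
}

.config_sections <- c("traits", "thermal_oxygen", "mrn", "simulation")

#' Read a parameter bundle from a YAML or JSON config file
#'
#' The file may contain a `preset` key naming a base preset (default
#' `"slow_dome"`) plus any of the sections `traits`, `thermal_oxygen`, `mrn`
#' and `simulation` whose fields override the preset. Unknown top-level keys
#' or unknown fields raise an error; the merged bundle is validated before it
#' is returned.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `fish_params` bundle.
#' @seealso [write_config()] for the inverse.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), c("preset", .config_sections))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  preset <- cfg$preset %||% "slow_dome"
  params <- fish_preset(preset)
  blocks <- list(traits = "traits", thermal_oxygen = "thermal",
                 mrn = "mrn", simulation = "sim")
  for (section in names(blocks)) {
    over <- cfg[[section]]
    if (is.null(over)) next
    slot <- blocks[[section]]
    bad <- setdiff(names(over), names(params[[slot]]))
    if (length(bad) > 0) {
      stop("unknown field(s) in `", section, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (f in names(over)) params[[slot]][[f]] <- over[[f]]
  }
  # normalize typed NAs that YAML/JSON cannot distinguish
  if (is.na(params$mrn$w_star)) params$mrn$w_star <- NA_real_
  if (is.na(params$sim$random_seed)) params$sim$random_seed <- NA_integer_
  validate_params(params)
  params
}

#' Write a parameter bundle to a YAML config file
#'
#' Serializes the full bundle so that [read_config()] reproduces it exactly.
#'
#' @param params A `fish_params` bundle.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_params(params)
  strip <- function(b) lapply(unclass(b), function(v) v)
  cfg <- list(traits = strip(params$traits),
              thermal_oxygen = strip(params$thermal),
              mrn = strip(params$mrn),
              simulation = strip(params$sim))
  if (!is.na(params$preset)) cfg <- c(list(preset = params$preset), cfg)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
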