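## Flat YAML configuration files and named parameter presets.

config_keys <- c("lambda_s", "lambda_d", "lambda_e", "mu",
                 "v_plus", "v_minus", "D", "kappa", "kappa_0",
                 "rho_plus_c", "rho_0_c", "rho_minus_c",
                 "growth_mode", "L")

#' Write a parameter set to a flat YAML file
#'
#' The file holds exactly the keys `lambda_s`, `lambda_d`, `lambda_e`,
#' `mu`, `v_plus`, `v_minus`, `D`, `kappa`, `kappa_0`, `rho_plus_c`,
#' `rho_0_c`, `rho_minus_c`, `growth_mode`, `L`; infinite carrying
#' capacities round-trip as `.inf`.
#'
#' @param params an [rt_params()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "rt_params"))
  r <- params$rates; tr <- params$transport
  ia <- params$interactions; cc <- params$carrying
  vals <- list(lambda_s = r$lambda_s, lambda_d = r$lambda_d,
               lambda_e = r$lambda_e, mu = r$mu,
               v_plus = tr$v_plus, v_minus = tr$v_minus, D = tr$D,
               kappa = ia$kappa, kappa_0 = ia$kappa_0,
               rho_plus_c = cc$rho_plus_c, rho_0_c = cc$rho_0_c,
               rho_minus_c = cc$rho_minus_c,
               growth_mode = params$growth_mode, L = params$L)
  fmt <- function(x) {
    if (is.character(x)) return(x)
    if (!is.finite(x)) return(".inf")
    # full double precision so that parameter files round-trip losslessly
    s <- formatC(x, digits = 17, format = "g")
    gsub(" ", "", s)
  }
  writeLines(paste0(names(vals), ": ", vapply(vals, fmt, character(1))),
             path)
  invisible(path)
}

#' Read and validate a parameter set from a flat YAML file
#'
#' Missing, unknown or ill-typed keys raise an error naming the offending
#' keys; numeric values are validated by the parameter constructors (so a
#' negative rate is reported by key name).
#'
#' @param path file path.
#' @return An [rt_params()] object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop_param("config file '", path, "' does not exist")
  vals <- yaml::read_yaml(path)
  missing <- setdiff(config_keys, names(vals))
  extra <- setdiff(names(vals), config_keys)
  if (length(missing))
    stop_param("config is missing key(s): ", paste(missing, collapse = ", "))
  if (length(extra))
    stop_param("config has unknown key(s): ", paste(extra, collapse = ", "))
  num_keys <- setdiff(config_keys, "growth_mode")
  bad <- num_keys[!vapply(vals[num_keys], is.numeric, logical(1))]
  if (length(bad))
    stop_param("config key(s) not numeric: ", paste(bad, collapse = ", "))
  if (!is.character(vals$growth_mode) ||
      !vals$growth_mode %in% c("linear", "logistic"))
    stop_param("config key 'growth_mode' must be \"linear\" or \"logistic\"")
  for (k in c("lambda_s", "lambda_d", "lambda_e", "mu", "v_plus", "v_minus",
              "D", "kappa", "kappa_0")) {
    if (vals[[k]] < 0) stop_param("config key '", k, "' is negative")
  }
  rt_params(
    rates = kinetic_rates(vals$lambda_s, vals$lambda_d, vals$lambda_e,
                          vals$mu),
    transport = transport(vals$v_plus, vals$v_minus, vals$D),
    interactions = interactions(vals$kappa, vals$kappa_0),
    carrying = carrying_capacity(vals$rho_plus_c, vals$rho_0_c,
                                 vals$rho_minus_c),
    growth_mode = vals$growth_mode,
    L = vals$L
  )
}

preset_registry <- function() {
  base_rates_01 <- kinetic_rates(0.1, 0.1, 1, 0.1)
  pattern_int <- interactions(kappa = 0.2, kappa_0 = 0.05)
  list(
    # Caulobacter crescentus, experimentally motivated rates and speeds
    # (SI values nondimensionalized with lambda_e and a 4.5 mm box, chosen
    # so the dimensionless diffusivity is ~1e-3 as in the pattern presets)
    cc_table1 = list(
      params = params_from_si(lambda_s = 1e-5, lambda_d = 1e-4,
                              lambda_e = 1e-1, mu = 1e-6,
                              v_plus = 4e-5, v_minus = 3.5e-5, D = 2e-9,
                              L = 4.5e-3,
                              kappa = 10, kappa_0 = 10,
                              carrying = carrying_capacity(0.04, 0.04, 0.04),
                              growth_mode = "logistic"),
      si = list(lambda_s = 1e-5, lambda_d = 1e-4, lambda_e = 1e-1,
                mu = 1e-6, v_plus = 4e-5, v_minus = 3.5e-5, D = 2e-9,
                L = 4.5e-3),
      description = "Caulobacter crescentus rates/speeds, logistic growth"),
    fig3_linear = list(
      params = rt_params(kinetic_rates(2.848, 1, 1, 2.848),
                         transport(0, 0, 0)),
      init = density_triple(0, 0.1, 0.479),
      description = "balanced linear well-mixed relaxation"),
    fig3_nonlinear = list(
      params = rt_params(kinetic_rates(3, 1, 1, 1), transport(0, 0, 0),
                         carrying = carrying_capacity(1, 1, 1),
                         growth_mode = "logistic"),
      init = density_triple(0, 0.1, 0.479),
      description = "logistic well-mixed growth, lambda_s = 3 mu"),
    fig4 = list(
      params = rt_params(kinetic_rates(1, 1, 1, 1), transport(1, 0.9, 0.2)),
      description = "free-cell moments, unequal speeds (v- = 0.9 v+)"),
    fig4_equal = list(
      params = rt_params(kinetic_rates(1, 1, 1, 1), transport(1, 1, 0.2)),
      description = "free-cell moments, equal speeds"),
    fig7 = list(
      params = rt_params(kinetic_rates(1, 1, 1, 1), transport(1, 1, 2),
                         interactions = interactions(kappa = 1, kappa_0 = 0)),
      R0 = 6,   # rho_hat_+ = 1, rho_hat_0 = 2: marginal at D = 2 v+^2
      description = "attraction-only dispersion relation, marginal D"),
    fig8 = list(
      params = rt_params(base_rates_01, transport(0.1, 0.1, 0.001),
                         interactions = pattern_int),
      R0 = 1,
      description = "linear-stability separatrix scan (speeds overridden)"),
    fig9 = list(
      params = rt_params(base_rates_01, transport(0.1, 0.05, 0.001),
                         interactions = pattern_int),
      R0 = 1,
      description = "traveling-wave regime, v+ = 2 v- = 0.1 L lambda_e"),
    fig10 = list(
      params = rt_params(base_rates_01, transport(0.1, 0.1, 0.001),
                         interactions = pattern_int),
      R0 = 1,
      description = "numerical state-diagram scan (speeds overridden)"),
    fig11 = list(
      params = rt_params(kinetic_rates(1e-4, 1e-3, 1, 1e-5),
                         transport(4e-5 / 4.5e-4, 3.5e-5 / 4.5e-4,
                                   2e-9 / (4.5e-3^2 * 0.1)),
                         interactions = interactions(10, 10),
                         carrying = carrying_capacity(0.04, 0.04, 0.04),
                         growth_mode = "logistic"),
      description = "Caulobacter wave formation with logistic growth")
  )
}

#' Named parameter presets
#'
#' Returns one of the shipped parameter presets by name (see
#' [preset_names()]), as a list with the `params` object plus, where
#' relevant, the background normalization `R0`, a well-mixed initial
#' condition `init`, the SI source values `si`, a precomputed homogeneous
#' state `hs` and a short `description`.
#'
#' @param name preset name.
#' @return A list as described.
#' @examples
#' rt_preset("fig4")$params
#' @export
rt_preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop_param("unknown preset '", name, "'; available: ",
               paste(names(reg), collapse = ", "))
  pre <- reg[[name]]
  pre$name <- name
  if (!is.null(pre$R0) &&
      abs(pre$params$rates$lambda_s - pre$params$rates$mu) <
        1e-9 * pre$params$rates$lambda_e)
    pre$hs <- homogeneous_state_from_R(pre$params$rates, pre$R0)
  pre
}

#' @rdname rt_preset
#' @export
preset_names <- function() names(preset_registry())
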