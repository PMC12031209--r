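#' Construct a metal-oxide sensor response model
#'
#' A phenomenological model of a cross-sensitive SnO2 (MOS) sensor. The sensor
#' reports the response ratio \eqn{s = R_0 / R} (baseline resistance over
#' in-gas resistance), which is 1 in clean air and rises above 1 for reducing
#' gases. Steady-state sensitivity per gas follows a power law
#' \eqn{s_\infty = 1 + \sum_g a_g C_g^{b_g}} and the transient response is a
#' first-order relaxation whose rate increases with concentration (higher
#' analyte pressure drives faster surface coverage).
#'
#' @param sensor_id Text label for the sensor.
#' @param r0 Baseline resistance in ohms (> 0). Only used when exporting raw
#'   resistance; the pipeline operates on response ratios.
#' @param a_eth,a_prop Dimensionless sensitivity coefficients (>= 0) for
#'   ethanol and n-propanol.
#' @param b_eth,b_prop Power-law exponents in (0, 1.5].
#' @param tau_eth,tau_prop Response time constants (seconds > 0) toward the
#'   steady state for each gas at vanishing concentration.
#' @param tau_off Recovery time constant (seconds > 0) in clean air.
#' @param kappa Rate-concentration coupling (>= 0): the effective exposure
#'   rate is \code{(1/tau_g) * (1 + kappa * C_g / 100)}.
#' @param noise_sd Relative (multiplicative) Gaussian noise standard deviation
#'   as a fraction of the signal (>= 0).
#' @param noise_corr Lag-1 autocorrelation of the noise process in [0, 1).
#'   MOS sensor noise at 2 Hz sampling is dominated by slow (1/f-like)
#'   fluctuations of the heater and surface state, not by sample-to-sample
#'   jitter; the default 0.99 gives a wander time scale of roughly a minute
#'   while keeping the stationary sd at \code{noise_sd}.
#' @return An object of class \code{sensor_model}.
#' @export
sensor_model <- function(sensor_id, r0 = 10000,
                         a_eth, b_eth, a_prop, b_prop,
                         tau_eth, tau_prop, tau_off,
                         kappa = 1, noise_sd = 0.01, noise_corr = 0.99) {
  if (r0 <= 0) stopf("r0 must be > 0")
  if (a_eth < 0 || a_prop < 0) stopf("sensitivities must be >= 0")
  if (b_eth <= 0 || b_eth > 1.5 || b_prop <= 0 || b_prop > 1.5)
    stopf("exponents must lie in (0, 1.5]")
  if (tau_eth <= 0 || tau_prop <= 0 || tau_off <= 0)
    stopf("time constants must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (noise_corr < 0 || noise_corr >= 1) stopf("noise_corr must be in [0, 1)")
  structure(list(
    sensor_id = sensor_id, r0 = r0,
    a_eth = a_eth, b_eth = b_eth, a_prop = a_prop, b_prop = b_prop,
    tau_eth = tau_eth, tau_prop = tau_prop, tau_off = tau_off,
    kappa = kappa, noise_sd = noise_sd, noise_corr = noise_corr
  ), class = "sensor_model")
}

#' Default 8-sensor cross-sensitive array
#'
#' Mimics an MQ-series array: every sensor responds to both gases but with
#' distinct sensitivities, exponents and time constants, so that channels
#' disagree and carry complementary information.
#'
#' @param noise_sd Relative noise applied to every sensor (default 1\%).
#' @return List of 8 \code{sensor_model} objects.
#' @export
default_sensor_bank <- function(noise_sd = 0.01) {
  spec <- list(
    #         a_e   b_e   a_p   b_p  t_e t_p t_off kappa
    s1 = c(0.08, 0.75, 0.15, 0.70, 25, 32, 60, 1.2),
    s2 = c(0.30, 0.80, 0.10, 0.65, 18, 26, 45, 0.8),
    s3 = c(0.05, 0.90, 0.06, 0.85, 35, 22, 70, 1.6),
    s4 = c(0.12, 0.65, 0.20, 0.75, 22, 40, 55, 1.0),
    s5 = c(0.20, 0.70, 0.25, 0.60, 30, 18, 65, 0.6),
    s6 = c(0.06, 0.85, 0.04, 0.95, 40, 28, 70, 1.4),
    s7 = c(0.15, 0.60, 0.08, 0.80, 15, 36, 40, 1.8),
    s8 = c(0.10, 0.78, 0.18, 0.68, 28, 20, 62, 1.0)
  )
  lapply(names(spec), function(id) {
    p <- spec[[id]]
    sensor_model(id, a_eth = p[1], b_eth = p[2], a_prop = p[3], b_prop = p[4],
                 tau_eth = p[5], tau_prop = p[6], tau_off = p[7],
                 kappa = p[8], noise_sd = noise_sd)
  })
}

#' Steady-state response ratio of a sensor to a gas pair
#'
#' \eqn{s_\infty = 1 + a_e C_e^{b_e} + a_p C_p^{b_p}}: exactly 1 in clean air,
#' non-decreasing in each concentration.
#'
#' @param model A \code{sensor_model}.
#' @param conc Length-2 numeric \code{c(ethanol_ppm, propanol_ppm)}, both >= 0.
#' @return Steady-state response ratio (>= 1).
#' @export
steady_state_response <- function(model, conc) {
  stopifnot(inherits(model, "sensor_model"), length(conc) == 2)
  if (any(conc < 0)) stopf("concentrations must be >= 0")
  1 + model$a_eth * conc[1]^model$b_eth + model$a_prop * conc[2]^model$b_prop
}

#' Convert raw resistance to response ratio
#'
#' @param resistance Numeric vector of in-gas resistances R (> 0).
#' @param r0 Baseline (clean-air) resistance.
#' @return Response ratios \eqn{s = R_0 / R}.
#' @export
resistance_to_response <- function(resistance, r0) {
  if (any(resistance <= 0) || r0 <= 0) stopf("resistances must be > 0")
  r0 / resistance
}
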