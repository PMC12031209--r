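#' Define an exposure scheme
#'
#' One scheme is a sequence of exposure/recovery cycles, each delivering a
#' fixed (ethanol, propanol) concentration pair for \code{exposure_s} seconds
#' followed by \code{recovery_s} seconds of clean air, sampled uniformly.
#'
#' @param scheme_id Identifier, conventionally \code{"G1"}..\code{"G7"}.
#' @param pairs Data frame with numeric columns \code{ethanol} and
#'   \code{propanol} (ppm, each in [0, 100]), one row per cycle in order.
#' @param exposure_s,recovery_s Phase durations in seconds.
#' @param sample_rate_hz Sampling frequency.
#' @return An \code{exposure_scheme} object.
#' @export
exposure_scheme <- function(scheme_id, pairs,
                            exposure_s = 300, recovery_s = 300,
                            sample_rate_hz = 2) {
  stopifnot(is.data.frame(pairs), all(c("ethanol", "propanol") %in% names(pairs)))
  if (nrow(pairs) == 0) stopf("scheme '%s': empty concentration list", scheme_id)
  if (any(pairs$ethanol < 0 | pairs$ethanol > 100 |
          pairs$propanol < 0 | pairs$propanol > 100))
    stopf("scheme '%s': concentrations must lie in [0, 100] ppm", scheme_id)
  structure(list(
    scheme_id = scheme_id, pairs = pairs,
    exposure_s = exposure_s, recovery_s = recovery_s,
    sample_rate_hz = sample_rate_hz
  ), class = "exposure_scheme")
}

#' Default seven-scheme test layout
#'
#' G1 steps pure ethanol and G2 pure n-propanol from 0 to 100 ppm in 20 ppm
#' increments; G3--G7 are binary mixtures that hold one gas fixed while the
#' other steps. The 0 ppm step of each test is a clean-air blank cycle (the
#' origin of the scheme's line in the concentration grid): it conditions the
#' array, produces no response peak, and gives the first true response enough
#' left margin for segmentation. Every test therefore yields five gas
#' responses, 7 x 5 x 5 repeats = 175 in the default campaign.
#'
#' @param sample_rate_hz Sampling frequency (default 2 Hz).
#' @return Named list of 7 \code{exposure_scheme} objects.
#' @export
default_schemes <- function(sample_rate_hz = 2) {
  steps <- seq(20, 100, by = 20)
  blank <- data.frame(ethanol = 0, propanol = 0)
  eth_steps <- function(fixed_prop)
    rbind(blank, data.frame(ethanol = steps, propanol = fixed_prop))
  prop_steps <- function(fixed_eth)
    rbind(blank, data.frame(ethanol = fixed_eth, propanol = steps))
  defs <- list(
    G1 = eth_steps(0),     # pure ethanol
    G2 = prop_steps(0),    # pure n-propanol
    G3 = eth_steps(20),    # ethanol steps, propanol fixed
    G4 = eth_steps(60),
    G5 = eth_steps(100),
    G6 = prop_steps(40),   # propanol steps, ethanol fixed
    G7 = prop_steps(80)
  )
  out <- lapply(names(defs), function(id)
    exposure_scheme(id, defs[[id]], sample_rate_hz = sample_rate_hz))
  names(out) <- names(defs)
  out
}

#' Class label for a concentration pair
#'
#' Labels follow actual composition: \code{"01"} single n-propanol,
#' \code{"10"} single ethanol, \code{"11"} mixture; a pair with both gases at
#' zero is a blank (\code{NA}, not a gas response).
#'
#' @param ethanol,propanol Concentrations in ppm.
#' @return Character label or \code{NA} for a blank.
#' @export
label_for_pair <- function(ethanol, propanol) {
  ifelse(ethanol == 0 & propanol == 0, NA_character_,
    ifelse(ethanol > 0 & propanol > 0, "11",
      ifelse(ethanol > 0, "10", "01")))
}

#' Class levels used throughout the package
#' @return Character vector \code{c("01", "10", "11")}.
#' @export
class_levels <- function() c("01", "10", "11")
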