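#' Ventilator settings
#'
#' Volume-controlled ventilation settings of the ex-vivo preparation:
#' tidal volume 6 mL/kg, breathing frequency 12 breaths/min and a constant
#' (square-wave) inspiratory flow of 45 L/min, at a given PEEP.
#'
#' @param peep Positive end-expiratory pressure, cmH2O (>= 0).
#' @param tidal_volume_per_kg Tidal volume per body mass, mL/kg.
#' @param body_mass Body mass, kg.
#' @param breathing_frequency Breaths per minute.
#' @param inspiratory_flow Constant inspiratory flow, L/min.
#' @return A list of class `"ventilator_settings"`.
#' @export
ventilator_settings <- function(peep,
                                tidal_volume_per_kg = 6,
                                body_mass = 40,
                                breathing_frequency = 12,
                                inspiratory_flow = 45) {
  vals <- c(tidal_volume_per_kg = tidal_volume_per_kg, body_mass = body_mass,
            breathing_frequency = breathing_frequency,
            inspiratory_flow = inspiratory_flow)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("ventilator settings must all be positive numbers.")
  }
  if (!is.finite(peep) || peep < 0) abort("`peep` must be >= 0 cmH2O.")
  s <- structure(
    list(peep = peep,
         tidal_volume_per_kg = tidal_volume_per_kg,
         body_mass = body_mass,
         breathing_frequency = breathing_frequency,
         inspiratory_flow = inspiratory_flow),
    class = "ventilator_settings"
  )
  te <- derive_expiratory_time(s)   # errors if the cycle is infeasible
  stopifnot(te > 0)
  s
}

#' Tidal volume in litres
#' @param settings A [ventilator_settings()] object.
#' @return Tidal volume, L.
#' @export
tidal_volume <- function(settings) {
  settings$tidal_volume_per_kg * settings$body_mass / 1000
}

#' Expiratory (deflation) time of the ventilatory cycle
#'
#' With a square inspiratory flow waveform, inspiration lasts
#' `VT / inspiratory_flow`; the remainder of the cycle,
#' `60/fb - VT/inspiratory_flow`, is the passive deflation window used as
#' the "time of deflation" when converting exhaled volume to mean
#' expiratory flow.
#'
#' @param settings A [ventilator_settings()] object.
#' @return Expiratory time in seconds.
#' @export
#' @examples
#' derive_expiratory_time(ventilator_settings(peep = 5)) # 4.68 s
derive_expiratory_time <- function(settings) {
  vt <- tidal_volume(settings)                       # L
  t_insp <- vt / (settings$inspiratory_flow / 60)    # s
  te <- 60 / settings$breathing_frequency - t_insp
  if (te <= 0) {
    abort("configuration error: tidal volume cannot be delivered within the cycle (expiratory time <= 0).")
  }
  te
}
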