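#' The porcine lobe set
#'
#' The seven lobes of the pig lung used throughout the package: right
#' anterior (RAL), right caudal (RCL), right diaphragmatic (RDL), right
#' internal (RIL), left diaphragmatic (LDL), left caudal (LCL) and left
#' anterior (LAL).  All region labels in airway trees and volume tables are
#' either one of these codes or `"central"`.  The lobe set is configurable
#' in most functions (other species have different lobation); the porcine
#' convention is the default.
#'
#' @return Character vector of the 7 lobe codes.
#' @export
#' @examples
#' porcine_lobes()
porcine_lobes <- function() {
  c("RAL", "RCL", "RDL", "RIL", "LDL", "LCL", "LAL")
}

#' Physical properties of the gas phase
#'
#' Dynamic viscosity enters the laminar (Hagen-Poiseuille) segment
#' resistance; density is carried for completeness but unused by the steady
#' laminar solver (no inertial terms).
#'
#' @param dynamic_viscosity Dynamic viscosity in Pa s.  Default
#'   `1.81e-5`, air at ~20 degrees C.
#' @param density Gas density in kg/m3.  Default 1.20.
#' @return A list of class `"gas_properties"`.
#' @export
gas_properties <- function(dynamic_viscosity = 1.81e-5, density = 1.20) {
  if (!is.numeric(dynamic_viscosity) || length(dynamic_viscosity) != 1 ||
      is.na(dynamic_viscosity) || dynamic_viscosity <= 0) {
    abort("`dynamic_viscosity` must be a single positive number (Pa s).")
  }
  if (!is.numeric(density) || length(density) != 1 || is.na(density) || density <= 0) {
    abort("`density` must be a single positive number (kg/m3).")
  }
  structure(
    list(dynamic_viscosity = dynamic_viscosity, density = density),
    class = "gas_properties"
  )
}

#' @export
print.gas_properties <- function(x, ...) {
  cat("<gas_properties> mu =", x$dynamic_viscosity, "Pa s, rho =",
      x$density, "kg/m3\n")
  invisible(x)
}

check_lobe_codes <- function(lobe, lobes = porcine_lobes(), what = "lobe") {
  bad <- setdiff(unique(lobe), lobes)
  if (length(bad) > 0) {
    abort(paste0("Unknown ", what, " code(s): ", paste(bad, collapse = ", "),
                 ". Expected one of: ", paste(lobes, collapse = ", "), "."))
  }
  invisible(lobe)
}
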