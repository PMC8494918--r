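#' Physical constants and unit helpers
#'
#' The transport model works internally in the unit system in which the
#' membrane permeability literature reports its constants: lengths in um,
#' time in min, pressure in atm, amounts in mol, osmolality in mol um^-3.
#' A molar (mol L^-1) concentration converts to mol um^-3 by the factor
#' 1e-15 (1 L = 1e15 um^3).
#'
#' @name units
NULL

## universal gas constant, um^3 atm mol^-1 K^-1
.R_GAS_UM3_ATM <- 8.205745e13
## universal gas constant, cal mol^-1 K^-1 (Arrhenius scaling)
.R_GAS_CAL <- 1.987204

#' Convert a molar concentration to osmolality in model units
#'
#' @param x concentration in mol L^-1
#' @return osmolality in mol um^-3
#' @examples
#' molPerL(1.5)   # 1.5e-15 mol um^-3
#' @export
molPerL <- function(x) x * 1e-15

#' Convert an osmolality in model units to mol L^-1
#'
#' @param x osmolality in mol um^-3
#' @return concentration in mol L^-1
#' @export
toMolPerL <- function(x) x * 1e15

#' Universal gas constant in model units
#'
#' @param units `"um3_atm"` for um^3 atm mol^-1 K^-1 (osmotic driving force)
#'   or `"cal"` for cal mol^-1 K^-1 (Arrhenius activation energies).
#' @return numeric scalar
#' @export
gasConstant <- function(units = c("um3_atm", "cal")) {
  units <- match.arg(units)
  if (units == "um3_atm") .R_GAS_UM3_ATM else .R_GAS_CAL
}
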