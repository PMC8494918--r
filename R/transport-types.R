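#' Oocyte cell geometry
#'
#' Static geometric and compositional properties of the cell used by the
#' two-parameter transport model: membrane area, isotonic volume, the
#' osmotically inactive ("solids") fraction, and the partial molar volume
#' of the permeating solute.
#'
#' @param A membrane area (um^2)
#' @param V0 isotonic cell volume (um^3)
#' @param Vbf fractional cell solids, dimensionless in (0, 1)
#' @param Vs_bar partial molar volume of the permeating solute (um^3 mol^-1)
#' @param Vb osmotically inactive volume (um^3); defaults to `V0 * Vbf` and
#'   must agree with it to within 0.01 um^3
#' @return an object of class `cellGeometry`
#' @seealso [table1Geometry()] for the packaged equine-oocyte values
#' @export
cellGeometry <- function(A, V0, Vbf, Vs_bar, Vb = V0 * Vbf) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A))
  if (A <= 0) stop("cellGeometry: membrane area A must be > 0")
  if (V0 <= 0) stop("cellGeometry: isotonic volume V0 must be > 0")
  if (Vbf <= 0 || Vbf >= 1) stop("cellGeometry: Vbf must satisfy 0 < Vbf < 1")
  if (Vs_bar <= 0) stop("cellGeometry: partial molar volume Vs_bar must be > 0")
  if (abs(Vb - V0 * Vbf) > 0.01)
    stop("cellGeometry: Vb is inconsistent with V0 * Vbf (|diff| > 0.01 um^3)")
  structure(list(A = A, V0 = V0, Vbf = Vbf, Vb = Vb, Vs_bar = Vs_bar),
            class = "cellGeometry")
}

#' @export
print.cellGeometry <- function(x, ...) {
  cat("<cellGeometry>\n")
  cat(sprintf("  A      = %.2f um^2\n", x$A))
  cat(sprintf("  V0     = %.2f um^3   (Vb = %.2f, Vbf = %.4f)\n", x$V0, x$Vb, x$Vbf))
  cat(sprintf("  Vs_bar = %.4e um^3 mol^-1\n", x$Vs_bar))
  invisible(x)
}

#' Membrane permeability parameter set
#'
#' Hydraulic (`Lp`) and solute (`Ps`) membrane permeabilities with their
#' Arrhenius activation energies and 0 degC reference values. `Lp`/`Ps` are
#' the experimentally fitted values at the measurement temperature `T_meas`;
#' `Lpg`/`Psg` are the reference values at `T0` = 273.15 K used when
#' temperature scaling is requested explicitly (see
#' [arrheniusPermeability()]). The two parameterizations are deliberately
#' kept side by side and are not reconciled against each other.
#'
#' @param Lp hydraulic permeability (um min^-1 atm^-1)
#' @param Ps solute permeability (um min^-1)
#' @param E_Lp activation energy for Lp (cal mol^-1)
#' @param E_Ps activation energy for Ps (cal mol^-1)
#' @param Lpg Lp at the reference temperature T0 (um min^-1 atm^-1)
#' @param Psg Ps at T0 (um min^-1)
#' @param T_meas temperature at which Lp and Ps were measured (K)
#' @param T0 Arrhenius reference temperature (K); must be 273.15
#' @return an object of class `membranePermeability`
#' @export
membranePermeability <- function(Lp, Ps, E_Lp, E_Ps, Lpg, Psg,
                                 T_meas = 295.15, T0 = 273.15) {
  vals <- c(Lp = Lp, Ps = Ps, E_Lp = E_Lp, E_Ps = E_Ps, Lpg = Lpg, Psg = Psg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("membranePermeability: all permeabilities and activation energies must be strictly positive")
  if (!isTRUE(all.equal(T0, 273.15)))
    stop("membranePermeability: the Arrhenius reference temperature T0 must be 273.15 K")
  structure(list(Lp = Lp, Ps = Ps, E_Lp = E_Lp, E_Ps = E_Ps,
                 Lpg = Lpg, Psg = Psg, T_meas = T_meas, T0 = T0),
            class = "membranePermeability")
}

#' @export
print.membranePermeability <- function(x, ...) {
  cat("<membranePermeability>\n")
  cat(sprintf("  Lp  = %.4f um min^-1 atm^-1, Ps = %.4f um min^-1 (at %.2f K)\n",
              x$Lp, x$Ps, x$T_meas))
  cat(sprintf("  Lpg = %.4f, Psg = %.4f (at T0 = %.2f K)\n", x$Lpg, x$Psg, x$T0))
  cat(sprintf("  E_Lp = %.0f, E_Ps = %.0f cal mol^-1\n", x$E_Lp, x$E_Ps))
  invisible(x)
}

#' Bath (extracellular medium) composition
#'
#' The bath is always specified by its explicit osmolality pair: the
#' non-permeating background (`Mn_e`, e.g. saline) and the permeating CPA
#' (`Ms_e`), both in mol um^-3. Use [molPerL()] to convert from mol L^-1.
#'
#' @param Mn_e external non-permeating osmolality (mol um^-3)
#' @param Ms_e external permeating-solute osmolality (mol um^-3)
#' @param T bath temperature (K)
#' @return an object of class `bathComposition` with derived total `Me`
#' @export
bathComposition <- function(Mn_e, Ms_e, T) {
  if (Mn_e < 0 || Ms_e < 0) stop("bathComposition: osmolalities must be >= 0")
  if (T <= 0) stop("bathComposition: temperature must be > 0 K")
  structure(list(Mn_e = Mn_e, Ms_e = Ms_e, Me = Mn_e + Ms_e, T = T),
            class = "bathComposition")
}

#' @export
print.bathComposition <- function(x, ...) {
  cat(sprintf("<bathComposition> Mn_e = %.3f, Ms_e = %.3f mol L^-1 (Me = %.3f), T = %.2f K\n",
              toMolPerL(x$Mn_e), toMolPerL(x$Ms_e), toMolPerL(x$Me), x$T))
  invisible(x)
}

#' Instantaneous cell state
#'
#' @param t time (min)
#' @param Vw intracellular water volume (um^3)
#' @param Vs intracellular permeating-solute volume (um^3)
#' @param geom optional [cellGeometry()]; if supplied, the derived total
#'   volume `Vc = Vw + Vs + Vb` and normalized volume `Vn = Vc / V0` are
#'   attached
#' @return an object of class `cellState`
#' @export
cellState <- function(t, Vw, Vs, geom = NULL) {
  if (Vw <= 0) stop("cellState: water volume Vw must be > 0 (cell fully dehydrated?)")
  if (Vs < 0) stop("cellState: solute volume Vs must be >= 0")
  st <- list(t = t, Vw = Vw, Vs = Vs)
  if (!is.null(geom)) {
    st$Vc <- Vw + Vs + geom$Vb
    st$Vn <- st$Vc / geom$V0
  }
  structure(st, class = "cellState")
}

#' Normalized volume trace
#'
#' A time series of normalized cell volume `Vn = Vc / V0` and intracellular
#' permeating-solute osmolality `Msi`, as produced by [simulateLoading()],
#' [simulateUnloading()] or [generateSyntheticTrace()]. Stored as a
#' data.frame with columns `time` (min), `Vn` (dimensionless) and `Msi`
#' (mol um^-3); extra columns (`Vw`, `Vs`) may be present.
#'
#' @param time ordered times (min)
#' @param Vn normalized volume, > 0
#' @param Msi intracellular permeating-solute osmolality (mol um^-3)
#' @param ... extra aligned columns
#' @return a `volumeTrace` (also a data.frame)
#' @export
volumeTrace <- function(time, Vn, Msi, ...) {
  if (length(time) == 0L) stop("volumeTrace: empty trace")
  if (length(time) != length(Vn) || length(time) != length(Msi))
    stop("volumeTrace: time, Vn and Msi must have equal length")
  if (any(diff(time) <= 0)) stop("volumeTrace: times must be strictly increasing")
  if (any(Vn <= 0)) stop("volumeTrace: Vn must be > 0")
  df <- data.frame(time = time, Vn = Vn, Msi = Msi, ...)
  class(df) <- c("volumeTrace", "data.frame")
  df
}

#' @export
print.volumeTrace <- function(x, ...) {
  cat(sprintf("<volumeTrace> %d samples over [%.3g, %.3g] min; Vn range [%.4f, %.4f]\n",
              nrow(x), x$time[1], x$time[nrow(x)], min(x$Vn), max(x$Vn)))
  invisible(x)
}

#' Osmotic tolerance window
#'
#' Bounds on the normalized volume excursion a cell is assumed to tolerate.
#'
#' @param Vn_min lower bound, in (0, 1)
#' @param Vn_max upper bound, > 1
#' @return an object of class `toleranceWindow`
#' @export
toleranceWindow <- function(Vn_min, Vn_max) {
  if (!(Vn_min > 0 && Vn_min < 1 && Vn_max > 1))
    stop("toleranceWindow: require 0 < Vn_min < 1 < Vn_max")
  structure(list(Vn_min = Vn_min, Vn_max = Vn_max), class = "toleranceWindow")
}
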