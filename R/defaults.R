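#' Packaged equine-oocyte transport parameters
#'
#' Default cell geometry, membrane permeabilities and bath compositions for
#' equine oocytes exposed to ethylene glycol (EG), as used throughout the
#' package examples. The permeabilities were measured at 1.5 mol L^-1 EG at
#' room temperature (22 degC); the activation energies and the 0 degC
#' reference permeabilities come from the literature.
#'
#' Bath compositions are identified by their explicit osmolality pairs
#' (non-permeating background 0.300 mol L^-1 plus the stated EG osmolality),
#' which for the standard EG media are 1.500, 0.700 and 0.450 mol L^-1.
#'
#' @return `table1Geometry()`: a [cellGeometry()];
#'   `table1Permeability()`: a [membranePermeability()];
#'   `table1Bath()`: a [bathComposition()].
#' @name table1
NULL

#' @rdname table1
#' @export
table1Geometry <- function() {
  cellGeometry(A = 34763.12, V0 = 609469.49, Vbf = 0.3123,
               Vs_bar = 5.5919e13, Vb = 190337.32)
}

#' @rdname table1
#' @export
table1Permeability <- function() {
  membranePermeability(Lp = 0.6284, Ps = 20.3660,
                       E_Lp = 11.19e3, E_Ps = 15.81e3,
                       Lpg = 0.1522, Psg = 3.7660,
                       T_meas = 295.15)
}

#' @rdname table1
#' @param cpa_mol_per_L EG osmolality of the medium in mol L^-1; the three
#'   standard media are 1.5, 0.7 and 0.45 (any non-negative value is allowed)
#' @param T bath temperature (K); default room temperature 295.15 K (22 degC)
#' @param Mn_mol_per_L non-permeating background osmolality (mol L^-1)
#' @export
table1Bath <- function(cpa_mol_per_L = 1.5, T = 295.15, Mn_mol_per_L = 0.300) {
  bathComposition(Mn_e = molPerL(Mn_mol_per_L), Ms_e = molPerL(cpa_mol_per_L), T = T)
}

#' Initial (isotonic) intracellular osmolality, mol um^-3
#' @export
table1Mn0i <- function() molPerL(0.300)

#' Packaged FEM material parameters
#'
#' Constitutive parameters of the phenomenological coupled
#' diffusion-elasticity model of the oocyte: Young's modulus and Poisson's
#' ratio of the cell continuum, the effective intracellular CPA diffusivity,
#' and the concentration-dependent eigenstrain law \eqn{\beta(C) = \beta_0
#' \exp(-\bar C / c_0)} with \eqn{\bar C = C / (C_{ref} - C)}.
#'
#' The default diffusivity is the package's own calibration: the literature
#' value is printed with ambiguous units, so the effective diffusivity was
#' fixed (once) at 2.83e-6 mm^2 s^-1, the value at which the coupled model
#' reproduces the characteristic response times of the two-parameter
#' transport model (pressure peak near 15 s, volume minimum near 30 s for
#' 1.5 mol L^-1 EG) while retaining center-to-membrane concentration
#' gradients at 240 s. See the methods vignette. Other diffusivities,
#' including the literal literature value under either time base, can be
#' passed explicitly.
#'
#' @return a [materialModel()]
#' @export
table2Material <- function() {
  materialModel(E = 14.52, nu = 0.49, D = 2.83e-6, beta0 = -0.20,
                c0 = 0.8, Cref = 1.5)
}
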