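#' FEM constitutive parameters
#'
#' Material model of the phenomenological coupled diffusion-elasticity
#' oocyte: isotropic linear elasticity (`E`, `nu`), isotropic Fickian
#' diffusivity `D`, and the concentration-dependent diffusion-expansion
#' coefficient \eqn{\beta(C) = \beta_0 \exp(-\bar C / c_0)} with the
#' dimensionless concentration \eqn{\bar C = C / (C_{ref} - C)}.
#'
#' @param E Young's modulus (kPa)
#' @param nu Poisson's ratio, in (0, 0.5)
#' @param D diffusivity (mm^2 per `D_time_base`)
#' @param beta0 expansion/contraction coefficient at C = 0 (dimensionless;
#'   negative = shrinkage)
#' @param c0 decay constant of the beta law (dimensionless)
#' @param Cref bath (reference) concentration (mol L^-1)
#' @param D_time_base `"s"` or `"min"`: the time unit of `D`; internally
#'   everything runs in seconds
#' @return an object of class `materialModel` with `D_s` (mm^2 s^-1)
#'   attached
#' @seealso [table2Material()] for the packaged defaults
#' @export
materialModel <- function(E, nu, D, beta0, c0, Cref, D_time_base = c("s", "min")) {
  D_time_base <- match.arg(D_time_base)
  if (E <= 0) stop("materialModel: E must be > 0")
  if (nu <= 0 || nu >= 0.5) stop("materialModel: nu must be in (0, 0.5)")
  if (D <= 0) stop("materialModel: D must be > 0")
  if (c0 <= 0) stop("materialModel: c0 must be > 0")
  if (Cref <= 0) stop("materialModel: Cref must be > 0")
  structure(list(E = E, nu = nu, D = D, D_time_base = D_time_base,
                 D_s = if (D_time_base == "s") D else D / 60,
                 beta0 = beta0, c0 = c0, Cref = Cref),
            class = "materialModel")
}

#' @export
print.materialModel <- function(x, ...) {
  cat(sprintf("<materialModel> E = %.3f kPa, nu = %.3f, D = %.3g mm^2 %s^-1\n",
              x$E, x$nu, x$D, x$D_time_base))
  cat(sprintf("  beta0 = %.3f, c0 = %.3f, Cref = %.3f mol L^-1\n",
              x$beta0, x$c0, x$Cref))
  invisible(x)
}

#' Dimensionless concentration
#'
#' \eqn{\bar C = C / (C_{ref} - C)}; diverges as C approaches Cref from
#' below. For `C >= Cref` the value is `Inf`, which downstream users
#' ([expansionCoefficient()]) consume as the continuous limit beta = 0.
#'
#' @param C concentration (mol L^-1), >= 0
#' @param Cref reference concentration (mol L^-1)
#' @return dimensionless concentration (vectorized)
#' @export
dimensionlessConcentration <- function(C, Cref) {
  if (any(C < 0)) stop("dimensionlessConcentration: C must be >= 0")
  ifelse(C >= Cref, Inf, C / (Cref - C))
}

#' Concentration-dependent expansion coefficient
#'
#' \eqn{\beta(C) = \beta_0 \exp(-\bar C / c_0)}, continuously extended by
#' beta = 0 at `C >= Cref` (the limit as the dimensionless concentration
#' diverges). `|beta|` is non-increasing in C.
#'
#' @param C concentration (mol L^-1), >= 0 (vectorized)
#' @param mat a [materialModel()]
#' @return beta values
#' @export
expansionCoefficient <- function(C, mat) {
  Cb <- dimensionlessConcentration(C, mat$Cref)
  out <- mat$beta0 * exp(-Cb / mat$c0)
  out[!is.finite(Cb)] <- 0
  out
}

#' Isotropic diffusion-induced eigenstrain
#'
#' The stress-free strain imposed by the local CPA concentration, analogous
#' to thermal expansion: each normal component equals
#' \eqn{\beta(C) (C - C_{strain,ref})}, shear components are zero. The
#' strain reference is the initial intracellular concentration (0 for
#' loading, Cref for unloading), so the body starts undeformed; the
#' literal bath-referenced form is available via `reference = "bath"`.
#'
#' @param C concentration (mol L^-1), >= 0 (vectorized)
#' @param mat a [materialModel()]
#' @param C_strain_ref strain reference concentration (mol L^-1); 0 for
#'   loading runs, `mat$Cref` for unloading runs
#' @param reference `"initial"` (default) uses `C_strain_ref`; `"bath"`
#'   uses `mat$Cref` regardless
#' @return the scalar normal-strain component per input C (the full Voigt
#'   vector is `c(e, e, e, 0, 0, 0)`)
#' @export
diffusionStrain <- function(C, mat, C_strain_ref = 0,
                            reference = c("initial", "bath")) {
  reference <- match.arg(reference)
  ref <- if (reference == "bath") mat$Cref else C_strain_ref
  expansionCoefficient(C, mat) * (C - ref)
}
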