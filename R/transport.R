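#' Intracellular osmolalities from a cell state
#'
#' The intracellular non-permeating osmolality follows the Boyle-van't Hoff
#' dilution of the initial cytosolic content, `Mn_i = Mn0_i (1 - Vbf) V0 /
#' Vw`; the permeating-solute osmolality is `Ms_i = Vs / (Vs_bar Vw)`; the
#' total is their sum (ideal, dilute mixing).
#'
#' @param state a [cellState()] (or any list with positive `Vw` and `Vs`)
#' @param geom a [cellGeometry()]
#' @param Mn0_i initial intracellular osmolality (mol um^-3); see
#'   [table1Mn0i()]
#' @return named list with `Mi`, `Mn_i`, `Ms_i` (mol um^-3)
#' @export
intracellularOsmolalities <- function(state, geom, Mn0_i = table1Mn0i()) {
  if (state$Vw <= 0)
    stop("intracellularOsmolalities: Vw must be > 0 (cell fully dehydrated)")
  Mn_i <- Mn0_i * (1 - geom$Vbf) * geom$V0 / state$Vw
  Ms_i <- state$Vs / (geom$Vs_bar * state$Vw)
  list(Mi = Mn_i + Ms_i, Mn_i = Mn_i, Ms_i = Ms_i)
}

#' Two-parameter transport fluxes
#'
#' Right-hand side of the two-parameter formalism: water leaves the cell
#' down the total osmotic gradient, the permeating solute crosses the
#' membrane down its own gradient, independently:
#' \deqn{dV_w/dt = -L_p A R T (M^e - M^i)}
#' \deqn{dV_s/dt = P_s A (M_s^e - M_s^i) \bar V_s}
#' with R = 8.205745e13 um^3 atm mol^-1 K^-1. CPA solutions are treated as
#' ideal.
#'
#' @inheritParams intracellularOsmolalities
#' @param perm a [membranePermeability()]; `Lp`/`Ps` are used as-is (no
#'   Arrhenius rescaling -- combine with [arrheniusPermeability()] if the
#'   bath temperature differs from `perm$T_meas`)
#' @param bath a [bathComposition()]
#' @return named list with `dVw_dt` and `dVs_dt` (um^3 min^-1)
#' @export
transportRhs <- function(state, geom, perm, bath, Mn0_i = table1Mn0i()) {
  if (perm$Lp <= 0 || perm$Ps <= 0)
    stop("transportRhs: permeabilities must be positive")
  osm <- intracellularOsmolalities(state, geom, Mn0_i)
  dVw <- -perm$Lp * geom$A * .R_GAS_UM3_ATM * bath$T * (bath$Me - osm$Mi)
  dVs <- perm$Ps * geom$A * (bath$Ms_e - osm$Ms_i) * geom$Vs_bar
  list(dVw_dt = dVw, dVs_dt = dVs)
}

#' Arrhenius temperature scaling of the membrane permeabilities
#'
#' \deqn{L_p(T) = L_{pg} \exp(-(E_{Lp}/R)(1/T - 1/T_0))} and likewise for
#' `Ps`, with R = 1.987204 cal mol^-1 K^-1 and T0 = 273.15 K. Both are
#' strictly increasing in temperature.
#'
#' @param perm a [membranePermeability()]
#' @param T temperature (K), > 0
#' @return named list with `Lp` and `Ps` at temperature `T`
#' @export
arrheniusPermeability <- function(perm, T) {
  if (T <= 0) stop("arrheniusPermeability: T must be > 0 K")
  f <- function(g, E) g * exp(-(E / .R_GAS_CAL) * (1 / T - 1 / perm$T0))
  list(Lp = f(perm$Lpg, perm$E_Lp), Ps = f(perm$Psg, perm$E_Ps))
}

#' Permeability set rescaled to a bath temperature
#'
#' Convenience wrapper: returns a [membranePermeability()] whose `Lp`/`Ps`
#' are the Arrhenius values at `T`.
#'
#' @inheritParams arrheniusPermeability
#' @return a [membranePermeability()]
#' @export
permeabilityAt <- function(perm, T) {
  sc <- arrheniusPermeability(perm, T)
  membranePermeability(Lp = sc$Lp, Ps = sc$Ps, E_Lp = perm$E_Lp,
                       E_Ps = perm$E_Ps, Lpg = perm$Lpg, Psg = perm$Psg,
                       T_meas = T, T0 = perm$T0)
}

## shared integrator core: from an arbitrary initial (Vw, Vs)
.integrateTransport <- function(Vw0, Vs0, geom, perm, bath, Mn0_i,
                                t_end, output_grid, rtol = 1e-9, atol = 1e-9) {
  times <- if (length(output_grid) > 1L) output_grid else
    seq(0, t_end, by = output_grid)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  collapse <- 1e-3 * geom$V0
  rhs <- function(t, x, p) {
    Mn_i <- Mn0_i * (1 - geom$Vbf) * geom$V0 / x[1]
    Ms_i <- x[2] / (geom$Vs_bar * x[1])
    dVw <- -perm$Lp * geom$A * .R_GAS_UM3_ATM * bath$T * (bath$Me - Mn_i - Ms_i)
    dVs <- perm$Ps * geom$A * (bath$Ms_e - Ms_i) * geom$Vs_bar
    list(c(dVw, dVs))
  }
  rootfun <- function(t, x, p) x[1] - collapse
  out <- try(deSolve::lsodar(c(Vw = Vw0, Vs = Vs0), times, rhs, parms = NULL,
                             rtol = rtol, atol = atol, rootfunc = rootfun),
             silent = TRUE)
  if (inherits(out, "try-error"))
    stop("transport integration failed: ", attr(out, "condition")$message)
  troot <- attr(out, "troot")
  if ((!is.null(troot) && length(troot) > 0) || nrow(out) < length(times))
    stop("osmotic collapse: intracellular water volume fell below 1e-3 * V0 at t = ",
         signif(out[nrow(out), 1], 4), " min")
  Vw <- out[, "Vw"]; Vs <- out[, "Vs"]
  volumeTrace(time = out[, 1],
              Vn = (Vw + Vs + geom$Vb) / geom$V0,
              Msi = Vs / (geom$Vs_bar * Vw),
              Vw = Vw, Vs = Vs)
}

#' Simulate CPA loading
#'
#' Integrates the two-parameter model from the isotonic initial state
#' (`Vw(0) = (1 - Vbf) V0`, `Vs(0) = 0`) during exposure to a CPA-bearing
#' bath. The response is biphasic for `Ms_e > 0`: fast osmotic water efflux
#' shrinks the cell to a single interior volume minimum, after which slow
#' solute entry (and water following it) recovers the volume towards the
#' equilibrium of [equilibriumState()].
#'
#' The integrator is an adaptive variable-order, variable-step method
#' (lsodar) run at `rtol = atol = 1e-9`, with a root function that aborts
#' the run if the water volume collapses below `1e-3 * V0`.
#'
#' @inheritParams transportRhs
#' @param t_end simulation horizon (min)
#' @param output_grid either a scalar output spacing (min) or a full vector
#'   of output times (min) starting at 0
#' @return a [volumeTrace()] (columns `time` min, `Vn`, `Msi` mol um^-3,
#'   plus `Vw`, `Vs` um^3)
#' @examples
#' tr <- simulateLoading(table1Geometry(), table1Permeability(), table1Bath(1.5))
#' vnMinimum(tr)
#' @export
simulateLoading <- function(geom, perm, bath, t_end = 4, output_grid = 1 / 600,
                            Mn0_i = table1Mn0i()) {
  .integrateTransport((1 - geom$Vbf) * geom$V0, 0, geom, perm, bath, Mn0_i,
                      t_end, output_grid)
}

#' Simulate CPA unloading
#'
#' The cell starts at the osmotic equilibrium reached after loading at
#' `cpa_conc_loaded` mol L^-1 (via [equilibriumState()]) and is returned to
#' an isotonic, CPA-free bath. The volume overshoots above its starting
#' value to a single interior maximum (water rushes in), then decays back
#' to the isotonic volume as the CPA leaves.
#'
#' @inheritParams simulateLoading
#' @param cpa_conc_loaded CPA osmolality at which the cell was equilibrated
#'   (mol L^-1)
#' @param bath_isotonic the unloading bath; default isotonic saline with no
#'   CPA at room temperature
#' @export
simulateUnloading <- function(geom, perm, cpa_conc_loaded,
                              bath_isotonic = table1Bath(0), t_end = 4,
                              output_grid = 1 / 600, Mn0_i = table1Mn0i()) {
  loaded <- bathComposition(Mn_e = bath_isotonic$Mn_e,
                            Ms_e = molPerL(cpa_conc_loaded),
                            T = bath_isotonic$T)
  eq <- equilibriumState(geom, loaded, Mn0_i)
  .integrateTransport(eq$Vw, eq$Vs, geom, perm, bath_isotonic, Mn0_i,
                      t_end, output_grid)
}

#' Closed-form osmotic equilibrium
#'
#' At equilibrium the total intracellular osmolality matches the bath and
#' the permeating solute is at equal osmolality on both sides, which gives
#' the Boyle-van't Hoff-type solution
#' `Vw_eq = Mn0_i (1 - Vbf) V0 / Mn_e` and `Vs_eq = Ms_e Vs_bar Vw_eq`.
#'
#' @inheritParams transportRhs
#' @return a [cellState()] (with `Vc`, `Vn` attached)
#' @export
equilibriumState <- function(geom, bath, Mn0_i = table1Mn0i()) {
  if (bath$Mn_e <= 0)
    stop("equilibriumState: no finite equilibrium when Mn_e = 0 (cell would swell without bound)")
  Vw_eq <- Mn0_i * (1 - geom$Vbf) * geom$V0 / bath$Mn_e
  Vs_eq <- bath$Ms_e * geom$Vs_bar * Vw_eq
  cellState(t = Inf, Vw = Vw_eq, Vs = Vs_eq, geom = geom)
}

#' Flag normalized-volume excursions outside a tolerance window
#'
#' @param trace a [volumeTrace()]
#' @param window a [toleranceWindow()]
#' @return data.frame of violating samples with columns `time` (min) and
#'   `Vn`; zero rows means the protocol stays within tolerance
#' @export
checkOsmoticExcursion <- function(trace, window) {
  if (!inherits(window, "toleranceWindow")) stop("window must be a toleranceWindow")
  if (nrow(trace) == 0L) stop("checkOsmoticExcursion: empty trace")
  bad <- trace$Vn < window$Vn_min | trace$Vn > window$Vn_max
  data.frame(time = trace$time[bad], Vn = trace$Vn[bad])
}

#' Locate the normalized-volume extremum of a trace
#'
#' Finds the discrete minimum (or maximum) of `Vn` and sharpens it by
#' fitting a quadratic through the three samples around it.
#'
#' @param trace a [volumeTrace()]
#' @param what `"min"` or `"max"`
#' @return list with `time_s` (interpolated extremum time, seconds),
#'   `time_min` (minutes) and `Vn` (interpolated extremum value)
#' @export
vnMinimum <- function(trace, what = c("min", "max")) {
  what <- match.arg(what)
  i <- if (what == "min") which.min(trace$Vn) else which.max(trace$Vn)
  n <- nrow(trace)
  if (i == 1L || i == n) {
    return(list(time_s = trace$time[i] * 60, time_min = trace$time[i],
                Vn = trace$Vn[i]))
  }
  t3 <- trace$time[(i - 1):(i + 1)]
  v3 <- trace$Vn[(i - 1):(i + 1)]
  co <- stats::coef(stats::lm(v3 ~ t3 + I(t3^2)))
  tm <- if (abs(co[3]) < .Machine$double.eps) trace$time[i] else -co[2] / (2 * co[3])
  ## keep the vertex inside the bracketing interval
  tm <- min(max(tm, t3[1]), t3[3])
  list(time_s = tm * 60, time_min = tm,
       Vn = sum(co * c(1, tm, tm^2)))
}
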