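#' Generate a synthetic video-microscopy volume trace
#'
#' Emulates the micromanipulator / video-microscopy experiment used to
#' measure oocyte volume responses: the noiseless two-parameter loading
#' curve is sampled on a regular grid and i.i.d. Gaussian measurement noise
#' is added to the normalized volume. The generator is deterministic given
#' `seed` and leaves the caller's RNG state untouched.
#'
#' @param perm true [membranePermeability()] used to generate the trace
#' @param geom a [cellGeometry()]
#' @param bath a [bathComposition()]
#' @param duration trace length (min)
#' @param sample_dt sampling interval (s); video frame spacing
#' @param noise_sd standard deviation of the additive noise on `Vn`
#'   (dimensionless); default 0.01
#' @param seed integer RNG seed
#' @param Mn0_i initial intracellular osmolality (mol um^-3)
#' @return a [volumeTrace()]; the noiseless `Vn` is kept in column
#'   `Vn_true`
#' @export
generateSyntheticTrace <- function(perm, geom = table1Geometry(),
                                   bath = table1Bath(1.5), duration = 4,
                                   sample_dt = 1, noise_sd = 0.01, seed = 1,
                                   Mn0_i = table1Mn0i()) {
  stopifnot(duration > 0, sample_dt > 0, noise_sd >= 0)
  grid <- seq(0, duration, by = sample_dt / 60)
  clean <- simulateLoading(geom, perm, bath, t_end = duration,
                           output_grid = grid, Mn0_i = Mn0_i)
  clean <- clean[seq_along(grid), ]
  noise <- .withSeed(seed, stats::rnorm(nrow(clean), 0, noise_sd))
  volumeTrace(time = clean$time, Vn = pmax(clean$Vn + noise, 1e-6),
              Msi = clean$Msi, Vn_true = clean$Vn)
}

## evaluate `expr` under a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit membrane permeabilities to a volume trace
#'
#' Estimates `Lp` and `Ps` by nonlinear least squares on the normalized
#' volume only (which is what video microscopy observes): the residual is
#' `Vn_model(t; Lp, Ps) - Vn_obs(t)` with the model trace integrated by
#' [simulateLoading()] at the observation times. The optimization runs over
#' `log(Lp)`, `log(Ps)` so positivity holds by construction, using
#' Levenberg-Marquardt least squares with finite-difference Jacobians
#' ([minpack.lm::nls.lm]) and a relative cost-decrease tolerance of 1e-10.
#'
#' @param trace observed [volumeTrace()] (only `time` and `Vn` are used);
#'   at least 10 samples
#' @param geom a [cellGeometry()]
#' @param bath the [bathComposition()] of the loading experiment
#' @param init length-2 numeric `c(Lp, Ps)` starting values, both > 0
#' @param Mn0_i initial intracellular osmolality (mol um^-3)
#' @return an object of class `fitResult`: list with `Lp_hat`, `Ps_hat`,
#'   `rss`, `n_iter`, `converged`
#' @examples
#' tr <- generateSyntheticTrace(table1Permeability(), noise_sd = 0)
#' fitTwoParameter(tr, init = c(0.3, 10))
#' @export
fitTwoParameter <- function(trace, geom = table1Geometry(),
                            bath = table1Bath(1.5), init = c(0.3, 10),
                            Mn0_i = table1Mn0i()) {
  if (nrow(trace) < 10L) stop("fitTwoParameter: need at least 10 samples")
  if (length(init) != 2L || any(init <= 0))
    stop("fitTwoParameter: init must be two positive values c(Lp, Ps)")
  tt <- trace$time
  grid <- if (tt[1] > 0) c(0, tt) else tt
  resid_fn <- function(logp) {
    perm <- membranePermeability(Lp = exp(logp[1]), Ps = exp(logp[2]),
                                 E_Lp = 11.19e3, E_Ps = 15.81e3,
                                 Lpg = 1, Psg = 1, T_meas = bath$T)
    mod <- simulateLoading(geom, perm, bath, t_end = tt[length(tt)],
                           output_grid = grid, Mn0_i = Mn0_i)
    mod$Vn[match(tt, mod$time)] - trace$Vn
  }
  fit <- minpack.lm::nls.lm(par = log(init), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-10, ptol = 1e-10, maxiter = 200))
  structure(list(Lp_hat = exp(fit$par[1]), Ps_hat = exp(fit$par[2]),
                 rss = fit$deviance, n_iter = fit$niter,
                 converged = fit$info %in% 1:4),
            class = "fitResult")
}

#' @export
print.fitResult <- function(x, ...) {
  cat(sprintf("<fitResult> Lp = %.4f um min^-1 atm^-1, Ps = %.4f um min^-1\n",
              x$Lp_hat, x$Ps_hat))
  cat(sprintf("  rss = %.4g, %d iterations, converged: %s\n",
              x$rss, x$n_iter, x$converged))
  invisible(x)
}
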