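test_that("intracellular osmolalities follow the dilution and partial-molar-volume laws", {
  isoVw <- (1 - geom1$Vbf) * geom1$V0
  # isotonic state: identity at the initial condition
  osm <- intracellularOsmolalities(list(Vw = isoVw, Vs = 0), geom1, Mn0)
  expect_equal(osm$Mn_i, molPerL(0.300))
  expect_equal(osm$Ms_i, 0)
  expect_equal(osm$Mi, molPerL(0.300))
  # inverse proportionality to water volume
  osm <- intracellularOsmolalities(list(Vw = isoVw / 2, Vs = 0), geom1, Mn0)
  expect_equal(osm$Mn_i, molPerL(0.600))
  # solute osmolality inverts the defining relation Vs = Ms * Vs_bar * Vw
  Ms <- molPerL(1.5)
  osm <- intracellularOsmolalities(
    list(Vw = isoVw, Vs = Ms * geom1$Vs_bar * isoVw), geom1, Mn0)
  expect_equal(osm$Ms_i, Ms)
  expect_error(intracellularOsmolalities(list(Vw = 0, Vs = 0), geom1, Mn0),
               "dehydrated")
})

test_that("transport fluxes vanish at equilibrium and match direct arithmetic off it", {
  bath <- table1Bath(1.5)
  eq <- equilibriumState(geom1, bath, Mn0)
  rhs <- transportRhs(eq, geom1, perm1, bath, Mn0)
  expect_equal(rhs$dVw_dt, 0, tolerance = 1e-12)
  expect_equal(rhs$dVs_dt, 0, tolerance = 1e-12)

  # isotonic start against 1.5 mol/L EG at 22 degC: independent arithmetic
  iso <- list(Vw = (1 - geom1$Vbf) * geom1$V0, Vs = 0)
  rhs <- transportRhs(iso, geom1, perm1, bath, Mn0)
  dVw_direct <- -0.6284 * 34763.12 * 8.205745e13 * 295.15 * 1.5e-15
  dVs_direct <- 20.3660 * 34763.12 * 1.5e-15 * 5.5919e13
  expect_equal(rhs$dVw_dt, dVw_direct)
  expect_equal(rhs$dVs_dt, dVs_direct)
  expect_equal(rhs$dVw_dt, -7.94e5, tolerance = 5e-3)
  expect_equal(rhs$dVs_dt, 5.94e4, tolerance = 5e-3)
})

test_that("Arrhenius scaling reduces to the reference values at 0 degC and increases with T", {
  at0 <- arrheniusPermeability(perm1, 273.15)
  expect_identical(at0$Lp, 0.1522)
  expect_identical(at0$Ps, 3.7660)
  at20 <- arrheniusPermeability(perm1, 293.15)
  expect_equal(at20$Lp,
               0.1522 * exp((11190 / 1.987204) * (1 / 273.15 - 1 / 293.15)))
  expect_equal(at20$Lp, 0.621, tolerance = 1e-3)
  # monotonicity in temperature
  Ts <- seq(263.15, 313.15, by = 5)
  vals <- vapply(Ts, function(T) unlist(arrheniusPermeability(perm1, T)),
                 numeric(2))
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) > 0))
  expect_error(arrheniusPermeability(perm1, -1), "T must be")
})

test_that("closed-form equilibrium matches the Boyle-van't Hoff construction", {
  # isotonic bath, no CPA: the isotonic state itself
  eq <- equilibriumState(geom1, table1Bath(0), Mn0)
  # Vb is the printed value, consistent with V0 * Vbf only to 0.01 um^3
  expect_equal(eq$Vn, 1, tolerance = 1e-8)
  # doubled external non-permeating osmolality halves the water volume
  eq <- equilibriumState(geom1, bathComposition(molPerL(0.6), 0, 295.15), Mn0)
  expect_equal(eq$Vw, (1 - geom1$Vbf) * geom1$V0 / 2)
  expect_equal(eq$Vn, (eq$Vw + geom1$Vb) / geom1$V0)
  expect_equal(eq$Vn, 0.656, tolerance = 1e-3)
  # 1.5 mol/L EG bath: swollen equilibrium accommodating the CPA
  eq <- equilibriumState(geom1, table1Bath(1.5), Mn0)
  Vw <- (1 - geom1$Vbf) * geom1$V0
  expect_equal(eq$Vn, (Vw + molPerL(1.5) * geom1$Vs_bar * Vw + geom1$Vb) / geom1$V0)
  expect_equal(eq$Vn, 1.058, tolerance = 1e-3)
  expect_error(equilibriumState(geom1, bathComposition(0, molPerL(1.5), 295.15), Mn0),
               "no finite equilibrium")
})

test_that("loading is flat in an isotonic bath and biphasic with CPA", {
  tr <- simulateLoading(geom1, perm1, table1Bath(0), t_end = 2)
  expect_true(all(abs(tr$Vn - 1) < 1e-7))
  tr <- simulateLoading(geom1, perm1, table1Bath(1.5), t_end = 4)
  expect_biphasic(tr$Vn)
  m <- vnMinimum(tr)
  expect_lt(m$Vn, 0.8)
  expect_gt(utils::tail(tr$Vn, 1), m$Vn)
})

test_that("long-time loading converges to the closed-form equilibrium", {
  for (conc in c(0.45, 0.7, 1.5)) {
    bath <- table1Bath(conc)
    tr <- simulateLoading(geom1, perm1, bath, t_end = 120, output_grid = 1)
    eq <- equilibriumState(geom1, bath, Mn0)
    n <- nrow(tr)
    expect_equal(tr$Vw[n], eq$Vw, tolerance = 1e-6)
    expect_equal(tr$Vs[n], eq$Vs, tolerance = 1e-6)
  }
})

test_that("adaptive solution agrees with a fixed-step RK4 reference", {
  bath <- table1Bath(1.5)
  ref <- rk4Transport(geom1, perm1, bath, Mn0, t_end = 4, dt = 1e-3)
  grid <- ref[seq(1, nrow(ref), by = 250), 1]   # every 0.25 min
  tr <- simulateLoading(geom1, perm1, bath, t_end = 4, output_grid = grid)
  Vn_ref <- (ref[seq(1, nrow(ref), by = 250), 2] +
             ref[seq(1, nrow(ref), by = 250), 3] + geom1$Vb) / geom1$V0
  expect_lt(max(abs(tr$Vn[seq_along(grid)] - Vn_ref)), 1e-5)
})

test_that("unloading swells to one interior maximum and relaxes to isotonic", {
  tr <- simulateUnloading(geom1, perm1, cpa_conc_loaded = 0, t_end = 2)
  expect_true(all(abs(tr$Vn - 1) < 1e-7))
  tr <- simulateUnloading(geom1, perm1, cpa_conc_loaded = 1.5, t_end = 60,
                          output_grid = 0.01)
  expect_biphasic(-tr$Vn)          # single interior maximum
  expect_true(all(diff(tr$Msi) < 1e-12))   # CPA leaves monotonically
  n <- nrow(tr)
  expect_equal(tr$Vn[n], 1, tolerance = 1e-6)
  expect_lt(tr$Msi[n] / molPerL(1.5), 1e-6)
  # peak value against an independent high-accuracy reference integration
  eq <- equilibriumState(geom1, table1Bath(1.5), Mn0)
  f <- function(x) {
    Mn_i <- Mn0 * (1 - geom1$Vbf) * geom1$V0 / x[1]
    Ms_i <- x[2] / (geom1$Vs_bar * x[1])
    c(-perm1$Lp * geom1$A * gasConstant("um3_atm") * 295.15 *
        (molPerL(0.3) - Mn_i - Ms_i),
      perm1$Ps * geom1$A * (0 - Ms_i) * geom1$Vs_bar)
  }
  x <- c(eq$Vw, eq$Vs); dt <- 5e-4; peak <- -Inf
  for (k in seq_len(round(4 / dt))) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1); k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    peak <- max(peak, (x[1] + x[2] + geom1$Vb) / geom1$V0)
  }
  expect_equal(vnMinimum(tr, "max")$Vn, peak, tolerance = 1e-4)
})

test_that("integration aborts with an osmotic-collapse diagnostic in extreme baths", {
  expect_error(
    simulateLoading(geom1, perm1, bathComposition(molPerL(500), 0, 295.15)),
    "osmotic collapse")
})

test_that("excursion checking flags exactly the out-of-window samples", {
  win <- toleranceWindow(0.7, 1.3)
  flat <- volumeTrace(time = 0:10, Vn = rep(1, 11), Msi = rep(0, 11))
  expect_identical(nrow(checkOsmoticExcursion(flat, win)), 0L)
  # constructed dip below the bound at exactly 4 samples
  vn <- c(1, 0.9, 0.65, 0.6, 0.62, 0.69, 0.75, 0.9, 1, 1, 1)
  tr <- volumeTrace(time = 0:10, Vn = vn, Msi = rep(0, 11))
  out <- checkOsmoticExcursion(tr, win)
  expect_identical(nrow(out), 4L)
  expect_equal(out$time, c(2, 3, 4, 5))
  expect_error(checkOsmoticExcursion(tr[0, ], win), "empty")
})

test_that("cell geometry and trace invariants are enforced", {
  expect_error(cellGeometry(A = 100, V0 = 1000, Vbf = 1.2, Vs_bar = 1), "Vbf")
  expect_error(cellGeometry(A = 100, V0 = 1000, Vbf = 0.3, Vs_bar = 1, Vb = 400),
               "inconsistent")
  expect_error(membranePermeability(-1, 1, 1, 1, 1, 1), "positive")
  expect_error(volumeTrace(time = c(0, 0), Vn = c(1, 1), Msi = c(0, 0)),
               "strictly increasing")
  expect_error(toleranceWindow(1.1, 1.3), "Vn_min")
})
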