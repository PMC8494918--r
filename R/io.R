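## Recognized configuration keys, their defaults and validation bounds.
## Transport keys mirror the symbol names of the permeability literature;
## concentrations in config are user-facing mol L^-1.
.configDefaults <- function() {
  list(
    mode = "load",
    seed = 0L,
    ## transport (cell + membrane + bath)
    A_um2 = 34763.12,
    V0_um3 = 609469.49,
    Vbf = 0.3123,
    Vsbar_um3_per_mol = 5.5919e13,
    Lp = 0.6284,
    Ps = 20.3660,
    E_Lp_cal = 11.19e3,
    E_Ps_cal = 15.81e3,
    Lpg = 0.1522,
    Psg = 3.7660,
    T_K = 295.15,
    Mn_e = 0.300,            # mol L^-1
    Ms_e = 1.500,            # mol L^-1
    Mn0_i = 0.300,           # mol L^-1
    t_end_min = 4,
    output_dt_s = 0.1,
    use_arrhenius = FALSE,
    ## synthetic traces / fitting
    duration_min = 4,
    sample_dt_s = 1,
    noise_sd = 0.01,
    init_Lp = 0.3,
    init_Ps = 10,
    ## FEM
    E_kPa = 14.52,
    nu = 0.49,
    D_mm2 = 2.83e-6,
    D_time_base = "s",
    beta0 = -0.20,
    c0 = 0.8,
    Cref_mol_per_L = 1.5,
    fem_t_end_s = 240,
    fem_dt_s = 0.5,
    mesh_subdivisions = 3,
    mesh_layers = 8,
    capillary_half_angle_deg = 20,
    asym_half_angle_deg = 0,
    asym_conc_factor = 0.5,
    snapshot_times_s = numeric()
  )
}

.modes <- c("load", "unload", "fit", "fem-load", "fem-unload", "fem-asym", "synth")

#' Load and validate a scenario configuration
#'
#' Reads a YAML (or JSON) configuration, fills omitted keys with the
#' packaged defaults, rejects unknown keys, and validates every value
#' against the type invariants of the objects it will construct (the
#' constructors are the single enforcement point; this function builds them
#' eagerly so a bad value fails here with the offending key named).
#'
#' @param path path to a YAML/JSON file, or `NULL` for pure defaults
#' @param overrides named list of overrides applied on top of the file
#' @return an object of class `scenarioConfig`: the validated key-value
#'   list plus pre-built `geom`, `perm`, `bath`, `material`, `bc` objects
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  cfg <- .configDefaults()
  user <- list()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("loadConfig: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)

  if (!cfg$mode %in% .modes)
    stop("loadConfig: mode must be one of ", paste(.modes, collapse = ", "))
  if (cfg$Vbf <= 0 || cfg$Vbf >= 1)
    stop("loadConfig: Vbf = ", cfg$Vbf, " violates 0 < Vbf < 1")
  if (cfg$noise_sd < 0) stop("loadConfig: noise_sd must be >= 0")
  if (cfg$fem_dt_s <= 0) stop("loadConfig: fem_dt_s must be > 0")

  cfg$geom <- cellGeometry(A = cfg$A_um2, V0 = cfg$V0_um3, Vbf = cfg$Vbf,
                           Vs_bar = cfg$Vsbar_um3_per_mol)
  cfg$perm <- membranePermeability(Lp = cfg$Lp, Ps = cfg$Ps,
                                   E_Lp = cfg$E_Lp_cal, E_Ps = cfg$E_Ps_cal,
                                   Lpg = cfg$Lpg, Psg = cfg$Psg, T_meas = cfg$T_K)
  if (isTRUE(cfg$use_arrhenius)) cfg$perm <- permeabilityAt(cfg$perm, cfg$T_K)
  cfg$bath <- bathComposition(Mn_e = molPerL(cfg$Mn_e), Ms_e = molPerL(cfg$Ms_e),
                              T = cfg$T_K)
  cfg$material <- materialModel(E = cfg$E_kPa, nu = cfg$nu, D = cfg$D_mm2,
                                beta0 = cfg$beta0, c0 = cfg$c0,
                                Cref = cfg$Cref_mol_per_L,
                                D_time_base = cfg$D_time_base)
  cfg$bc <- boundarySpec(capillary_half_angle = cfg$capillary_half_angle_deg,
                         asym_half_angle = cfg$asym_half_angle_deg,
                         asym_conc_factor = cfg$asym_conc_factor)
  structure(cfg, class = "scenarioConfig")
}

#' Write a time series to CSV
#'
#' A [volumeTrace()] is written with header `time_s,Vn,Msi_mol_per_L`
#' (time converted to seconds, intracellular osmolality to mol L^-1); a
#' `femTimeSeries` is written with its native seven columns. Re-reading
#' reproduces the arrays exactly (full double precision).
#'
#' @param x a [volumeTrace()] or `femTimeSeries`
#' @param path output file
#' @return `path`, invisibly
#' @export
writeTimeseries <- function(x, path) {
  if (nrow(x) == 0L) stop("writeTimeseries: empty series")
  if (inherits(x, "volumeTrace")) {
    out <- data.frame(time_s = x$time * 60, Vn = x$Vn,
                      Msi_mol_per_L = toMolPerL(x$Msi))
  } else if (inherits(x, "femTimeSeries")) {
    out <- as.data.frame(x)
  } else stop("writeTimeseries: unsupported object")
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a volume trace from CSV
#'
#' Accepts the `time_s,Vn[,Msi_mol_per_L]` schema written by
#' [writeTimeseries()] (fitting only needs the first two columns).
#'
#' @param path CSV file
#' @return a [volumeTrace()]
#' @export
readTrace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "Vn") %in% names(df)))
    stop("readTrace: expected columns time_s and Vn")
  msi <- if ("Msi_mol_per_L" %in% names(df)) molPerL(df$Msi_mol_per_L) else
    rep(NA_real_, nrow(df))
  volumeTrace(time = df$time_s / 60, Vn = df$Vn, Msi = msi)
}

#' Write a FEM field snapshot as a legacy VTK unstructured grid
#'
#' ASCII legacy `.vtk` with the tetrahedral mesh, point data (displacement
#' vector, concentration) and cell data (hydrostatic pressure; positive =
#' compression).
#'
#' @param mesh a `tetMesh`
#' @param path output file
#' @param displacement length-3n nodal displacement (mm), optional
#' @param concentration length-n nodal concentration (mol L^-1), optional
#' @param pressure per-element hydrostatic pressure (kPa), optional
#' @param point_data named list of extra per-node scalar fields
#' @return `path`, invisibly
#' @export
writeVtk <- function(mesh, path, displacement = NULL, concentration = NULL,
                     pressure = NULL, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 3.0", "cpaload FEM snapshot", "ASCII",
     "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n))
  utils::write.table(format(mesh$nodes, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl(sprintf("CELLS %d %d", m, 5 * m))
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  wl(sprintf("CELL_TYPES %d", m))
  writeLines(rep("10", m), con)
  has_pd <- !is.null(displacement) || !is.null(concentration) || length(point_data)
  if (has_pd) {
    wl(sprintf("POINT_DATA %d", n))
    if (!is.null(concentration)) {
      wl("SCALARS concentration double 1", "LOOKUP_TABLE default")
      writeLines(format(concentration, digits = 10, trim = TRUE), con)
    }
    for (nm in names(point_data)) {
      wl(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default")
      writeLines(format(point_data[[nm]], digits = 10, trim = TRUE), con)
    }
    if (!is.null(displacement)) {
      wl("VECTORS displacement double")
      U <- matrix(displacement, ncol = 3, byrow = TRUE)
      utils::write.table(format(U, digits = 10, trim = TRUE), con,
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(pressure)) {
    wl(sprintf("CELL_DATA %d", m), "SCALARS hydrostatic_pressure double 1",
       "LOOKUP_TABLE default")
    writeLines(format(pressure, digits = 10, trim = TRUE), con)
  }
  invisible(path)
}

#' Execute a configured scenario
#'
#' Dispatches on `config$mode`:
#' \describe{
#'   \item{load / unload}{two-parameter transport simulation, CSV trace}
#'   \item{synth}{synthetic noisy trace (seeded), CSV}
#'   \item{fit}{fit `Lp`, `Ps` to a trace CSV, JSON fit report}
#'   \item{fem-load / fem-unload / fem-asym}{coupled FEM run, CSV time
#'     series plus VTK snapshots}
#' }
#' Every run writes `manifest.json` with all effective parameters, the
#' seed and the package version, from which the run can be reproduced.
#'
#' @param config a [loadConfig()] result
#' @param out_dir output directory (created if missing)
#' @param trace_path CSV trace to fit (modes `fit`), see [readTrace()]
#' @param quiet suppress progress lines
#' @return named list of artifact paths (plus the main result object,
#'   invisibly in `$result`)
#' @export
runScenario <- function(config, out_dir = ".", trace_path = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "scenarioConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- list()
  t0 <- proc.time()[3]
  mode <- config$mode

  if (mode %in% c("load", "unload", "synth")) {
    tr <- switch(mode,
      load = simulateLoading(config$geom, config$perm, config$bath,
                             t_end = config$t_end_min,
                             output_grid = config$output_dt_s / 60,
                             Mn0_i = molPerL(config$Mn0_i)),
      unload = simulateUnloading(config$geom, config$perm,
                                 cpa_conc_loaded = config$Ms_e,
                                 bath_isotonic = bathComposition(
                                   molPerL(config$Mn_e), 0, config$T_K),
                                 t_end = config$t_end_min,
                                 output_grid = config$output_dt_s / 60,
                                 Mn0_i = molPerL(config$Mn0_i)),
      synth = generateSyntheticTrace(config$perm, config$geom, config$bath,
                                     duration = config$duration_min,
                                     sample_dt = config$sample_dt_s,
                                     noise_sd = config$noise_sd,
                                     seed = config$seed,
                                     Mn0_i = molPerL(config$Mn0_i)))
    artifacts$trace <- file.path(out_dir, "trace.csv")
    writeTimeseries(tr, artifacts$trace)
    say("%s: %d samples written (%.2f s)", mode, nrow(tr), proc.time()[3] - t0)
    result <- tr
  } else if (mode == "fit") {
    if (is.null(trace_path)) stop("runScenario: mode 'fit' needs trace_path")
    tr <- readTrace(trace_path)
    fit <- fitTwoParameter(tr, config$geom, config$bath,
                           init = c(config$init_Lp, config$init_Ps),
                           Mn0_i = molPerL(config$Mn0_i))
    artifacts$fit <- file.path(out_dir, "fit.json")
    jsonlite::write_json(unclass(fit), artifacts$fit, auto_unbox = TRUE,
                         digits = NA)
    say("fit: Lp = %.4f, Ps = %.4f (rss %.3g, %.2f s)", fit$Lp_hat, fit$Ps_hat,
        fit$rss, proc.time()[3] - t0)
    result <- fit
  } else {                                  # fem-*
    bc <- config$bc
    if (mode == "fem-asym" && bc$asym_half_angle <= 0)
      bc <- boundarySpec(capillary_half_angle = bc$capillary_half_angle,
                         asym_half_angle = 60,
                         asym_conc_factor = bc$asym_conc_factor)
    mesh <- buildCapillarySphereMesh(subdivisions = config$mesh_subdivisions,
                                     layers = config$mesh_layers, bc = bc)
    say("fem: mesh with %d nodes, %d tets", nrow(mesh$nodes), nrow(mesh$tets))
    ts <- runFem(mesh, config$material, bc,
                 t_end = config$fem_t_end_s, dt = config$fem_dt_s,
                 mode = if (mode == "fem-unload") "unload" else "load",
                 snapshot_times = config$snapshot_times_s)
    artifacts$timeseries <- file.path(out_dir, "fem_timeseries.csv")
    writeTimeseries(ts, artifacts$timeseries)
    sys <- attr(ts, "systems")
    for (sn in attr(ts, "snapshots")) {
      p <- file.path(out_dir, sprintf("fields_t%07.2fs.vtk", sn$t))
      bfac <- rep(NA_real_, nrow(mesh$nodes))
      bfac[sys$dir_nodes] <- sys$C_dir / config$material$Cref
      writeVtk(mesh, p, displacement = sn$u, concentration = sn$C,
               pressure = .elementPressure(sys, sn$u, sn$C),
               point_data = list(boundary_factor = ifelse(is.na(bfac), -1, bfac)))
      artifacts[[paste0("snapshot_", sn$t)]] <- p
    }
    say("%s: %d steps (%.2f s)", mode, nrow(ts) - 1, proc.time()[3] - t0)
    result <- ts
  }

  manifest <- config[setdiff(names(config),
                             c("geom", "perm", "bath", "material", "bc"))]
  manifest$package_version <- as.character(utils::packageVersion("cpaload"))
  manifest$artifacts <- lapply(artifacts, normalizePath)
  artifacts$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, artifacts$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  out <- artifacts
  out$result <- result
  invisible(out)
}
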