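#' Precompute the coupled FEM systems for time stepping
#'
#' Assembles and factorizes everything [stepCoupled()] needs: the
#' backward-Euler diffusion operator `M/dt + K` with Dirichlet rows on
#' exposed boundary nodes eliminated, and the elasticity stiffness with the
#' capillary nodes pinned. Both factorizations are reused for every step
#' (the matrices are constant in time; the coupling is one-way staggered:
#' diffusion -> eigenstrain -> quasi-static elasticity).
#'
#' Boundary conditions: the prescribed concentration on an exposed node is
#' `factor * Cref` during loading (factor from the [boundarySpec()], 1 by
#' default, `asym_conc_factor` on the asymmetric cap) and 0 during
#' unloading; capillary nodes carry the natural zero-flux condition and
#' `u = 0`.
#'
#' @param mesh a `tetMesh`
#' @param mat a [materialModel()]
#' @param bc a [boundarySpec()]
#' @param dt time step (s)
#' @param mode `"load"` (C starts at 0, bath at Cref, strain referenced to
#'   0) or `"unload"` (C starts at Cref, bath at 0, strain referenced to
#'   Cref)
#' @param strain_reference `"initial"` (default) or `"bath"`, see
#'   [diffusionStrain()]
#' @return an object of class `femSystems`
#' @export
femSystems <- function(mesh, mat, bc = mesh$bc, dt = 0.5,
                       mode = c("load", "unload"),
                       strain_reference = c("initial", "bath")) {
  mode <- match.arg(mode)
  strain_reference <- match.arg(strain_reference)
  if (dt <= 0) stop("femSystems: dt must be > 0")
  n <- nrow(mesh$nodes)
  g <- .tetGradients(mesh)
  diff_sys <- assembleDiffusionSystem(mesh, mat)

  ## per-node boundary concentration factors
  dir_nodes <- boundaryNodes(mesh, "EXPOSED")
  factor <- rep(bc$exposed_conc_factor, length(dir_nodes))
  if (bc$asym_half_angle > 0) {
    xyz <- mesh$nodes[dir_nodes, , drop = FALSE]
    polar_from_bottom <- acos(pmin(1, pmax(-1,
      -xyz[, 3] / sqrt(rowSums(xyz^2))))) * 180 / pi
    factor[polar_from_bottom <= bc$asym_half_angle] <- bc$asym_conc_factor
  }
  C_dir <- if (mode == "load") factor * mat$Cref else rep(0, length(dir_nodes))
  free_c <- setdiff(seq_len(n), dir_nodes)

  A <- diff_sys$damping / dt + diff_sys$conductivity
  A_ff <- A[free_c, free_c, drop = FALSE]
  b_bc <- as.vector(A[free_c, dir_nodes, drop = FALSE] %*% C_dir)
  chol_diff <- Matrix::Cholesky(Matrix::forceSymmetric(A_ff), LDL = FALSE)

  K <- assembleElasticitySystem(mesh, mat)
  cap_nodes <- boundaryNodes(mesh, "CAPILLARY")
  fixed_u <- as.vector(rbind(3 * cap_nodes - 2, 3 * cap_nodes - 1, 3 * cap_nodes))
  free_u <- setdiff(seq_len(3 * n), fixed_u)
  chol_elast <- try(Matrix::Cholesky(
    Matrix::forceSymmetric(K[free_u, free_u, drop = FALSE]), LDL = FALSE),
    silent = TRUE)
  if (inherits(chol_elast, "try-error"))
    stop("femSystems: singular elasticity system -- are any constraints applied? ",
         "(no CAPILLARY nodes on this mesh?)")

  structure(list(mesh = mesh, mat = mat, bc = bc, dt = dt, mode = mode,
                 strain_reference = strain_reference,
                 C_strain_ref = if (mode == "load") 0 else mat$Cref,
                 geom = g, M = diff_sys$damping, Kc = diff_sys$conductivity,
                 dir_nodes = dir_nodes, C_dir = C_dir, free_c = free_c,
                 chol_diff = chol_diff, b_bc = b_bc,
                 free_u = free_u, chol_elast = chol_elast),
            class = "femSystems")
}

#' Initial FEM state for a loading or unloading run
#'
#' @param systems a [femSystems()]
#' @return an object of class `femState`: list with `t` (s), `u`
#'   (displacement, length 3n, mm) and `C` (nodal concentration, mol L^-1)
#' @export
femInitialState <- function(systems) {
  n <- nrow(systems$mesh$nodes)
  ## uniform initial field: the prescribed boundary values apply for t > 0
  ## (first step), so the body starts undeformed and stress-free
  C0 <- rep(if (systems$mode == "load") 0 else systems$mat$Cref, n)
  structure(list(t = 0, u = numeric(3 * n), C = C0), class = "femState")
}

#' Advance the coupled system by one time step
#'
#' (i) backward-Euler transient diffusion solve for the concentration at
#' `t + dt` (Dirichlet on exposed nodes, natural zero flux on the capillary
#' patch), with the result clamped to the physical range `[0, Cref]` to
#' guard against the small over/undershoots of consistent-mass FEM;
#' (ii) quasi-static elasticity solve under the eigenstrain load of the new
#' concentration field, with `u = 0` on capillary nodes.
#'
#' @param state a `femState`
#' @param systems a [femSystems()] (carries `dt`)
#' @return the advanced `femState`
#' @export
stepCoupled <- function(state, systems) {
  s <- systems
  rhs <- as.vector(s$M %*% (state$C / s$dt))[s$free_c] - s$b_bc
  C_free <- as.vector(Matrix::solve(s$chol_diff, rhs, system = "A"))
  C <- state$C
  C[s$free_c] <- C_free
  C[s$dir_nodes] <- s$C_dir
  Cmax <- max(s$mat$Cref, state$C)
  C <- pmin(pmax(C, 0), Cmax)

  f <- .eigenForce(s$geom, s$mesh, C, s$mat,
                   if (s$strain_reference == "bath") s$mat$Cref else s$C_strain_ref)
  u <- numeric(length(state$u))
  u[s$free_u] <- as.vector(Matrix::solve(s$chol_elast, f[s$free_u], system = "A"))
  structure(list(t = state$t + s$dt, u = u, C = C), class = "femState")
}

## per-element hydrostatic pressure -tr(sigma)/3 = -K (div u - 3 e_di)
.elementPressure <- function(systems, u, C) {
  s <- systems
  mesh <- s$mesh
  U <- matrix(u, ncol = 3, byrow = TRUE)
  divu <- numeric(nrow(mesh$tets))
  for (i in 1:4) {
    nd <- mesh$tets[, i]
    divu <- divu + rowSums(s$geom$grads[, i, ] * U[nd, , drop = FALSE])
  }
  Cc <- rowMeans(matrix(C[mesh$tets], ncol = 4))
  e <- diffusionStrain(pmax(Cc, 0), s$mat,
                       if (s$strain_reference == "bath") s$mat$Cref else s$C_strain_ref)
  Kbulk <- s$mat$E / (3 * (1 - 2 * s$mat$nu))
  -Kbulk * (divu - 3 * e)
}

#' Interpolate the concentration at a named probe location
#'
#' Probe points sit on the radial ray opposite the capillary patch (the -z
#' pole) at radii 1.0, 0.9 and 0.1 times the mesh radius for `"membrane"`,
#' `"near_membrane"` and `"near_center"`. Linear (barycentric)
#' interpolation of the nodal field in the containing tetrahedron.
#'
#' @param mesh a `tetMesh`
#' @param C nodal field values, length n
#' @param location one of `"membrane"`, `"near_membrane"`, `"near_center"`,
#'   or a numeric length-3 point (mm)
#' @return interpolated value
#' @export
probeConcentration <- function(mesh, C, location = c("membrane", "near_membrane",
                                                     "near_center")) {
  if (is.character(location)) {
    location <- match.arg(location)
    r <- switch(location, membrane = 1.0, near_membrane = 0.9, near_center = 0.1)
    ## nudge the on-membrane probe just inside the polyhedral surface
    p <- c(0, 0, -r * mesh$radius * (1 - 1e-9))
  } else p <- location
  w <- .probeWeights(mesh, p)
  sum(C[w$nodes] * w$lambda)
}

## barycentric location of a point: tet index + weights
.probeWeights <- function(mesh, p, tol = 1e-7) {
  g <- .tetGradients(mesh)
  m <- nrow(mesh$tets)
  lam <- matrix(0, m, 4)
  x1 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  d <- cbind(p[1] - x1[, 1], p[2] - x1[, 2], p[3] - x1[, 3])
  for (i in 1:4)
    lam[, i] <- (i == 1) + rowSums(g$grads[, i, ] * d)
  inside <- which(apply(lam, 1, min) >= -tol)
  if (length(inside) == 0L)
    stop("probeConcentration: point (", paste(signif(p, 4), collapse = ", "),
         ") lies outside the mesh")
  e <- inside[which.max(apply(lam[inside, , drop = FALSE], 1, min))]
  list(tet = e, nodes = mesh$tets[e, ], lambda = pmax(lam[e, ], 0) / sum(pmax(lam[e, ], 0)))
}

#' Run the coupled diffusion-elasticity simulation
#'
#' Time-marches the one-way coupled system over the exposure window and
#' post-processes, per output step: the deformed-to-initial volume ratio
#' `Vn` (sum of deformed tetrahedron volumes over the initial mesh volume),
#' the volume-averaged hydrostatic pressure `p_mean` (volume-weighted
#' element average of -tr(sigma)/3, kPa; positive = compression), the
#' volume-averaged concentration `C_mean`, and the three probe
#' concentrations. During loading `Vn` is biphasic (single minimum near
#' 30 s at the packaged parameters) and `|p_mean|` rises to a single
#' maximum (near 15 s) before decaying.
#'
#' @inheritParams femSystems
#' @param t_end exposure duration (s); default 240
#' @param dt time step (s); default 0.5 (backward-Euler diffusion is
#'   unconditionally stable)
#' @param output_every record the time series every this many steps
#' @param snapshot_times times (s) at which full `(C, u)` field snapshots
#'   are kept
#' @return a `femTimeSeries`: data.frame with columns `time_s`, `Vn`,
#'   `p_mean_kPa`, `C_mean_mol_per_L`, `probe_membrane`,
#'   `probe_near_membrane`, `probe_center`; attribute `snapshots` holds the
#'   requested field snapshots, attribute `systems` the [femSystems()]
#' @examples
#' \donttest{
#' mesh <- buildCapillarySphereMesh(subdivisions = 2, layers = 5)
#' ts <- runFem(mesh, table2Material(), t_end = 60)
#' }
#' @export
runFem <- function(mesh, mat, bc = mesh$bc, t_end = 240, dt = 0.5,
                   mode = c("load", "unload"), output_every = 1,
                   snapshot_times = numeric(),
                   strain_reference = c("initial", "bath")) {
  mode <- match.arg(mode)
  strain_reference <- match.arg(strain_reference)
  sys <- femSystems(mesh, mat, bc, dt, mode, strain_reference)
  state <- femInitialState(sys)
  nstep <- ceiling(t_end / dt)
  V0e <- sys$geom$vol
  Vtot <- sum(V0e)
  ones_n <- rep(1, nrow(mesh$nodes))
  MC1 <- as.vector(sys$M %*% ones_n)   # nodal volume weights

  pw <- lapply(c(1.0, 0.9, 0.1), function(r)
    .probeWeights(mesh, c(0, 0, -r * mesh$radius * (1 - 1e-9))))

  rec_steps <- seq(0, nstep, by = output_every)
  rec <- matrix(NA_real_, length(rec_steps), 7)
  colnames(rec) <- c("time_s", "Vn", "p_mean_kPa", "C_mean_mol_per_L",
                     "probe_membrane", "probe_near_membrane", "probe_center")
  snapshots <- list()
  record <- function(k, state) {
    U <- matrix(state$u, ncol = 3, byrow = TRUE)
    Vdef <- sum(tetVolumes(mesh, mesh$nodes + U))
    p <- .elementPressure(sys, state$u, state$C)
    c(state$t,
      Vdef / Vtot,
      sum(p * V0e) / Vtot,
      sum(MC1 * state$C) / Vtot,
      vapply(pw, function(w) sum(state$C[w$nodes] * w$lambda), 0))
  }
  ri <- 1
  if (0 %in% rec_steps) { rec[ri, ] <- record(0, state); ri <- ri + 1 }
  for (k in seq_len(nstep)) {
    state <- stepCoupled(state, sys)
    if (k %in% rec_steps) { rec[ri, ] <- record(k, state); ri <- ri + 1 }
    if (length(snapshot_times) && any(abs(snapshot_times - state$t) < dt / 2)) {
      snapshots[[length(snapshots) + 1]] <-
        list(t = state$t, C = state$C, u = state$u)
    }
  }
  out <- as.data.frame(rec)
  class(out) <- c("femTimeSeries", "data.frame")
  attr(out, "snapshots") <- snapshots
  attr(out, "systems") <- sys
  out
}

#' @export
print.femTimeSeries <- function(x, ...) {
  cat(sprintf("<femTimeSeries> %d records over [0, %.1f] s\n",
              nrow(x), x$time_s[nrow(x)]))
  cat(sprintf("  Vn range [%.4f, %.4f]; |p_mean| max %.4g kPa; C_mean final %.4f mol/L\n",
              min(x$Vn), max(x$Vn), max(abs(x$p_mean_kPa)),
              x$C_mean_mol_per_L[nrow(x)]))
  invisible(x)
}
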