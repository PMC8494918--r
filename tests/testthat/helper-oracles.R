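# Shared fixtures and independent oracles.

geom1 <- table1Geometry()
perm1 <- table1Permeability()
Mn0 <- table1Mn0i()

# small meshes reused across FEM tests (built once per test run)
coarseMesh <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- buildCapillarySphereMesh(subdivisions = 2, layers = 5)
    m
  }
})

defaultMesh <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- buildCapillarySphereMesh()   # subdivisions 3, layers 8
    m
  }
})

# diffusion-only stepping with Dirichlet Cref on the whole surface (the
# unconstrained symmetric sphere), returning the nodal field after n steps
dirichletSphereField <- function(mesh, mat, dt, nstep) {
  d <- assembleDiffusionSystem(mesh, mat)
  n <- nrow(mesh$nodes)
  surf <- unique(as.vector(mesh$boundary_tris))
  free <- setdiff(seq_len(n), surf)
  A <- d$damping / dt + d$conductivity
  Aff <- A[free, free]; Afd <- A[free, surf]
  C <- numeric(n); C[surf] <- mat$Cref
  for (k in seq_len(nstep)) {
    rhs <- as.vector(d$damping %*% (C / dt))[free] - as.vector(Afd %*% C[surf])
    C[free] <- as.vector(Matrix::solve(Aff, rhs))
  }
  C
}

# Independent fixed-step classical RK4 integrator of the transport ODEs,
# written directly from the flux laws (no deSolve).
rk4Transport <- function(geom, perm, bath, Mn0_i, t_end, dt) {
  f <- function(x) {
    Mn_i <- Mn0_i * (1 - geom$Vbf) * geom$V0 / x[1]
    Ms_i <- x[2] / (geom$Vs_bar * x[1])
    c(-perm$Lp * geom$A * gasConstant("um3_atm") * bath$T *
        (bath$Me - Mn_i - Ms_i),
      perm$Ps * geom$A * (bath$Ms_e - Ms_i) * geom$Vs_bar)
  }
  n <- round(t_end / dt)
  x <- c((1 - geom$Vbf) * geom$V0, 0)
  out <- matrix(0, n + 1, 3)
  out[1, ] <- c(0, x)
  for (k in seq_len(n)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1); k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[k + 1, ] <- c(k * dt, x)
  }
  out
}

# strict biphasic check: one interior minimum, no interior maximum before it
expect_biphasic <- function(Vn, tol = 1e-10) {
  d <- diff(Vn)
  s <- sign(d[abs(d) > tol])
  runs <- rle(s)$values
  expect_identical(runs, c(-1, 1))
}

# barycentric shape-function gradients of one tet via a direct linear solve
# (independent of the package's cross-product construction)
baryGradients <- function(x) {
  # N(p) = A %*% c(1, p); rows of A from inverting [1 | x_i]
  Ainv <- solve(cbind(1, x))            # 4x4, column i -> coeffs of N_i
  t(Ainv)[, 2:4]                        # 4 x 3 gradients
}
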