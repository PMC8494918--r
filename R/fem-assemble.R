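## Element-level geometry for linear (4-node) tetrahedra: constant shape
## function gradients. Returns a list with per-element volumes (m-vector)
## and gradients (m x 4 x 3 array).
.tetGradients <- function(mesh) {
  nodes <- mesh$nodes
  tets <- mesh$tets
  m <- nrow(tets)
  vol <- tetVolumes(mesh)
  grads <- array(0, c(m, 4, 3))
  x <- array(0, c(m, 4, 3))
  for (j in 1:4) x[, j, ] <- nodes[tets[, j], ]
  ## grad N_i is constant; obtained from the inverse Jacobian. For node i,
  ## grad N_i = (opposite-face normal) * area / (3 V) with inward sign;
  ## computed via cross products of the edge vectors.
  for (i in 1:4) {
    oth <- setdiff(1:4, i)
    a <- matrix(x[, oth[1], ], m, 3); b <- matrix(x[, oth[2], ], m, 3)
    c <- matrix(x[, oth[3], ], m, 3)
    u <- b - a; v <- c - a
    n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])  # 2*area * unit normal
    ## orient towards node i (inward normal of the opposite face)
    d <- matrix(x[, i, ], m, 3) - a
    s <- sign(rowSums(n * d))
    n <- n * s
    grads[, i, ] <- n / (6 * vol)
  }
  list(vol = vol, grads = grads)
}

#' Assemble the transient-diffusion FEM system
#'
#' Consistent damping (mass) and conductivity matrices for linear
#' tetrahedra with isotropic diffusivity. The conductivity matrix is
#' symmetric positive semi-definite with the constant field in its null
#' space (a uniform concentration drives no flux); the damping matrix is
#' symmetric positive definite and its entries sum to the mesh volume.
#'
#' @param mesh a `tetMesh`
#' @param mat a [materialModel()] (only `D_s` is used)
#' @return list with sparse matrices `damping` (n x n) and `conductivity`
#'   (n x n), in mm^3 and mm^3 s^-1 units respectively
#' @export
assembleDiffusionSystem <- function(mesh, mat) {
  g <- .tetGradients(mesh)
  if (any(g$vol <= 0))
    stop("assembleDiffusionSystem: inverted element, tet ", which(g$vol <= 0)[1])
  m <- nrow(mesh$tets)
  n <- nrow(mesh$nodes)
  ii <- jj <- kk <- cc <- numeric(16 * m)
  idx <- 0
  for (a in 1:4) for (b in 1:4) {
    sl <- idx + seq_len(m)
    ii[sl] <- mesh$tets[, a]
    jj[sl] <- mesh$tets[, b]
    ## consistent mass: V/10 diagonal, V/20 off-diagonal
    cc[sl] <- g$vol * (if (a == b) 1 / 10 else 1 / 20)
    kk[sl] <- mat$D_s * g$vol *
      rowSums(matrix(g$grads[, a, ], m, 3) * matrix(g$grads[, b, ], m, 3))
    idx <- idx + m
  }
  list(damping = Matrix::sparseMatrix(i = ii, j = jj, x = cc, dims = c(n, n)),
       conductivity = Matrix::sparseMatrix(i = ii, j = jj, x = kk, dims = c(n, n)))
}

## 6x6 isotropic elasticity matrix (Voigt, engineering shear strains), kPa
.elasticityD <- function(mat) {
  E <- mat$E; nu <- mat$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

## B matrix (6 x 12) of one tet from its 4 shape gradients (4 x 3)
.bMatrix <- function(gr) {
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    cix <- 3 * (i - 1) + 1:3
    B[1, cix[1]] <- gr[i, 1]
    B[2, cix[2]] <- gr[i, 2]
    B[3, cix[3]] <- gr[i, 3]
    B[4, cix[1]] <- gr[i, 2]; B[4, cix[2]] <- gr[i, 1]   # xy
    B[5, cix[2]] <- gr[i, 3]; B[5, cix[3]] <- gr[i, 2]   # yz
    B[6, cix[1]] <- gr[i, 3]; B[6, cix[3]] <- gr[i, 1]   # xz
  }
  B
}

#' Assemble the linear-elasticity stiffness matrix
#'
#' Isotropic linear elasticity on 4-node tetrahedra (constant-strain
#' elements, exact one-point integration). Before boundary constraints the
#' matrix is symmetric with a six-dimensional rigid-body null space.
#' Degrees of freedom are ordered `(u_x1, u_y1, u_z1, u_x2, ...)`.
#'
#' @param mesh a `tetMesh`
#' @param mat a [materialModel()]
#' @return sparse symmetric stiffness matrix (3n x 3n, kPa mm)
#' @export
assembleElasticitySystem <- function(mesh, mat) {
  g <- .tetGradients(mesh)
  if (any(g$vol <= 0))
    stop("assembleElasticitySystem: inverted element, tet ", which(g$vol <= 0)[1])
  Dm <- .elasticityD(mat)
  m <- nrow(mesh$tets)
  ii <- jj <- vv <- numeric(144 * m)
  idx <- 0
  for (e in seq_len(m)) {
    B <- .bMatrix(g$grads[e, , ])
    Ke <- g$vol[e] * crossprod(B, Dm %*% B)
    dof <- as.vector(t(cbind(3 * mesh$tets[e, ] - 2, 3 * mesh$tets[e, ] - 1,
                             3 * mesh$tets[e, ])))
    sl <- idx + seq_len(144)
    ii[sl] <- rep(dof, times = 12)
    jj[sl] <- rep(dof, each = 12)
    vv[sl] <- as.vector(Ke)
    idx <- idx + 144
  }
  n3 <- 3 * nrow(mesh$nodes)
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n3, n3))
}

#' Equivalent nodal forces of the diffusion eigenstrain
#'
#' Element-wise \eqn{\int B^T [E] \epsilon^{di}(C) dV} with the
#' concentration interpolated at the element centroid (one-point
#' quadrature, exact for constant-strain tets). For a uniform concentration
#' the eigenstrain is self-equilibrated: the total force resultant is zero.
#'
#' @param mesh a `tetMesh`
#' @param C_field nodal concentrations (mol L^-1), length n
#' @param mat a [materialModel()]
#' @param C_strain_ref strain reference concentration, see
#'   [diffusionStrain()]
#' @return numeric force vector of length 3n (kPa mm^2)
#' @export
eigenstrainLoadVector <- function(mesh, C_field, mat, C_strain_ref = 0) {
  .eigenForce(.tetGradients(mesh), mesh, C_field, mat, C_strain_ref)
}

## worker with precomputed element geometry `g` (see .tetGradients); the
## initial stress of an isotropic eigenstrain e is sigma0 = 3K e on the
## normal components (3K = row sum of the normal block of [E]), and
## B^T sigma0 integrates to V * 3K * e * grad N_i at node i.
.eigenForce <- function(g, mesh, C_field, mat, C_strain_ref = 0) {
  trD <- sum(.elasticityD(mat)[1, 1:3])
  Cc <- rowMeans(matrix(C_field[mesh$tets], ncol = 4))
  e <- diffusionStrain(pmax(Cc, 0), mat, C_strain_ref)
  coef <- g$vol * trD * e
  f <- numeric(3 * nrow(mesh$nodes))
  for (i in 1:4) {
    nd <- mesh$tets[, i]
    for (d in 1:3) {
      tab <- rowsum(coef * g$grads[, i, d], 3 * (nd - 1) + d)
      at <- as.integer(rownames(tab))
      f[at] <- f[at] + tab[, 1]
    }
  }
  f
}
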