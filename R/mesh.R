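#' Boundary specification for the capillary-held sphere
#'
#' The oocyte is held by a micro-capillary over a spherical cap around the
#' +z pole; displacement is pinned and solute flux is zero there. The rest
#' of the surface is exposed to the bath (Dirichlet concentration). A
#' non-uniform exposure can be modelled by scaling the prescribed boundary
#' concentration over a second cap on the opposite (-z) side.
#'
#' @param capillary_half_angle polar half-angle of the held patch (degrees),
#'   in (0, 90); default 20
#' @param exposed_conc_factor multiplier of the reference concentration on
#'   exposed boundary nodes, in `[0, 1]`; default 1 (uniform)
#' @param asym_half_angle if > 0, boundary nodes whose polar angle measured
#'   from the -z pole is below this half-angle (degrees) get
#'   `asym_conc_factor` instead, producing a non-symmetric exposure
#' @param asym_conc_factor factor on the asymmetric cap, in `[0, 1]`
#' @return an object of class `boundarySpec`
#' @export
boundarySpec <- function(capillary_half_angle = 20, exposed_conc_factor = 1,
                         asym_half_angle = 0, asym_conc_factor = 0.5) {
  if (capillary_half_angle <= 0 || capillary_half_angle >= 90)
    stop("boundarySpec: capillary_half_angle must be in (0, 90) degrees")
  ok <- function(f) f >= 0 && f <= 1
  if (!ok(exposed_conc_factor) || !ok(asym_conc_factor))
    stop("boundarySpec: concentration factors must lie in [0, 1]")
  structure(list(capillary_half_angle = capillary_half_angle,
                 exposed_conc_factor = exposed_conc_factor,
                 asym_half_angle = asym_half_angle,
                 asym_conc_factor = asym_conc_factor),
            class = "boundarySpec")
}

## ---- icosphere surface ----------------------------------------------------

## unit icosahedron vertices / faces
.icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

## subdivide each triangle into 4, reprojecting midpoints onto the sphere
.subdivide <- function(v, f) {
  key <- function(a, b) paste(min(a, b), max(a, b))
  mid <- new.env(hash = TRUE)
  verts <- v
  midpoint <- function(a, b) {
    k <- key(a, b)
    id <- mid[[k]]
    if (!is.null(id)) return(id)
    p <- verts[a, ] + verts[b, ]
    p <- p / sqrt(sum(p^2))
    verts <<- rbind(verts, p)
    id <- nrow(verts)
    mid[[k]] <- id
    id
  }
  nf <- matrix(0L, 4 * nrow(f), 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    nf[4 * i - 3, ] <- c(a, ab, ca)
    nf[4 * i - 2, ] <- c(b, bc, ab)
    nf[4 * i - 1, ] <- c(c, ca, bc)
    nf[4 * i, ]     <- c(ab, bc, ca)
  }
  list(v = verts, f = nf)
}

.icosphereSurface <- function(subdivisions) {
  s <- .icosahedron()
  for (i in seq_len(subdivisions)) s <- .subdivide(s$v, s$f)
  s
}

## ---- prism -> tets (consistent Dompierre-style splitting) -----------------

## split prism (b1 b2 b3 | t1 t2 t3), ti radially above bi, into 3 tets so
## that shared quad faces between neighbouring prisms get the same diagonal
## (the diagonal through the smallest global node index on the quad).
.splitPrism <- function(p) {
  imin <- which.min(p)
  if (imin > 3) {                      # flip so the smallest index is on the bottom
    p <- p[c(4, 5, 6, 1, 2, 3)]
    imin <- imin - 3L
  }
  rot <- switch(imin, c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  p <- p[c(rot, rot + 3L)]
  if (min(p[2], p[6]) < min(p[3], p[5])) {
    rbind(p[c(1, 2, 3, 6)], p[c(1, 2, 6, 5)], p[c(1, 5, 6, 4)])
  } else {
    rbind(p[c(1, 2, 3, 5)], p[c(1, 5, 3, 6)], p[c(1, 5, 6, 4)])
  }
}

## signed volumes (x6) of tets, vectorized
.tetVolume6 <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
    b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
    b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])
}

#' Tetrahedron volumes of a mesh
#'
#' @param mesh a `tetMesh`
#' @param nodes optional alternative node coordinates (e.g. deformed
#'   positions `mesh$nodes + u`)
#' @return numeric vector of (positive) element volumes, mm^3
#' @export
tetVolumes <- function(mesh, nodes = mesh$nodes) {
  .tetVolume6(nodes, mesh$tets) / 6
}

#' Build a layered-icosphere tetrahedral mesh of the capillary-held oocyte
#'
#' The surface is an icosphere (subdivided icosahedron); concentric copies
#' at radii `k/L * radius` plus a center node fill the interior. Each
#' triangular prism between consecutive layers is split into three
#' tetrahedra with a globally consistent diagonal rule, and the innermost
#' layer connects to the center node. Outer-surface triangles whose
#' centroid polar angle (from +z) is at most the capillary half-angle are
#' tagged `CAPILLARY`, the rest `EXPOSED`.
#'
#' @param radius sphere radius (mm); default the radius of a sphere with
#'   the isotonic oocyte volume, `(3 V0 / 4 pi)^(1/3)` ~ 0.0526 mm
#' @param subdivisions icosphere subdivision level (>= 1); level 3 gives
#'   642 surface nodes and a polyhedral volume within 2 per mille of the
#'   sphere
#' @param layers number of radial layers (>= 1)
#' @param bc a [boundarySpec()]
#' @return an object of class `tetMesh`: list with `nodes` (n x 3, mm),
#'   `tets` (m x 4 indices, positively oriented), `boundary_tris` (b x 3),
#'   `boundary_tag` (factor `CAPILLARY`/`EXPOSED`), `radius`, and
#'   `surface_nodes` (indices of outer-layer nodes)
#' @export
buildCapillarySphereMesh <- function(radius = (3 * 609469.49e-9 / (4 * pi))^(1 / 3),
                                     subdivisions = 3, layers = 8,
                                     bc = boundarySpec()) {
  if (radius <= 0) stop("buildCapillarySphereMesh: radius must be > 0")
  if (subdivisions < 1 || layers < 1)
    stop("buildCapillarySphereMesh: need subdivisions >= 1 and layers >= 1")
  surf <- .icosphereSurface(subdivisions)
  nsurf <- nrow(surf$v)
  ## node 1 = center; layer k occupies 1 + (k-1)*nsurf + (1:nsurf)
  nodes <- matrix(0, 1 + layers * nsurf, 3)
  for (k in seq_len(layers))
    nodes[1 + (k - 1) * nsurf + seq_len(nsurf), ] <- surf$v * (radius * k / layers)
  off <- function(k) 1L + (k - 1L) * nsurf

  ntri <- nrow(surf$f)
  tets <- matrix(0L, ntri + 3L * ntri * (layers - 1L), 4)
  tets[seq_len(ntri), ] <- cbind(1L, surf$f + off(1))
  if (layers > 1) {
    row <- ntri
    for (k in seq_len(layers - 1L)) {
      lo <- surf$f + off(k)
      hi <- surf$f + off(k + 1L)
      for (i in seq_len(ntri)) {
        tets[row + 1:3, ] <- .splitPrism(c(lo[i, ], hi[i, ]))
        row <- row + 3L
      }
    }
  }
  ## enforce positive orientation
  v6 <- .tetVolume6(nodes, tets)
  flip <- v6 < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  if (any(.tetVolume6(nodes, tets) <= 0))
    stop("buildCapillarySphereMesh: degenerate (zero-volume) tetrahedron produced")

  btris <- surf$f + off(layers)
  cent <- (nodes[btris[, 1], ] + nodes[btris[, 2], ] + nodes[btris[, 3], ]) / 3
  polar <- acos(pmin(1, pmax(-1, cent[, 3] / sqrt(rowSums(cent^2))))) * 180 / pi
  tag <- factor(ifelse(polar <= bc$capillary_half_angle, "CAPILLARY", "EXPOSED"),
                levels = c("CAPILLARY", "EXPOSED"))
  structure(list(nodes = nodes, tets = tets, boundary_tris = btris,
                 boundary_tag = tag, radius = radius,
                 surface_nodes = off(layers) + seq_len(nsurf),
                 bc = bc),
            class = "tetMesh")
}

#' @export
print.tetMesh <- function(x, ...) {
  cat(sprintf("<tetMesh> %d nodes, %d tets, %d boundary triangles (%d CAPILLARY)\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$boundary_tris),
              sum(x$boundary_tag == "CAPILLARY")))
  cat(sprintf("  radius %.4g mm; total volume %.4g mm^3 (sphere: %.4g)\n",
              x$radius, sum(tetVolumes(x)), 4 / 3 * pi * x$radius^3))
  invisible(x)
}

#' Boundary node indices of a mesh by region
#'
#' @param mesh a `tetMesh`
#' @param tag `"CAPILLARY"` or `"EXPOSED"`; a node touching triangles of
#'   both regions counts as `CAPILLARY` (the pinned/no-flux condition wins
#'   on the rim)
#' @return integer node indices
#' @export
boundaryNodes <- function(mesh, tag = c("EXPOSED", "CAPILLARY")) {
  tag <- match.arg(tag)
  cap <- unique(as.vector(mesh$boundary_tris[mesh$boundary_tag == "CAPILLARY", ]))
  if (tag == "CAPILLARY") return(sort(cap))
  exp_ <- unique(as.vector(mesh$boundary_tris[mesh$boundary_tag == "EXPOSED", ]))
  sort(setdiff(exp_, cap))
}
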